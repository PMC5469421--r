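#' Probe depth-response model
#'
#' Each detection fiber collects signal from a characteristic depth range in
#' tissue. The cumulative fraction of a channel's saturated signal collected
#' from depths up to `z` is modelled as a saturating exponential
#' \deqn{W_c(z) = 1 - \exp(-z / z_{0,c}),}
#' so `W_c(0) = 0` and `W_c` rises monotonically to 1. The scale `z0_um` is
#' parameterized through the depth at which a channel reaches 90% of its
#' saturated signal (`z0 = depth90 / ln 10`). Default 90% depths are 750, 900
#' and 1100 um for the parallel fibers BF1--BF3 and 1200, 1250 and 1400 um for
#' the perpendicular fibers: perpendicular channels probe deeper because
#' linearly polarized light gradually depolarizes with depth.
#'
#' The probe table also carries the per-channel power throughput `P`
#' (dimensionless relative collection efficiency) and collection area `A`
#' (relative area at the tissue interface; fibers farther from the illumination
#' fiber collect from larger areas). Both enter the preprocessing
#' normalization.
#'
#' @param depth90_um Named numeric vector of 90%-saturation depths (um), one
#'   per channel.
#' @param P Named numeric vector of power throughputs (> 0).
#' @param A Named numeric vector of collection areas (> 0).
#'
#' @return A tibble with columns `channel`, `z0_um`, `depth90_um`, `P`, `A`.
#' @examples
#' default_probe()
#' @export
default_probe <- function(depth90_um = c(
                            BF1 = 750, BF2 = 900, BF3 = 1100,
                            BF1per = 1200, BF2per = 1250, BF3per = 1400
                          ),
                          P = c(
                            BF1 = 1.00, BF2 = 0.95, BF3 = 0.90,
                            BF1per = 0.98, BF2per = 0.93, BF3per = 0.88
                          ),
                          A = c(
                            BF1 = 1.0, BF2 = 1.3, BF3 = 1.6,
                            BF1per = 1.0, BF2per = 1.3, BF3per = 1.6
                          )) {
  chs <- channel_names()
  for (v in list(depth90_um, P, A)) {
    if (!all(chs %in% names(v))) {
      abort("probe parameter vectors must be named for all six channels")
    }
  }
  if (any(depth90_um <= 0) || any(P <= 0) || any(A <= 0)) {
    abort("probe parameters must be positive")
  }
  d90 <- unname(depth90_um[chs])
  probe <- tibble(
    channel = chs,
    depth90_um = d90,
    z0_um = d90 / log(10),
    P = unname(P[chs]),
    A = unname(A[chs])
  )
  validate_probe(probe)
  probe
}

validate_probe <- function(probe) {
  needed <- c("channel", "z0_um", "P", "A")
  if (!all(needed %in% names(probe))) {
    abort("probe must have columns channel, z0_um, P, A")
  }
  if (!setequal(probe$channel, channel_names())) {
    abort("probe must describe exactly the six detection channels")
  }
  z0 <- setNames(probe$z0_um, probe$channel)
  par <- parallel_channels()
  if (is.unsorted(z0[par], strictly = TRUE) ||
    is.unsorted(z0[perpendicular_channels()], strictly = TRUE)) {
    abort("z0 must increase with source-detector separation within each polarization")
  }
  if (any(z0[paired_channel(par)] <= z0[par])) {
    abort("perpendicular z0 must exceed the paired parallel z0")
  }
  invisible(probe)
}

probe_param <- function(probe, channel, what) {
  i <- match(channel, probe$channel)
  if (anyNA(i)) abort(paste0("channel absent from probe model: ",
                             paste(channel[is.na(i)], collapse = ", ")))
  probe[[what]][i]
}

#' Cumulative depth response of a channel
#'
#' Fraction of a channel's saturated signal originating above depth `z_um`.
#'
#' @param z_um Depth(s) in um.
#' @param probe Probe table from [default_probe()].
#' @param channel Channel name.
#' @return Numeric vector in `[0, 1)`.
#' @export
depth_response <- function(z_um, probe, channel) {
  z0 <- probe_param(probe, channel, "z0_um")
  1 - exp(-z_um / z0)
}
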