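#' Simulate a phantom depth-response series
#'
#' Emulates the scattering-phantom experiment in which the probe is backed
#' away from a transparent spacer in 50-um steps up to 2500 um while recording
#' the integrated intensity collected by each channel: the recorded curve is
#' the channel's cumulative depth response scaled by its gain (P x A), rising
#' from 0 and saturating at the channel plateau.
#'
#' @param probe Probe table from [default_probe()].
#' @param thickness_um Ascending thickness grid in um within `[0, 2500]`.
#' @return A tibble with `thickness_um` plus one intensity column per channel.
#' @examples
#' curves <- simulate_phantom_series()
#' saturation_depths(curves)
#' @export
simulate_phantom_series <- function(probe = default_probe(),
                                    thickness_um = seq(0, 2500, by = 50)) {
  if (length(thickness_um) == 0) abort("thickness grid must not be empty")
  if (is.unsorted(thickness_um, strictly = TRUE)) {
    abort("thickness grid must be strictly ascending")
  }
  if (min(thickness_um) < 0 || max(thickness_um) > 2500) {
    abort("thickness grid must lie within [0, 2500] um")
  }
  validate_probe(probe)
  out <- tibble(thickness_um = thickness_um)
  for (ch in channel_names()) {
    gain <- probe_param(probe, ch, "P") * probe_param(probe, ch, "A")
    out[[ch]] <- gain * depth_response(thickness_um, probe, ch)
  }
  out
}
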