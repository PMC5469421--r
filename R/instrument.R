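#' Simulate a session calibration set
#'
#' One calibration is acquired per measurement session (per patient): a white
#' diffuse-reflectance standard spectrum and a dark (minimally reflecting
#' substrate) spectrum per channel. The white spectrum follows a smooth
#' lamp-like shape; perpendicular channels see a dimmer white standard because
#' the standard is not a perfect depolarizer, which is exactly what the
#' depolarization coefficient D corrects for downstream.
#'
#' @param session_id Calibration identifier.
#' @param grid Wavelength grid.
#' @param lamp_gain Overall lamp counts scale.
#' @param depol Fraction of the parallel white signal seen by perpendicular
#'   channels (< 1 for an imperfect depolarizer; implies D = 1/depol).
#' @param dark_level Flat dark counts.
#' @param jitter_sd Lognormal sd of a per-session lamp intensity jitter
#'   (0 = deterministic).
#' @return A tibble with columns `calibration_id`, `role` ("white"/"dark"),
#'   `wavelength_nm` and the six channel columns, in counts.
#' @export
simulate_calibration <- function(session_id, grid = wavelength_grid(),
                                 lamp_gain = 40000, depol = 0.85,
                                 dark_level = 120, jitter_sd = 0.05) {
  jit <- if (jitter_sd > 0) rlnorm(1, 0, jitter_sd) else 1
  lamp <- lamp_gain * jit * exp(-((grid - 640) / 260)^2)
  white <- tibble(
    calibration_id = session_id, role = "white", wavelength_nm = grid
  )
  dark <- tibble(
    calibration_id = session_id, role = "dark", wavelength_nm = grid
  )
  for (ch in channel_names()) {
    pol <- if (ch %in% perpendicular_channels()) depol else 1
    white[[ch]] <- dark_level + lamp * pol
    dark[[ch]] <- rep(dark_level, length(grid))
  }
  bind_rows(white, dark)
}

calibration_mats <- function(calibration, grid) {
  white <- filter(calibration, .data$role == "white") %>% arrange(.data$wavelength_nm)
  dark <- filter(calibration, .data$role == "dark") %>% arrange(.data$wavelength_nm)
  if (!isTRUE(all.equal(white$wavelength_nm, grid))) {
    abort("calibration grid does not match the measurement grid")
  }
  list(white = white, dark = dark)
}

#' Wrap true spectra into a raw instrument measurement
#'
#' Algebraic inverse of the preprocessing normalization: given noiseless
#' normalized channel spectra, produce the raw counts a detector would have
#' recorded under a given calibration, integration time, throughput and
#' collection area, such that [normalize_measurement()] with the same
#' calibration recovers the input exactly when `noise_sd = 0`. Perpendicular
#' channels include the depolarization coefficient implied by the
#' calibration. Noise is multiplicative Gaussian on the dark-subtracted
#' signal.
#'
#' @param true_spectra Tibble from [forward_true_spectra()].
#' @param calibration Calibration tibble (one session) from
#'   [simulate_calibration()].
#' @param probe Probe table (supplies P and A per channel).
#' @param t_seconds Integration time in seconds.
#' @param noise_sd Relative noise level (>= 0).
#' @return A tibble `wavelength_nm` + six channels of nonnegative raw counts.
#' @export
wrap_instrument <- function(true_spectra, calibration, probe, t_seconds = 1,
                            noise_sd = 0) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (t_seconds <= 0) abort("t_seconds must be positive")
  grid <- true_spectra$wavelength_nm
  cal <- calibration_mats(calibration, grid)
  out <- tibble(wavelength_nm = grid)
  for (ch in channel_names()) {
    p <- probe_param(probe, ch, "P")
    a <- probe_param(probe, ch, "A")
    white_net <- cal$white[[ch]] - cal$dark[[ch]]
    denom <- white_net
    if (ch %in% perpendicular_channels()) {
      par_ch <- paired_channel(ch)
      d <- (cal$white[[par_ch]] - cal$dark[[par_ch]]) /
        (cal$white[[ch]] - cal$dark[[ch]])
      denom <- white_net * d
    }
    signal <- true_spectra[[ch]] * t_seconds * p * a * denom
    if (noise_sd > 0) {
      signal <- signal * (1 + rnorm(length(signal), 0, noise_sd))
    }
    out[[ch]] <- pmax(cal$dark[[ch]] + signal, 0)
  }
  out
}
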