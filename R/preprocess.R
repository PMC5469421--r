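#' Depolarization coefficient
#'
#' The diffuse reflectance standard used for the white calibration is not a
#' perfect depolarizer, so the perpendicular white signal under-represents the
#' true throughput. The correction is the ratio of the dark-subtracted
#' parallel to perpendicular white spectra,
#' \deqn{D = (I_{white,\parallel} - I_{dark,\parallel}) /
#'           (I_{white,\perp} - I_{dark,\perp}).}
#' By default D is computed per wavelength (the correction is written
#' spectrally); `spectral = FALSE` returns the single scalar ratio of the
#' integrated intensities instead.
#'
#' @param white_par,dark_par,white_perp,dark_perp Calibration spectra
#'   (counts) on a common grid.
#' @param spectral Per-wavelength D (default) or a single integrated ratio.
#' @param wavelength_nm Grid, required only for `spectral = FALSE`.
#' @return Numeric vector (length of the grid) or scalar; always > 0.
#' @export
depolarization_coefficient <- function(white_par, dark_par, white_perp,
                                       dark_perp, spectral = TRUE,
                                       wavelength_nm = NULL) {
  num <- white_par - dark_par
  den <- white_perp - dark_perp
  if (any(den <= 0) || any(num <= 0)) {
    abort("white spectra must exceed dark spectra at every wavelength")
  }
  if (spectral) {
    num / den
  } else {
    if (is.null(wavelength_nm)) abort("scalar D needs the wavelength grid")
    pracma::trapz(wavelength_nm, num) / pracma::trapz(wavelength_nm, den)
  }
}

normalize_one <- function(raw, cal, probe, t_seconds, spectral_d = TRUE,
                          grid) {
  out <- tibble(wavelength_nm = grid)
  for (ch in channel_names()) {
    p <- probe_param(probe, ch, "P")
    a <- probe_param(probe, ch, "A")
    if (p <= 0 || a <= 0 || t_seconds <= 0) {
      abort("t, P and A must all be positive")
    }
    white_net <- cal$white[[ch]] - cal$dark[[ch]]
    denom <- white_net
    if (ch %in% perpendicular_channels()) {
      par_ch <- paired_channel(ch)
      d <- depolarization_coefficient(
        cal$white[[par_ch]], cal$dark[[par_ch]],
        cal$white[[ch]], cal$dark[[ch]],
        spectral = spectral_d, wavelength_nm = grid
      )
      denom <- white_net * d
    }
    out[[ch]] <- (raw[[ch]] - cal$dark[[ch]]) / denom / (t_seconds * p * a)
  }
  out
}

#' Normalize raw spectra against their session calibration
#'
#' Converts raw counts into comparable dimensionless reflectance:
#' \deqn{I_\parallel = \frac{I_{meas,\parallel} - I_{dark,\parallel}}
#'       {I_{white,\parallel} - I_{dark,\parallel}}
#'       \cdot \frac{1}{t} \cdot \frac{1}{P_\parallel} \cdot \frac{1}{A},}
#' with the perpendicular denominator additionally multiplied by the
#' depolarization coefficient D. Values that come out slightly negative due
#' to noise are retained (clipping would bias downstream means); a warning is
#' issued if more than 1% of points are negative.
#'
#' @param spectra Raw spectra tibble (`measurement_id`, `wavelength_nm`, six
#'   channels).
#' @param manifest Manifest tibble with `measurement_id`, `t_seconds`,
#'   `calibration_id`.
#' @param calibrations Calibration tibble covering every `calibration_id`.
#' @param probe Probe table (P and A per channel).
#' @param spectral_d Use per-wavelength D (default) or the integrated scalar.
#' @return A tibble shaped like `spectra` with normalized reflectance values.
#' @export
normalize_cohort <- function(spectra, manifest, calibrations, probe,
                             spectral_d = TRUE) {
  check_spectra_frame(spectra)
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    raw <- filter(spectra, .data$measurement_id == row$measurement_id) %>%
      arrange(.data$wavelength_nm)
    if (nrow(raw) == 0) {
      abort(paste0("no spectra for measurement ", row$measurement_id))
    }
    grid <- raw$wavelength_nm
    cal <- calibration_mats(
      filter(calibrations, .data$calibration_id == row$calibration_id), grid
    )
    norm <- normalize_one(raw, cal, probe, row$t_seconds,
      spectral_d = spectral_d, grid = grid
    )
    norm$measurement_id <- row$measurement_id
    out[[i]] <- norm
  }
  res <- select(
    bind_rows(out), "measurement_id", "wavelength_nm",
    dplyr::all_of(channel_names())
  )
  vals <- as.matrix(res[channel_names()])
  frac_neg <- mean(vals < 0)
  if (frac_neg > 0.01) {
    warn(sprintf(
      "%.1f%% of normalized reflectance values are negative", 100 * frac_neg
    ))
  }
  res
}
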