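#' Oxyhemoglobin extinction shape
#'
#' Parametric approximation of the visible oxyhemoglobin extinction spectrum
#' as two Gaussian bands at the beta (542 nm) and alpha (576 nm) absorption
#' peaks, width ~12 nm. Amplitudes are relative (the alpha band slightly
#' weaker); the absolute absorption strength is carried by the tissue-class
#' `hemoglobin` parameter.
#'
#' @param wavelength_nm Wavelengths in nm.
#' @return Dimensionless extinction shape, peak value 1 at 542 nm.
#' @export
hemoglobin_extinction <- function(wavelength_nm) {
  exp(-(wavelength_nm - 542)^2 / (2 * 12^2)) +
    0.85 * exp(-(wavelength_nm - 576)^2 / (2 * 12^2))
}

layer_spectrum <- function(wavelength_nm, amp, slope) {
  amp * (wavelength_nm / 600)^(-slope)
}

#' Forward model: noiseless normalized channel spectra
#'
#' Computes the six detection-channel spectra of a tissue instance as a
#' depth-weighted mixture of three layer spectra: keratin (strong scattering
#' with a steep blue slope), viable epithelium (milder power-law scattering),
#' and stroma filtered by oxyhemoglobin absorption. The layer weights come
#' from the channel's cumulative depth response `W_c`:
#' \deqn{I_c = W_c(z_{ker}) S_{ker} + [W_c(z_{tot}) - W_c(z_{ker})] S_{epi} +
#'       [1 - W_c(z_{tot})] S_{str} H,}
#' with `H = exp(-c_Hb * eps(lambda))`. Perpendicular channels use their
#' deeper depth scale, so their stromal weight exceeds that of the paired
#' parallel channel.
#'
#' @param instance One-row tibble from [sample_tissue_instances()].
#' @param probe Probe table from [default_probe()].
#' @param grid Wavelength grid from [wavelength_grid()].
#' @param apply_patient_scale Multiply the spectra by the instance's
#'   per-patient scale factor (default `TRUE`).
#' @return A tibble with `wavelength_nm` and the six channel columns
#'   (dimensionless reflectance).
#' @export
forward_true_spectra <- function(instance, probe, grid = wavelength_grid(),
                                 apply_patient_scale = TRUE) {
  if (nrow(instance) != 1) abort("instance must be a single row")
  if (instance$total_um < 0 || instance$total_um > 2500 ||
    instance$keratin_um < 0) {
    abort("thicknesses must lie within [0, 2500] um")
  }
  validate_probe(probe)
  s_ker <- layer_spectrum(grid, instance$keratin_amp, instance$keratin_slope)
  s_epi <- layer_spectrum(grid, instance$epithelium_amp, 1.0)
  s_str <- layer_spectrum(grid, 1.0, 1.0) *
    exp(-instance$hemoglobin * hemoglobin_extinction(grid))
  scale <- if (apply_patient_scale) instance$patient_scale else 1
  out <- tibble(wavelength_nm = grid)
  for (ch in channel_names()) {
    w_ker <- depth_response(instance$keratin_um, probe, ch)
    w_tot <- depth_response(instance$total_um, probe, ch)
    out[[ch]] <- scale * (w_ker * s_ker + (w_tot - w_ker) * s_epi +
      (1 - w_tot) * s_str)
  }
  out
}
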