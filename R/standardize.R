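#' Per-patient standardization factors
#'
#' Interpatient differences in overall reflectance magnitude (anatomy, probe
#' coupling) are removed by scaling each patient's spectra so that their
#' normal-site intensity matches the cohort average: the factor is
#' \deqn{S_i = N_{mean} / N_i,} where `N_i` is the integrated intensity
#' (trapezoid over the grid) of the patient's averaged normal spectrum and
#' `N_mean` the integrated intensity of the grand average over all normal
#' spectra. By default the integrated intensities of all six channels are
#' summed; `channels` restricts the definition (the same definition is used
#' for `N_i` and `N_mean` by construction).
#'
#' @param spectra Normalized spectra tibble.
#' @param manifest Manifest with `measurement_id`, `patient_id`, `class`.
#' @param channels Channels whose integrated intensities define N.
#' @return A tibble `patient_id`, `n_normal`, `N_i`, `N_mean`, `S_i` with one
#'   row per patient; `S_i * N_i == N_mean` exactly.
#' @export
patient_factors <- function(spectra, manifest, channels = channel_names()) {
  check_spectra_frame(spectra)
  stopifnot(all(channels %in% channel_names()))
  norm_ids <- manifest$measurement_id[manifest$class == "normal"]
  no_normal <- setdiff(manifest$patient_id,
                       manifest$patient_id[manifest$class == "normal"])
  if (length(no_normal) > 0) {
    abort(paste0(
      "patient(s) without a normal measurement: ",
      paste(sort(unique(no_normal)), collapse = ", ")
    ))
  }
  normals <- filter(spectra, .data$measurement_id %in% norm_ids) %>%
    left_join(select(manifest, "measurement_id", "patient_id"),
      by = "measurement_id"
    )
  integrate_mean_spectrum <- function(df) {
    # average spectra first, then integrate; sum the chosen channels
    avg <- df %>%
      group_by(.data$wavelength_nm) %>%
      summarise(dplyr::across(dplyr::all_of(channels), mean), .groups = "drop")
    sum(vapply(
      channels,
      function(ch) pracma::trapz(avg$wavelength_nm, avg[[ch]]),
      numeric(1)
    ))
  }
  n_mean <- integrate_mean_spectrum(normals)
  per_patient <- normals %>%
    group_by(.data$patient_id) %>%
    dplyr::group_modify(~ tibble(
      n_normal = length(unique(.x$measurement_id)),
      N_i = integrate_mean_spectrum(.x)
    )) %>%
    ungroup()
  mutate(per_patient, N_mean = n_mean, S_i = n_mean / .data$N_i)
}

#' Apply standardization factors
#'
#' Multiplies every channel of every measurement by its patient's factor
#' `S_i` (`M_i' = S_i * M_i`); spectral shape is preserved exactly. After
#' standardization every patient's integrated normal intensity equals
#' `N_mean`.
#'
#' @param spectra Normalized spectra tibble.
#' @param manifest Manifest with `measurement_id`, `patient_id`.
#' @param factors Output of [patient_factors()].
#' @param missing How to treat measurements whose patient has no factor:
#'   `"error"` (default) or `"one"` (leave unscaled with a warning).
#' @return Standardized spectra tibble, same shape as the input.
#' @export
apply_standardization <- function(spectra, manifest, factors,
                                  missing = c("error", "one")) {
  missing <- match.arg(missing)
  check_spectra_frame(spectra)
  si <- setNames(factors$S_i, factors$patient_id)
  pat <- setNames(manifest$patient_id, manifest$measurement_id)
  meas_pat <- pat[spectra$measurement_id]
  if (anyNA(meas_pat)) abort("spectra contain measurements absent from the manifest")
  s <- unname(si[meas_pat])
  if (anyNA(s)) {
    bad <- sort(unique(meas_pat[is.na(s)]))
    if (missing == "error") {
      abort(paste0(
        "no standardization factor for patient(s): ", paste(bad, collapse = ", ")
      ))
    }
    warn(paste0(
      "no factor for patient(s) ", paste(bad, collapse = ", "),
      "; leaving S_i = 1"
    ))
    s[is.na(s)] <- 1
  }
  out <- spectra
  for (ch in channel_names()) out[[ch]] <- out[[ch]] * s
  out
}
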