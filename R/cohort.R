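#' Cohort configuration
#'
#' Per-(anatomical site x diagnostic class) measurement counts plus the number
#' of patients. The default reproduces the study cohort: 93 measurements from
#' 25 patients with class totals normal 42, benign 17, MD 24, SD 10 spread
#' over five anatomical sites (buccal mucosa, floor of mouth, gingiva,
#' mandible, tongue).
#'
#' @param counts A tibble with columns `site`, `class`, `n`.
#' @param n_patients Number of patients; every patient receives at least one
#'   normal measurement, so `n_patients` must not exceed the normal count.
#' @return A list with elements `counts` and `n_patients`, class
#'   `oprs_cohort_config`.
#' @export
cohort_config <- function(counts = default_site_counts(), n_patients = 25) {
  stopifnot(all(c("site", "class", "n") %in% names(counts)))
  if (any(counts$n < 0)) abort("counts must be >= 0")
  if (n_patients < 1) abort("need at least one patient")
  n_normal <- sum(counts$n[counts$class == "normal"])
  if (n_normal < n_patients) {
    abort("not enough normal measurements to give every patient one")
  }
  structure(
    list(counts = as_tibble(counts), n_patients = as.integer(n_patients)),
    class = "oprs_cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_site_counts <- function() {
  tibble(
    site = rep(c("buccal", "floor", "gingiva", "mandible", "tongue"), each = 4),
    class = rep(c("normal", "benign", "MD", "SD"), times = 5),
    n = c(
      8, 3, 4, 0,
      2, 1, 0, 1,
      1, 2, 1, 0,
      0, 0, 1, 0,
      31, 11, 18, 9
    )
  )
}

# round-robin patient allocation: normals cycle through all patients first
# (so everyone gets >= 1, most get 2-3), abnormals cycle independently
allocate_patients <- function(classes, n_patients) {
  patient <- integer(length(classes))
  is_norm <- classes == "normal"
  patient[is_norm] <- rep_len(seq_len(n_patients), sum(is_norm))
  patient[!is_norm] <- rep_len(seq_len(n_patients), sum(!is_norm))
  patient
}

#' Simulate a full measurement cohort
#'
#' Generates a manifest, raw six-channel spectra and per-session calibrations
#' with the statistical structure the downstream analysis assumes:
#' class-dependent layered-tissue spectra, fiber-specific depth responses,
#' a shared per-patient intensity scale (which standardization must remove),
#' and per-patient calibration sessions.
#'
#' @param config From [cohort_config()].
#' @param class_params From [tissue_class_params()].
#' @param probe From [default_probe()].
#' @param grid Wavelength grid.
#' @param noise_sd Relative multiplicative measurement noise.
#' @param t_seconds Integration time applied to every measurement.
#' @param seed Integer root seed; the same seed reproduces the cohort exactly.
#' @return A list of class `oprs_cohort` with elements `manifest` (tibble:
#'   `measurement_id`, `patient_id`, `site`, `class`, `t_seconds`,
#'   `calibration_id`), `spectra` (raw counts, one row per measurement x
#'   wavelength), `calibrations`, `instances` (the underlying tissue truths),
#'   `probe`, `grid` and `seed`.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' dplyr::count(cohort$manifest, class)
#' @export
simulate_cohort <- function(config = cohort_config(),
                            class_params = tissue_class_params(),
                            probe = default_probe(),
                            grid = wavelength_grid(),
                            noise_sd = 0.02,
                            t_seconds = 1,
                            seed = 1) {
  withr::with_seed(seed, {
    counts <- filter(config$counts, .data$n > 0)
    meta <- tibble(
      site = rep(counts$site, counts$n),
      class = rep(counts$class, counts$n)
    ) %>%
      arrange(factor(.data$class, levels = c("normal", "benign", "MD", "SD")))
    n_meas <- nrow(meta)
    meta$measurement_id <- sprintf("m%03d", seq_len(n_meas))
    meta$patient_id <- sprintf(
      "p%02d", allocate_patients(meta$class, config$n_patients)
    )
    meta$t_seconds <- t_seconds
    meta$calibration_id <- sub("^p", "cal", meta$patient_id)

    patients <- sort(unique(meta$patient_id))
    patient_scale <- setNames(
      rlnorm(length(patients), 0, class_params$patient_log_sd[1]), patients
    )

    calibrations <- bind_rows(lapply(
      sort(unique(meta$calibration_id)),
      function(id) simulate_calibration(id, grid = grid)
    ))

    instances <- vector("list", n_meas)
    spectra <- vector("list", n_meas)
    for (i in seq_len(n_meas)) {
      row <- meta[i, ]
      inst <- sample_tissue_instances(
        filter(class_params, .data$class == row$class), 1
      )
      inst$patient_scale <- unname(patient_scale[row$patient_id])
      inst$measurement_id <- row$measurement_id
      true <- forward_true_spectra(inst, probe, grid)
      cal <- filter(calibrations, .data$calibration_id == row$calibration_id)
      raw <- wrap_instrument(true, cal, probe,
        t_seconds = row$t_seconds, noise_sd = noise_sd
      )
      raw$measurement_id <- row$measurement_id
      instances[[i]] <- inst
      spectra[[i]] <- raw
    }

    structure(
      list(
        manifest = select(
          meta, "measurement_id", "patient_id", "site", "class",
          "t_seconds", "calibration_id"
        ),
        spectra = select(
          bind_rows(spectra), "measurement_id", "wavelength_nm",
          dplyr::all_of(channel_names())
        ),
        calibrations = calibrations,
        instances = bind_rows(instances),
        probe = probe,
        grid = grid,
        seed = seed
      ),
      class = "oprs_cohort"
    )
  })
}

#' @export
print.oprs_cohort <- function(x, ...) {
  cat("OPRS synthetic cohort:", nrow(x$manifest), "measurements from",
      length(unique(x$manifest$patient_id)), "patients\n")
  print(dplyr::count(x$manifest, .data$class))
  invisible(x)
}
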