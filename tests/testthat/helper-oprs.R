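# shared fixtures, all generated in code

# a small cohort: 8 patients, 16 normal + 8 benign + 8 MD + 4 SD = 36 measurements
small_cohort <- function(seed = 42, noise_sd = 0.02, ...) {
  cfg <- cohort_config(
    counts = tibble::tibble(
      site = "tongue",
      class = c("normal", "benign", "MD", "SD"),
      n = c(16, 8, 8, 4)
    ),
    n_patients = 8
  )
  simulate_cohort(cfg, noise_sd = noise_sd, seed = seed, ...)
}

# class parameter table with no class differences at all (null data)
null_class_params <- function() {
  cp <- tissue_class_params()
  for (col in setdiff(names(cp), "class")) cp[[col]] <- rep(cp[[col]][1], 4)
  cp
}

# run preprocessing + standardization + channel building in one go
standardized_channels <- function(cohort) {
  norm <- normalize_cohort(
    cohort$spectra, cohort$manifest, cohort$calibrations, cohort$probe
  )
  fac <- patient_factors(norm, cohort$manifest)
  std <- apply_standardization(norm, cohort$manifest, fac)
  build_channels(std)
}

# flat six-channel spectra frame for hand-computable cases
flat_spectra <- function(values, grid = wavelength_grid(),
                         id = "m1") {
  df <- tibble::tibble(measurement_id = id, wavelength_nm = grid)
  for (ch in channel_names()) {
    df[[ch]] <- rep(values[[ch]], length(grid))
  }
  df
}

# flat calibration (white/dark constant per channel)
flat_calibration <- function(white, dark, grid = wavelength_grid(),
                             id = "cal1") {
  w <- tibble::tibble(calibration_id = id, role = "white", wavelength_nm = grid)
  d <- tibble::tibble(calibration_id = id, role = "dark", wavelength_nm = grid)
  for (ch in channel_names()) {
    w[[ch]] <- rep(white[[ch]], length(grid))
    d[[ch]] <- rep(dark[[ch]], length(grid))
  }
  dplyr::bind_rows(w, d)
}

# probe with unit P and A everywhere (depth response as in the default)
unit_probe <- function() {
  default_probe(
    P = stats::setNames(rep(1, 6), channel_names()),
    A = stats::setNames(rep(1, 6), channel_names())
  )
}

# independent brute-force AUC: pair counting with half-weight ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels == "pos"]
  neg <- scores[labels == "neg"]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# independent plug-in MI from a 2-way contingency table (nats)
brute_mi <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  s
}
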