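#' Area-normalize a spectrum
#'
#' Divides a spectrum by its trapezoid integral over the grid so the result
#' integrates to 1, emphasizing spectral shape over magnitude.
#'
#' @param y Spectrum values.
#' @param wavelength_nm Grid.
#' @return Unit-area spectrum.
#' @export
area_normalize <- function(y, wavelength_nm) {
  a <- pracma::trapz(wavelength_nm, y)
  if (!is.finite(a) || a <= 0) abort("spectrum area must be positive")
  y / a
}

#' Per-wavelength Welch t-statistic between two classes
#'
#' Contrasts patient-level spectra of two diagnostic classes at each
#' wavelength: the absolute difference of across-patient means relative to
#' the interpatient variation,
#' \deqn{t(\lambda) = |\bar x_A - \bar x_B| /
#'       \sqrt{s_A^2/n_A + s_B^2/n_B}.}
#' Rows of the inputs are patient-level units (each patient's mean spectrum
#' within the class).
#'
#' @param a,b Matrices (patients x wavelengths) for the two classes; at least
#'   two rows each.
#' @return Numeric vector of t values, one per wavelength (NA where either
#'   class has no finite data).
#' @export
welch_t_spectrum <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2) {
    abort("each class needs at least two patients")
  }
  col_stats <- function(m) {
    n <- colSums(is.finite(m))
    mu <- colMeans(m, na.rm = TRUE)
    v <- (colSums(m^2, na.rm = TRUE) - n * mu^2) / (n - 1)
    list(n = n, mu = mu, v = pmax(v, 0))
  }
  sa <- col_stats(a)
  sb <- col_stats(b)
  t <- abs(sa$mu - sb$mu) / sqrt(sa$v / sa$n + sb$v / sb$n)
  t[sa$n < 2 | sb$n < 2] <- NA_real_
  t
}

# patient-level mean spectra for measurements of one class, NA-aware
patient_mean_spectra <- function(mat, patient, idx) {
  m <- mat[idx, , drop = FALSE]
  g <- patient[idx]
  fin <- is.finite(m)
  m0 <- m
  m0[!fin] <- 0
  sums <- rowsum(m0, g)
  cnts <- rowsum(fin * 1, g)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Most discriminatory wavelength of a t-spectrum
#'
#' @param t_values Welch t values on the grid.
#' @param wavelength_nm Grid.
#' @return The wavelength maximizing t; ties break toward the shortest
#'   wavelength.
#' @export
discriminatory_wavelength <- function(t_values, wavelength_nm) {
  if (all(!is.finite(t_values))) abort("t-spectrum contains no finite values")
  t_values[!is.finite(t_values)] <- -Inf
  wavelength_nm[which.max(t_values)]
}

#' Discriminatory wavelengths for every combination channel
#'
#' For one binary task, computes the Welch t-spectrum (across patient-level
#' mean spectra of the two classes) for each of the 27 combination channels
#' in both variants, and selects the wavelength with the largest t.
#'
#' @param channels [build_channels()] object.
#' @param patient_id Patient of each measurement (aligned with
#'   `channels$measurement_id`).
#' @param labels Class of each measurement: `"neg"`/`"pos"` (non-task
#'   measurements must already be excluded via `subset`).
#' @param subset Optional logical/index vector restricting the measurements.
#' @return A tibble `combo`, `variant`, `lambda_star_nm`, `t_max` (54 rows).
#' @export
discriminatory_wavelengths <- function(channels, patient_id, labels,
                                       subset = NULL) {
  wl <- channels$wavelength_nm
  if (is.null(subset)) subset <- seq_along(channels$measurement_id)
  idx_pos <- subset[labels[subset] == "pos"]
  idx_neg <- subset[labels[subset] == "neg"]
  combos <- names(channels$mats$unnorm)
  n_out <- 2 * length(combos)
  combo_v <- character(n_out)
  variant_v <- character(n_out)
  lam_v <- numeric(n_out)
  tmax_v <- numeric(n_out)
  k <- 1
  for (variant in c("unnorm", "norm")) {
    for (combo in combos) {
      mat <- channels$mats[[variant]][[combo]]
      a <- patient_mean_spectra(mat, patient_id, idx_neg)
      b <- patient_mean_spectra(mat, patient_id, idx_pos)
      t <- welch_t_spectrum(a, b)
      combo_v[k] <- combo
      variant_v[k] <- variant
      lam_v[k] <- discriminatory_wavelength(t, wl)
      tmax_v[k] <- max(t[is.finite(t)])
      k <- k + 1
    }
  }
  tibble(
    combo = combo_v, variant = variant_v,
    lambda_star_nm = lam_v, t_max = tmax_v
  )
}

#' The 120-entry feature catalogue
#'
#' Per normalization variant (unnormalized, area-normalized): the spectral
#' mean of each of the 27 combination channels, the intensity at the task's
#' most discriminatory wavelength for each, and the 576/610 nm intensity
#' ratio (hemoglobin absorption magnitude) for the six fiber channels --
#' 60 features per variant, 120 in total.
#'
#' @return A tibble `feature`, `family`, `combo`, `statistic`, `variant`
#'   (120 rows, stable order).
#' @export
feature_catalogue <- function() {
  cached <- .oprs_cache$feature_catalogue
  if (!is.null(cached)) {
    return(cached)
  }
  cc <- channel_catalogue()
  one_variant <- function(variant) {
    suffix <- ifelse(variant == "norm", ".norm", "")
    bind_rows(
      tibble(
        feature = paste0("mean(", cc$combo, ")", suffix),
        family = cc$family, combo = cc$combo,
        statistic = "mean", variant = variant
      ),
      tibble(
        feature = paste0("I_dw(", cc$combo, ")", suffix),
        family = cc$family, combo = cc$combo,
        statistic = "intensity_at_dw", variant = variant
      ),
      tibble(
        feature = paste0("r576/610(", channel_names(), ")", suffix),
        family = ifelse(grepl("per$", channel_names()),
          "ratio576_610_perp", "ratio576_610_par"
        ),
        combo = channel_names(),
        statistic = "ratio576_610", variant = variant
      )
    )
  }
  out <- bind_rows(one_variant("unnorm"), one_variant("norm"))
  .oprs_cache$feature_catalogue <- out
  out
}

.oprs_cache <- new.env(parent = emptyenv())

#' Extract the 120-feature vectors
#'
#' Computes every catalogue feature for every measurement: spectral means
#' (plain average over the grid, masked wavelengths excluded), intensities at
#' the task's discriminatory wavelengths, and 576/610 ratios. The
#' label-independent features (means and ratios) are cached inside the
#' channels object, so repeated extraction with different discriminatory
#' wavelengths (per-fold policy, permutation shuffles) only re-reads the
#' intensity columns.
#'
#' @param channels [build_channels()] object.
#' @param lambda_report Output of [discriminatory_wavelengths()] for the task.
#' @return A tibble: `measurement_id` plus 120 named feature columns in
#'   catalogue order.
#' @export
extract_features <- function(channels, lambda_report) {
  wl <- channels$wavelength_nm
  cat120 <- feature_catalogue()
  i576 <- match(576, wl)
  i610 <- match(610, wl)
  if (is.na(i576) || is.na(i610)) abort("wavelengths 576 and 610 nm must be on the grid")
  static <- channels$cache$static
  if (is.null(static)) {
    static <- list()
    for (j in which(cat120$statistic != "intensity_at_dw")) {
      f <- cat120[j, ]
      mat <- channels$mats[[f$variant]][[f$combo]]
      static[[f$feature]] <- if (f$statistic == "mean") {
        unname(rowMeans(mat, na.rm = TRUE))
      } else {
        unname(mat[, i576] / mat[, i610])
      }
    }
    channels$cache$static <- static
  }
  lam_key <- paste(lambda_report$combo, lambda_report$variant)
  cols <- vector("list", nrow(cat120))
  names(cols) <- cat120$feature
  for (j in seq_len(nrow(cat120))) {
    feature <- cat120$feature[j]
    combo <- cat120$combo[j]
    variant <- cat120$variant[j]
    cols[[j]] <- if (cat120$statistic[j] == "intensity_at_dw") {
      lam <- lambda_report$lambda_star_nm[match(paste(combo, variant), lam_key)]
      if (is.na(lam)) abort(paste0("missing lambda* for ", combo, " ", variant))
      unname(channels$mats[[variant]][[combo]][, match(lam, wl)])
    } else {
      static[[feature]]
    }
  }
  bind_cols(
    tibble(measurement_id = channels$measurement_id),
    as_tibble(cols)
  )
}

#' Band frequency of discriminatory wavelengths
#'
#' Splits 450--750 nm into 20-nm bands (450--469, 470--489, ..., 710--729 and
#' a final 730--750 band spanning 21 nm) and tabulates, per variant, the
#' percentage of the 27 discriminatory wavelengths falling in each band.
#'
#' @param lambda_report Output of [discriminatory_wavelengths()].
#' @param min_pct Only report bands whose percentage exceeds this value
#'   (default 10, mirroring how such tables are usually presented; use 0 for
#'   the complete table).
#' @return A tibble `variant`, `band`, `band_start_nm`, `count`, `pct`
#'   (integer percent of 27).
#' @export
band_frequency <- function(lambda_report, min_pct = 10) {
  lam <- lambda_report$lambda_star_nm
  if (any(lam < 450 | lam > 750)) abort("wavelengths outside 450-750 nm")
  starts <- seq(450, 730, by = 20)
  band_of <- function(l) pmin((l - 450) %/% 20 + 1, length(starts))
  labels <- paste0(starts, " to ", c(starts[-1] - 1, 750))
  lambda_report %>%
    mutate(band_idx = band_of(.data$lambda_star_nm)) %>%
    group_by(.data$variant, .data$band_idx) %>%
    summarise(count = n(), .groups = "drop") %>%
    mutate(
      band = labels[.data$band_idx],
      band_start_nm = starts[.data$band_idx],
      pct = as.integer(round(.data$count / 27 * 100))
    ) %>%
    filter(.data$pct > min_pct) %>%
    arrange(.data$variant, dplyr::desc(.data$pct), .data$band_start_nm) %>%
    select("variant", "band", "band_start_nm", "count", "pct")
}
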