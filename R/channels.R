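#' Spectral combination-channel catalogue
#'
#' The nine families of combination spectra, three per family, built from the
#' six detection channels: parallel and perpendicular fiber spectra,
#' polarization-gated differences (parallel minus paired perpendicular, which
#' isolates shallow weakly-depolarized photons), diffuse sums, parallel/
#' perpendicular ratios, parallel and perpendicular differentials (adjacent
#' fiber differences, emphasizing a depth shell), differential ratios, and
#' gated ratios -- 27 combination spectra in total.
#'
#' @return A tibble `family`, `combo` (27 rows, stable order).
#' @export
channel_catalogue <- function() {
  tibble(
    family = rep(c(
      "parallel", "perpendicular", "gated", "diffuse", "par_over_perp",
      "differential_par", "differential_perp", "differential_ratio",
      "gated_ratio"
    ), each = 3),
    combo = c(
      "BF1", "BF2", "BF3",
      "BF1per", "BF2per", "BF3per",
      "BF1-BF1per", "BF2-BF2per", "BF3-BF3per",
      "BF1+BF1per", "BF2+BF2per", "BF3+BF3per",
      "BF1/BF1per", "BF2/BF2per", "BF3/BF3per",
      "BF1-BF2", "BF2-BF3", "BF1-BF3",
      "BF1per-BF2per", "BF2per-BF3per", "BF1per-BF3per",
      "(BF1-BF2)/(BF1per-BF2per)", "(BF2-BF3)/(BF2per-BF3per)",
      "(BF1-BF3)/(BF1per-BF3per)",
      "(BF1-BF1per)/(BF2-BF2per)", "(BF1-BF1per)/(BF3-BF3per)",
      "(BF2-BF2per)/(BF3-BF3per)"
    )
  )
}

# mask ratio entries where the denominator is within tol of zero relative to
# the denominator's overall scale; masked points are NA and are excluded from
# means, integrals and argmax downstream
safe_ratio <- function(num, den, rel_tol = 1e-6) {
  scale <- stats::median(abs(den), na.rm = TRUE)
  thresh <- rel_tol * max(scale, .Machine$double.eps)
  out <- num / den
  out[abs(den) < thresh] <- NA_real_
  out
}

#' Build the 27 combination spectra for a set of measurements
#'
#' Computes every catalogue combination per wavelength for each measurement,
#' in both an unnormalized and an area-normalized variant (each spectrum
#' divided by its own trapezoid integral, emphasizing spectral shape over
#' magnitude). Ratio spectra are masked (`NA`) at wavelengths where the
#' denominator is within `1e-6` of zero relative to its median magnitude.
#'
#' @param spectra Standardized spectra tibble.
#' @return An object of class `oprs_channels`: a list with `measurement_id`,
#'   `wavelength_nm`, and `mats[[variant]][[combo]]` matrices (measurements x
#'   wavelengths) for variants `"unnorm"` and `"norm"`.
#' @export
build_channels <- function(spectra) {
  ch <- spectra_to_matrices(spectra)
  wl <- attr(ch, "wavelength_nm")
  m <- list(
    "BF1" = ch$BF1, "BF2" = ch$BF2, "BF3" = ch$BF3,
    "BF1per" = ch$BF1per, "BF2per" = ch$BF2per, "BF3per" = ch$BF3per,
    "BF1-BF1per" = ch$BF1 - ch$BF1per,
    "BF2-BF2per" = ch$BF2 - ch$BF2per,
    "BF3-BF3per" = ch$BF3 - ch$BF3per,
    "BF1+BF1per" = ch$BF1 + ch$BF1per,
    "BF2+BF2per" = ch$BF2 + ch$BF2per,
    "BF3+BF3per" = ch$BF3 + ch$BF3per,
    "BF1/BF1per" = safe_ratio(ch$BF1, ch$BF1per),
    "BF2/BF2per" = safe_ratio(ch$BF2, ch$BF2per),
    "BF3/BF3per" = safe_ratio(ch$BF3, ch$BF3per),
    "BF1-BF2" = ch$BF1 - ch$BF2,
    "BF2-BF3" = ch$BF2 - ch$BF3,
    "BF1-BF3" = ch$BF1 - ch$BF3,
    "BF1per-BF2per" = ch$BF1per - ch$BF2per,
    "BF2per-BF3per" = ch$BF2per - ch$BF3per,
    "BF1per-BF3per" = ch$BF1per - ch$BF3per
  )
  m[["(BF1-BF2)/(BF1per-BF2per)"]] <- safe_ratio(m[["BF1-BF2"]], m[["BF1per-BF2per"]])
  m[["(BF2-BF3)/(BF2per-BF3per)"]] <- safe_ratio(m[["BF2-BF3"]], m[["BF2per-BF3per"]])
  m[["(BF1-BF3)/(BF1per-BF3per)"]] <- safe_ratio(m[["BF1-BF3"]], m[["BF1per-BF3per"]])
  m[["(BF1-BF1per)/(BF2-BF2per)"]] <- safe_ratio(m[["BF1-BF1per"]], m[["BF2-BF2per"]])
  m[["(BF1-BF1per)/(BF3-BF3per)"]] <- safe_ratio(m[["BF1-BF1per"]], m[["BF3-BF3per"]])
  m[["(BF2-BF2per)/(BF3-BF3per)"]] <- safe_ratio(m[["BF2-BF2per"]], m[["BF3-BF3per"]])
  m <- m[channel_catalogue()$combo]

  norm <- lapply(m, function(mat) {
    areas <- apply(mat, 1, function(y) trapz_na(wl, y))
    bad <- !is.finite(areas) | abs(areas) < 1e-12
    scaled <- mat / areas
    if (any(bad)) scaled[bad, ] <- NA_real_
    scaled
  })

  structure(
    list(
      measurement_id = rownames(m[[1]]),
      wavelength_nm = wl,
      mats = list(unnorm = m, norm = norm),
      cache = new.env(parent = emptyenv())
    ),
    class = "oprs_channels"
  )
}

#' @export
print.oprs_channels <- function(x, ...) {
  cat(
    "OPRS combination channels:", length(x$measurement_id), "measurements,",
    length(x$mats$unnorm), "combinations x 2 variants,",
    length(x$wavelength_nm), "wavelengths\n"
  )
  invisible(x)
}
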