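#' Wavelength grid
#'
#' The common spectral grid on which all channels are recorded. The default
#' covers the visible analysis window 450--750 nm at 1-nm spacing, i.e. 301
#' sample points.
#'
#' @param start_nm First wavelength in nm.
#' @param end_nm Last wavelength in nm.
#' @param step_nm Grid spacing in nm; must divide `end_nm - start_nm` evenly.
#'
#' @return A numeric vector of wavelengths (strictly ascending, evenly spaced).
#' @examples
#' length(wavelength_grid()) # 301
#' @export
wavelength_grid <- function(start_nm = 450, end_nm = 750, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm))
  if (!(step_nm > 0) || end_nm <= start_nm) {
    abort("wavelength grid must be strictly ascending with positive step")
  }
  n_steps <- (end_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    abort("step_nm must divide the grid range evenly")
  }
  seq(start_nm, end_nm, by = step_nm)
}

#' Detection channel names
#'
#' The six detection fibers: three collecting co-polarized (parallel) light at
#' increasing source-detector separation (`BF1`, `BF2`, `BF3`) and three
#' collecting cross-polarized (perpendicular) light (`BF1per`, `BF2per`,
#' `BF3per`).
#'
#' @return Character vector of length 6.
#' @export
channel_names <- function() {
  c("BF1", "BF2", "BF3", "BF1per", "BF2per", "BF3per")
}

parallel_channels <- function() c("BF1", "BF2", "BF3")
perpendicular_channels <- function() c("BF1per", "BF2per", "BF3per")

# paired perpendicular channel for a parallel channel (and vice versa)
paired_channel <- function(channel) {
  ifelse(grepl("per$", channel), sub("per$", "", channel), paste0(channel, "per"))
}

# trapezoid integral that tolerates masked (NA) samples by integrating over
# the non-NA subgrid
trapz_na <- function(x, y) {
  ok <- is.finite(y)
  if (sum(ok) < 2) {
    return(NA_real_)
  }
  pracma::trapz(x[ok], y[ok])
}

check_spectra_frame <- function(spectra, id_col = "measurement_id") {
  needed <- c(id_col, "wavelength_nm", channel_names())
  missing <- setdiff(needed, names(spectra))
  if (length(missing) > 0) {
    abort(paste0(
      "spectra frame is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  invisible(spectra)
}

# spectra tibble -> named list of (n_measurement x n_wavelength) matrices,
# one per channel, rows ordered/named by measurement id
spectra_to_matrices <- function(spectra, grid = NULL) {
  check_spectra_frame(spectra)
  spectra <- arrange(spectra, .data$measurement_id, .data$wavelength_nm)
  wl <- sort(unique(spectra$wavelength_nm))
  if (!is.null(grid) && !isTRUE(all.equal(wl, grid))) {
    abort("spectra wavelengths do not match the expected grid")
  }
  ids <- unique(spectra$measurement_id)
  out <- lapply(channel_names(), function(ch) {
    m <- matrix(spectra[[ch]], nrow = length(ids), ncol = length(wl), byrow = TRUE)
    rownames(m) <- ids
    m
  })
  names(out) <- channel_names()
  attr(out, "wavelength_nm") <- wl
  out
}

matrices_to_spectra <- function(mats, wl) {
  ids <- rownames(mats[[1]])
  base <- tibble(
    measurement_id = rep(ids, each = length(wl)),
    wavelength_nm = rep(wl, times = length(ids))
  )
  for (ch in names(mats)) {
    base[[ch]] <- as.vector(t(mats[[ch]]))
  }
  base
}
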