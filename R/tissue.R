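#' Tissue class parameters
#'
#' Generative parameters of the two-layer tissue model for the four diagnostic
#' classes (normal mucosa, benign lesion, mild dysplasia `MD`, severe
#' dysplasia `SD`). The epithelium (including its superficial keratin layer)
#' sits on a scattering, hemoglobin-absorbing stroma. Defaults encode the
#' cohort-level structure the analysis assumes:
#'
#' * mean total epithelial thickness (epithelium + keratin) of 426, 504 and
#'   701 um for benign, MD and SD sites -- epithelium thickens with dysplasia
#'   progression;
#' * a keratin layer whose scattering amplitude is strongest and whose
#'   thickness is by far the most variable in the benign class
#'   (hyperkeratosis of chronically irritated but non-dysplastic lesions),
#'   which is what makes benign-versus-dysplasia discrimination hard;
#' * epithelial scattering amplitude increasing with dysplasia grade
#'   (nuclear enlargement, hyperchromasia, pleomorphism);
#' * a keratin blue-slope exponent giving the steep negative 450--500 nm slope
#'   of keratinized sites;
#' * a lognormal per-patient intensity scale (log-sd 0.4) emulating
#'   interpatient variation that standardization must remove.
#'
#' @return A tibble with one row per diagnostic class and columns
#'   `class`, `keratin_mean_um`, `keratin_sd_um`, `total_mean_um`,
#'   `total_sd_um`, `keratin_amp`, `keratin_slope`, `epithelium_amp`,
#'   `hemoglobin`, `patient_log_sd`.
#' @examples
#' tissue_class_params()
#' @export
tissue_class_params <- function() {
  tibble(
    class = c("normal", "benign", "MD", "SD"),
    keratin_mean_um = c(10, 120, 80, 90),
    keratin_sd_um = c(5, 80, 40, 45),
    total_mean_um = c(300, 426, 504, 701),
    total_sd_um = c(50, 90, 100, 130),
    keratin_amp = c(1.2, 4.0, 2.0, 2.2),
    keratin_slope = c(4.0, 4.5, 4.0, 4.0),
    epithelium_amp = c(0.8, 1.0, 1.3, 1.6),
    hemoglobin = c(1.5, 1.5, 1.5, 1.5),
    patient_log_sd = c(0.4, 0.4, 0.4, 0.4)
  )
}

# truncated-at-zero normal via inverse CDF; exact, vectorized, sd = 0 allowed
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(max(mean, 0), n))
  }
  p0 <- pnorm(0, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}

#' Sample tissue instances for one diagnostic class
#'
#' Draws per-measurement tissue realizations: keratin thickness and total
#' epithelial thickness from normal distributions truncated at zero (keratin
#' clipped to not exceed the total), and a per-patient lognormal intensity
#' scale factor. With all sd fields zero the draw equals the class means.
#'
#' @param params A single row of [tissue_class_params()] (or a compatible
#'   one-row data frame).
#' @param n Number of instances.
#' @param seed Optional integer seed; when supplied the draw is deterministic
#'   and leaves the global RNG untouched.
#' @return A tibble with columns `class`, `keratin_um`, `total_um`,
#'   `keratin_amp`, `keratin_slope`, `epithelium_amp`, `hemoglobin`,
#'   `patient_scale`.
#' @examples
#' sd_row <- dplyr::filter(tissue_class_params(), class == "SD")
#' sample_tissue_instances(sd_row, 5, seed = 1)
#' @export
sample_tissue_instances <- function(params, n, seed = NULL) {
  if (nrow(params) != 1) abort("params must be a single class row")
  num <- unlist(params[setdiff(names(params), "class")])
  if (any(!is.finite(num))) abort("non-finite tissue parameters")
  if (params$keratin_sd_um < 0 || params$total_sd_um < 0 ||
    params$patient_log_sd < 0) {
    abort("sd parameters must be >= 0")
  }
  draw <- function() {
    total <- rnorm_trunc0(n, params$total_mean_um, params$total_sd_um)
    keratin <- pmin(rnorm_trunc0(n, params$keratin_mean_um, params$keratin_sd_um), total)
    tibble(
      class = params$class,
      keratin_um = keratin,
      total_um = total,
      keratin_amp = params$keratin_amp,
      keratin_slope = params$keratin_slope,
      epithelium_amp = params$epithelium_amp,
      hemoglobin = params$hemoglobin,
      patient_scale = rlnorm(n, 0, params$patient_log_sd)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
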