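#' Scattering coefficient from collimated transmission
#'
#' Beer-Lambert inversion of a transmission measurement through a scattering
#' phantom of path length `L`: \eqn{\mu_s = -\ln(T) / L}.
#'
#' @param transmission Fraction transmitted, in (0, 1].
#' @param path_length_mm Path length in mm.
#' @return Scattering coefficient in 1/mm.
#' @export
scattering_from_transmission <- function(transmission, path_length_mm) {
  if (any(transmission <= 0) || any(transmission > 1)) {
    abort("transmission must lie in (0, 1]")
  }
  if (any(path_length_mm <= 0)) abort("path length must be positive")
  -log(transmission) / path_length_mm
}

#' Reduced scattering coefficient
#'
#' \eqn{\mu_s' = \mu_s (1 - g)} with scattering anisotropy `g` (default
#' 0.752, the Intralipid value at 600 nm).
#'
#' @param mu_s Scattering coefficient, 1/mm.
#' @param g Anisotropy in `[0, 1)`.
#' @return Reduced scattering coefficient, 1/mm.
#' @export
reduced_scattering <- function(mu_s, g = 0.752) {
  if (any(g < 0) || any(g >= 1)) abort("g must lie in [0, 1)")
  mu_s * (1 - g)
}

#' Linear concentration-to-scattering calibration
#'
#' Fits a least-squares line of reduced scattering versus phantom
#' concentration, used to find the concentration achieving a target
#' scattering level.
#'
#' @param concentration_pct Concentrations (%, >= 2 distinct values).
#' @param mu_s_prime Reduced scattering values, 1/mm.
#' @return An object of class `oprs_concentration_fit` wrapping the `lm` fit
#'   (elements `slope`, `intercept`, `fit`).
#' @export
fit_concentration_curve <- function(concentration_pct, mu_s_prime) {
  if (length(concentration_pct) < 2 || length(unique(concentration_pct)) < 2) {
    abort("need at least two distinct concentrations")
  }
  fit <- lm(mu_s_prime ~ concentration_pct)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      fit = fit
    ),
    class = "oprs_concentration_fit"
  )
}

#' Invert the concentration calibration
#'
#' @param object An [fit_concentration_curve()] result.
#' @param target_mu_s_prime Target reduced scattering, 1/mm.
#' @return Concentration (%) achieving the target on the fitted line.
#' @export
concentration_for <- function(object, target_mu_s_prime) {
  (target_mu_s_prime - object$intercept) / object$slope
}

#' @export
print.oprs_concentration_fit <- function(x, ...) {
  cat(sprintf(
    "mu_s' = %.4f + %.4f * concentration(%%)  [1/mm]\n", x$intercept, x$slope
  ))
  invisible(x)
}

estimate_plateau <- function(thickness_um, intensity,
                             method = c("fit", "tail"), tail_frac = 0.1) {
  method <- match.arg(method)
  if (method == "fit") {
    asym0 <- max(intensity)
    z63 <- thickness_um[which(intensity >= 0.63 * asym0)[1]]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        intensity ~ Asym * (1 - exp(-thickness_um / z0)),
        start = list(Asym = asym0, z0 = max(z63, min(diff(thickness_um)))),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && coef(fit)["Asym"] > 0) {
      return(unname(coef(fit)["Asym"]))
    }
    # fall through to tail mean when the curve is not exponential-like
  }
  n_tail <- max(1, ceiling(tail_frac * length(intensity)))
  mean(tail(intensity, n_tail))
}

#' 90%-saturation depth of a depth-response curve
#'
#' Estimates the channel's saturated signal level and returns the first
#' thickness at which the curve reaches 90% of it, refined by linear
#' interpolation between the bracketing grid points. The saturated level is
#' estimated by fitting a saturating exponential through the curve (default;
#' exact for exponential-family responses whose plateau lies beyond the
#' scanned range) or, with `plateau = "tail"`, as the mean of the last 10% of
#' grid points.
#'
#' @param thickness_um Ascending thickness grid (>= 5 points).
#' @param intensity Collected intensity at each thickness.
#' @param plateau `"fit"` (default) or `"tail"`.
#' @param tail_frac Tail fraction for the `"tail"` estimator.
#' @return A tibble `saturated`, `depth90_um`.
#' @export
saturation_depth_90 <- function(thickness_um, intensity,
                                plateau = c("fit", "tail"), tail_frac = 0.1) {
  if (length(thickness_um) < 5) abort("need at least 5 grid points")
  if (is.unsorted(thickness_um, strictly = TRUE)) {
    abort("thickness grid must be strictly ascending")
  }
  sat <- estimate_plateau(thickness_um, intensity, match.arg(plateau), tail_frac)
  if (!(sat > 0)) abort("saturated level must be positive")
  level <- 0.9 * sat
  above <- which(intensity >= level)
  if (length(above) == 0) {
    abort("curve never reaches 90% of its saturation estimate")
  }
  i <- above[1]
  depth <- if (i == 1) {
    thickness_um[1]
  } else {
    y0 <- intensity[i - 1]
    y1 <- intensity[i]
    thickness_um[i - 1] +
      (level - y0) / (y1 - y0) * (thickness_um[i] - thickness_um[i - 1])
  }
  tibble(saturated = sat, depth90_um = depth)
}

#' 90%-saturation depths for every channel of a phantom series
#'
#' @param curves Tibble from [simulate_phantom_series()] (or measured data in
#'   the same layout: `thickness_um` + one column per channel).
#' @inheritParams saturation_depth_90
#' @return A tibble `channel`, `saturated`, `depth90_um`.
#' @export
saturation_depths <- function(curves, plateau = c("fit", "tail"),
                              tail_frac = 0.1) {
  plateau <- match.arg(plateau)
  chs <- setdiff(names(curves), "thickness_um")
  bind_rows(lapply(chs, function(ch) {
    res <- saturation_depth_90(curves$thickness_um, curves[[ch]],
      plateau = plateau, tail_frac = tail_frac
    )
    mutate(res, channel = ch, .before = 1)
  }))
}
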