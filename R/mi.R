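#' Plug-in mutual information between a feature and binary labels
#'
#' The feature is discretized by equal-frequency binning (default 3 bins;
#' features with at most `bins` distinct values are used as-is), then the
#' plug-in mutual information of the joint histogram is computed in nats.
#'
#' @param x Numeric feature values.
#' @param y Labels (any discrete vector).
#' @param bins Number of equal-frequency bins.
#' @return MI in nats (>= 0); 0 with a warning for a constant feature.
#' @export
mutual_information <- function(x, y, bins = 3) {
  bx <- discretize_ef(x, bins)
  if (length(unique(bx)) < 2) {
    warn("constant feature: mutual information is 0")
    return(0)
  }
  mi_binned(bx, as.integer(factor(y)))
}

# equal-frequency binning into integer codes; NA values get their own bin
discretize_ef <- function(x, bins = 3) {
  finite <- is.finite(x)
  ux <- unique(x[finite])
  if (length(ux) <= bins) {
    codes <- match(x, sort(ux))
  } else {
    br <- unique(stats::quantile(x[finite],
      probs = seq(0, 1, length.out = bins + 1), names = FALSE, type = 7
    ))
    codes <- as.integer(cut(x, breaks = br, include.lowest = TRUE))
  }
  codes[!finite] <- 0L
  codes + 1L
}

mi_binned <- function(bx, by) {
  nx <- max(bx)
  ny <- max(by)
  joint <- tabulate(bx + nx * (by - 1L), nbins = nx * ny)
  p <- matrix(joint / sum(joint), nrow = nx, ncol = ny)
  e <- outer(rowSums(p), colSums(p))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

#' Greedy mRMR feature ranking
#'
#' Minimum-redundancy maximum-relevance selection with the difference (MID)
#' criterion: the first feature maximizes relevance `MI(f; y)`; each
#' subsequent feature maximizes
#' `MI(f; y) - mean_{s in selected} MI(f; s)`. All mutual information terms
#' use the same equal-frequency discretization. Ties (within `1e-12`) break
#' toward the lexicographically smallest feature name, so the ranking does
#' not depend on column order.
#'
#' @param features A data frame / tibble of numeric feature columns.
#' @param labels Class labels, one per row.
#' @param k Number of features to rank (at most the number of columns).
#' @param bins Discretization bins.
#' @param scheme `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @return Character vector of `k` feature names in selection order.
#' @export
mrmr_rank <- function(features, labels, k = ncol(features), bins = 3,
                      scheme = c("MID", "MIQ")) {
  scheme <- match.arg(scheme)
  if (ncol(features) == 0) abort("empty feature set")
  if (k > ncol(features)) abort("k exceeds the number of features")
  nms <- sort(colnames(features))
  binned <- lapply(nms, function(nm) discretize_ef(features[[nm]], bins))
  names(binned) <- nms
  by <- as.integer(factor(labels))
  relevance <- vapply(binned, function(b) mi_binned(b, by), numeric(1))

  selected <- character(0)
  red_sum <- setNames(numeric(length(nms)), nms)
  remaining <- nms
  for (step in seq_len(k)) {
    score <- if (step == 1) {
      relevance[remaining]
    } else {
      red <- red_sum[remaining] / length(selected)
      if (scheme == "MID") {
        relevance[remaining] - red
      } else {
        relevance[remaining] / (red + .Machine$double.eps)
      }
    }
    best <- remaining[score >= max(score) - 1e-12][1]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) == 0) break
    for (nm in remaining) {
      red_sum[nm] <- red_sum[nm] + mi_binned(binned[[nm]], binned[[best]])
    }
  }
  selected
}
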