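# Minimum-redundancy maximum-relevance (MRMR) feature selection.
#
# Continuous features are discretized by equal-frequency binning; mutual
# information (MI) is the plug-in estimate from the empirical joint
# distribution, in bits. Ranking uses the MID (difference) scheme:
# score(f) = MI(f; y) - mean over selected s of MI(f; s), built greedily.
# Selection is performed inside each training fold only; the selected set
# travels with the model artifact.

#' Equal-frequency discretization
#'
#' Bin edges are the empirical quantiles; tied quantiles are merged (ties
#' broadened to the right), so heavily tied features get fewer bins. Already
#' discrete inputs with at most `bins` distinct values are passed through
#' as integer codes.
#'
#' @param x Numeric vector.
#' @param bins Target number of bins (default 10).
#' @return Integer vector of bin codes in `1..bins`.
#' @export
discretize_ef <- function(x, bins = 10L) {
  ux <- unique(x)
  if (length(ux) <= bins) {
    return(match(x, sort(ux)))
  }
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                   names = FALSE, type = 7))
  if (length(breaks) < 2L) return(rep(1L, length(x)))
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

# MI in bits from two integer code vectors with known alphabet sizes.
.mi_codes <- function(xi, yi, kx, ky) {
  n <- length(xi)
  joint <- tabulate((xi - 1L) * ky + yi, nbins = kx * ky) / n
  px <- tabulate(xi, nbins = kx) / n
  py <- tabulate(yi, nbins = ky) / n
  # joint index (xi-1)*ky + yi pairs with px[x] * py[y] in the same order
  pxpy <- rep(px, each = ky) * rep.int(py, kx)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / pxpy[nz]))
}

#' Plug-in mutual information
#'
#' MI between two variables from their empirical joint distribution, log
#' base 2 (bits). Continuous inputs are discretized by equal-frequency
#' binning first; factors and character vectors are used as-is. A constant
#' input gives 0 by convention.
#'
#' @param x,y Vectors of equal length (numeric, factor or character).
#' @param bins Bin count for continuous inputs.
#' @return MI in bits (>= 0).
#' @export
mutual_information <- function(x, y, bins = 10L) {
  if (length(x) != length(y)) abort_input("x and y lengths differ")
  if (length(x) < 2L) abort_input("need >= 2 observations")
  code <- function(v) {
    if (is.numeric(v)) discretize_ef(v, bins) else as.integer(factor(v))
  }
  xi <- code(x)
  yi <- code(y)
  .mi_codes(xi, yi, max(xi), max(yi))
}

#' Greedy MRMR feature ranking
#'
#' The first feature maximizes relevance `MI(f; y)`; each subsequent
#' feature maximizes `MI(f; y) - (1/|S|) * sum over selected s of MI(f; s)`
#' (MID scheme) or the quotient analogue (MIQ). The score recorded for each
#' feature is its criterion value at the moment of selection. The ranking
#' covers all features unless `max_features` stops it early.
#'
#' @param features Numeric matrix or data.frame of feature columns.
#' @param labels Binary class labels (factor, character or numeric).
#' @param bins Equal-frequency bin count for discretization.
#' @param scheme `"mid"` (difference, default) or `"miq"` (quotient).
#' @param max_features Stop after ranking this many features (default: all).
#' @return Object of class `mrmr_ranking`: data.frame `ranking` (feature,
#'   score, relevance), plus `bins` and `scheme`.
#' @export
mrmr_rank <- function(features, labels, bins = 10L,
                      scheme = c("mid", "miq"), max_features = Inf) {
  scheme <- match.arg(scheme)
  features <- as.matrix(features)
  if (ncol(features) < 2L) abort_input("need >= 2 features")
  if (length(unique(labels)) < 2L) {
    abort_input("labels contain a single class")
  }
  p <- ncol(features)
  nm <- colnames(features)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))

  codes <- matrix(0L, nrow = nrow(features), ncol = p)
  kx <- integer(p)
  for (j in seq_len(p)) {
    codes[, j] <- discretize_ef(features[, j], bins)
    kx[j] <- max(codes[, j])
  }
  yi <- as.integer(factor(labels))
  ky <- max(yi)

  relevance <- vapply(seq_len(p), function(j) .mi_codes(codes[, j], yi,
                                                        kx[j], ky),
                      numeric(1))
  n_rank <- min(p, max_features)
  sel <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p) # sum of MI(f, s) over selected s
  remaining <- seq_len(p)
  eps <- .Machine$double.eps
  for (step in seq_len(n_rank)) {
    crit <- if (!length(sel)) {
      relevance[remaining]
    } else if (scheme == "mid") {
      relevance[remaining] - red_sum[remaining] / length(sel)
    } else {
      relevance[remaining] / (red_sum[remaining] / length(sel) + eps)
    }
    k <- remaining[which.max(crit)]
    scores <- c(scores, max(crit))
    sel <- c(sel, k)
    remaining <- setdiff(remaining, k)
    if (length(remaining)) {
      for (j in remaining) {
        red_sum[j] <- red_sum[j] +
          .mi_codes(codes[, j], codes[, k], kx[j], kx[k])
      }
    }
  }
  structure(
    list(ranking = data.frame(feature = nm[sel], score = scores,
                              relevance = relevance[sel],
                              stringsAsFactors = FALSE),
         bins = bins, scheme = scheme),
    class = "mrmr_ranking")
}

#' Select features with importance score at or above a threshold
#'
#' The cut is inclusive (score >= threshold) and preserves the greedy
#' ranking order. An empty selection triggers a warning; downstream model
#' fitting refuses to train on zero features.
#'
#' @param ranking An [mrmr_rank()] result.
#' @param threshold Importance-score cut (default 0.015 bits).
#' @return Character vector of selected feature names.
#' @export
apply_threshold <- function(ranking, threshold = 0.015) {
  stopifnot(inherits(ranking, "mrmr_ranking"))
  sel <- ranking$ranking$feature[ranking$ranking$score >= threshold]
  if (!length(sel)) {
    warning("no feature reaches the importance-score threshold ", threshold)
  }
  sel
}
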