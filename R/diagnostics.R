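#' Tracer panel for selection diagnostics
#'
#' A samples-by-tracers matrix of delta15N values with optional source-group
#' labels, used by the tracer-selection diagnostics.
#'
#' @param x an [omsm_sources()] object, or a numeric matrix/data frame of
#'   tracer values (columns are tracers).
#' @param tracers amino acids to keep (default: all).
#' @return numeric matrix with a `groups` attribute (or `NULL`).
#' @export
tracer_panel <- function(x, tracers = NULL) {
  if (inherits(x, "omsm_sources")) {
    keep <- if (is.null(tracers)) x$tracers else aa_canonical(tracers)
    mat <- as.matrix(x$data[, keep, drop = FALSE])
    attr(mat, "groups") <- as.character(x$data$group)
  } else {
    mat <- as.matrix(x)
    if (!is.null(tracers)) mat <- mat[, aa_canonical(tracers), drop = FALSE]
    storage.mode(mat) <- "double"
  }
  if (nrow(mat) < 3L) stop("tracer panel needs at least 3 samples", call. = FALSE)
  if (anyNA(mat)) stop("tracer panel has missing cells", call. = FALSE)
  mat
}

#' Pairwise Pearson correlations of tracers
#'
#' @param panel a [tracer_panel()] (or any samples x tracers matrix).
#' @return correlation matrix with a `mean_abs_r` attribute, the mean
#'   absolute off-diagonal correlation — high values signal that tracers
#'   carry largely redundant information.
#' @export
correlation_matrix <- function(panel) {
  panel <- tracer_panel(panel)
  sds <- apply(panel, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance tracer(s): ",
         paste(colnames(panel)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(panel)
  off <- abs(r[upper.tri(r)])
  attr(r, "mean_abs_r") <- mean(off)
  r
}

#' PCA variance decomposition
#'
#' Fractions of total variance explained by each principal component of the
#' (by default unscaled) tracer covariance matrix.
#'
#' @inheritParams correlation_matrix
#' @param scale standardise tracers first? Default `FALSE` (covariance PCA,
#'   appropriate when all tracers share the per-mil scale).
#' @return numeric vector of variance fractions (non-increasing, sums to 1).
#' @export
pca_variance <- function(panel, scale = FALSE) {
  panel <- tracer_panel(panel)
  if (ncol(panel) < 2L) stop("need at least 2 tracers", call. = FALSE)
  tot <- sum(apply(panel, 2, stats::var))
  if (tot == 0) stop("degenerate covariance: all tracers constant", call. = FALSE)
  p <- stats::prcomp(panel, center = TRUE, scale. = scale)
  ev <- p$sdev^2
  ev / sum(ev)
}

#' Effective dimensionality of a tracer panel
#'
#' Shannon-entropy effective dimensionality of the covariance spectrum: with
#' normalised eigenvalues \eqn{p_i = \lambda_i / \sum \lambda_i},
#' \deqn{n_1 = \exp(-\sum_i p_i \ln p_i).}
#' Ranges from 1 (a single axis carries all variance) to the number of
#' tracers (isotropic variance). For resolving an n-component mixture, about
#' n - 1 effective dimensions are needed.
#'
#' @inheritParams correlation_matrix
#' @return scalar effective dimensionality.
#' @export
effective_dimensionality <- function(panel) {
  p <- pca_variance(panel, scale = FALSE)
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' Tracer diagnostics report
#'
#' Runs the full tracer-selection screen on a source dataset: pairwise
#' correlations (with mean |r|), PCA variance fractions, and effective
#' dimensionality, for a chosen tracer subset.
#'
#' @param sources an [omsm_sources()] dataset.
#' @param tracers amino acids to screen (default: all in the data).
#' @return list of class `omsm_diagnostics` with `correlation`,
#'   `mean_abs_r`, `pca_variance`, `effective_dimensionality`, `tracers`.
#' @export
tracer_diagnostics <- function(sources, tracers = NULL) {
  panel <- tracer_panel(sources, tracers)
  r <- correlation_matrix(panel)
  structure(list(tracers = colnames(panel),
                 correlation = r,
                 mean_abs_r = attr(r, "mean_abs_r"),
                 pca_variance = pca_variance(panel),
                 effective_dimensionality = effective_dimensionality(panel)),
            class = "omsm_diagnostics")
}

#' @export
print.omsm_diagnostics <- function(x, ...) {
  cat("<omsm_diagnostics> tracers:", paste(x$tracers, collapse = ", "), "\n")
  cat(sprintf("mean |r| = %.3f\n", x$mean_abs_r))
  cat("PCA variance fractions:",
      paste(sprintf("%.3f", x$pca_variance), collapse = ", "), "\n")
  cat(sprintf("effective dimensionality = %.2f\n", x$effective_dimensionality))
  invisible(x)
}
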