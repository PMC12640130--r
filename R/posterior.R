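#' Highest density interval
#'
#' The shortest contiguous interval containing a given fraction of the
#' draws: among all windows of `ceiling(level * n)` consecutive sorted
#' draws, the narrowest is returned (ties broken deterministically in favour
#' of the lowest window).
#'
#' @param draws numeric vector of posterior draws (at least 100).
#' @param level probability mass to contain, in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' x <- stats::rnorm(10000)
#' hdi(x, 0.95)  # close to c(-1.96, 1.96)
#' @export
hdi <- function(draws, level = 0.95) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 100L) stop("hdi requires at least 100 draws", call. = FALSE)
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  xs <- sort(draws)
  m <- ceiling(level * n)
  if (m >= n) return(c(lower = xs[1], upper = xs[n]))
  widths <- xs[m:n] - xs[1:(n - m + 1)]
  i <- which.min(widths)            # which.min returns the first minimum
  c(lower = xs[i], upper = xs[i + m - 1])
}

#' Posterior mode via kernel density estimation
#'
#' The argmax of a Gaussian kernel density estimate (Silverman's bandwidth,
#' 512-point grid spanning the draw range). For parameters with known bounds
#' (e.g. mixing coefficients in \[0, 1\]) the density is estimated on the
#' logit scale and the mode back-transformed, which avoids boundary bias.
#'
#' @param draws numeric vector of posterior draws (at least 100).
#' @param lower,upper optional finite bounds; when both are given the
#'   logit-scale estimate is used.
#' @return scalar mode estimate.
#' @export
posterior_mode <- function(draws, lower = NULL, upper = NULL) {
  draws <- as.numeric(draws)
  if (length(draws) < 100L) {
    stop("posterior_mode requires at least 100 draws", call. = FALSE)
  }
  if (stats::var(draws) == 0) return(draws[1])
  if (!is.null(lower) && !is.null(upper)) {
    eps <- (upper - lower) * 1e-9
    z <- (pmin(pmax(draws, lower + eps), upper - eps) - lower) / (upper - lower)
    lz <- stats::qlogis(z)
    d <- stats::density(lz, bw = "nrd0", n = 512)
    lower + (upper - lower) * stats::plogis(d$x[which.max(d$y)])
  } else {
    d <- stats::density(draws, bw = "nrd0", n = 512)
    d$x[which.max(d$y)]
  }
}

#' Does the HDI exclude a value?
#'
#' The workhorse of the HDI-based hypothesis framework: a null value (e.g. a
#' source contribution of zero) can be rejected at the given confidence when
#' the corresponding HDI excludes it. The interval is treated as closed, so
#' a value sitting exactly on an endpoint is not excluded.
#'
#' @inheritParams hdi
#' @param value scalar to test.
#' @return `TRUE` when `value` lies outside the closed HDI.
#' @export
hdi_excludes <- function(draws, value, level = 0.95) {
  h <- hdi(draws, level)
  value < h[["lower"]] || value > h[["upper"]]
}

#' Summarise posterior draws
#'
#' One row per parameter: posterior mean, kernel-density mode, and the 50%,
#' 75%, 90%, and 95% highest density intervals, plus the convergence
#' diagnostics carried by the draws. Mixing coefficients (`f` parameters)
#' have their mode estimated on the logit scale.
#'
#' @param draws an `omsm_draws` object from [run_mcmc()].
#' @param levels HDI probability levels.
#' @return a data frame of class `omsm_summary` with columns `parameter`,
#'   `family`, `tracer`, `group`, `consumer`, `mean`, `mode`,
#'   `hdi50_lo` ... `hdi95_hi`, `rhat`, `ess`, `converged`.
#' @export
summarize_posterior <- function(draws, levels = c(0.50, 0.75, 0.90, 0.95)) {
  stopifnot(inherits(draws, "omsm_draws"))
  mat <- draws$mat
  meta <- draws$meta
  out <- meta
  out$mean <- colMeans(mat)
  out$mode <- vapply(seq_len(ncol(mat)), function(p) {
    if (meta$family[p] == "f") {
      posterior_mode(mat[, p], lower = 0, upper = 1)
    } else {
      posterior_mode(mat[, p])
    }
  }, numeric(1))
  for (lev in levels) {
    h <- vapply(seq_len(ncol(mat)), function(p) hdi(mat[, p], lev), numeric(2))
    tag <- sprintf("hdi%02d", round(lev * 100))
    out[[paste0(tag, "_lo")]] <- h[1, ]
    out[[paste0(tag, "_hi")]] <- h[2, ]
  }
  out$rhat <- draws$diagnostics$rhat
  out$ess <- draws$diagnostics$ess
  out$converged <- draws$diagnostics$ok
  rownames(out) <- NULL
  class(out) <- c("omsm_summary", "data.frame")
  out
}

#' Write a posterior summary to CSV
#'
#' @param summary an `omsm_summary` from [summarize_posterior()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
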