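#' HDI coverage counts
#'
#' Counts, at each HDI level, how many samples' true parameter values fall
#' inside the posterior HDI. Intervals are treated as closed (a truth
#' exactly on an endpoint counts as covered). Because HDIs nest across
#' levels, counts are non-decreasing in the level.
#'
#' @param summaries data frame with one row per sample carrying
#'   `hdiXX_lo`/`hdiXX_hi` columns (e.g. a filtered [summarize_posterior()]
#'   output).
#' @param truths numeric vector of true values, aligned with the rows.
#' @param levels HDI levels to count at.
#' @return named integer vector of coverage counts per level.
#' @export
coverage_counts <- function(summaries, truths, levels = c(0.50, 0.75, 0.90, 0.95)) {
  if (nrow(summaries) != length(truths)) {
    stop("summaries and truths must describe the same samples", call. = FALSE)
  }
  out <- vapply(levels, function(lev) {
    tag <- sprintf("hdi%02d", round(lev * 100))
    lo <- summaries[[paste0(tag, "_lo")]]
    hi <- summaries[[paste0(tag, "_hi")]]
    if (is.null(lo) || is.null(hi)) {
      stop("summaries lack HDI columns for level ", lev, call. = FALSE)
    }
    sum(truths >= lo & truths <= hi)
  }, numeric(1))
  names(out) <- sprintf("%d%%", round(levels * 100))
  out
}

#' Mode-versus-truth discrepancy statistics
#'
#' @param modes posterior modes, one per sample.
#' @param truths true values, same length.
#' @param percent report in percentage points (multiply by 100; use for
#'   mixing fractions).
#' @return list with `mean` and `max` absolute discrepancy.
#' @export
discrepancy_stats <- function(modes, truths, percent = FALSE) {
  if (length(modes) == 0L) stop("empty input", call. = FALSE)
  if (length(modes) != length(truths)) stop("length mismatch", call. = FALSE)
  d <- abs(modes - truths)
  if (percent) d <- 100 * d
  list(mean = mean(d), max = max(d))
}

#' Recovery regression of modelled on true values
#'
#' Fits the modelled value (posterior mode) against the truth, and the
#' discrepancy (mode - truth) against the truth, to expose systematic bias.
#' Compositional responses (mixing fractions) use a quasibinomial GLM with a
#' logistic link; other parameters use ordinary least squares. Perfect
#' recovery gives slope 1 and intercept 0 in the linear case.
#'
#' @inheritParams discrepancy_stats
#' @param compositional is the response a fraction in \[0, 1\]?
#' @return list of class `omsm_recovery_fit`: `fit` (the mode-on-truth
#'   model), `slope`, `intercept`, `slope_ci` (95%), and
#'   `discrepancy_fit` (always OLS).
#' @export
recovery_regression <- function(modes, truths, compositional = FALSE) {
  if (length(modes) < 5L) stop("need at least 5 mode/truth pairs", call. = FALSE)
  if (stats::var(truths) == 0) stop("degenerate truth variance", call. = FALSE)
  df <- data.frame(mode = modes, truth = truths)
  if (compositional) {
    eps <- 1e-6
    df$mode <- pmin(pmax(df$mode, eps), 1 - eps)
    fit <- stats::glm(mode ~ truth, data = df,
                      family = stats::quasibinomial(link = "logit"))
    co <- summary(fit)$coefficients
  } else {
    fit <- stats::lm(mode ~ truth, data = df)
    co <- summary(fit)$coefficients
  }
  slope <- co["truth", "Estimate"]
  se <- co["truth", "Std. Error"]
  disc <- stats::lm(I(mode - truth) ~ truth, data = df)
  structure(list(fit = fit, slope = slope, intercept = co["(Intercept)", "Estimate"],
                 slope_ci = slope + c(-1, 1) * stats::qt(0.975, stats::df.residual(fit)) * se,
                 compositional = compositional, discrepancy_fit = disc),
            class = "omsm_recovery_fit")
}

#' Full parameter-recovery report
#'
#' Compares a joint posterior against the simulation truth for every
#' parameter family: each source's mixing fraction, PTS, MTS, and FWL.
#' Reports HDI coverage counts per level, mean and maximum absolute
#' mode-truth discrepancies (percentage points for fractions), and the
#' recovery regressions.
#'
#' @param summary an [summarize_posterior()] output for a fit of simulated
#'   consumers.
#' @param truth the truth table from [simulate_consumers()].
#' @param levels HDI levels for coverage.
#' @return list of class `omsm_recovery_report`: per-family list with
#'   elements `n`, `coverage` (counts per level), `mean_abs_discrepancy`,
#'   `max_abs_discrepancy`, `regression`; plus `families` and `n_samples`.
#' @export
recovery_report <- function(summary, truth, levels = c(0.50, 0.75, 0.90, 0.95)) {
  stopifnot(inherits(summary, "data.frame"))
  fams <- list()
  f_rows <- summary[summary$family == "f", , drop = FALSE]
  for (g in unique(stats::na.omit(f_rows$group))) {
    rows <- f_rows[f_rows$group == g, , drop = FALSE]
    rows <- rows[match(truth$sample_id, rows$consumer), , drop = FALSE]
    tr <- truth[[paste0("f_", g)]]
    fams[[paste0("f_", g)]] <- list(
      n = nrow(rows),
      coverage = coverage_counts(rows, tr, levels),
      mean_abs_discrepancy = discrepancy_stats(rows$mode, tr, percent = TRUE)$mean,
      max_abs_discrepancy = discrepancy_stats(rows$mode, tr, percent = TRUE)$max,
      regression = if (nrow(rows) >= 5L)
        recovery_regression(rows$mode, tr, compositional = TRUE))
  }
  for (fam in c("PTS", "MTS", "FWL")) {
    rows <- summary[summary$family == fam, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows <- rows[match(truth$sample_id, rows$consumer), , drop = FALSE]
    tr <- truth[[fam]]
    fams[[fam]] <- list(
      n = nrow(rows),
      coverage = coverage_counts(rows, tr, levels),
      mean_abs_discrepancy = discrepancy_stats(rows$mode, tr)$mean,
      max_abs_discrepancy = discrepancy_stats(rows$mode, tr)$max,
      regression = if (nrow(rows) >= 5L)
        recovery_regression(rows$mode, tr, compositional = FALSE))
  }
  structure(list(families = names(fams), n_samples = nrow(truth),
                 levels = levels, results = fams),
            class = "omsm_recovery_report")
}

#' @export
print.omsm_recovery_report <- function(x, ...) {
  cat("<omsm_recovery_report> ", x$n_samples, " samples\n", sep = "")
  for (fam in x$families) {
    r <- x$results[[fam]]
    cov <- paste(sprintf("%s: %d/%d", names(r$coverage), r$coverage, r$n),
                 collapse = ", ")
    unit <- if (startsWith(fam, "f_")) " pp" else " steps"
    cat(sprintf("%-10s coverage %s | mean |mode-truth| %.2f%s (max %.2f)\n",
                fam, cov, r$mean_abs_discrepancy, unit, r$max_abs_discrepancy))
  }
  invisible(x)
}

#' Flatten a recovery report for export
#'
#' @param report an [recovery_report()] output.
#' @return data frame with one row per parameter family: coverage counts
#'   per level and discrepancy statistics.
#' @export
recovery_table <- function(report) {
  rows <- lapply(report$families, function(fam) {
    r <- report$results[[fam]]
    row <- data.frame(family = fam, n = r$n,
                      mean_abs_discrepancy = r$mean_abs_discrepancy,
                      max_abs_discrepancy = r$max_abs_discrepancy,
                      slope = if (is.null(r$regression)) NA_real_ else
                        r$regression$slope,
                      stringsAsFactors = FALSE)
    for (i in seq_along(r$coverage)) {
      row[[paste0("cover_", sub("%", "", names(r$coverage)[i]))]] <- r$coverage[i]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
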