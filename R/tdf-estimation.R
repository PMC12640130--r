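#' Filter a feeding-study compilation with declarative rules
#'
#' Controlled-feeding-study compilations mix habitats, excretion modes, and
#' trophic positions; TDF aggregation for planktonic marine food webs should
#' use a filtered subset. Rules are supplied as named predicate functions of
#' the experiment table and are applied one by one, with a message recording
#' how many experiments each rule removed; the log is attached as the
#' `"filter_log"` attribute.
#'
#' @param experiments data frame of feeding experiments: columns `species`,
#'   `group` (`"protozoa"` or `"metazoa"`), per-amino-acid \eqn{\Delta^{15}N}
#'   columns, and any metadata columns the rules use (the defaults expect
#'   `habitat`, `excretion`, `tp`, `diet`).
#' @param rules named list of functions, each taking the table and returning
#'   a logical keep-vector.
#' @return the filtered table with a `filter_log` attribute
#'   (data frame: rule, removed).
#' @export
filter_experiments <- function(experiments, rules = default_feeding_filters()) {
  log <- data.frame(rule = character(0), removed = integer(0))
  for (nm in names(rules)) {
    keep <- rules[[nm]](experiments)
    keep[is.na(keep)] <- FALSE
    removed <- sum(!keep)
    if (removed > 0) {
      message("filter '", nm, "' removed ", removed, " experiment(s)")
    }
    experiments <- experiments[keep, , drop = FALSE]
    log <- rbind(log, data.frame(rule = nm, removed = removed))
  }
  attr(experiments, "filter_log") <- log
  experiments
}

#' @rdname filter_experiments
#' @details `default_feeding_filters()` keeps aquatic, ammonia-excreting
#'   consumers with trophic position of at most 3, and drops the
#'   *Acanthopagrus butcheri* vegetable-meal experiment, whose discrimination
#'   values are anomalously high.
#' @export
default_feeding_filters <- function() {
  list(
    aquatic_ammonia = function(d) {
      keep <- rep(TRUE, nrow(d))
      if ("habitat" %in% names(d)) keep <- keep & grepl("aquatic|marine|fresh", tolower(d$habitat))
      if ("excretion" %in% names(d)) keep <- keep & tolower(d$excretion) == "ammonia"
      keep
    },
    tp_at_most_3 = function(d) {
      if (!"tp" %in% names(d)) return(rep(TRUE, nrow(d)))
      d$tp <= 3
    },
    drop_vegetable_meal_bream = function(d) {
      !(grepl("Acanthopagrus butcheri", d$species, ignore.case = TRUE) &
          ("diet" %in% names(d) & grepl("vegetable", tolower(d$diet))))
    }
  )
}

.experiment_aa_cols <- function(experiments) {
  cols <- names(experiments)[vapply(names(experiments), is_aa_name, logical(1))]
  if (length(cols) == 0L) {
    stop("no amino-acid columns found in the experiment table", call. = FALSE)
  }
  cols
}

#' Aggregate trophic discrimination factors from feeding studies
#'
#' Per-amino-acid arithmetic mean and SD of \eqn{\Delta^{15}N} across
#' feeding experiments, for all experiments or restricted to metazoan or
#' protozoan consumers. The experiment is the unit of averaging (replicates
#' are assumed already pooled per experiment); missing values are skipped.
#' Amino acids with fewer than two experiments in the subset are omitted
#' with a warning.
#'
#' @inheritParams filter_experiments
#' @param subset `"all"`, `"metazoa"`, or `"protozoa"`.
#' @return data frame with columns `aa`, `n`, `mean`, `sd` (per mil).
#' @export
aggregate_tdfs <- function(experiments, subset = c("all", "metazoa", "protozoa")) {
  subset <- match.arg(subset)
  if (subset != "all") {
    experiments <- experiments[tolower(experiments$group) == subset, , drop = FALSE]
  }
  cols <- .experiment_aa_cols(experiments)
  rows <- lapply(cols, function(cl) {
    v <- as.numeric(experiments[[cl]])
    v <- v[!is.na(v)]
    if (length(v) < 2L) {
      warning("amino acid ", aa_canonical(cl), " has fewer than 2 experiments ",
              "in subset '", subset, "'; omitted", call. = FALSE)
      return(NULL)
    }
    data.frame(aa = aa_canonical(cl), n = length(v), mean = mean(v),
               sd = stats::sd(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare discrimination between protozoa and metazoa
#'
#' Welch's two-sample (heteroskedastic, two-tailed) t-test of an amino
#' acid's \eqn{\Delta^{15}N} values between protozoan and metazoan feeding
#' experiments.
#'
#' @inheritParams filter_experiments
#' @param amino_acid amino-acid name (aliases accepted).
#' @return the p-value.
#' @export
compare_groups <- function(experiments, amino_acid) {
  aa <- aa_canonical(amino_acid)
  cols <- .experiment_aa_cols(experiments)
  col <- cols[aa_canonical(cols) == aa]
  if (length(col) != 1L) stop("amino acid ", aa, " not in experiment table", call. = FALSE)
  grp <- tolower(experiments$group)
  v <- as.numeric(experiments[[col]])
  a <- v[grp == "protozoa" & !is.na(v)]
  b <- v[grp == "metazoa" & !is.na(v)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 experiments per group for ", aa, call. = FALSE)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Classify a tracer from the protozoa-vs-metazoa comparison
#'
#' Tracers whose discrimination differs significantly between protozoa and
#' metazoa are modelled with separate TDFs (`variable`); tracers with no
#' evidence of a difference use a single pooled TDF (`constant`); marginal
#' cases are flagged for exclusion.
#'
#' @param p_value p-value from [compare_groups()].
#' @param thresholds length-2 numeric `(significant, marginal)`.
#' @return `"variable"` (p below the first threshold), `"marginal"`
#'   (between thresholds; exclusion recommended), or `"constant"`.
#' @export
classify_tracer <- function(p_value, thresholds = c(0.05, 0.1)) {
  stopifnot(length(p_value) == 1L, p_value >= 0, p_value <= 1)
  if (p_value < thresholds[1]) "variable"
  else if (p_value <= thresholds[2]) "marginal"
  else "constant"
}

#' Regression-based trophic discrimination factor
#'
#' Estimates an amino acid's \eqn{\Delta^{15}N} from wild (field) data by
#' regressing its Phe-normalised value against a trophic-position proxy.
#' With \eqn{y = \delta^{15}N_{AA} - \delta^{15}N_{Phe}} and
#' \eqn{x = \delta^{15}N_{ref} - \delta^{15}N_{Phe}} (reference Glx or Ala,
#' whose TDFs are comparatively well constrained), an ordinary least squares
#' fit of `y ~ x + location` (location as a non-interacting covariate)
#' yields slope \eqn{m} and
#' \deqn{\Delta^{15}N_{AA} = m \cdot TDF_{ref} + \Delta^{15}N_{Phe}.}
#' Uncertainty combines, in first-order quadrature, the slope standard
#' error scaled by `tdf_ref`, the reference-TDF uncertainty scaled by the
#' slope, and the Phe TDF uncertainty:
#' \eqn{\sigma^2 = (se_m TDF_{ref})^2 + (m\,\sigma_{ref})^2 + \sigma_{Phe}^2}.
#'
#' @param data data frame with a `location` column (optional) and
#'   per-amino-acid delta15N columns including `Phe`, the reference tracer,
#'   and `amino_acid`; at least 10 rows.
#' @param amino_acid target amino acid.
#' @param reference `"Glx"` or `"Ala"`.
#' @param tdf_ref TDF of the reference tracer (per mil).
#' @param delta_phe TDF of Phe (per mil; 0.3 in the default registry).
#' @param sd_tdf_ref,sd_delta_phe their SDs (default 0).
#' @return a list of class `omsm_regression_tdf`: `aa`, `slope`, `slope_se`,
#'   `delta` (derived TDF, per mil), `sd` (propagated SD), `reference`,
#'   `r_squared`, `f_statistic`, `df`, and the `lm` fit.
#' @export
regression_tdf <- function(data, amino_acid, reference = c("Glx", "Ala"),
                           tdf_ref, delta_phe, sd_tdf_ref = 0,
                           sd_delta_phe = 0) {
  reference <- match.arg(reference)
  aa <- aa_canonical(amino_acid)
  cols <- names(data)
  canon <- suppressWarnings(aa_canonical(cols, error = FALSE))
  pick <- function(target) {
    cl <- cols[!is.na(canon) & canon == target]
    if (length(cl) != 1L) stop("column for ", target, " not found", call. = FALSE)
    as.numeric(data[[cl]])
  }
  y <- pick(aa) - pick("Phe")
  x <- pick(reference) - pick("Phe")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10L) stop("regression_tdf needs at least 10 observations", call. = FALSE)
  df_fit <- data.frame(y = y[ok], x = x[ok])
  has_loc <- "location" %in% cols && length(unique(data$location[ok])) > 1L
  if (has_loc) {
    df_fit$location <- factor(data$location[ok])
    fit <- stats::lm(y ~ x + location, data = df_fit)
  } else {
    fit <- stats::lm(y ~ x, data = df_fit)
  }
  sm <- summary(fit)
  if (!"x" %in% rownames(sm$coefficients)) {
    stop("rank-deficient design: slope not estimable", call. = FALSE)
  }
  m <- sm$coefficients["x", "Estimate"]
  se <- sm$coefficients["x", "Std. Error"]
  delta <- m * tdf_ref + delta_phe
  sd <- sqrt((se * tdf_ref)^2 + (m * sd_tdf_ref)^2 + sd_delta_phe^2)
  structure(list(aa = aa, slope = m, slope_se = se, delta = delta, sd = sd,
                 reference = reference, tdf_ref = tdf_ref,
                 delta_phe = delta_phe,
                 r_squared = sm$r.squared,
                 f_statistic = unname(sm$fstatistic[1]),
                 df = unname(sm$fstatistic[2:3]), fit = fit),
            class = "omsm_regression_tdf")
}

#' @export
print.omsm_regression_tdf <- function(x, ...) {
  cat(sprintf("<regression TDF> %s vs %s: slope %.3f +/- %.3f, Delta15N = %.2f +/- %.2f permil (R2 = %.2f)\n",
              x$aa, x$reference, x$slope, x$slope_se, x$delta, x$sd, x$r_squared))
  invisible(x)
}
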