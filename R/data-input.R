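#' Construct a source dataset
#'
#' Wraps a wide table of replicate tracer measurements for each candidate
#' basal organic-matter source group. Columns: `sample_id`, `group`, then one
#' column per amino acid (delta15N, per mil); amino-acid column names are
#' canonicalised (aliases such as `Glu` become `Glx`).
#'
#' @param data data frame in the wide layout above.
#' @return an object of class `omsm_sources`: list with `data` (canonicalised
#'   data frame), `groups` (character), and `tracers` (amino acids present).
#' @seealso [read_sources()], [simulate_sources()]
#' @export
omsm_sources <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(data))) {
    stop("source table must have columns sample_id and group", call. = FALSE)
  }
  aa_cols <- setdiff(names(data), need)
  if (length(aa_cols) == 0L) stop("source table has no tracer columns", call. = FALSE)
  canon <- aa_canonical(aa_cols)
  names(data)[match(aa_cols, names(data))] <- canon
  for (a in canon) {
    v <- data[[a]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(as.character(v))))
      if (length(bad)) {
        stop("non-numeric value in source column ", a, ", row ", bad[1],
             call. = FALSE)
      }
      v <- vn
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop("missing or non-finite value in source column ", a, ", row ",
           which(is.na(v) | !is.finite(v))[1], call. = FALSE)
    }
    data[[a]] <- v
  }
  groups <- unique(as.character(data$group))
  if (length(groups) == 0L || nrow(data) == 0L) {
    stop("source table is empty", call. = FALSE)
  }
  structure(list(data = data, groups = groups, tracers = canon),
            class = "omsm_sources")
}

#' Empirical per-group source statistics
#'
#' @param sources an `omsm_sources` object.
#' @param tracers amino acids to include (default: all present).
#' @return `source_means` / `source_sds`: a tracer-by-group numeric matrix.
#' @export
source_means <- function(sources, tracers = sources$tracers) {
  .source_stat(sources, tracers, mean)
}

#' @rdname source_means
#' @export
source_sds <- function(sources, tracers = sources$tracers) {
  .source_stat(sources, tracers, stats::sd)
}

.source_stat <- function(sources, tracers, fn) {
  tracers <- aa_canonical(tracers)
  missing <- setdiff(tracers, sources$tracers)
  if (length(missing)) {
    stop("tracer(s) absent from source data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- sapply(sources$groups, function(g) {
    sub <- sources$data[sources$data$group == g, tracers, drop = FALSE]
    apply(as.matrix(sub), 2, fn)
  })
  out <- matrix(out, nrow = length(tracers),
                dimnames = list(tracers, sources$groups))
  out
}

#' @export
print.omsm_sources <- function(x, ...) {
  cat("<omsm_sources> ", length(x$groups), " group(s), ",
      nrow(x$data), " replicate(s), tracers: ",
      paste(x$tracers, collapse = ", "), "\n", sep = "")
  print(table(x$data$group))
  invisible(x)
}

#' Construct consumer samples
#'
#' Wraps measured consumer tracer values and their per-tracer analytical
#' standard deviations. Input is wide: `sample_id`, one column per amino
#' acid, and optionally `<AA>_sd` columns giving the analytical SD for that
#' tracer; tracers without an SD column take `default_alpha`.
#'
#' @param data wide data frame as above.
#' @param default_alpha analytical SD (per mil) used where no `_sd` column is
#'   given. The default, 0.5 per mil, is a typical uncertainty for amino-acid
#'   nitrogen isotope measurements.
#' @return an object of class `omsm_consumers`: list with `ids`, `values`
#'   (tracer x sample matrix, per mil) and `alpha` (matching SD matrix).
#' @seealso [read_consumers()], [simulate_consumers()]
#' @export
omsm_consumers <- function(data, default_alpha = 0.5) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(data)) {
    stop("consumer table must have a sample_id column", call. = FALSE)
  }
  if (nrow(data) == 0L) stop("consumer table is empty", call. = FALSE)
  other <- setdiff(names(data), "sample_id")
  sd_cols <- grep("_sd$", other, value = TRUE)
  aa_cols <- setdiff(other, sd_cols)
  aa_cols <- aa_cols[vapply(aa_cols, is_aa_name, logical(1))]
  if (length(aa_cols) == 0L) stop("consumer table has no tracer columns", call. = FALSE)
  canon <- aa_canonical(aa_cols)
  ids <- as.character(data$sample_id)

  values <- t(as.matrix(data[, aa_cols, drop = FALSE]))
  rownames(values) <- canon
  colnames(values) <- ids
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(is.na(values) | !is.finite(values), arr.ind = TRUE)[1, ]
    stop("missing or non-finite consumer value for ", rownames(values)[bad[1]],
         ", sample ", ids[bad[2]], call. = FALSE)
  }

  alpha <- matrix(default_alpha, nrow = length(canon), ncol = length(ids),
                  dimnames = dimnames(values))
  for (sc in sd_cols) {
    base <- sub("_sd$", "", sc)
    if (!is_aa_name(base)) next
    alpha[aa_canonical(base), ] <- as.numeric(data[[sc]])
  }
  if (anyNA(alpha) || any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("analytical SDs (alpha) must be finite and > 0 for all tracers",
         call. = FALSE)
  }
  structure(list(ids = ids, values = values, alpha = alpha),
            class = "omsm_consumers")
}

#' @export
print.omsm_consumers <- function(x, ...) {
  cat("<omsm_consumers> ", length(x$ids), " sample(s), tracers: ",
      paste(rownames(x$values), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a model configuration against data
#'
#' Structural validation run before model building. Errors (model cannot be
#' fit): overlapping mixing/trophic tracer sets, source groups with fewer
#' than two replicates, modelled tracers missing from the source or consumer
#' data, missing or non-positive analytical SDs. Warnings (model runs but
#' results may be weak): source groups with fewer than three replicates, and
#' fewer total modelled tracers than `n_sources + 1` (the number needed to
#' fully constrain mixing coefficients plus trophic steps).
#'
#' Validation is pure: its inputs are never modified.
#'
#' @param config an [omsm_config()].
#' @param sources an [omsm_sources()] dataset.
#' @param consumers an [omsm_consumers()] object.
#' @return a list of class `omsm_validation` with character vectors `errors`
#'   and `warnings` and logical `ok` (`TRUE` when no errors).
#' @export
validate_config <- function(config, sources, consumers) {
  stopifnot(inherits(config, "omsm_config"), inherits(sources, "omsm_sources"),
            inherits(consumers, "omsm_consumers"))
  if (length(sources$groups) == 0L) stop("no source groups", call. = FALSE)
  if (length(consumers$ids) == 0L) stop("no consumer samples", call. = FALSE)

  errors <- character(0)
  warnings <- character(0)
  used <- config$tracers$aa

  reps <- table(sources$data$group)
  few <- names(reps)[reps < 2]
  if (length(few)) {
    errors <- c(errors, paste0("source group(s) with fewer than 2 replicates: ",
                               paste(few, collapse = ", ")))
  }
  small <- names(reps)[reps == 2]
  if (length(small)) {
    warnings <- c(warnings, paste0("source group(s) with only 2 replicates ",
                                   "(three or more are preferred): ",
                                   paste(small, collapse = ", ")))
  }

  miss_src <- setdiff(used, sources$tracers)
  if (length(miss_src)) {
    errors <- c(errors, paste0("modelled tracer(s) missing from source data: ",
                               paste(miss_src, collapse = ", ")))
  }
  miss_con <- setdiff(used, rownames(consumers$values))
  if (length(miss_con)) {
    errors <- c(errors, paste0("modelled tracer(s) missing from consumer data: ",
                               paste(miss_con, collapse = ", ")))
  }

  n_src <- length(sources$groups)
  if (length(used) < n_src + 1) {
    warnings <- c(warnings, paste0(
      "only ", length(used), " modelled tracer(s) for ", n_src,
      " sources; at least n_sources + 1 = ", n_src + 1,
      " independent tracers are needed to fully constrain the model"))
  }

  structure(list(errors = errors, warnings = warnings,
                 ok = length(errors) == 0L),
            class = "omsm_validation")
}

#' @export
print.omsm_validation <- function(x, ...) {
  cat("<omsm_validation> ", if (x$ok) "OK" else "FAILED", "\n", sep = "")
  if (length(x$errors)) cat("errors:\n", paste0("  - ", x$errors, "\n"), sep = "")
  if (length(x$warnings)) cat("warnings:\n", paste0("  - ", x$warnings, "\n"), sep = "")
  invisible(x)
}
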