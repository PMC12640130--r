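#' Read source data from CSV
#'
#' Expects a wide CSV with columns `sample_id`, `group`, then one column per
#' amino acid (delta15N, per mil). Amino-acid headers are canonicalised
#' (`Glu` is parsed as `Glx`, etc.); unknown headers are an error. Blank or
#' non-numeric cells are reported with their row and column.
#'
#' @param path CSV file path.
#' @return an [omsm_sources()] dataset.
#' @export
read_sources <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("malformed header in ", path,
         ": need columns sample_id and group", call. = FALSE)
  }
  aa_cols <- setdiff(names(df), c("sample_id", "group"))
  unknown <- aa_cols[!vapply(aa_cols, is_aa_name, logical(1))]
  if (length(unknown)) {
    stop("unknown amino-acid column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  omsm_sources(df)
}

#' @rdname read_sources
#' @param sources an `omsm_sources` dataset to write.
#' @export
write_sources <- function(sources, path) {
  out <- sources$data
  for (a in sources$tracers) {
    out[[a]] <- format(out[[a]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read consumer data from CSV
#'
#' Expects a wide CSV with `sample_id`, per-amino-acid value columns, and
#' optionally `<AA>_sd` columns carrying per-tracer analytical SDs; tracers
#' without an SD column take `default_alpha`. Extra non-amino-acid columns
#' (e.g. truth columns in a simulation table) are ignored.
#'
#' @param path CSV file path.
#' @param default_alpha analytical SD used where no `_sd` column is present.
#' @return an [omsm_consumers()] object.
#' @export
read_consumers <- function(path, default_alpha = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("malformed header in ", path, ": need a sample_id column", call. = FALSE)
  }
  keep <- c("sample_id",
            names(df)[vapply(names(df), function(nm) {
              is_aa_name(nm) || (grepl("_sd$", nm) && is_aa_name(sub("_sd$", "", nm)))
            }, logical(1))])
  omsm_consumers(df[, keep, drop = FALSE], default_alpha = default_alpha)
}

#' @rdname read_consumers
#' @param consumers an `omsm_consumers` object to write.
#' @export
write_consumers <- function(consumers, path) {
  df <- data.frame(sample_id = consumers$ids,
                   as.data.frame(t(consumers$values)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  asd <- as.data.frame(t(consumers$alpha))
  names(asd) <- paste0(rownames(consumers$alpha), "_sd")
  df <- cbind(df, asd)
  for (cl in setdiff(names(df), "sample_id")) {
    df[[cl]] <- format(df[[cl]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export / import posterior draws as long-format CSV
#'
#' Columns: `chain`, `iteration` (within chain), `parameter`, `value`.
#'
#' @param draws an `omsm_draws` object.
#' @param path CSV file path.
#' @return `write_draws` returns `path` invisibly; `read_draws` returns a
#'   lightweight `omsm_draws` object (draw matrix, chain index, and
#'   parameter metadata reconstructed from the names; diagnostics
#'   recomputed).
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "omsm_draws"))
  it <- stats::ave(draws$chain, draws$chain, FUN = seq_along)
  long <- data.frame(
    chain = rep(draws$chain, times = ncol(draws$mat)),
    iteration = rep(it, times = ncol(draws$mat)),
    parameter = rep(colnames(draws$mat), each = nrow(draws$mat)),
    value = as.vector(draws$mat))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  params <- unique(long$parameter)
  sub <- long[long$parameter == params[1], ]
  ord <- order(sub$chain, sub$iteration)
  chain <- sub$chain[ord]
  mat <- sapply(params, function(p) {
    s <- long[long$parameter == p, ]
    s$value[order(s$chain, s$iteration)]
  })
  mat <- matrix(mat, ncol = length(params), dimnames = list(NULL, params))
  fam <- sub("\\[.*$", "", params)
  labs <- regmatches(params, regexpr("\\[.*\\]", params))
  meta <- data.frame(parameter = params, family = fam,
                     tracer = NA_character_, group = NA_character_,
                     consumer = NA_character_, stringsAsFactors = FALSE)
  for (p in seq_along(params)) {
    if (length(labs) < p || is.na(labs[p]) || !nzchar(labs[p])) next
    parts <- strsplit(gsub("[][]", "", labs[p]), ",")[[1]]
    if (fam[p] == "f") {
      meta$group[p] <- parts[1]; meta$consumer[p] <- parts[2]
    } else if (fam[p] %in% c("FWL", "MTS", "PTS")) {
      meta$consumer[p] <- parts[1]
    } else if (fam[p] %in% c("mu_src", "sigma_src")) {
      meta$tracer[p] <- parts[1]; meta$group[p] <- parts[2]
    } else if (fam[p] == "mu_base") {
      meta$tracer[p] <- parts[1]; meta$consumer[p] <- parts[2]
    }
  }
  ess <- vapply(seq_len(ncol(mat)), function(j)
    as.numeric(coda::effectiveSize(mat[, j])), numeric(1))
  rhat <- apply_split_rhat(mat, chain)
  const <- apply(mat, 2, function(x) stats::var(x) == 0)
  diagnostics <- data.frame(parameter = params, rhat = rhat, ess = ess,
                            ok = (is.na(rhat) | rhat < 1.05) & (const | ess > 200),
                            stringsAsFactors = FALSE)
  structure(list(mat = mat, chain = chain, meta = meta,
                 diagnostics = diagnostics,
                 groups = unique(stats::na.omit(meta$group)),
                 consumer_ids = unique(stats::na.omit(meta$consumer)),
                 tracers = unique(stats::na.omit(meta$tracer)),
                 mcmc = NULL),
            class = "omsm_draws")
}

#' Run manifest
#'
#' Records everything needed to reproduce a run: input file paths with MD5
#' content hashes, a configuration snapshot, the seed, the package version,
#' and a timestamp.
#'
#' @param inputs named character vector of input file paths.
#' @param config an [omsm_config()] (or any serialisable list).
#' @param mcmc an [mcmc_config()] or `NULL`.
#' @param seed integer seed used for the run.
#' @return list of class `omsm_manifest`.
#' @export
run_manifest <- function(inputs = character(0), config = NULL, mcmc = NULL,
                         seed = NA_integer_) {
  hashes <- if (length(inputs)) {
    vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  } else {
    character(0)
  }
  structure(list(
    inputs = as.list(inputs),
    input_md5 = as.list(hashes),
    config = if (!is.null(config)) unclass(config[setdiff(names(config), "tdf")]) else NULL,
    tdf = if (!is.null(config)) as.data.frame(config$tdf) else NULL,
    mcmc = if (!is.null(mcmc)) unclass(mcmc) else NULL,
    seed = seed,
    package_version = as.character(utils::packageVersion("omsm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "omsm_manifest")
}

#' @rdname run_manifest
#' @param manifest an `omsm_manifest`.
#' @param path JSON output path.
#' @export
write_manifest <- function(manifest, path) {
  x <- unclass(manifest)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}
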