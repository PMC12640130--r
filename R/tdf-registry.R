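#' Default trophic discrimination factor registry
#'
#' Per-amino-acid nitrogen-isotope trophic discrimination factors (TDFs,
#' \eqn{\Delta^{15}N} in per mil) with separate values for metazoan and
#' protozoan trophic steps, compiled from controlled feeding studies of
#' ammonia-excreting aquatic consumers and from regression analysis of wild
#' plankton data.
#'
#' Discrimination classes:
#' \describe{
#'   \item{`conservative`}{no trophic fractionation; both TDFs and their SDs
#'     are zero.}
#'   \item{`constant`}{the same fractionation per protozoan and metazoan
#'     step (`delta_proto == delta_meta`). Values are means across all
#'     feeding experiments (metazoa and protozoa pooled).}
#'   \item{`variable`}{significantly different fractionation in protozoa
#'     versus metazoa; separate group means are used. The metazoan Thr value
#'     comes from regression analysis, which agrees with the feeding-study
#'     mean but carries less uncertainty.}
#' }
#'
#' Ile and Val are included for completeness (pooled-experiment values) but
#' their protozoan-versus-metazoan differences are only marginally
#' significant, so they are excluded from the default model configuration.
#'
#' @param treat_phe_conservative logical; if `TRUE` (default) phenylalanine
#'   is registered as a conservative tracer (TDF fixed at zero). Phe's
#'   empirical TDF (0.3 +/- 0.5 per mil) is small enough that treating it as
#'   conservative avoids propagating its uncertainty in short food webs. Set
#'   `FALSE` to keep the empirical value as a constant-class TDF.
#' @return a data frame of class `omsm_tdf` with columns `aa`, `class`,
#'   `delta_meta`, `sd_meta`, `delta_proto`, `sd_proto` (all TDF columns in
#'   per mil).
#' @examples
#' tdf <- tdf_default()
#' tdf[tdf$aa == "Glx", ]
#' @export
tdf_default <- function(treat_phe_conservative = TRUE) {
  tab <- data.frame(
    aa         = c("Ala", "Pro", "Gly", "Ser", "Phe", "Lys",
                   "Glx", "Asx", "Leu", "Thr", "Ile", "Val"),
    class      = c(rep("constant", 6), rep("variable", 4), "constant", "constant"),
    delta_meta = c(6.3, 5.8, 2.9, 2.6, 0.3, 1.2,  8.0, 5.7, 5.6, -5.9, 4.6, 3.9),
    sd_meta    = c(2.6, 1.7, 3.1, 3.2, 0.5, 1.2,  1.7, 1.9, 2.4,  1.5, 3.2, 2.8),
    stringsAsFactors = FALSE
  )
  tab$delta_proto <- tab$delta_meta
  tab$sd_proto <- tab$sd_meta
  var_rows <- match(c("Glx", "Asx", "Leu", "Thr"), tab$aa)
  tab$delta_proto[var_rows] <- c(0.5, 0.8, 1.4, -2.0)
  tab$sd_proto[var_rows] <- c(1.0, 1.4, 0.6, 0.6)
  if (treat_phe_conservative) {
    phe <- tab$aa == "Phe"
    tab$class[phe] <- "conservative"
    tab[phe, c("delta_meta", "sd_meta", "delta_proto", "sd_proto")] <- 0
  }
  validate_tdf(tab)
}

#' Validate (and coerce) a TDF registry table
#'
#' Checks the structural invariants of a TDF registry: canonical amino-acid
#' names, known discrimination classes, non-negative SDs, conservative rows
#' identically zero, and constant rows with equal metazoan and protozoan
#' parameters.
#'
#' @param tab data frame with columns `aa`, `class`, `delta_meta`, `sd_meta`,
#'   `delta_proto`, `sd_proto`.
#' @return the table with class `omsm_tdf`, amino-acid names canonicalised.
#' @export
validate_tdf <- function(tab) {
  needed <- c("aa", "class", "delta_meta", "sd_meta", "delta_proto", "sd_proto")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("TDF table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  tab$aa <- aa_canonical(tab$aa)
  if (anyDuplicated(tab$aa)) {
    stop("TDF table has duplicated amino acids: ",
         paste(unique(tab$aa[duplicated(tab$aa)]), collapse = ", "), call. = FALSE)
  }
  bad_class <- setdiff(tab$class, c("conservative", "constant", "variable"))
  if (length(bad_class)) {
    stop("unknown discrimination class(es): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  num <- c("delta_meta", "sd_meta", "delta_proto", "sd_proto")
  for (cl in num) {
    tab[[cl]] <- as.numeric(tab[[cl]])
    if (anyNA(tab[[cl]]) || any(!is.finite(tab[[cl]]))) {
      stop("non-finite values in TDF column ", cl, call. = FALSE)
    }
  }
  if (any(tab$sd_meta < 0) || any(tab$sd_proto < 0)) {
    stop("TDF standard deviations must be >= 0", call. = FALSE)
  }
  cons <- tab$class == "conservative"
  if (any(abs(as.matrix(tab[cons, num])) > 0)) {
    stop("conservative tracers must have all TDF parameters equal to zero",
         call. = FALSE)
  }
  const <- tab$class == "constant"
  if (any(tab$delta_proto[const] != tab$delta_meta[const]) ||
      any(tab$sd_proto[const] != tab$sd_meta[const])) {
    stop("constant-class tracers must have identical metazoan and protozoan ",
         "TDF parameters", call. = FALSE)
  }
  rownames(tab) <- NULL
  class(tab) <- c("omsm_tdf", "data.frame")
  tab
}

#' Look up one tracer's TDF parameters
#'
#' @param tdf an `omsm_tdf` registry.
#' @param aa a single amino-acid name (aliases accepted).
#' @return a one-row data frame (`aa`, `class`, `delta_meta`, `sd_meta`,
#'   `delta_proto`, `sd_proto`).
#' @export
tdf_lookup <- function(tdf, aa) {
  aa <- aa_canonical(aa)
  stopifnot(length(aa) == 1L)
  row <- tdf[tdf$aa == aa, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("amino acid ", aa, " is not in the TDF registry", call. = FALSE)
  }
  rownames(row) <- NULL
  row
}

#' Read / write a TDF registry as CSV
#'
#' The on-disk format has columns `aa`, `class`, `delta_meta`, `sd_meta`,
#' `delta_proto`, `sd_proto`. Values round-trip exactly (full double
#' precision is written).
#'
#' @param path file path.
#' @return `read_tdf` returns an `omsm_tdf` table; `write_tdf` returns `path`
#'   invisibly.
#' @export
read_tdf <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tdf(tab)
}

#' @rdname read_tdf
#' @param tdf an `omsm_tdf` registry to write.
#' @export
write_tdf <- function(tdf, path) {
  tdf <- validate_tdf(tdf)
  out <- tdf
  for (cl in c("delta_meta", "sd_meta", "delta_proto", "sd_proto")) {
    out[[cl]] <- format(out[[cl]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
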