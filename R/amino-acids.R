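#' Canonical amino-acid tracer names
#'
#' Amino-acid tracers are identified by three-letter codes. Because acid/amide
#' pairs hydrolyse together during sample preparation, glutamic acid and
#' glutamine are reported jointly as `Glx`, and aspartic acid and asparagine
#' as `Asx`; `Glu`, `Gln`, `Asp`, and `Asn` are accepted as aliases. Matching
#' is case-insensitive and full names (e.g. `"alanine"`) are also recognised.
#'
#' @param x character vector of amino-acid names or aliases.
#' @param error if `TRUE` (default) unknown names raise an error; otherwise
#'   they are returned as `NA`.
#' @return character vector of canonical codes (`Ala`, `Asx`, `Gly`, `Glx`,
#'   `Ile`, `Leu`, `Lys`, `Phe`, `Pro`, `Ser`, `Thr`, `Val`).
#' @examples
#' aa_canonical(c("glu", "ASP", "phenylalanine"))
#' @export
aa_canonical <- function(x, error = TRUE) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.aa_alias_table[key])
  if (error && anyNA(out) && length(x)) {
    bad <- unique(x[is.na(out)])
    stop("unknown amino-acid name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

.aa_codes <- c("Glx", "Asx", "Ala", "Ile", "Leu", "Pro", "Val", "Gly", "Ser",
               "Phe", "Lys", "Thr")

.aa_alias_table <- local({
  full <- c(
    glx = "Glx", glu = "Glx", gln = "Glx",
    "glutamic acid" = "Glx", glutamate = "Glx", glutamine = "Glx",
    asx = "Asx", asp = "Asx", asn = "Asx",
    "aspartic acid" = "Asx", aspartate = "Asx", asparagine = "Asx",
    ala = "Ala", alanine = "Ala",
    ile = "Ile", isoleucine = "Ile",
    leu = "Leu", leucine = "Leu",
    pro = "Pro", proline = "Pro",
    val = "Val", valine = "Val",
    gly = "Gly", glycine = "Gly",
    ser = "Ser", serine = "Ser",
    phe = "Phe", phenylalanine = "Phe",
    lys = "Lys", lysine = "Lys",
    thr = "Thr", threonine = "Thr"
  )
  full
})

#' @keywords internal
is_aa_name <- function(x) !is.na(unname(.aa_alias_table[tolower(trimws(x))]))
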