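## Shared tabular I/O with strict schemas, FASTA reading for the
## intrinsic-rate calculator, and the two-variant comparison report.

## column schemas for the tables the pipeline reads and writes
.schemas <- list(
  rates = c("residue_id", "r1", "r1_sd", "r2", "r2_sd", "noe", "noe_sd"),
  intensity = c("residue_id", "delay_s", "intensity"),
  modelfree = c("residue_id", "model", "s2", "s2_sd", "te", "rex",
                "rex_sd", "chi2", "bic"),
  cpmg = c("residue_id", "field_1h_hz", "nu_cpmg_hz", "intensity"),
  dispersion = c("residue_id", "field_1h", "dw", "r20", "chi2"),
  hdx = c("residue_id", "time_s", "intensity", "mode"),
  hdx_result = c("residue_id", "ke", "ke_sd", "lifetime", "kint",
                 "protection", "dg", "lifetime_class"),
  ddg = c("residue_id", "p_ref", "p_var", "ddg_kj_mol")
)

#' Read a tab-separated result or input table with schema checking
#'
#' Column names are matched by header (order-free, case-sensitive);
#' missing required columns raise an error naming the expected schema.
#' The literal token \code{NA} is the missing-value sentinel.
#'
#' @param path file path.
#' @param schema one of \code{names(ProtDynamics:::.schemas)} or a
#'   character vector of required column names.
#' @return data.frame with columns in schema order.
#' @export
readTable <- function(path, schema) {
  cols <- if (is.character(schema) && length(schema) == 1L &&
              schema %in% names(.schemas)) .schemas[[schema]] else schema
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), "; expected schema: ",
         paste(cols, collapse = ", "))
  extra <- setdiff(names(tab), cols)
  if (length(extra))
    stop("file ", path, " has unknown column(s): ",
         paste(extra, collapse = ", "), "; expected schema: ",
         paste(cols, collapse = ", "))
  tab[, cols, drop = FALSE]
}

#' Write a table in the package's tab-separated format
#'
#' Floats are serialized at full precision (round-trip stable);
#' missing values as the token \code{NA}.
#'
#' @param tab data.frame.
#' @param path output path.
#' @param schema optional schema name or column vector to validate
#'   against before writing.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(tab, path, schema = NULL) {
  if (!is.null(schema)) {
    cols <- if (is.character(schema) && length(schema) == 1L &&
                schema %in% names(.schemas)) .schemas[[schema]] else schema
    miss <- setdiff(cols, names(tab))
    if (length(miss))
      stop("table is missing required column(s): ",
           paste(miss, collapse = ", "))
    tab <- tab[, cols, drop = FALSE]
  }
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a single protein sequence from a FASTA file
#'
#' Thin wrapper over Biostrings for the one-letter sequence consumed by
#' \code{\link{intrinsicRate}}.
#'
#' @param path FASTA file path.
#' @return one-letter character string (first record).
#' @export
readFastaSequence <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    as.character(Biostrings::readAAStringSet(path))[[1]]
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^[;>]", lines)]
    gsub("\\s", "", paste(lines, collapse = ""))
  }
}

#' Compare the per-residue dynamics of two variants
#'
#' Joins per-residue results of a reference and a variant into one
#' comparison table with deltas, and summarizes the contrast: mean S2
#' per variant, exchange-significance counts, global (kex, pB) pairs,
#' the mean-lifetime ratio and, where protection factors are present,
#' per-residue ddG. Residues present in only one input are listed in
#' the \code{unmatched} element and excluded from deltas.
#'
#' @param ref,var lists with any of: \code{modelFree} (data.frame with
#'   residue_id, s2, rex), \code{hdx} (data.frame with residue_id,
#'   lifetime and optionally P, dg), \code{kex}, \code{pb} (scalars from
#'   the global dispersion fit).
#' @param temperature K, for the ddG computed from protection factors.
#' @return list with \code{table}, \code{unmatched}, \code{summary}.
#' @export
compareVariants <- function(ref, var, temperature = 298.15) {
  tabs <- list()
  unmatched <- list()
  joinOn <- function(a, b, cols, suff) {
    shared <- intersect(a$residue_id, b$residue_id)
    if (!length(shared)) return(NULL)
    m <- merge(a[, c("residue_id", cols)], b[, c("residue_id", cols)],
               by = "residue_id", suffixes = suff)
    m
  }
  if (!is.null(ref$modelFree) && !is.null(var$modelFree)) {
    m <- joinOn(ref$modelFree, var$modelFree,
                intersect(c("s2", "rex"), names(ref$modelFree)),
                c("_ref", "_var"))
    if (is.null(m)) stop("model-free inputs share no residues")
    if (all(c("s2_ref", "s2_var") %in% names(m)))
      m$delta_s2 <- m$s2_var - m$s2_ref
    tabs$modelFree <- m
    unmatched$modelFree <- list(
      ref_only = setdiff(ref$modelFree$residue_id, var$modelFree$residue_id),
      var_only = setdiff(var$modelFree$residue_id, ref$modelFree$residue_id))
  }
  if (!is.null(ref$hdx) && !is.null(var$hdx)) {
    cols <- intersect(c("lifetime", "P", "dg"), names(ref$hdx))
    m <- joinOn(ref$hdx, var$hdx, cols, c("_ref", "_var"))
    if (is.null(m)) stop("HDX inputs share no residues")
    if (all(c("P_ref", "P_var") %in% names(m)))
      m$ddg_kj_mol <- ddgBetweenVariants(m$P_var, m$P_ref, temperature)
    tabs$hdx <- m
    unmatched$hdx <- list(
      ref_only = setdiff(ref$hdx$residue_id, var$hdx$residue_id),
      var_only = setdiff(var$hdx$residue_id, ref$hdx$residue_id))
  }
  if (!length(tabs)) stop("no comparable components in the two inputs")
  summary <- list()
  if (!is.null(tabs$modelFree)) {
    summary$mean_s2_ref <- mean(tabs$modelFree$s2_ref, na.rm = TRUE)
    summary$mean_s2_var <- mean(tabs$modelFree$s2_var, na.rm = TRUE)
  }
  if (!is.null(ref$kex) && !is.null(var$kex)) {
    summary$kex_ref <- ref$kex; summary$kex_var <- var$kex
    summary$pb_ref <- ref$pb; summary$pb_var <- var$pb
  }
  if (!is.null(tabs$hdx) &&
      all(c("lifetime_ref", "lifetime_var") %in% names(tabs$hdx))) {
    summary$lifetime_ratio <-
      mean(tabs$hdx$lifetime_ref, na.rm = TRUE) /
      mean(tabs$hdx$lifetime_var, na.rm = TRUE)
  }
  list(table = tabs, unmatched = unmatched, summary = summary)
}
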