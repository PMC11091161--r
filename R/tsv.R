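# Plain-text output surface: TSV writers with fixed 6-significant-digit
# float formatting so repeated runs are byte-identical.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write a score matrix as TSV (header row and column of structure ids)
#' @param m a `locohd_score_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix_tsv <- function(m, path) {
  lines <- c(paste(c("id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-residue score table as TSV
#' @param tab data frame (chain, resnum, icode, resname, locohd, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_residue_table_tsv <- function(tab, path) {
  num <- vapply(tab, is.numeric, TRUE) & !names(tab) %in% "resnum"
  out <- tab
  out[num] <- lapply(tab[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an external per-residue score table
#'
#' Expects TSV with columns `chain`, `resnum`, `icode`, `score` (e.g. an
#' externally computed lDDT column); extra columns are carried through.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_external_scores <- function(path) {
  if (!file.exists(path)) stop_parse("external score file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chain", "resnum", "score")
  if (!all(needed %in% names(tab))) {
    stop_parse("external score table must have columns %s",
               paste(needed, collapse = ", "))
  }
  if (!"icode" %in% names(tab)) tab$icode <- ""
  tab$icode[is.na(tab$icode)] <- ""
  tab
}
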