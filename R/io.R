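# Readers and writers for the pipeline's plain-text formats: ORF FASTA,
# tRNA pool / s-value / expression / library TSVs, and commented TSV output.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an ORF set from FASTA
#'
#' Gene ids are the first whitespace-delimited token of each description
#' line. With `validate = TRUE` every sequence is checked as an in-frame ORF
#' (length multiple of 3, unambiguous bases, no internal stop) and the error
#' names the offending gene.
#'
#' @param path FASTA file of in-frame coding sequences.
#' @param validate Check each sequence on read? Default `TRUE`.
#' @return Tibble with `id`, `seq`.
#' @export
read_orf_fasta <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop("failed to parse FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop("no sequences in FASTA: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  out <- tibble::tibble(id = ids, seq = unname(as.character(set)))
  check_orf_tbl(out)
  if (validate) {
    for (i in seq_len(nrow(out))) split_codons(out$seq[i], out$id[i])
  }
  out
}

#' Write sequences as FASTA
#'
#' @param orfs Tibble with `id` (or `variant_id`) and `seq`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  id_col <- if ("variant_id" %in% names(orfs)) "variant_id" else "id"
  set <- Biostrings::DNAStringSet(stats::setNames(orfs$seq, orfs[[id_col]]))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

read_checked_tsv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  tbl <- tryCatch(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) stop("failed to parse ", what, " '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    stop(what, " '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Read a tRNA pool TSV
#'
#' Columns: `anticodon` (3-letter RNA string, unique), `copy_number`
#' (non-negative integer). Lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @return Validated tibble.
#' @export
read_trna_pool <- function(path) {
  check_trna_pool(read_checked_tsv(path, c("anticodon", "copy_number"),
                                   "tRNA pool"))
}

#' Read a pairing-class s-value TSV
#'
#' Columns: `pairing_class`, `s` (in \[0, 1\]).
#'
#' @param path TSV file.
#' @return Validated tibble.
#' @export
read_s_values <- function(path) {
  check_s_values(read_checked_tsv(path, c("pairing_class", "s"), "s-value table"))
}

#' Read a gene expression level TSV
#'
#' Columns: `gene_id`, `mrna_level` (non-negative, arbitrary units).
#'
#' @param path TSV file.
#' @return Tibble.
#' @export
read_expression_levels <- function(path) {
  tbl <- read_checked_tsv(path, c("gene_id", "mrna_level"), "expression table")
  if (any(tbl$mrna_level < 0, na.rm = TRUE)) {
    stop("expression table '", path, "' has negative mRNA levels",
         call. = FALSE)
  }
  tbl
}

#' Read a library measurement table, joining variant sequences
#'
#' The TSV carries `variant_id`, `protein_abundance`, `od` and optionally
#' `folding_energy`; sequences come from a FASTA keyed by the same variant
#' ids. Every measured variant must have a sequence.
#'
#' @param path Measurement TSV.
#' @param fasta FASTA of variant coding sequences.
#' @return Library tibble ready for the analysis functions.
#' @export
read_library_table <- function(path, fasta) {
  tbl <- read_checked_tsv(path, c("variant_id", "protein_abundance", "od"),
                          "library table")
  seqs <- read_orf_fasta(fasta)
  missing <- setdiff(tbl$variant_id, seqs$id)
  if (length(missing) > 0L) {
    stop("variants without sequences in '", fasta, "': ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(tbl,
                          dplyr::rename(seqs, variant_id = "id"),
                          by = "variant_id")
  check_library_tbl(dplyr::relocate(out, "variant_id", "seq"))
}

#' Write a result table as TSV with a commented header
#'
#' Writes `# `-prefixed comment lines (units and conventions; codon indices
#' are 1-based throughout) followed by a plain tab-separated table.
#'
#' @param tbl Data frame to write.
#' @param path Output file.
#' @param comments Character vector of header comment lines.
#' @return The path, invisibly.
#' @export
write_result_tsv <- function(tbl, path, comments = character()) {
  comments <- c(comments, "coordinates are 1-based codon indices")
  writeLines(paste0("# ", comments), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
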