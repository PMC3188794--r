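# Genetic-code constants and codon-level sequence utilities.
# Codons are handled in the DNA alphabet throughout (the RNA codon
# UCA is TCA here); anticodons, living on tRNA, stay in the RNA alphabet.

#' The 61 sense codons
#'
#' Returns the 61 sense codons of the standard genetic code in the DNA
#' alphabet, alphabetically ordered. Stop codons (TAA, TAG, TGA) are excluded
#' everywhere in this package: from codon counts, usage profiles and gene
#' lengths.
#'
#' @return Character vector of length 61.
#' @export
#' @examples
#' length(sense_codons())
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

stop_codons <- function() c("TAA", "TAG", "TGA")

#' Amino acid encoded by each sense codon
#'
#' @param codons Character vector of DNA codons.
#' @return Character vector of one-letter amino-acid codes.
#' @export
codon_amino_acid <- function(codons = sense_codons()) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# synonyms[[aa]] = character vector of codons encoding aa
synonymous_codons <- function() {
  split(sense_codons(), codon_amino_acid(sense_codons()))
}

#' Split an in-frame coding sequence into codons
#'
#' Validates the sequence as an in-frame ORF: length a multiple of three,
#' unambiguous A/C/G/T alphabet, no internal stop codons, at least one sense
#' codon. A single terminal stop codon, if present, is trimmed (stop codons
#' are excluded from all downstream counts and lengths).
#'
#' @param seq A single DNA string.
#' @param id Identifier used in error messages.
#' @return Character vector of sense codons.
#' @export
#' @examples
#' split_codons("ATGAAACGTTAA")
split_codons <- function(seq, id = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("'", id, "': empty or missing sequence", call. = FALSE)
  }
  seq <- toupper(chartr("u", "U", seq))
  seq <- chartr("U", "T", seq) # tolerate RNA input
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    stop("'", id, "': ambiguity codes or non-nucleotide characters (",
         paste(bad, collapse = ", "), ") are not allowed", call. = FALSE)
  }
  if (nchar(seq) %% 3L != 0L) {
    stop("'", id, "': length ", nchar(seq),
         " nt is not a multiple of 3; refusing to trim", call. = FALSE)
  }
  codons <- substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
  n <- length(codons)
  if (codons[n] %in% stop_codons()) codons <- codons[-n]
  if (length(codons) == 0L) {
    stop("'", id, "': no sense codons (stop codon only)", call. = FALSE)
  }
  internal_stop <- which(codons %in% stop_codons())
  if (length(internal_stop) > 0L) {
    stop("'", id, "': internal stop codon at codon position ",
         internal_stop[1L], call. = FALSE)
  }
  codons
}

#' Translate an in-frame coding sequence
#'
#' @inheritParams split_codons
#' @return Single amino-acid string (stop codon excluded).
#' @export
translate_codons <- function(seq, id = "sequence") {
  paste(codon_amino_acid(split_codons(seq, id)), collapse = "")
}

# Number of sense codons of each sequence in an ORF table.
codon_lengths <- function(orfs) {
  vapply(seq_len(nrow(orfs)),
         function(i) length(split_codons(orfs$seq[i], orfs$id[i])),
         integer(1))
}

# Validate an ORF/variant table: tibble with id + seq columns.
# `id_col` lets library tables use variant_id.
check_orf_tbl <- function(orfs, id_col = "id") {
  if (!is.data.frame(orfs) || !all(c(id_col, "seq") %in% names(orfs))) {
    stop("expected a data frame with columns '", id_col, "' and 'seq'",
         call. = FALSE)
  }
  if (nrow(orfs) == 0L) stop("empty sequence table", call. = FALSE)
  if (anyDuplicated(orfs[[id_col]])) {
    stop("duplicated sequence ids: ",
         paste(unique(orfs[[id_col]][duplicated(orfs[[id_col]])]),
               collapse = ", "), call. = FALSE)
  }
  invisible(orfs)
}

#' Per-variant codon count matrix
#'
#' Counts each of the 61 sense codons in every sequence of a table. Counting
#' partitions the gene: each row sums to the sequence's length in codons.
#'
#' @param orfs Data frame with `id` (or `variant_id`) and `seq` columns.
#' @return Integer matrix, one row per sequence (rownames = ids), one column
#'   per sense codon.
#' @export
codon_count_matrix <- function(orfs) {
  id_col <- if ("variant_id" %in% names(orfs)) "variant_id" else "id"
  check_orf_tbl(orfs, id_col)
  sc <- sense_codons()
  m <- t(vapply(seq_len(nrow(orfs)), function(i) {
    tab <- table(factor(split_codons(orfs$seq[i], orfs[[id_col]][i]),
                        levels = sc))
    as.integer(tab)
  }, integer(length(sc))))
  dimnames(m) <- list(orfs[[id_col]], sc)
  m
}
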