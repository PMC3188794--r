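# Codon usage profiles over genomes, transcriptomes, and single genes.

#' Codon usage profile of a set of ORFs
#'
#' Counts each sense codon over all ORFs and normalizes by the total sense
#' codon count (genome scope). When an expression table is supplied, each
#' gene's codon counts are weighted by its mRNA level before summing
#' (transcriptome scope): freq(c) = sum_g level(g) * count_g(c) /
#' sum_g level(g) * length(g). Genes absent from the expression table are
#' treated as having zero mRNA and contribute nothing; with uniform positive
#' levels the transcriptome profile equals the genome profile exactly.
#'
#' @param orfs Data frame with `id`, `seq` columns.
#' @param expression Optional data frame with `gene_id`, `mrna_level`
#'   (non-negative). Supplying it switches to transcriptome weighting.
#' @param weighting With expression data, `"counts"` (default) weights each
#'   gene's raw codon counts, so longer genes contribute more at equal mRNA
#'   level (the normalization denominator is a codon total); `"frequencies"`
#'   weights each gene's within-gene codon fractions instead.
#' @return Tibble of class `codon_usage_tbl` with columns `codon`,
#'   `amino_acid`, `count`, `fraction`; fractions sum to 1 within 1e-9.
#'   Attribute `scope` is `"genome"`, `"transcriptome"`, or `"single-gene"`.
#' @export
codon_usage <- function(orfs, expression = NULL,
                        weighting = c("counts", "frequencies")) {
  weighting <- match.arg(weighting)
  check_orf_tbl(orfs)
  counts <- codon_count_matrix(orfs)
  if (is.null(expression)) {
    tot <- colSums(counts)
    scope <- if (nrow(orfs) == 1L) "single-gene" else "genome"
  } else {
    if (!all(c("gene_id", "mrna_level") %in% names(expression))) {
      stop("expression table needs columns 'gene_id' and 'mrna_level'",
           call. = FALSE)
    }
    if (any(expression$mrna_level < 0)) {
      stop("mRNA levels must be non-negative", call. = FALSE)
    }
    lev <- stats::setNames(expression$mrna_level, expression$gene_id)
    gl <- lev[rownames(counts)]
    gl[is.na(gl)] <- 0 # genes with no recorded mRNA have zero level
    if (all(gl == 0)) {
      stop("all mRNA levels are zero for the supplied ORFs", call. = FALSE)
    }
    if (weighting == "frequencies") {
      counts <- counts / rowSums(counts)
    }
    tot <- colSums(counts * gl)
    scope <- "transcriptome"
  }
  out <- tibble::tibble(codon = colnames(counts),
                        amino_acid = codon_amino_acid(colnames(counts)),
                        count = unname(tot),
                        fraction = unname(tot / sum(tot)))
  class(out) <- c("codon_usage_tbl", class(out))
  attr(out, "scope") <- scope
  out
}

#' Write a codon usage profile as TSV
#'
#' @param usage A `codon_usage_tbl`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_codon_usage <- function(usage, path) {
  write_result_tsv(usage, path, comments = c(
    paste0("codon usage profile; scope: ",
           attr(usage, "scope") %||% "unknown"),
    "codons in DNA alphabet; fractions over the 61 sense codons"))
}
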