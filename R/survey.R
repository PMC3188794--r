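# Genome-scale bottleneck survey: batch scanning with a length filter,
# location histograms, hypergeometric quadrant enrichment, and expression
# class selection.

#' Batch bottleneck scan over a genome's ORFs
#'
#' Scans every ORF of at least `min_length` codons with [find_bottleneck()];
#' shorter genes are skipped (with a warning and a skip report) rather than
#' failing the batch. The default filter keeps genes longer than 100 codons.
#'
#' @inheritParams find_bottleneck
#' @param min_length Minimum gene length in codons to scan (default 101,
#'   i.e. genes longer than 100 codons).
#' @return The scan tibble (one row per retained gene), with attribute
#'   `skipped`: a tibble of `id`, `length_codons` for genes below the filter.
#' @export
survey_genome <- function(orfs, weights = codon_weights(), n = 21,
                          min_length = 101) {
  check_orf_tbl(orfs)
  if (min_length < n) {
    stop("min_length must be at least the window size n", call. = FALSE)
  }
  lens <- codon_lengths(orfs)
  keep <- lens >= min_length
  skipped <- tibble::tibble(id = orfs$id[!keep], length_codons = lens[!keep])
  if (nrow(skipped) > 0L) {
    warning(nrow(skipped), " gene(s) shorter than ", min_length,
            " codons skipped", call. = FALSE)
  }
  out <- if (any(keep)) {
    find_bottleneck(orfs[keep, , drop = FALSE], weights, n)
  } else {
    tibble::tibble(id = character(), length_codons = integer(),
                   window_n = integer(), location_k = integer(),
                   relative_location = numeric(), strength = numeric(),
                   relative_strength = numeric())
  }
  attr(out, "skipped") <- skipped
  attr(out, "min_length") <- min_length
  out
}

quadrant_interval <- function(quadrant) {
  switch(quadrant,
    first  = c(0.00, 0.25),
    second = c(0.25, 0.50),
    third  = c(0.50, 0.75),
    fourth = c(0.75, 1.00))
}

in_quadrant <- function(x, quadrant) {
  iv <- quadrant_interval(quadrant)
  # half-open [lo, hi), except the fourth quadrant which closes at 1
  if (quadrant == "fourth") x >= iv[1] & x <= iv[2] else x >= iv[1] & x < iv[2]
}

#' Hypergeometric quadrant enrichment of strong bottlenecks
#'
#' Tests whether genes with a strong bottleneck (relative strength strictly
#' above `strength_threshold`) are enriched or depleted for bottlenecks lying
#' in a given quarter of the transcript. Quadrants partition relative
#' location into \[0, 0.25), \[0.25, 0.5), \[0.5, 0.75), \[0.75, 1\]; the
#' "first quadrant" is relative location below 0.25. Tail probabilities are
#' one-sided and include the observed count: enrichment = P(X >= overlap),
#' depletion = P(X <= overlap), with X hypergeometric on (population = all
#' scanned genes, successes = genes whose bottleneck lies in the quadrant,
#' draws = strong-bottleneck genes).
#'
#' @param scan A bottleneck scan tibble ([survey_genome()]/[find_bottleneck()]).
#' @param strength_threshold Strict lower bound on relative strength defining
#'   the strong-bottleneck sample (default 1.3).
#' @param quadrant One of `"first"`, `"second"`, `"third"`, `"fourth"`.
#' @return One-row tibble: `quadrant`, `strength_threshold`,
#'   `population_size`, `n_success_in_population`, `sample_size`, `n_overlap`,
#'   `fraction` (= n_overlap / sample_size), `p_enrichment`, `p_depletion`.
#' @export
quadrant_enrichment <- function(scan, strength_threshold = 1.3,
                                quadrant = c("first", "second", "third",
                                             "fourth")) {
  quadrant <- match.arg(quadrant)
  if (!is.data.frame(scan) ||
      !all(c("relative_location", "relative_strength") %in% names(scan))) {
    stop("expected a bottleneck scan table", call. = FALSE)
  }
  if (nrow(scan) == 0L) stop("empty bottleneck table", call. = FALSE)
  pop <- nrow(scan)
  succ <- sum(in_quadrant(scan$relative_location, quadrant))
  strong <- scan$relative_strength > strength_threshold
  samp <- sum(strong)
  if (samp == 0L) {
    stop("no gene exceeds relative strength ", strength_threshold,
         "; lower the threshold", call. = FALSE)
  }
  overlap <- sum(strong & in_quadrant(scan$relative_location, quadrant))
  tibble::tibble(
    quadrant = quadrant,
    strength_threshold = strength_threshold,
    population_size = pop,
    n_success_in_population = succ,
    sample_size = samp,
    n_overlap = overlap,
    fraction = overlap / samp,
    p_enrichment = stats::phyper(overlap - 1, succ, pop - succ, samp,
                                 lower.tail = FALSE),
    p_depletion = stats::phyper(overlap, succ, pop - succ, samp))
}

#' Histogram of bottleneck relative locations
#'
#' Bins relative locations into equal-width bins over (0, 1].
#'
#' @param scan A bottleneck scan tibble.
#' @param bins Number of bins (default 20).
#' @return Tibble with `bin_lo`, `bin_hi`, `count`, `fraction`.
#' @export
location_histogram <- function(scan, bins = 20) {
  br <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(ceiling(scan$relative_location * bins), 1L), bins)
  cnt <- tabulate(idx, nbins = bins)
  tibble::tibble(bin_lo = br[-length(br)], bin_hi = br[-1],
                 count = cnt, fraction = cnt / sum(cnt))
}

#' Select highly and lowly expressed genes
#'
#' Ranks genes with recorded mRNA levels, takes the `top` highest and
#' `bottom` lowest, and intersects each slice with the genes present in the
#' (length-filtered) bottleneck table -- so the returned groups can be
#' smaller than the slices. Genes with no recorded mRNA are ignored. Ties at
#' either cut are resolved deterministically by (level, then gene id
#' ascending).
#'
#' @param expression Data frame with `gene_id`, `mrna_level`.
#' @param scan A bottleneck scan tibble whose `id` column defines the
#'   analyzable genes.
#' @param top,bottom Sizes of the highly/lowly expressed slices (default 500
#'   each).
#' @return Tibble with `gene_id`, `mrna_level`, `class` (`"high"`/`"low"`),
#'   containing only genes present in `scan`.
#' @export
expression_classes <- function(expression, scan, top = 500, bottom = 500) {
  if (!all(c("gene_id", "mrna_level") %in% names(expression))) {
    stop("expression table needs columns 'gene_id' and 'mrna_level'",
         call. = FALSE)
  }
  rec <- expression[!is.na(expression$mrna_level), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no genes with recorded mRNA levels", call. = FALSE)
  if (top + bottom > nrow(rec)) {
    stop("top + bottom (", top + bottom, ") exceeds the ", nrow(rec),
         " recorded genes; slices would overlap", call. = FALSE)
  }
  ord_desc <- order(-rec$mrna_level, rec$gene_id)
  ord_asc <- order(rec$mrna_level, rec$gene_id)
  high <- rec[ord_desc[seq_len(top)], , drop = FALSE]
  low <- rec[ord_asc[seq_len(bottom)], , drop = FALSE]
  out <- dplyr::bind_rows(
    tibble::tibble(gene_id = high$gene_id, mrna_level = high$mrna_level,
                   class = "high"),
    tibble::tibble(gene_id = low$gene_id, mrna_level = low$mrna_level,
                   class = "low"))
  out[out$gene_id %in% scan$id, , drop = FALSE]
}
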