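# Per-codon translation-speed weights from tRNA pools (tAI relative
# adaptiveness), gene-level tAI, and per-codon time profiles.

rna_complement <- function(x) chartr("ACGU", "UGCA", x)

# Candidate (anticodon, pairing_class) pairs able to read one RNA codon.
# Anticodons are written 5'->3', position 34 first, so position 34 pairs with
# codon position 3. Watson-Crick anticodon is therefore the reverse complement
# of the codon; wobble replaces position 34.
codon_anticodon_candidates <- function(codon_rna) {
  n <- strsplit(codon_rna, "")[[1]]
  tail_ac <- paste0(rna_complement(n[2]), rna_complement(n[1]))
  wc <- paste0(rna_complement(n[3]), tail_ac)
  wob <- switch(n[3],
    U = c("G", "wobble_GU"),
    C = c("A", "wobble_IC"),
    A = c("A", "wobble_IA"),
    G = c("U", "wobble_UG"))
  out <- tibble::tibble(
    anticodon = c(wc, paste0(wob[1], tail_ac)),
    pairing_class = c("watson_crick", wob[2]))
  # AUA is read by the lysidine-modified CAU tRNA, not by its Watson-Crick
  # or inosine anticodons (absent in bacteria).
  if (codon_rna == "AUA") {
    out <- dplyr::bind_rows(
      out, tibble::tibble(anticodon = "CAU", pairing_class = "lysidine_CA"))
  }
  out
}

#' Bundled default tRNA pool (approximate E. coli K-12)
#'
#' Anticodon-level tRNA gene copy numbers compiled from standard E. coli
#' anticodon repertoires (initiator fMet genes excluded; the lysidine-modified
#' Ile2 tRNA is pooled under its genomic anticodon CAU). This is a bundled
#' repository default intended for simulation and method development; replace
#' it with curated organism-specific counts for production analyses.
#'
#' @return Tibble with columns `anticodon` (RNA), `copy_number`, `amino_acid`.
#' @export
#' @examples
#' trna_pool_default()
trna_pool_default <- function() {
  read_trna_pool(system.file("extdata", "trna_gcn_ecoli.tsv",
                             package = "ribotraffic", mustWork = TRUE))
}

#' Bundled wobble-pairing selective constraints (s-values)
#'
#' The standard prokaryotic constraint set: Watson-Crick pairs are
#' unconstrained (s = 0); wobble classes carry the usual penalties
#' (G34:U3 0.41, I34:C3 0.28, I34:A3 0.9999, U34:G3 0.68, lysidine C34:A3
#' 0.89).
#'
#' @return Tibble with columns `pairing_class`, `s`.
#' @export
s_values_default <- function() {
  read_s_values(system.file("extdata", "wobble_s_values.tsv",
                            package = "ribotraffic", mustWork = TRUE))
}

#' Compute per-codon relative adaptiveness weights (codon tAI)
#'
#' For each sense codon, the absolute adaptiveness is
#' W = sum over readable anticodons of (1 - s) * gene copy number, where s is
#' the selective constraint of the codon:anticodon pairing class. Weights are
#' W normalized by the maximum, so the best-adapted codon has w = 1. The
#' weight of codon CGA is then overridden with `cga_weight`: its natural
#' inosine-read weight is more than an order of magnitude below every other
#' codon and would otherwise dominate every harmonic-mean window.
#'
#' @param pool Tibble of `anticodon` (RNA, unique) and `copy_number` (>= 0).
#' @param s_values Tibble of `pairing_class` and `s` in \[0, 1\].
#' @param cga_weight Replacement weight for codon CGA, in (0, 1\]. Set to
#'   `NA` to keep the raw computed value.
#' @param zero_weight Policy for codons with W = 0 (no readable anticodon in
#'   the pool): `"error"` names the codons and stops; `"geomean"` imputes the
#'   geometric mean of the non-zero weights.
#' @return Tibble of class `codon_weight_tbl` with columns `codon`,
#'   `amino_acid`, `weight`; 61 rows, all weights > 0, and max weight 1 over
#'   the non-overridden codons.
#' @export
#' @examples
#' w <- codon_weights()
#' w[w$codon == "CGA", ]
codon_weights <- function(pool = trna_pool_default(),
                          s_values = s_values_default(),
                          cga_weight = 0.1333,
                          zero_weight = c("error", "geomean")) {
  zero_weight <- match.arg(zero_weight)
  check_trna_pool(pool)
  check_s_values(s_values)
  if (!is.na(cga_weight) && (cga_weight <= 0 || cga_weight > 1)) {
    stop("cga_weight must lie in (0, 1]", call. = FALSE)
  }
  s_map <- stats::setNames(s_values$s, s_values$pairing_class)
  gcn <- stats::setNames(pool$copy_number, pool$anticodon)
  sc <- sense_codons()
  W <- vapply(sc, function(codon) {
    cand <- codon_anticodon_candidates(chartr("T", "U", codon))
    miss <- setdiff(cand$pairing_class, names(s_map))
    if (length(miss) > 0L) {
      stop("no s-value for pairing class: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    present <- cand$anticodon %in% names(gcn)
    sum((1 - s_map[cand$pairing_class[present]]) * gcn[cand$anticodon[present]])
  }, numeric(1))
  if (all(W == 0)) stop("tRNA pool yields zero adaptiveness for every codon",
                        call. = FALSE)
  w <- W / max(W)
  zero <- names(w)[w == 0]
  if (length(zero) > 0L) {
    if (zero_weight == "error") {
      stop("codons with zero adaptiveness and no imputation policy: ",
           paste(zero, collapse = ", "),
           " (use zero_weight = \"geomean\")", call. = FALSE)
    }
    w[zero] <- exp(mean(log(w[w > 0])))
  }
  if (!is.na(cga_weight)) w["CGA"] <- cga_weight
  out <- tibble::tibble(codon = sc,
                        amino_acid = codon_amino_acid(sc),
                        weight = unname(w[sc]))
  class(out) <- c("codon_weight_tbl", class(out))
  attr(out, "cga_override") <- if (is.na(cga_weight)) NA_real_ else cga_weight
  attr(out, "source") <- "computed from tRNA pool (dos Reis-style W = sum (1-s)*tGCN)"
  out
}

check_trna_pool <- function(pool) {
  if (!is.data.frame(pool) ||
      !all(c("anticodon", "copy_number") %in% names(pool))) {
    stop("tRNA pool needs columns 'anticodon' and 'copy_number'", call. = FALSE)
  }
  if (nrow(pool) == 0L) stop("empty tRNA pool", call. = FALSE)
  if (anyDuplicated(pool$anticodon)) {
    stop("duplicated anticodons in tRNA pool: ",
         paste(unique(pool$anticodon[duplicated(pool$anticodon)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(grepl("[^ACGU]", pool$anticodon)) ||
      any(nchar(pool$anticodon) != 3L)) {
    stop("anticodons must be 3-letter RNA strings (A/C/G/U)", call. = FALSE)
  }
  if (any(pool$copy_number < 0) || any(pool$copy_number != round(pool$copy_number))) {
    stop("gene copy numbers must be non-negative integers", call. = FALSE)
  }
  invisible(pool)
}

check_s_values <- function(s_values) {
  if (!is.data.frame(s_values) ||
      !all(c("pairing_class", "s") %in% names(s_values))) {
    stop("s-value table needs columns 'pairing_class' and 's'", call. = FALSE)
  }
  if (any(s_values$s < 0 | s_values$s > 1)) {
    stop("all s-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(s_values)
}

# weight lookup vector from a codon_weight_tbl
weight_vector <- function(weights) {
  if (!is.data.frame(weights) ||
      !all(c("codon", "weight") %in% names(weights))) {
    stop("expected a codon weight table (see codon_weights())", call. = FALSE)
  }
  if (any(weights$weight <= 0)) stop("codon weights must be > 0", call. = FALSE)
  stats::setNames(weights$weight, weights$codon)
}

#' Gene-level tAI (geometric mean of codon weights)
#'
#' tAI of a gene is the geometric mean of its codons' relative adaptiveness
#' weights, computed in the log domain for numerical stability. It is
#' order-free by construction -- precisely the limitation that motivates the
#' bottleneck scan.
#'
#' @param orfs Data frame with `id` and `seq` columns (in-frame ORFs).
#' @param weights A `codon_weight_tbl` from [codon_weights()].
#' @return Tibble with `id`, `length_codons`, `tai` (in (0, 1\]).
#' @export
gene_tai <- function(orfs, weights = codon_weights()) {
  id_col <- if ("variant_id" %in% names(orfs)) "variant_id" else "id"
  check_orf_tbl(orfs, id_col)
  w <- weight_vector(weights)
  rows <- purrr::map(seq_len(nrow(orfs)), function(i) {
    codons <- split_codons(orfs$seq[i], orfs[[id_col]][i])
    tibble::tibble(id = orfs[[id_col]][i],
                   length_codons = length(codons),
                   tai = exp(mean(log(w[codons]))))
  })
  dplyr::bind_rows(rows)
}

#' Per-codon translation-time profile
#'
#' The reciprocal weight 1/w of each codon is its translation time in
#' arbitrary units (the best-adapted codon takes 1 unit).
#'
#' @param seq A single in-frame DNA coding sequence.
#' @param weights A `codon_weight_tbl`.
#' @param id Identifier for error messages.
#' @return Tibble with `position` (1-based codon index), `codon`, `weight`,
#'   `time` (= 1/weight, all >= the minimum over codons of 1).
#' @export
time_profile <- function(seq, weights = codon_weights(), id = "sequence") {
  w <- weight_vector(weights)
  codons <- split_codons(seq, id)
  tibble::tibble(position = seq_along(codons),
                 codon = codons,
                 weight = unname(w[codons]),
                 time = unname(1 / w[codons]))
}
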