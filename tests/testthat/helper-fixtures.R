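# Shared fixtures and independent oracles. Oracles deliberately use naive
# loops / closed forms so they stay independent of the implementation paths
# they check.

# default weights, computed once per test run
default_w <- codon_weights()
default_wvec <- stats::setNames(default_w$weight, default_w$codon)

# random in-frame ORF of l sense codons (no stops by construction)
random_orf_seq <- function(l) {
  paste(sample(sense_codons(), l, replace = TRUE), collapse = "")
}

random_orf_tbl <- function(n, lengths) {
  tibble::tibble(id = sprintf("g%04d", seq_len(n)),
                 seq = vapply(lengths, random_orf_seq, character(1)))
}

# a codon_weight_tbl with hand-set weights (defaults to 1 elsewhere)
toy_weight_tbl <- function(...) {
  w <- c(...)
  out <- tibble::tibble(codon = sense_codons(),
                        amino_acid = codon_amino_acid(sense_codons()),
                        weight = 1)
  out$weight[match(names(w), out$codon)] <- unname(w)
  class(out) <- c("codon_weight_tbl", class(out))
  out
}

# Brute-force bottleneck oracle: enumerate every window, compute the harmonic
# mean of the weights directly, take the leftmost minimum.
oracle_bottleneck <- function(wvals, n) {
  l <- length(wvals)
  hm <- vapply(seq_len(l - n + 1), function(k) {
    n / sum(1 / wvals[k:(k + n - 1)])
  }, numeric(1))
  k <- which(hm == min(hm))[1]
  list(location_k = k,
       strength = mean(1 / wvals[k:(k + n - 1)]),
       harmonic_means = hm)
}

# Direct evaluation of the jam condition: all window sums by explicit loops.
oracle_jam <- function(profile, H, B) {
  tw <- vapply(seq_len(length(profile) - H + 1), function(k) {
    sum(profile[k:(k + H - 1)])
  }, numeric(1))
  k <- which(tw == max(tw))[1]
  list(jam = tw[k] > tw[1] + B, argmax_k = k,
       max_window_time = tw[k], reference_time = tw[1] + B)
}

# Hypergeometric tail probabilities by direct pmf summation with choose().
oracle_hyper_tails <- function(k, K, N, n) {
  j <- 0:n
  pmf <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  list(enrich = sum(pmf[j >= k]), deplete = sum(pmf[j <= k]))
}

# minimal library table built from explicit codon strings + measurements
make_library <- function(seqs, abundance, od, folding = NULL) {
  out <- tibble::tibble(variant_id = sprintf("v%02d", seq_along(seqs)),
                        seq = seqs, protein_abundance = abundance, od = od)
  if (!is.null(folding)) out$folding_energy <- folding
  out
}
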