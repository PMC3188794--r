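test_that("per-cell abundance divides by OD, elementwise", {
  lib <- make_library(rep("ATGAAA", 3), c(100, 0, 7), c(2, 5, 3.5))
  out <- per_cell_abundance(lib)
  expect_equal(out$per_cell_abundance, c(50, 0, 2))
  # loop oracle on a larger table
  set.seed(61)
  lib2 <- make_library(rep("ATGAAA", 10), stats::runif(10, 0, 100),
                       stats::runif(10, 0.5, 3))
  got <- per_cell_abundance(lib2)$per_cell_abundance
  for (i in 1:10) {
    expect_equal(got[i], lib2$protein_abundance[i] / lib2$od[i])
  }
  # constant-OD measurements bypass normalization
  expect_equal(per_cell_abundance(lib, normalize_od = FALSE)$per_cell_abundance,
               lib$protein_abundance)
  lib$od[1] <- 0
  expect_error(per_cell_abundance(lib), "strictly positive")
})

test_that("correlations agree with the textbook formula and handle ties", {
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0, 6.3, 7.7, 8.1)
  y <- c(2.0, 1.1, 4.5, 3.3, 6.6, 5.2, 8.8, 7.4)
  hand_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- correlate(x, y, "pearson")
  expect_equal(got$r, hand_r)
  tstat <- hand_r * sqrt(6 / (1 - hand_r^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), 6))

  perfect <- correlate(x, 2 * x + 1, "pearson")
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p_value, 1e-12)
  expect_equal(correlate(x, rev(sort(y)), "spearman")$r, -1)
  # average ranks on ties
  xt <- c(1, 1, 2, 3); yt <- c(4, 5, 6, 7)
  expect_equal(correlate(xt, yt, "spearman")$r, stats::cor(rank(xt), rank(yt)))

  z <- correlate(rep(3, 5), 1:5, "pearson")
  expect_true(z$undefined)
  expect_true(is.na(z$r))
  expect_error(correlate(1:3, 1:4), "lengths differ")
  expect_error(correlate(c(1, 2, Inf), 1:3), "non-finite")
})

test_that("correlation is symmetric and invariant to positive affine maps", {
  set.seed(62)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  for (m in c("pearson", "spearman")) {
    expect_equal(correlate(x, y, m)$r, correlate(y, x, m)$r)
    expect_equal(correlate(3 * x + 5, y, m)$r, correlate(x, y, m)$r)
  }
})

test_that("partial correlation equals the residual-regression construction", {
  set.seed(63)
  for (i in 1:5) {
    z <- stats::rnorm(50)
    x <- 0.6 * z + stats::rnorm(50)
    y <- -0.4 * z + 0.5 * x + stats::rnorm(50)
    got <- partial_correlate(x, y, z, "pearson")
    rx <- stats::residuals(stats::lm(x ~ z))
    ry <- stats::residuals(stats::lm(y ~ z))
    expect_equal(got$r, stats::cor(rx, ry), tolerance = 1e-12)
    # rank-based variant: same construction on ranks
    gs <- partial_correlate(x, y, z, "spearman")
    rxs <- stats::residuals(stats::lm(rank(x) ~ rank(z)))
    rys <- stats::residuals(stats::lm(rank(y) ~ rank(z)))
    expect_equal(gs$r, stats::cor(rxs, rys), tolerance = 1e-12)
  }
})

test_that("degenerate controls flag the result undefined", {
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  expect_true(partial_correlate(x, y, x)$undefined)
  expect_true(partial_correlate(x, y, rep(1, 20))$undefined)
  expect_error(partial_correlate(x[1:3], y[1:3], x[1:3]), "at least 4")
})

test_that("bottleneck-vs-expression analysis recovers planted signs", {
  lib <- default_library(seed = 64, weights = default_w)
  ana <- analyze_bottleneck_vs_expression(lib, default_w)
  ct <- tidy(ana)
  loc <- ct[ct$parameter == "relative_location" & ct$scope == "all", ]
  expect_true(all(loc$r < 0))
  str_band <- ct[ct$parameter == "relative_strength" & ct$scope == "band" &
                   ct$method %in% c("pearson", "spearman"), ]
  expect_true(all(str_band$r > 0))
  # partial correlations controlling folding energy stay negative for location
  part <- ct[ct$parameter == "relative_location" & ct$scope == "all" &
               ct$method == "partial_pearson", ]
  expect_equal(part$controlled_for, "folding_energy")
  expect_lt(part$r, 0)
  g <- glance(ana)
  expect_equal(g$n_variants, 150L)
  expect_equal(g$n_band, ana$band_n)
  expect_s3_class(ggplot2::autoplot(ana), "ggplot")
})

test_that("abundance driven purely by folding energy leaves ~0 partials", {
  set.seed(65)
  spec <- library_spec(n_variants = 150, seed = 65)
  vars <- generate_library(spec, default_w)
  fe <- stats::rnorm(150, -8, 2)
  od <- rep(1.5, 150)
  abundance <- (50 + 4 * fe + stats::rnorm(150, 0, 0.3)) * od
  lib <- tibble::tibble(variant_id = vars$variant_id, seq = vars$seq,
                        protein_abundance = abundance, od = od,
                        folding_energy = fe)
  ct <- tidy(analyze_bottleneck_vs_expression(lib, default_w))
  part <- ct[ct$scope == "all" & ct$method == "partial_pearson" &
               ct$parameter == "relative_location", ]
  expect_lt(abs(part$r), 0.2)
})

test_that("duplicating the library leaves correlations unchanged", {
  lib <- default_library(seed = 66, weights = default_w, n_variants = 40)
  dup <- dplyr::mutate(dplyr::bind_rows(lib, lib),
                       variant_id = sprintf("d%03d", 1:80))
  r1 <- tidy(analyze_bottleneck_vs_expression(lib, default_w,
                                              location_band = NULL))
  r2 <- tidy(analyze_bottleneck_vs_expression(dup, default_w,
                                              location_band = NULL))
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
})

test_that("scaling all abundances rescales per-cell values but not r", {
  lib <- default_library(seed = 67, weights = default_w, n_variants = 30)
  scaled <- dplyr::mutate(lib, protein_abundance = protein_abundance * 17)
  expect_equal(per_cell_abundance(scaled)$per_cell_abundance,
               17 * per_cell_abundance(lib)$per_cell_abundance)
  r1 <- tidy(analyze_bottleneck_vs_expression(lib, default_w,
                                              location_band = NULL))
  r2 <- tidy(analyze_bottleneck_vs_expression(scaled, default_w,
                                              location_band = NULL))
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
})

test_that("per-codon fitness scan classifies planted penalties and constants", {
  lib <- default_library(seed = 68, weights = default_w)
  fs <- codon_fitness_scan(lib)
  expect_equal(nrow(fs), 61L)
  expect_equal(attr(fs, "alpha_corrected"), 0.05 / 61)
  # single-synonym codons never vary across synonymous variants
  expect_equal(fs$class[fs$codon == "ATG"], "constant")
  expect_equal(fs$class[fs$codon == "TGG"], "constant")
  expect_true(is.na(fs$r[fs$codon == "ATG"]))
  expect_equal(fs$class[fs$codon == "TCA"], "negative")
  expect_equal(fs$class[fs$codon == "CAT"], "negative")
  expect_s3_class(ggplot2::autoplot(fs), "ggplot")
})

test_that("shuffled OD rarely reaches the corrected threshold", {
  lib <- default_library(seed = 69, weights = default_w)
  set.seed(70)
  frac_ns <- replicate(20, {
    sh <- dplyr::mutate(lib, od = sample(od))
    fs <- codon_fitness_scan(sh)
    tested <- fs[fs$class != "constant", ]
    mean(tested$class == "not_significant")
  })
  expect_gte(mean(frac_ns), 0.95)
})

test_that("codon ranking puts the planted penalty codons on top", {
  lib <- default_library(seed = 71, weights = default_w)
  rk <- rank_fitness_codons(lib)
  expect_setequal(rk$codon[rk$rank <= 2], c("TCA", "CAT"))
  expect_true(all(rk$raw_r < 0))
  expect_true(all(diff(rk$min_abs_partial_r) <= 1e-12))
  expect_true(all(c("ATG", "TGG") %in% attr(rk, "excluded_constant")))
  # M(i, j) agrees with the residual-regression oracle on sampled pairs
  m <- attr(rk, "partial_matrix")
  counts <- codon_count_matrix(lib)
  set.seed(72)
  ij <- which(!is.na(m), arr.ind = TRUE)
  for (row in sample(nrow(ij), 5)) {
    i <- rownames(m)[ij[row, 1]]; j <- colnames(m)[ij[row, 2]]
    rx <- stats::residuals(stats::lm(counts[, i] ~ counts[, j]))
    ry <- stats::residuals(stats::lm(lib$od ~ counts[, j]))
    expect_equal(m[i, j], stats::cor(rx, ry), tolerance = 1e-10)
  }
})

test_that("a single negatively correlated codon falls back to its raw r", {
  # counts vary only in TCA/TCG serine choice; OD decreases exactly with TCA
  n <- 8
  seqs <- vapply(seq_len(n), function(i) {
    paste(c("ATG", rep("TCA", i), rep("TCG", n + 1 - i)), collapse = "")
  }, character(1))
  lib <- make_library(seqs, abundance = rep(5, n), od = 10 - seq_len(n))
  rk <- rank_fitness_codons(lib)
  expect_equal(nrow(rk), 1L)
  expect_equal(rk$codon, "TCA")
  expect_equal(rk$min_abs_partial_r, abs(rk$raw_r))
  expect_true(is.na(rk$controlling_codon))
})
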