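test_that("every variant translates back to the spec's protein", {
  for (policy in c("uniform_synonymous", "frequency_weighted",
                   "planted_bottleneck")) {
    spec <- library_spec(n_variants = 4, seed = 81, codon_policy = policy)
    vars <- generate_library(spec, default_w)
    expect_equal(nrow(vars), 4L)
    for (s in vars$seq) {
      expect_equal(translate_codons(s), spec$aa_sequence)
    }
  }
})

test_that("generation is seed-deterministic and variants are distinct", {
  spec <- library_spec(n_variants = 3, seed = 82,
                       codon_policy = "uniform_synonymous")
  a <- generate_library(spec, default_w)
  b <- generate_library(spec, default_w)
  expect_identical(a, b)
  expect_equal(length(unique(a$seq)), 3L)
  spec2 <- library_spec(n_variants = 3, seed = 83,
                        codon_policy = "uniform_synonymous")
  expect_false(identical(a$seq, generate_library(spec2, default_w)$seq))
  # written FASTA is byte-identical across runs of the same seed
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_orf_fasta(generate_library(spec, default_w), f1)
  write_orf_fasta(generate_library(spec, default_w), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("library_spec validates its inputs", {
  expect_error(library_spec(n_variants = 2), ">= 3")
  expect_error(library_spec(aa_sequence = "MKB"), "non-standard")
  expect_error(library_spec(planted = list(relative_location = 1.5,
                                           relative_strength = 1.5,
                                           window_n = 21)), "\\(0, 1\\]")
  expect_error(library_spec(aa_sequence = "MKT",
                            planted = list(relative_location = 0.5,
                                           relative_strength = 1.5,
                                           window_n = 21)), "window_n")
})

test_that("a planted bottleneck at 0.2 is recovered by the scan", {
  spec <- library_spec(n_variants = 100, seed = 84,
                       planted = list(relative_location = 0.2,
                                      relative_strength = 1.5,
                                      window_n = 21))
  vars <- generate_library(spec, default_w)
  scan <- find_bottleneck(vars, default_w, n = 21)
  expect_gt(mean(scan$relative_location), 0.15)
  expect_lt(mean(scan$relative_location), 0.25)
  expect_gte(mean(abs(scan$relative_location - 0.2) <= 0.05), 0.9)
})

test_that("measurements carry the planted structure and invert exactly", {
  spec <- library_spec(n_variants = 30, seed = 85)
  vars <- generate_library(spec, default_w)
  lib <- simulate_measurements(vars, default_w, seed = 86)
  truth <- attr(lib, "truth")
  expect_equal(per_cell_abundance(lib)$per_cell_abundance,
               truth$per_cell_abundance, tolerance = 1e-12)
  expect_true(all(lib$od > 0))
  # same seed, same measurements
  lib2 <- simulate_measurements(vars, default_w, seed = 86)
  expect_equal(lib$protein_abundance, lib2$protein_abundance)
})

test_that("the null model produces constant measurements", {
  spec <- library_spec(n_variants = 5, seed = 87)
  vars <- generate_library(spec, default_w)
  null_model <- effect_model(beta_location = 0, beta_strength_proximal = 0,
                             beta_folding = 0, gamma = numeric(0),
                             noise_sd_abundance = 0, noise_sd_od = 0)
  lib <- simulate_measurements(vars, default_w, null_model, seed = 88)
  expect_equal(stats::sd(lib$od), 0)
  expect_equal(stats::sd(lib$protein_abundance), 0)
})

test_that("excessive codon penalties trip the OD floor guard", {
  spec <- library_spec(n_variants = 10, seed = 89)
  vars <- generate_library(spec, default_w)
  harsh <- effect_model(gamma = c(AAA = 1))
  expect_error(simulate_measurements(vars, default_w, harsh, seed = 90),
               "OD floor")
})

test_that("effect_model rejects invalid fields", {
  expect_error(effect_model(beta_location = 1), "<= 0")
  expect_error(effect_model(beta_strength_proximal = -1), ">= 0")
  expect_error(effect_model(noise_sd_od = -1), "non-negative")
  expect_error(effect_model(gamma = c(0.1)), "named")
  expect_error(effect_model(gamma = c(XXX = 0.1)), "named by sense codons")
})

test_that("measured correlations land near the analytic targets", {
  lib <- default_library(seed = 91, weights = default_w)
  scan <- find_bottleneck(lib, default_w)
  targets <- planted_correlation_targets(scan, effect_model())
  ana <- analyze_bottleneck_vs_expression(lib, default_w)
  ct <- tidy(ana)
  for (i in seq_len(nrow(targets))) {
    got <- ct[ct$parameter == targets$parameter[i] &
                ct$scope == targets$scope[i] & ct$method == "spearman", ]
    expect_lt(abs(got$r - targets$target_r[i]), 0.15)
  }
})

test_that("zeroed effects leave bottleneck correlations centered on zero", {
  null_model <- effect_model(beta_location = 0, beta_strength_proximal = 0,
                             beta_folding = 0, gamma = numeric(0))
  rs <- vapply(1:5, function(s) {
    spec <- library_spec(n_variants = 60, seed = 900 + s)
    vars <- generate_library(spec, default_w)
    lib <- simulate_measurements(vars, default_w, null_model, seed = 950 + s)
    ct <- tidy(analyze_bottleneck_vs_expression(lib, default_w,
                                                location_band = NULL))
    ct$r[ct$parameter == "relative_location" & ct$method == "spearman"]
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})
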