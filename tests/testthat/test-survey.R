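test_that("length filter keeps genes longer than 100 codons", {
  orfs <- tibble::tibble(id = c("g100", "g101", "g150"),
                         seq = vapply(c(100, 101, 150), random_orf_seq,
                                      character(1)))
  expect_warning(scan <- survey_genome(orfs, default_w), "1 gene")
  expect_setequal(scan$id, c("g101", "g150"))
  skipped <- attr(scan, "skipped")
  expect_equal(skipped$id, "g100")
  expect_equal(skipped$length_codons, 100L)
})

test_that("survey rows equal the per-gene scan", {
  set.seed(51)
  orfs <- random_orf_tbl(50, sample(80:300, 50, replace = TRUE))
  suppressWarnings(scan <- survey_genome(orfs, default_w))
  keep <- orfs[orfs$id %in% scan$id, ]
  direct <- find_bottleneck(keep, default_w, n = 21)
  expect_equal(as.data.frame(scan), as.data.frame(direct),
               ignore_attr = TRUE)
})

test_that("an empty post-filter set yields an empty table plus skip report", {
  orfs <- random_orf_tbl(3, c(30, 40, 50))
  expect_warning(scan <- survey_genome(orfs, default_w), "3 gene")
  expect_equal(nrow(scan), 0L)
  expect_equal(nrow(attr(scan, "skipped")), 3L)
})

make_scan <- function(rel_loc, rel_strength) {
  tibble::tibble(id = sprintf("g%03d", seq_along(rel_loc)),
                 length_codons = 200L, window_n = 21L, location_k = 1L,
                 relative_location = rel_loc, strength = rel_strength,
                 relative_strength = rel_strength)
}

test_that("quadrant enrichment matches the closed-form hypergeometric", {
  # population 20, 5 in the first quadrant, sample of 4 strong genes all in
  # the quadrant: P(X >= 4) = C(5,4) C(15,0) / C(20,4) = 5 / 4845
  loc <- c(rep(0.1, 5), rep(0.6, 15))
  strong <- c(rep(2, 4), rep(1, 16)) # 4 strong, all in quadrant
  e <- quadrant_enrichment(make_scan(loc, strong), 1.3, "first")
  expect_equal(e$population_size, 20L)
  expect_equal(e$n_success_in_population, 5L)
  expect_equal(e$sample_size, 4L)
  expect_equal(e$n_overlap, 4L)
  expect_equal(e$fraction, 1)
  expect_equal(e$p_enrichment, 5 / 4845, tolerance = 1e-12)
})

test_that("sample equal to population gives trivial tails", {
  loc <- c(rep(0.1, 3), rep(0.9, 7))
  e <- quadrant_enrichment(make_scan(loc, rep(2, 10)), 1.3, "first")
  expect_equal(e$fraction, 0.3)
  expect_equal(e$p_enrichment, 1)
  expect_equal(e$p_depletion, 1)
})

test_that("quadrant boundaries are half-open and strength is strict", {
  loc <- c(0, 0.249, 0.25, 0.5, 0.75, 1)
  scan <- make_scan(loc, c(2, 2, 2, 2, 2, 1.3)) # last gene not strong (strict)
  first <- quadrant_enrichment(scan, 1.3, "first")
  expect_equal(first$n_success_in_population, 2L) # 0 and 0.249 only
  expect_equal(first$sample_size, 5L)
  fourth <- quadrant_enrichment(scan, 1.3, "fourth")
  expect_equal(fourth$n_success_in_population, 2L) # 0.75 and 1 (closed at 1)
  # four quadrant fractions of the population partition it
  counts <- vapply(c("first", "second", "third", "fourth"), function(q) {
    quadrant_enrichment(scan, 1.3, q)$n_success_in_population
  }, integer(1))
  expect_equal(sum(counts), nrow(scan))
  expect_error(quadrant_enrichment(scan, 99), "lower the threshold")
})

test_that("tails match brute-force pmf summation and are monotone", {
  set.seed(52)
  for (i in 1:10) {
    N <- sample(10:60, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    loc <- c(rep(0.1, K), rep(0.6, N - K))
    strong <- rep(1, N)
    strong[sample(N, n)] <- 2
    e <- quadrant_enrichment(make_scan(loc, strong), 1.3, "first")
    o <- oracle_hyper_tails(e$n_overlap, K, N, n)
    expect_equal(e$p_enrichment, o$enrich, tolerance = 1e-12)
    expect_equal(e$p_depletion, o$deplete, tolerance = 1e-12)
    expect_true(e$p_enrichment > 0 && e$p_enrichment <= 1)
    expect_true(e$p_depletion > 0 && e$p_depletion <= 1)
  }
})

test_that("a planted location-strength dependence is detected", {
  set.seed(53)
  N <- 300
  strong <- stats::runif(N) < 0.3
  loc <- ifelse(strong, stats::runif(N, 0, 0.35), stats::runif(N))
  scan <- make_scan(loc, ifelse(strong, 1.8, 1.05))
  expect_lt(quadrant_enrichment(scan, 1.3, "first")$p_enrichment, 0.01)
  fourth <- quadrant_enrichment(scan, 1.3, "fourth")
  expect_gt(fourth$p_enrichment, 0.5) # opposite quadrant shows no enrichment
  expect_lt(fourth$p_depletion, 0.05)
})

test_that("expression classes take top/bottom slices among recorded genes", {
  scan <- make_scan(rep(0.2, 40), rep(1.5, 40))
  expr <- tibble::tibble(gene_id = scan$id,
                         mrna_level = seq_len(40))
  cls <- expression_classes(expr, scan, top = 10, bottom = 10)
  expect_equal(sum(cls$class == "high"), 10L)
  expect_equal(sum(cls$class == "low"), 10L)
  expect_setequal(cls$gene_id[cls$class == "high"], scan$id[31:40])
  expect_setequal(cls$gene_id[cls$class == "low"], scan$id[1:10])

  # unrecorded genes are ignored; genes not in the scan drop out
  expr2 <- expr[1:30, ]
  cls2 <- expression_classes(expr2, scan[1:20, ], top = 5, bottom = 5)
  expect_true(all(cls2$gene_id %in% scan$id[1:20]))
  expect_setequal(cls2$gene_id[cls2$class == "low"], scan$id[1:5])

  expect_error(expression_classes(expr, scan, top = 25, bottom = 25),
               "overlap")
})

test_that("ties at the cut resolve deterministically by level then id", {
  scan <- make_scan(rep(0.2, 6), rep(1.5, 6))
  expr <- tibble::tibble(gene_id = scan$id,
                         mrna_level = c(5, 5, 5, 1, 1, 1))
  cls <- expression_classes(expr, scan, top = 2, bottom = 2)
  expect_equal(sort(cls$gene_id[cls$class == "high"]), scan$id[1:2])
  expect_equal(sort(cls$gene_id[cls$class == "low"]), scan$id[4:5])
})
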