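# Expression-library statistics: per-cell abundance normalization,
# (partial) correlations, bottleneck-vs-expression analysis, the per-codon
# fitness scan, and the partial-correlation codon ranking.

check_library_tbl <- function(library, need_od = TRUE) {
  need <- c("variant_id", "seq", "protein_abundance", "od")
  if (!is.data.frame(library) || !all(need %in% names(library))) {
    stop("library table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(library$protein_abundance < 0)) {
    stop("protein abundance must be non-negative", call. = FALSE)
  }
  if (need_od && any(library$od <= 0)) {
    stop("optical density must be strictly positive", call. = FALSE)
  }
  invisible(library)
}

#' Per-cell protein abundance
#'
#' Divides bulk protein abundance by optical density (a proxy for population
#' size), yielding abundance per cell. Measurements taken at a fixed culture
#' density are already per-cell: set `normalize_od = FALSE` to pass the
#' abundance through unchanged.
#'
#' @param library Library tibble with `variant_id`, `seq`,
#'   `protein_abundance`, `od` (and optionally `folding_energy`).
#' @param normalize_od Divide by OD? Default `TRUE`.
#' @return The input with a `per_cell_abundance` column appended.
#' @export
per_cell_abundance <- function(library, normalize_od = TRUE) {
  check_library_tbl(library, need_od = normalize_od)
  dplyr::mutate(library, per_cell_abundance = if (normalize_od) {
    .data$protein_abundance / .data$od
  } else {
    .data$protein_abundance
  })
}

#' Correlation with two-sided p-value
#'
#' Pearson product-moment or Spearman rank correlation (average ranks on
#' ties) with a two-sided p-value from the large-sample t approximation.
#' A zero-variance input yields an undefined result (r and p `NA`,
#' `undefined = TRUE`) rather than an error, mirroring the treatment of
#' constant codon counts in the per-codon scan.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite).
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: `method`, `r`, `p_value`, `n_obs`,
#'   `controlled_for` (`NA` here), `undefined`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in correlation input", call. = FALSE)
  }
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(method = method, r = NA_real_, p_value = NA_real_,
                          n_obs = n, controlled_for = NA_character_,
                          undefined = TRUE))
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  r <- stats::cor(x, y)
  p <- pvalue_from_r(r, df = n - 2)
  tibble::tibble(method = method, r = r, p_value = p, n_obs = n,
                 controlled_for = NA_character_, undefined = FALSE)
}

# two-sided p for a correlation via t = r * sqrt(df / (1 - r^2))
pvalue_from_r <- function(r, df) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}

#' First-order partial correlation
#'
#' Correlation between x and y after removing the linear effect of a single
#' covariate z: r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
#' with a two-sided p-value on n - 3 residual degrees of freedom. The
#' rank-based variant applies the same formula to rank-transformed data.
#' Equivalent to correlating the residuals of x ~ z and y ~ z.
#'
#' @param x,y,z Equal-length numeric vectors (n >= 4, finite).
#' @param method `"pearson"` or `"spearman"`.
#' @param controlled_for Covariate name recorded in the result.
#' @return One-row tibble as in [correlate()], with method
#'   `"partial_pearson"`/`"partial_spearman"`. If z is collinear with x or y
#'   (|r| = 1) the result is flagged undefined.
#' @export
partial_correlate <- function(x, y, z, method = c("pearson", "spearman"),
                              controlled_for = "z") {
  method <- match.arg(method)
  if (length(unique(c(length(x), length(y), length(z)))) != 1L) {
    stop("x, y and z lengths differ", call. = FALSE)
  }
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  if (any(!is.finite(c(x, y, z)))) {
    stop("non-finite values in partial correlation input", call. = FALSE)
  }
  n <- length(x)
  out_method <- paste0("partial_", method)
  undef <- tibble::tibble(method = out_method, r = NA_real_,
                          p_value = NA_real_, n_obs = n,
                          controlled_for = controlled_for, undefined = TRUE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) return(undef)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  denom <- (1 - rxz^2) * (1 - ryz^2)
  if (denom <= .Machine$double.eps) return(undef)
  r <- (rxy - rxz * ryz) / sqrt(denom)
  r <- max(-1, min(1, r))
  tibble::tibble(method = out_method, r = r,
                 p_value = pvalue_from_r(r, df = n - 3), n_obs = n,
                 controlled_for = controlled_for, undefined = FALSE)
}

#' Correlate bottleneck parameters with per-cell protein abundance
#'
#' The library-analysis stage: computes each variant's bottleneck parameters
#' and gene tAI, normalizes abundance per cell, then correlates relative
#' location and relative strength (and tAI) against per-cell abundance --
#' over the whole library and over the proximal-location band -- with both
#' Pearson and Spearman methods. When a `folding_energy` column is present,
#' partial correlations controlling for it are added, separating bottleneck
#' effects from mRNA secondary-structure effects.
#'
#' @param library Library tibble (`variant_id`, `seq`, `protein_abundance`,
#'   `od`, optional `folding_energy`).
#' @param weights A `codon_weight_tbl`.
#' @param n Bottleneck window size in codons (default 21).
#' @param location_band Inclusive relative-location interval defining the
#'   proximal band (default `c(0.16, 0.28)`). `NULL` skips the band analysis.
#' @param normalize_od Passed to [per_cell_abundance()].
#' @return Object of class `bottleneck_expression`: a list with `variants`
#'   (per-variant parameters and measurements) and `correlations` (the
#'   parameter x scope x method grid). Use [generics::tidy()] for the
#'   correlation table, [generics::glance()] for a one-row summary, and
#'   `autoplot()` for the location-vs-abundance scatter.
#' @export
analyze_bottleneck_vs_expression <- function(library,
                                             weights = codon_weights(),
                                             n = 21,
                                             location_band = c(0.16, 0.28),
                                             normalize_od = TRUE) {
  check_library_tbl(library, need_od = normalize_od)
  if (nrow(library) < 3) stop("need at least 3 library records", call. = FALSE)
  scan <- find_bottleneck(library, weights, n)
  tai <- gene_tai(library, weights)
  variants <- per_cell_abundance(library, normalize_od) |>
    dplyr::left_join(dplyr::rename(scan, variant_id = "id"), by = "variant_id") |>
    dplyr::left_join(dplyr::select(dplyr::rename(tai, variant_id = "id"),
                                   "variant_id", "tai"), by = "variant_id")
  have_fe <- "folding_energy" %in% names(variants) &&
    !any(is.na(variants$folding_energy))

  one_scope <- function(dat, scope) {
    params <- c("relative_location", "relative_strength", "tai")
    purrr::map(params, function(p) {
      rows <- dplyr::bind_rows(
        correlate(dat[[p]], dat$per_cell_abundance, "pearson"),
        correlate(dat[[p]], dat$per_cell_abundance, "spearman"),
        if (have_fe) partial_correlate(dat[[p]], dat$per_cell_abundance,
                                       dat$folding_energy, "pearson",
                                       "folding_energy"),
        if (have_fe) partial_correlate(dat[[p]], dat$per_cell_abundance,
                                       dat$folding_energy, "spearman",
                                       "folding_energy"))
      dplyr::mutate(rows, parameter = p, scope = scope, .before = 1)
    }) |> dplyr::bind_rows()
  }

  correlations <- one_scope(variants, "all")
  band_n <- NA_integer_
  if (!is.null(location_band)) {
    band <- variants[variants$relative_location >= location_band[1] &
                     variants$relative_location <= location_band[2], ,
                     drop = FALSE]
    band_n <- nrow(band)
    if (band_n < 3) {
      warning("only ", band_n, " variant(s) in the location band [",
              location_band[1], ", ", location_band[2],
              "]; band analysis skipped", call. = FALSE)
    } else {
      correlations <- dplyr::bind_rows(correlations, one_scope(band, "band"))
    }
  }
  structure(list(variants = variants, correlations = correlations,
                 window_n = n, location_band = location_band,
                 band_n = band_n, normalized = normalize_od),
            class = "bottleneck_expression")
}

#' Per-codon usage vs fitness scan
#'
#' For each of the 61 sense codons, correlates the codon's copy number per
#' variant against optical density (the fitness proxy) with Pearson
#' correlation, and classifies it at a Bonferroni-corrected threshold
#' alpha / 61 (61 is the number of codon tests, fixed regardless of how many
#' turn out constant). Codons whose count never varies across the library
#' are classed `"constant"` and carry no correlation value.
#'
#' @param library Library tibble.
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_tests Bonferroni divisor (default 61).
#' @return Tibble of class `codon_fitness` with one row per sense codon:
#'   `codon`, `amino_acid`, `min_count`, `max_count`, `mean_count`, `r`,
#'   `p_value`, `class` in positive/negative/not_significant/constant.
#'   Attribute `alpha_corrected` holds alpha / n_tests.
#' @export
codon_fitness_scan <- function(library, alpha = 0.05, n_tests = 61) {
  check_library_tbl(library)
  if (nrow(library) < 3) stop("need at least 3 library records", call. = FALSE)
  counts <- codon_count_matrix(library)
  alpha_c <- alpha / n_tests
  rows <- purrr::map(colnames(counts), function(cd) {
    cnt <- counts[, cd]
    base <- tibble::tibble(codon = cd,
                           amino_acid = codon_amino_acid(cd),
                           min_count = min(cnt), max_count = max(cnt),
                           mean_count = mean(cnt))
    cr <- correlate(cnt, library$od, "pearson")
    cls <- if (cr$undefined) {
      "constant"
    } else if (cr$p_value < alpha_c) {
      if (cr$r > 0) "positive" else "negative"
    } else {
      "not_significant"
    }
    dplyr::mutate(base, r = cr$r, p_value = cr$p_value, class = cls)
  }) |> dplyr::bind_rows()
  class(rows) <- c("codon_fitness", class(rows))
  attr(rows, "alpha_corrected") <- alpha_c
  rows
}

#' Rank fitness-reducing codons by minimum absolute partial correlation
#'
#' Three-step ranking of the codons that drive the fitness cost:
#' codons with constant counts are set aside, then (1) codons with a
#' negative raw correlation to OD are kept; (2) for every ordered pair (i, j)
#' of kept codons the partial correlation M(i, j) = r(count_i, OD | count_j)
#' is computed; (3) each codon is scored by min_j |M(i, j)| and codons are
#' ranked by that score, descending. A codon whose association with OD
#' survives control by every other candidate -- no single codon explains it
#' away -- ranks at the top. With a single surviving codon the minimum over
#' an empty controlling set falls back to |raw r|.
#'
#' @param library Library tibble (>= 5 records).
#' @return Tibble of class `codon_rank`, one row per negatively correlated
#'   codon, sorted by `min_abs_partial_r` descending: `rank`, `codon`,
#'   `raw_r`, `raw_p_value`, `min_abs_partial_r`, `controlling_codon` (the
#'   arg-min partner), `partial_p_value` (at the arg-min). Attribute
#'   `excluded_constant` lists codons dropped for constant counts; attribute
#'   `partial_matrix` holds M.
#' @export
rank_fitness_codons <- function(library) {
  check_library_tbl(library)
  if (nrow(library) < 5) stop("need at least 5 library records", call. = FALSE)
  counts <- codon_count_matrix(library)
  variable <- colnames(counts)[apply(counts, 2, function(v) stats::sd(v) > 0)]
  constant <- setdiff(colnames(counts), variable)
  raw <- purrr::map(variable, function(cd) {
    cr <- correlate(counts[, cd], library$od, "pearson")
    tibble::tibble(codon = cd, raw_r = cr$r, raw_p_value = cr$p_value)
  }) |> dplyr::bind_rows()
  neg <- raw[raw$raw_r < 0, , drop = FALSE]
  if (nrow(neg) == 0L) {
    stop("no codon is negatively correlated with OD", call. = FALSE)
  }
  kept <- neg$codon
  # first-order partial correlations for all ordered pairs at once, from the
  # pairwise correlation matrix (identical to partial_correlate pairwise;
  # the equivalence is covered by tests)
  rmat <- stats::cor(cbind(counts[, kept, drop = FALSE], od = library$od))
  r_io <- rmat[kept, "od"]
  r_ij <- rmat[kept, kept, drop = FALSE]
  denom2 <- (1 - r_ij^2) * matrix(1 - r_io^2, nrow = length(kept),
                                  ncol = length(kept), byrow = TRUE)
  m <- (matrix(r_io, length(kept), length(kept)) - r_ij *
          matrix(r_io, length(kept), length(kept), byrow = TRUE)) /
    sqrt(denom2)
  m[denom2 <= .Machine$double.eps] <- NA_real_
  diag(m) <- NA_real_
  m <- pmin(pmax(m, -1), 1)
  dimnames(m) <- list(kept, kept)
  pmat <- matrix(vapply(as.vector(m), function(r) {
    if (is.na(r)) NA_real_ else pvalue_from_r(r, df = nrow(library) - 3)
  }, numeric(1)), nrow = length(kept), dimnames = dimnames(m))
  score <- vapply(kept, function(i) {
    vals <- abs(m[i, setdiff(kept, i)])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) abs(neg$raw_r[neg$codon == i]) else min(vals)
  }, numeric(1))
  argmin <- vapply(kept, function(i) {
    vals <- abs(m[i, setdiff(kept, i), drop = FALSE])
    vals <- vals[, !is.na(vals[1, ]), drop = FALSE]
    if (ncol(vals) == 0L) NA_character_ else colnames(vals)[which.min(vals)]
  }, character(1))
  out <- neg |>
    dplyr::mutate(min_abs_partial_r = unname(score[.data$codon]),
                  controlling_codon = unname(argmin[.data$codon]),
                  partial_p_value = purrr::map2_dbl(
                    .data$codon, .data$controlling_codon,
                    function(i, j) if (is.na(j)) NA_real_ else pmat[i, j])) |>
    dplyr::arrange(dplyr::desc(.data$min_abs_partial_r), .data$codon) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  class(out) <- c("codon_rank", class(out))
  attr(out, "excluded_constant") <- constant
  attr(out, "partial_matrix") <- m
  out
}
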