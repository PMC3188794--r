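# Synthetic synonymous-codon library generator with controllable bottleneck
# geometry, plus a measurement simulator that plants the statistical
# structure the analysis stage is designed to detect: proximal + strong
# bottlenecks raise per-cell abundance, specific codon counts depress OD.

#' Bundled synthetic GFP-like amino-acid sequence
#'
#' A fixed 239-residue sequence whose composition loosely mimics GFP
#' (glycine/lysine/leucine rich, ~10 serines, a histidine-rich tail). It is a
#' synthetic stand-in generated for this package, not the GFP sequence.
#'
#' @return Single amino-acid string of length 239.
#' @export
gfp_like_aa <- function() {
  lines <- readLines(system.file("extdata", "gfp_like_aa_synthetic.txt",
                                 package = "ribotraffic", mustWork = TRUE))
  paste(lines[!startsWith(lines, "#")], collapse = "")
}

#' Specification of a synthetic synonymous library
#'
#' @param aa_sequence Amino-acid string every variant must translate to
#'   (default [gfp_like_aa()]). Must start from the 20 standard letters.
#' @param n_variants Number of variants (>= 3; default 150).
#' @param seed Integer seed; the whole generation is reproducible from it.
#' @param codon_policy `"planted_bottleneck"` tilts synonymous choices so a
#'   chosen window is slow and the rest fast; `"uniform_synonymous"` samples
#'   synonyms uniformly; `"frequency_weighted"` samples proportionally to the
#'   codon weights.
#' @param planted For the planted policy: list with `relative_location`,
#'   `relative_strength` and `window_n`. The first two may each be a single
#'   target shared by all variants, or a length-2 range from which each
#'   variant draws its own target uniformly (the default ranges give the
#'   between-variant variation that correlation recovery needs).
#' @return List of class `library_spec`.
#' @export
library_spec <- function(aa_sequence = gfp_like_aa(),
                         n_variants = 150,
                         seed = 101,
                         codon_policy = c("planted_bottleneck",
                                          "uniform_synonymous",
                                          "frequency_weighted"),
                         planted = list(relative_location = c(0.05, 0.65),
                                        relative_strength = c(1.2, 2.0),
                                        window_n = 21)) {
  codon_policy <- match.arg(codon_policy)
  if (n_variants < 3) stop("n_variants must be >= 3", call. = FALSE)
  aa_sequence <- toupper(aa_sequence)
  bad <- setdiff(unique(strsplit(aa_sequence, "")[[1]]),
                 unique(codon_amino_acid(sense_codons())))
  if (length(bad) > 0L) {
    stop("non-standard amino acid letters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (codon_policy == "planted_bottleneck") {
    rl <- range(planted$relative_location)
    rs <- range(planted$relative_strength)
    if (rl[1] <= 0 || rl[2] > 1) {
      stop("planted relative_location must lie in (0, 1]", call. = FALSE)
    }
    if (rs[1] < 1) {
      stop("planted relative_strength must be >= 1", call. = FALSE)
    }
    if (planted$window_n > nchar(aa_sequence)) {
      stop("planted window_n exceeds the protein length", call. = FALSE)
    }
  }
  structure(list(aa_sequence = aa_sequence, n_variants = n_variants,
                 seed = as.integer(seed), codon_policy = codon_policy,
                 planted = planted),
            class = "library_spec")
}

# draw a scalar target from a scalar-or-range field
draw_target <- function(field) {
  if (length(field) == 1L) field else stats::runif(1, field[1], field[2])
}

#' Generate a synonymous-codon library
#'
#' Back-translates the spec's amino-acid sequence once per variant. Under
#' `planted_bottleneck`, synonymous choices inside the planted window are
#' sampled with probability proportional to w^-b (favoring slow codons) and
#' outside proportional to w^b (favoring fast codons), where the inside tilt
#' grows with the planted strength target; a bottleneck scan then recovers
#' the planted location for the large majority of variants. Strength targets
#' are best-effort: windows dominated by single-synonym amino acids (M, W)
#' cannot be slowed, and a warning is issued if a planted window is mostly
#' single-synonym.
#'
#' @param spec A [library_spec()].
#' @param weights A `codon_weight_tbl`.
#' @return Tibble with `variant_id`, `seq`, and (planted policy) the drawn
#'   `target_relative_location` and `target_relative_strength`. Every
#'   sequence translates exactly to `spec$aa_sequence`; generation is
#'   byte-reproducible from `spec$seed`.
#' @export
generate_library <- function(spec, weights = codon_weights()) {
  stopifnot(inherits(spec, "library_spec"))
  w <- weight_vector(weights)
  syn <- synonymous_codons()
  aa <- strsplit(spec$aa_sequence, "")[[1]]
  l <- length(aa)
  set.seed(spec$seed)
  planted_policy <- spec$codon_policy == "planted_bottleneck"
  n_win <- if (planted_policy) spec$planted$window_n else NA_integer_

  sample_group <- function(codons, size, prob = NULL) {
    if (length(codons) == 1L) rep(codons, size)
    else codons[sample.int(length(codons), size, replace = TRUE, prob = prob)]
  }

  rows <- purrr::map(seq_len(spec$n_variants), function(v) {
    codons <- character(l)
    t_loc <- t_str <- NA_real_
    if (planted_policy) {
      t_loc <- draw_target(spec$planted$relative_location)
      t_str <- draw_target(spec$planted$relative_strength)
      k <- max(1L, min(l - n_win + 1L, round(t_loc * (l - n_win + 1L))))
      inside <- seq.int(k, k + n_win - 1L)
      single <- vapply(syn[aa[inside]], length, integer(1)) == 1L
      if (mean(single) > 0.5) {
        warning("planted window is dominated by single-synonym amino acids; ",
                "strength target is best-effort", call. = FALSE)
      }
      b_in <- 2 + 2 * (t_str - 1)
      for (a in unique(aa)) {
        cods <- syn[[a]]
        pos <- which(aa == a)
        pin <- intersect(pos, inside)
        pout <- setdiff(pos, inside)
        if (length(pin) > 0L) {
          codons[pin] <- sample_group(cods, length(pin), w[cods]^(-b_in))
        }
        if (length(pout) > 0L) {
          codons[pout] <- sample_group(cods, length(pout), w[cods]^3)
        }
      }
    } else {
      prob_of <- switch(spec$codon_policy,
        uniform_synonymous = function(cods) NULL,
        frequency_weighted = function(cods) w[cods])
      for (a in unique(aa)) {
        cods <- syn[[a]]
        pos <- which(aa == a)
        codons[pos] <- sample_group(cods, length(pos), prob_of(cods))
      }
    }
    seqstr <- paste(codons, collapse = "")
    tibble::tibble(variant_id = sprintf("var%03d", v), seq = seqstr,
                   target_relative_location = t_loc,
                   target_relative_strength = t_str)
  })
  out <- dplyr::bind_rows(rows)
  if (!planted_policy) {
    out$target_relative_location <- NULL
    out$target_relative_strength <- NULL
  }
  # translation fidelity is a hard invariant of the generator
  ok <- vapply(out$seq, function(s) translate_codons(s) == spec$aa_sequence,
               logical(1))
  stopifnot(all(ok))
  out
}

#' Effect model for simulated measurements
#'
#' Encodes, as generative truth, the qualitative structure the analysis is
#' meant to detect: log per-cell abundance rises for proximal
#' (`beta_location` <= 0 acting on relative location) and, within the
#' proximal region, strong bottlenecks (`beta_strength_proximal` >= 0);
#' folding energy acts as an independent covariate; OD falls linearly with
#' the copy numbers of the penalized codons (`gamma`, defaulting to TCA and
#' CAT -- UCA and CAU in RNA letters -- whose rare cognate tRNAs make them
#' natural fitness liabilities).
#'
#' @param beta_location Effect of relative location on log per-cell
#'   abundance (<= 0).
#' @param beta_strength_proximal Effect of relative strength when the
#'   bottleneck lies at relative location <= `proximal_cutoff` (>= 0).
#' @param proximal_cutoff Relative-location cutoff for the strength effect.
#' @param beta_folding Effect of folding energy (kcal/mol; positive means
#'   less stable mRNA -> more protein).
#' @param gamma Named non-negative vector of per-copy OD penalties by codon.
#' @param noise_sd_abundance,noise_sd_od Gaussian noise SDs (> 0).
#' @param od_baseline Baseline OD (> 0).
#' @param od_floor Positive floor applied to OD after penalties and noise.
#' @param intercept Baseline log per-cell abundance.
#' @param folding_mean,folding_sd Distribution of the simulated folding
#'   energy covariate (kcal/mol).
#' @return List of class `effect_model`.
#' @export
effect_model <- function(beta_location = -1.2,
                         beta_strength_proximal = 2,
                         proximal_cutoff = 0.28,
                         beta_folding = 0.1,
                         gamma = c(TCA = 0.08, CAT = 0.08),
                         noise_sd_abundance = 0.3,
                         noise_sd_od = 0.05,
                         od_baseline = 2,
                         od_floor = 0.05,
                         intercept = 7,
                         folding_mean = -8,
                         folding_sd = 2) {
  if (beta_location > 0) stop("beta_location must be <= 0", call. = FALSE)
  if (beta_strength_proximal < 0) {
    stop("beta_strength_proximal must be >= 0", call. = FALSE)
  }
  if (noise_sd_abundance < 0 || noise_sd_od < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  if (od_baseline <= 0 || od_floor <= 0) {
    stop("od_baseline and od_floor must be > 0", call. = FALSE)
  }
  if (length(gamma) > 0 &&
      (is.null(names(gamma)) || any(!names(gamma) %in% sense_codons()) ||
       any(gamma < 0))) {
    stop("gamma must be a non-negative vector named by sense codons",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "effect_model")
}

#' Simulate library measurements from planted effects
#'
#' Computes each variant's bottleneck parameters, then draws folding energy
#' ~ Normal(folding_mean, folding_sd), log per-cell abundance =
#' intercept + beta_location * relative_location + beta_strength_proximal *
#' relative_strength * \[relative_location <= cutoff\] + beta_folding *
#' folding_energy + noise, and OD = od_baseline - sum_c gamma_c * count_c +
#' noise, floored at `od_floor`. Bulk protein abundance is per-cell
#' abundance times OD, so [per_cell_abundance()] inverts the population
#' scaling exactly.
#'
#' @param variants Tibble with `variant_id`, `seq` ([generate_library()]).
#' @param weights A `codon_weight_tbl`.
#' @param model An [effect_model()].
#' @param seed Integer seed for the measurement noise.
#' @param n Bottleneck window size (default 21).
#' @return Library tibble: `variant_id`, `seq`, `protein_abundance`, `od`,
#'   `folding_energy`. Attribute `truth` carries the per-variant latent
#'   values (bottleneck parameters, per-cell abundance).
#' @export
simulate_measurements <- function(variants, weights = codon_weights(),
                                  model = effect_model(), seed = 1, n = 21) {
  stopifnot(inherits(model, "effect_model"))
  if (nrow(variants) < 3) stop("need at least 3 variants", call. = FALSE)
  scan <- find_bottleneck(variants, weights, n)
  set.seed(seed)
  nv <- nrow(variants)
  fe <- stats::rnorm(nv, model$folding_mean, model$folding_sd)
  proximal <- as.numeric(scan$relative_location <= model$proximal_cutoff)
  log_pc <- model$intercept +
    model$beta_location * scan$relative_location +
    model$beta_strength_proximal * scan$relative_strength * proximal +
    model$beta_folding * fe +
    stats::rnorm(nv, 0, model$noise_sd_abundance)
  penalty <- rep(0, nv)
  if (length(model$gamma) > 0) {
    counts <- codon_count_matrix(variants)
    penalty <- as.numeric(counts[, names(model$gamma), drop = FALSE] %*%
                            model$gamma)
  }
  od_raw <- model$od_baseline - penalty + stats::rnorm(nv, 0, model$noise_sd_od)
  floored <- od_raw < model$od_floor
  if (mean(floored) > 0.1) {
    stop(sum(floored), " of ", nv, " variants hit the OD floor; ",
         "reduce the codon penalties or raise od_baseline", call. = FALSE)
  }
  od <- pmax(od_raw, model$od_floor)
  per_cell <- exp(log_pc)
  out <- tibble::tibble(variant_id = variants$variant_id, seq = variants$seq,
                        protein_abundance = per_cell * od, od = od,
                        folding_energy = fe)
  attr(out, "truth") <- dplyr::mutate(scan, per_cell_abundance = per_cell,
                                      proximal = proximal == 1)
  out
}

#' Analytic target correlations implied by the effect model
#'
#' Given the realized bottleneck parameters of a library and the effect
#' model that generated its measurements, computes the correlations the
#' analysis should recover: corr(x, y) where y = deterministic mean of log
#' per-cell abundance plus the independent folding and noise terms, for
#' x = relative location (whole library) and x = relative strength (within
#' the proximal band). Pure variance algebra -- no simulated measurements
#' are used.
#'
#' @param scan Bottleneck scan tibble of the library's variants.
#' @param model The [effect_model()] used for simulation.
#' @param location_band Inclusive band for the strength target (default
#'   `c(0.16, 0.28)`).
#' @return Tibble with `parameter`, `scope`, `target_r`.
#' @export
planted_correlation_targets <- function(scan, model,
                                        location_band = c(0.16, 0.28)) {
  extra_var <- model$beta_folding^2 * model$folding_sd^2 +
    model$noise_sd_abundance^2
  target <- function(dat, x) {
    ind <- as.numeric(dat$relative_location <= model$proximal_cutoff)
    mu <- model$beta_location * dat$relative_location +
      model$beta_strength_proximal * dat$relative_strength * ind
    if (stats::sd(dat[[x]]) == 0 || stats::sd(mu) == 0) return(NA_real_)
    stats::cov(mu, dat[[x]]) /
      (stats::sd(dat[[x]]) * sqrt(stats::var(mu) + extra_var))
  }
  band <- scan[scan$relative_location >= location_band[1] &
               scan$relative_location <= location_band[2], , drop = FALSE]
  tibble::tibble(
    parameter = c("relative_location", "relative_strength"),
    scope = c("all", "band"),
    target_r = c(target(scan, "relative_location"),
                 if (nrow(band) >= 3) target(band, "relative_strength")
                 else NA_real_))
}

#' Default synthetic library (generation + measurements)
#'
#' Convenience wrapper producing the package's default study library: 150
#' planted-bottleneck variants of the GFP-like protein with simulated
#' abundance, OD and folding energy under the default [effect_model()].
#'
#' @param seed Integer seed controlling both generation and measurements.
#' @param weights A `codon_weight_tbl`.
#' @param n_variants Number of variants (default 150).
#' @param model An [effect_model()].
#' @return Library tibble as from [simulate_measurements()].
#' @export
default_library <- function(seed = 101, weights = codon_weights(),
                            n_variants = 150, model = effect_model()) {
  spec <- library_spec(n_variants = n_variants, seed = seed)
  variants <- generate_library(spec, weights)
  simulate_measurements(variants, weights, model, seed = seed + 1)
}
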