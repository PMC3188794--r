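# Pipeline configuration and runnable steps tying the stages together.
# Each step writes its module's TSV artifacts plus a run manifest (config
# echo, package version, input checksums, seed) so a run can be reproduced
# bit-identically.

#' Pipeline configuration
#'
#' Collects every analysis constant in one overridable, serializable place:
#' window size 21 codons, minimum gene length 101 codons (genes longer than
#' 100), strength threshold 1.3, proximal band 0.16-0.28, alpha 0.05 with
#' Bonferroni divisor 61, CGA weight override 0.1333.
#'
#' @param window_n Bottleneck window size in codons.
#' @param min_gene_length Minimum gene length in codons for genome surveys.
#' @param strength_threshold Strict relative-strength cutoff for enrichment.
#' @param proximal_band Inclusive relative-location band, lo < hi.
#' @param alpha Family-wise significance level.
#' @param bonferroni_divisor Number of codon tests.
#' @param cga_weight Weight override for codon CGA.
#' @param expression_top,expression_bottom Sizes of the highly/lowly
#'   expressed slices used by the genome-survey step.
#' @param seed Integer seed for stochastic steps.
#' @param paths Named list of input/output paths used by [run_pipeline()]:
#'   `orf_fasta`, `library_table`, `variant_fasta`, `expression_table`,
#'   `trna_pool`, `s_values`, `out_dir`.
#' @return List of class `pipeline_config`; round-trips losslessly through
#'   YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#' @export
pipeline_config <- function(window_n = 21, min_gene_length = 101,
                            strength_threshold = 1.3,
                            proximal_band = c(0.16, 0.28),
                            alpha = 0.05, bonferroni_divisor = 61,
                            cga_weight = 0.1333,
                            expression_top = 500, expression_bottom = 500,
                            seed = 1,
                            paths = list()) {
  cfg <- list(window_n = as.integer(window_n),
              min_gene_length = as.integer(min_gene_length),
              strength_threshold = strength_threshold,
              proximal_band = as.numeric(proximal_band),
              alpha = alpha,
              bonferroni_divisor = as.integer(bonferroni_divisor),
              cga_weight = cga_weight,
              expression_top = as.integer(expression_top),
              expression_bottom = as.integer(expression_bottom),
              seed = as.integer(seed),
              paths = paths)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$window_n < 1 || cfg$min_gene_length < 1 ||
      cfg$strength_threshold <= 0 || cfg$alpha <= 0 ||
      cfg$bonferroni_divisor < 1 || cfg$cga_weight <= 0 ||
      cfg$expression_top < 1 || cfg$expression_bottom < 1) {
    stop("config error: all thresholds must be positive", call. = FALSE)
  }
  if (length(cfg$proximal_band) != 2 ||
      cfg$proximal_band[1] >= cfg$proximal_band[2]) {
    stop("config error: proximal_band must satisfy lo < hi", call. = FALSE)
  }
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file.
#' @return `write_pipeline_config()` the path invisibly;
#'   `read_pipeline_config()` the config.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

write_manifest <- function(out_dir, step, config, inputs, outputs) {
  inputs <- unlist(inputs)
  inputs <- if (length(inputs) > 0) inputs[file.exists(inputs)] else character()
  manifest <- list(
    step = step,
    tool = paste0("ribotraffic ",
                  as.character(utils::packageVersion("ribotraffic"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(inputs)),
    outputs = unlist(outputs, use.names = FALSE))
  path <- file.path(out_dir, paste0(step, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

config_weights <- function(config) {
  pool <- if (!is.null(config$paths$trna_pool)) {
    read_trna_pool(config$paths$trna_pool)
  } else trna_pool_default()
  sv <- if (!is.null(config$paths$s_values)) {
    read_s_values(config$paths$s_values)
  } else s_values_default()
  codon_weights(pool, sv, cga_weight = config$cga_weight)
}

#' Run one pipeline step
#'
#' Steps mirror the analysis stages: `"scan"` (bottleneck scan of an ORF
#' FASTA), `"library-analyze"` (bottleneck-vs-expression correlations,
#' per-codon fitness scan and codon ranking for a measurement table +
#' variant FASTA), `"genome-survey"` (length-filtered batch scan, location
#' histogram, quadrant enrichment, optional expression classes),
#' `"codon-usage"` (genome and, given expression data, transcriptome
#' profiles), `"simulate"` (write the default synthetic library). Each step
#' writes TSV artifacts and a JSON manifest into `config$paths$out_dir` and
#' returns the written paths.
#'
#' @param step One of `"scan"`, `"library-analyze"`, `"genome-survey"`,
#'   `"codon-usage"`, `"simulate"`.
#' @param config A [pipeline_config()]; its `paths` entries name the inputs.
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(step = c("scan", "library-analyze", "genome-survey",
                                  "codon-usage", "simulate"),
                         config = pipeline_config()) {
  step <- match.arg(step)
  validate_pipeline_config(config)
  out_dir <- config$paths$out_dir %||% stop("config error: paths$out_dir unset",
                                            call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  weights <- config_weights(config)
  p <- function(name) file.path(out_dir, name)
  inputs <- config$paths[setdiff(names(config$paths), "out_dir")]
  outputs <- list()

  if (step == "scan") {
    orfs <- read_orf_fasta(config$paths$orf_fasta)
    scan <- find_bottleneck(orfs, weights, config$window_n)
    outputs$scan <- write_bottleneck_scan(scan, p("bottleneck_scan.tsv"))
  } else if (step == "library-analyze") {
    library_tbl <- read_library_table(config$paths$library_table,
                                      config$paths$variant_fasta)
    ana <- analyze_bottleneck_vs_expression(
      library_tbl, weights, config$window_n, config$proximal_band)
    outputs$correlations <- write_result_tsv(
      ana$correlations, p("bottleneck_expression_correlations.tsv"),
      "parameter x measurement correlation grid; per-cell abundance = protein/OD")
    outputs$variants <- write_bottleneck_scan(
      dplyr::select(ana$variants, -"seq"), p("variant_parameters.tsv"))
    scan_fit <- codon_fitness_scan(library_tbl, config$alpha,
                                   config$bonferroni_divisor)
    outputs$codon_fitness <- write_result_tsv(
      scan_fit, p("codon_fitness.tsv"),
      paste0("per-codon count vs OD (Pearson); corrected alpha = ",
             signif(attr(scan_fit, "alpha_corrected"), 4)))
    ranked <- rank_fitness_codons(library_tbl)
    outputs$codon_rank <- write_result_tsv(
      ranked, p("codon_rank.tsv"),
      "codons ranked by min |partial r(count, OD | other codon)|, descending")
  } else if (step == "genome-survey") {
    orfs <- read_orf_fasta(config$paths$orf_fasta)
    scan <- survey_genome(orfs, weights, config$window_n,
                          config$min_gene_length)
    outputs$scan <- write_bottleneck_scan(scan, p("genome_scan.tsv"))
    outputs$skipped <- write_result_tsv(
      attr(scan, "skipped"), p("genome_scan_skipped.tsv"),
      paste0("genes shorter than ", config$min_gene_length, " codons"))
    outputs$histogram <- write_result_tsv(
      location_histogram(scan), p("location_histogram.tsv"),
      "bottleneck relative-location histogram, 20 bins")
    enr <- dplyr::bind_rows(lapply(
      c("first", "second", "third", "fourth"),
      function(q) quadrant_enrichment(scan, config$strength_threshold, q)))
    outputs$enrichment <- write_result_tsv(
      enr, p("quadrant_enrichment.tsv"),
      "hypergeometric enrichment/depletion of strong bottlenecks by quadrant")
    if (!is.null(config$paths$expression_table)) {
      expr <- read_expression_levels(config$paths$expression_table)
      outputs$classes <- write_result_tsv(
        expression_classes(expr, scan, config$expression_top,
                           config$expression_bottom),
        p("expression_classes.tsv"),
        "top/bottom expression slices intersected with the scanned genes")
    }
  } else if (step == "codon-usage") {
    orfs <- read_orf_fasta(config$paths$orf_fasta)
    outputs$genome <- write_codon_usage(codon_usage(orfs),
                                        p("codon_usage_genome.tsv"))
    if (!is.null(config$paths$expression_table)) {
      expr <- read_expression_levels(config$paths$expression_table)
      outputs$transcriptome <- write_codon_usage(
        codon_usage(orfs, expr), p("codon_usage_transcriptome.tsv"))
    }
  } else if (step == "simulate") {
    library_tbl <- default_library(seed = config$seed, weights = weights)
    outputs$fasta <- write_orf_fasta(library_tbl, p("simulated_variants.fasta"))
    outputs$table <- write_result_tsv(
      dplyr::select(library_tbl, -"seq"), p("simulated_library.tsv"),
      "simulated measurements; folding_energy in kcal/mol")
  }

  outputs$manifest <- write_manifest(out_dir, step, config, inputs, outputs)
  invisible(outputs)
}
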