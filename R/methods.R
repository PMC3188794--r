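# broom-style tidy()/glance() methods, autoplot() figures, and print methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.bottleneck_expression <- function(x, ...) x$correlations

#' @export
glance.bottleneck_expression <- function(x, ...) {
  tibble::tibble(n_variants = nrow(x$variants),
                 n_band = x$band_n,
                 window_n = x$window_n,
                 band_lo = x$location_band[1] %||% NA_real_,
                 band_hi = x$location_band[2] %||% NA_real_,
                 od_normalized = x$normalized)
}

#' @export
tidy.codon_fitness <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "codon_fitness")
  out
}

#' @export
glance.codon_fitness <- function(x, ...) {
  tibble::tibble(alpha_corrected = attr(x, "alpha_corrected"),
                 n_positive = sum(x$class == "positive"),
                 n_negative = sum(x$class == "negative"),
                 n_constant = sum(x$class == "constant"))
}

#' @export
tidy.codon_rank <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "codon_rank")
  out
}

#' @export
print.bottleneck_expression <- function(x, ...) {
  cat("Bottleneck vs expression analysis\n")
  cat("  variants:", nrow(x$variants), " window:", x$window_n, "codons\n")
  if (!is.null(x$location_band)) {
    cat("  proximal band [", x$location_band[1], ", ", x$location_band[2],
        "]: ", x$band_n, " variants\n", sep = "")
  }
  print(x$correlations, ...)
  invisible(x)
}

#' Scatter of bottleneck location vs per-cell abundance
#'
#' One point per variant, colored by relative strength, with the proximal
#' band marked by vertical lines.
#'
#' @param object A `bottleneck_expression` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bottleneck_expression <- function(object, ...) {
  p <- ggplot2::ggplot(object$variants,
                       ggplot2::aes(x = .data$relative_location,
                                    y = .data$per_cell_abundance,
                                    colour = .data$relative_strength)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "relative strength") +
    ggplot2::labs(x = "bottleneck relative location",
                  y = "per-cell protein abundance") +
    ggplot2::theme_minimal()
  if (!is.null(object$location_band)) {
    p <- p + ggplot2::geom_vline(xintercept = object$location_band,
                                 linetype = "dashed")
  }
  p
}

#' Per-codon fitness correlation bar chart
#'
#' Bar height is the Pearson correlation of codon count with OD; bars are
#' colored by significance class at the Bonferroni-corrected alpha. Constant
#' codons have no bar.
#'
#' @param object A `codon_fitness` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.codon_fitness <- function(object, ...) {
  dat <- object[object$class != "constant", , drop = FALSE]
  dat$label <- paste0(dat$codon, " (", dat$amino_acid, ")")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$r,
                                    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(positive = "#c0392b",
                                          negative = "#2980b9",
                                          not_significant = "grey70")) +
    ggplot2::labs(x = NULL, y = "Pearson r (codon count vs OD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Histogram of bottleneck relative locations
#'
#' @param scan A bottleneck scan tibble.
#' @param bins Number of bins (default 20).
#' @return A ggplot.
#' @export
plot_location_distribution <- function(scan, bins = 20) {
  h <- location_histogram(scan, bins)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$fraction)) +
    ggplot2::geom_col(width = 1 / bins, fill = "#2c7fb8") +
    ggplot2::labs(x = "bottleneck relative location",
                  y = "fraction of genes") +
    ggplot2::theme_minimal()
}
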