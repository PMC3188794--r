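# Bottleneck scan: the sliding window with minimal harmonic-mean codon weight
# (equivalently maximal mean translation time), the window size derived from
# ribosome spacing, and the analytic ribosome traffic-jam condition.

# Core scan of a time profile t = 1/w. Returns leftmost window maximizing the
# window mean of t (= minimizing the harmonic mean of w). O(l) via cumsum;
# near-maximal windows are re-evaluated by direct summation so that windows
# tied in exact arithmetic (cumsum differences carry rounding noise) break
# toward the leftmost, deterministically.
scan_time_profile <- function(times, n) {
  l <- length(times)
  cs <- c(0, cumsum(times))
  sums <- cs[(n + 1):(l + 1)] - cs[1:(l - n + 1)]
  m <- max(sums)
  cand <- which(sums >= m - 1e-9 * max(1, abs(m)))
  direct <- vapply(cand, function(k) sum(times[k:(k + n - 1)]), numeric(1))
  k <- cand[which.max(direct)] # leftmost tie by which.max
  strength <- mean(times[k:(k + n - 1)])
  list(location_k = k,
       strength = strength,
       relative_location = k / (l - n + 1),
       relative_strength = strength / mean(times))
}

#' Locate and score the translation bottleneck of each gene
#'
#' Slides a window of `n` codons along each coding sequence and returns the
#' window whose codons have the minimal harmonic mean of adaptiveness weights
#' -- equivalently, since time per codon is 1/w, the window with the longest
#' mean translation time. Ties are broken toward the leftmost (most proximal)
#' window, deterministically.
#'
#' The bottleneck `strength` is the arithmetic mean of 1/w over the window;
#' `relative_strength` divides by the gene-wide mean of 1/w (so a gene whose
#' window is no slower than average scores 1). `relative_location` is the
#' 1-based window start divided by the number of possible windows
#' (l - n + 1), spanning (0, 1].
#'
#' @param orfs Data frame with `id` (or `variant_id`) and `seq` columns.
#' @param weights A `codon_weight_tbl` from [codon_weights()].
#' @param n Window size in codons (default 21, the mean ribosome-to-ribosome
#'   spacing; see [window_size_from_spacing()]).
#' @return Tibble with one row per gene: `id`, `length_codons`, `window_n`,
#'   `location_k`, `relative_location`, `strength`, `relative_strength`.
#' @seealso [survey_genome()] for batch scans that skip short genes instead
#'   of failing.
#' @export
#' @examples
#' w <- codon_weights()
#' find_bottleneck(tibble::tibble(id = "g1",
#'   seq = strrep("ATGGAACGTCGA", 4)), w, n = 4)
find_bottleneck <- function(orfs, weights = codon_weights(), n = 21) {
  id_col <- if ("variant_id" %in% names(orfs)) "variant_id" else "id"
  check_orf_tbl(orfs, id_col)
  if (n < 1 || n != round(n)) stop("window size n must be a positive integer",
                                   call. = FALSE)
  w <- weight_vector(weights)
  rows <- purrr::map(seq_len(nrow(orfs)), function(i) {
    id <- orfs[[id_col]][i]
    codons <- split_codons(orfs$seq[i], id)
    l <- length(codons)
    if (l < n) {
      stop("gene '", id, "' has ", l, " codons, shorter than the window (n = ",
           n, "); cannot scan", call. = FALSE)
    }
    res <- scan_time_profile(unname(1 / w[codons]), n)
    tibble::tibble(id = id, length_codons = l, window_n = as.integer(n),
                   location_k = as.integer(res$location_k),
                   relative_location = res$relative_location,
                   strength = res$strength,
                   relative_strength = res$relative_strength)
  })
  dplyr::bind_rows(rows)
}

#' Window size from ribosome-to-ribosome spacing
#'
#' Converts a physical ribosome spacing on the mRNA into a codon count:
#' round(distance / nm_per_base / 3). The measured mean center-to-center
#' distance of 21.6 nm on bacterial polysomes gives 21 codons at 0.34 nm per
#' base; the 10.2 nm ribosome footprint gives 10 codons.
#'
#' @param distance_nm Physical distance in nanometres (> 0).
#' @param nm_per_base Helix rise per base in nanometres (default 0.34).
#' @return Integer number of codons.
#' @export
#' @examples
#' window_size_from_spacing(21.6) # 21
window_size_from_spacing <- function(distance_nm, nm_per_base = 0.34) {
  if (any(distance_nm <= 0) || any(nm_per_base <= 0)) {
    stop("distance and nm-per-base must both be positive", call. = FALSE)
  }
  as.integer(round(distance_nm / nm_per_base / 3))
}

#' Analytic ribosome traffic-jam condition
#'
#' With ribosomes H codons apart under fast initiation, a trailing ribosome
#' collides with the leading one iff some window's translation time
#' Tw(k, H) = sum of t(i) for i = k..k+H-1 exceeds the first window's time
#' plus the initiation assembly time B: max_k Tw(k, H) > Tw(1, H) + B,
#' strictly. Equality means the trailing ribosome arrives exactly on time --
#' no jam.
#'
#' @param profile Numeric vector of per-codon translation times (e.g. the
#'   `time` column of [time_profile()]).
#' @param H Ribosome spacing in codons (window length).
#' @param B Assembly time of a ribosome on the start codon, >= 0, same units
#'   as `profile`. The underlying model leaves B free; no default is imposed.
#' @return A one-row tibble of class `jam_prediction`: `jam` (logical),
#'   `argmax_k` (leftmost window start maximizing Tw), `max_window_time`,
#'   `reference_time` (= Tw(1, H) + B), `H`, `B`.
#' @export
#' @examples
#' predict_jam(c(1, 1, 1, 5, 5), H = 2, B = 0)
predict_jam <- function(profile, H, B) {
  if (!is.numeric(profile) || any(!is.finite(profile))) {
    stop("profile must be a finite numeric vector", call. = FALSE)
  }
  if (length(profile) < H) {
    stop("profile has ", length(profile), " codons, shorter than H = ", H,
         call. = FALSE)
  }
  if (B < 0) stop("assembly time B must be >= 0", call. = FALSE)
  l <- length(profile)
  cs <- c(0, cumsum(profile))
  tw <- cs[(H + 1):(l + 1)] - cs[1:(l - H + 1)]
  k <- which.max(tw)
  ref <- tw[1] + B
  out <- tibble::tibble(jam = unname(tw[k] > ref),
                        argmax_k = as.integer(k),
                        max_window_time = unname(tw[k]),
                        reference_time = unname(ref),
                        H = as.integer(H), B = B)
  class(out) <- c("jam_prediction", class(out))
  out
}

#' Write a bottleneck scan table as TSV
#'
#' @param scan Tibble from [find_bottleneck()] or [survey_genome()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_bottleneck_scan <- function(scan, path) {
  write_result_tsv(scan, path, comments = c(
    "bottleneck scan; location_k is a 1-based codon index",
    "relative_location = location_k / (length_codons - window_n + 1)",
    "strength = mean window 1/w; relative_strength = strength / gene mean 1/w"))
}
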