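# Rarefaction: seeded subsampling of count tables to a common depth
# (hypergeometric, i.e. without replacement) and the matching analytic
# expectation used for rarefaction curves.

#' Rarefy an OTU table to a fixed depth
#'
#' Subsamples every sample (row) to exactly `depth` reads without
#' replacement, via [vegan::rrarefy()]. The draw is reproducible under
#' `seed`.
#'
#' @param table Integer count matrix, rows = samples, columns = OTUs.
#' @param depth Target number of reads per sample; must not exceed the
#'   smallest sample total. Defaults to the smallest sample total (the
#'   "lowest populous sample" convention).
#' @param seed Integer seed for the subsampling draw.
#' @return Integer matrix of the same shape with all row sums equal to
#'   `depth`.
#' @export
rarefy_table <- function(table, depth = min(rowSums(table)), seed = 1L) {
  validate_otu_table(table)
  totals <- rowSums(table)
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1 || depth != round(depth))
    cryodiv_stop("depth_error", "depth must be a positive integer")
  if (depth > min(totals))
    cryodiv_stop("depth_error",
                 paste0("depth ", depth, " exceeds the smallest sample total (",
                        min(totals), ")"))
  set.seed(seed)
  out <- suppressWarnings(vegan::rrarefy(table, depth))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(table)
  out
}

#' Expected richness under rarefaction
#'
#' Analytic expectation of the number of OTUs observed when `depth` reads are
#' drawn without replacement from a sample with counts `counts`:
#' \deqn{E[S_{depth}] = \sum_i \left[1 - \binom{N - N_i}{depth} /
#'   \binom{N}{depth}\right]}
#' with \eqn{N} the sample total. This is the quantity plotted on a
#' rarefaction curve.
#'
#' @param counts Non-negative integer vector of per-OTU counts.
#' @param depth Number of reads drawn, `1 <= depth <= sum(counts)`.
#' @return Expected observed richness (a real number).
#' @examples
#' expected_rarefaction_richness(c(5, 3, 2), 4)
#' @export
expected_rarefaction_richness <- function(counts, depth) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1 || depth != round(depth))
    cryodiv_stop("depth_error", "depth must be a positive integer")
  if (depth > N)
    cryodiv_stop("depth_error", paste0("depth ", depth, " exceeds total count ", N))
  # log-scale binomial ratio; lchoose returns -Inf when N - Ni < depth,
  # making the retention probability exactly 1
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

#' Analytic rarefaction curve
#'
#' Evaluates [expected_rarefaction_richness()] over a grid of depths.
#'
#' @param counts Non-negative integer vector of per-OTU counts.
#' @param depths Integer vector of depths; default 20 evenly spaced depths up
#'   to the sample total.
#' @return Data frame with columns `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts,
                              depths = unique(round(seq(1, sum(counts), length.out = 20)))) {
  data.frame(
    depth = depths,
    expected_richness = vapply(depths, function(d)
      expected_rarefaction_richness(counts, d), numeric(1))
  )
}

# shared count-vector validation for the alpha indices and rarefaction
check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0L || anyNA(counts) ||
      any(counts < 0) || any(counts != round(counts)))
    cryodiv_stop("format_error", "counts must be non-negative integers")
  if (sum(counts) == 0)
    cryodiv_stop("empty_sample_error", "sample has no positive counts")
  counts
}
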