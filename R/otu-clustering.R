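# Average-neighbor OTU definition: agglomerative average-linkage clustering
# of a sequence distance matrix, merging while the closest cluster pair has
# mean between-cluster distance <= the identity cutoff (0.03 for the
# conventional 97% OTU definition).

#' Define OTUs by average-neighbor clustering
#'
#' Clusters sequences from a pairwise distance matrix with the
#' average-neighbor (unweighted pair-group average linkage) criterion: at each
#' step the pair of clusters with the smallest mean between-cluster distance
#' is merged, as long as that mean is at or below `cutoff`. With distances as
#' 1 - fractional identity, `cutoff = 0.03` reproduces the conventional 97%
#' OTU definition. Ties are broken deterministically by merging the
#' lexicographically lowest label pair first.
#'
#' @param dist Symmetric numeric distance matrix with zero diagonal and
#'   unique labels (see [validate_distance_matrix()]).
#' @param cutoff Maximum mean between-cluster distance at which two clusters
#'   may still merge, in \[0, 1\]. Default 0.03.
#' @return Named integer vector mapping each label to an OTU index in
#'   `1..K` (clusters numbered by the position of their first member in the
#'   input label order), with attribute `cutoff`.
#' @examples
#' d <- matrix(c(0, 0.01, 0.5, 0.01, 0, 0.5, 0.5, 0.5, 0), 3, 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' cluster_average_neighbor(d, 0.03)  # a, b together; c alone
#' @export
cluster_average_neighbor <- function(dist, cutoff = 0.03) {
  validate_distance_matrix(dist)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1)
    cryodiv_stop("format_error", "cutoff must be a single number in [0, 1]")
  labels <- rownames(dist)
  n <- length(labels)
  members <- as.list(seq_len(n))          # clusters as index sets
  # pairwise sums of original distances between cluster members; average
  # linkage is recovered as sum / (size_i * size_j)
  sums <- dist
  active <- rep(TRUE, n)
  repr <- labels                          # lexicographically smallest member label
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- NULL
    best_avg <- Inf
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in seq((ii + 1L), length(idx))) {
        a <- idx[ii]; b <- idx[jj]
        avg <- sums[a, b] / (length(members[[a]]) * length(members[[b]]))
        if (avg < best_avg - 1e-15) {
          best_avg <- avg
          best <- c(a, b)
        } else if (abs(avg - best_avg) <= 1e-15 && !is.null(best)) {
          # tie: lowest label pair first
          cand <- sort(c(repr[a], repr[b]))
          cur <- sort(c(repr[best[1L]], repr[best[2L]]))
          if (cand[1L] < cur[1L] || (cand[1L] == cur[1L] && cand[2L] < cur[2L]))
            best <- c(a, b)
        }
      }
    }
    if (best_avg > cutoff) break
    a <- best[1L]; b <- best[2L]
    members[[a]] <- c(members[[a]], members[[b]])
    sums[a, ] <- sums[, a] <- sums[a, ] + sums[b, ]
    sums[a, a] <- 0
    repr[a] <- min(repr[a], repr[b])
    active[b] <- FALSE
  }
  live <- which(active)
  # number clusters by first-member position in the input order
  live <- live[order(vapply(members[live], min, integer(1)))]
  assignment <- integer(n)
  for (k in seq_along(live)) assignment[members[[live[k]]]] <- k
  names(assignment) <- labels
  attr(assignment, "cutoff") <- cutoff
  assignment
}
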