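# Group-difference testing on a distance matrix (ANOSIM) and metric
# ordination (principal coordinates analysis).

# all permutations of 1..n, one per column; guarded to small n
all_perms <- function(n) {
  if (n > 8L) cryodiv_stop("design_error", "exhaustive permutations limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (pos in seq_len(n)) {
    for (j in seq_len(ncol(sub))) {
      k <- k + 1L
      out[, k] <- append(sub[, j] + (sub[, j] >= pos), pos, after = pos - 1L)
    }
  }
  out
}

anosim_statistic <- function(ranks, same_group) {
  m <- length(ranks)
  (mean(ranks[!same_group]) - mean(ranks[same_group])) / (m / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group distances exceed
#' within-group distances. All \eqn{n(n-1)/2} distances are ranked (mid-ranks
#' for ties) and \eqn{R = (\bar r_B - \bar r_W) / (M/2)} with
#' \eqn{M = n(n-1)/2}; \eqn{R \in [-1, 1]}, 0 under no group structure. The
#' p-value is obtained by permuting group labels, with the add-one convention
#' \eqn{p = (1 + \#\{R_{perm} \ge R_{obs}\}) / (1 + n_{perm})}, or by exact
#' enumeration of all label permutations when `exhaustive = TRUE`.
#'
#' @param dist Distance matrix over samples (see
#'   [validate_distance_matrix()]).
#' @param groups Named character vector mapping every sample to a group
#'   label; at least 2 groups, each of size >= 2.
#' @param n_permutations Number of random label permutations (default 999).
#' @param seed Integer seed for the permutation draw.
#' @param exhaustive Enumerate all `n!` label permutations instead
#'   (exact p, includes the identity; `n <= 8`).
#' @return List with elements `R`, `p`, `n_permutations`.
#' @export
anosim <- function(dist, groups, n_permutations = 999L, seed = 1L,
                   exhaustive = FALSE) {
  validate_distance_matrix(dist)
  samples <- rownames(dist)
  missing <- setdiff(samples, names(groups))
  if (length(missing) > 0L)
    cryodiv_stop("grouping_error",
                 paste0("sample(s) without a group: ", paste(missing, collapse = ", ")))
  g <- as.character(groups[samples])
  sizes <- table(g)
  if (length(sizes) < 2L) cryodiv_stop("design_error", "ANOSIM needs at least 2 groups")
  if (any(sizes < 2L)) cryodiv_stop("design_error", "every group needs at least 2 samples")
  if (any(sizes < 5L))
    cryodiv_warn("group(s) with fewer than 5 samples: permutation test has low resolution")
  n <- length(samples)
  ranks <- rank(lower_vec(dist))           # mid-ranks for ties
  pair_i <- row(dist)[lower.tri(dist)]
  pair_j <- col(dist)[lower.tri(dist)]
  same <- g[pair_i] == g[pair_j]
  r_obs <- anosim_statistic(ranks, same)
  if (exhaustive) {
    perms <- all_perms(n)
    r_perm <- apply(perms, 2L, function(p) {
      gp <- g[p]
      anosim_statistic(ranks, gp[pair_i] == gp[pair_j])
    })
    p_val <- mean(r_perm >= r_obs - 1e-12)
    n_perm <- ncol(perms)
  } else {
    set.seed(seed)
    r_perm <- replicate(n_permutations, {
      gp <- sample(g)
      anosim_statistic(ranks, gp[pair_i] == gp[pair_j])
    })
    p_val <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  list(R = r_obs, p = p_val, n_permutations = n_perm)
}

#' Principal coordinates analysis (PCoA)
#'
#' Classical metric scaling of a distance matrix (Gower double-centering of
#' \eqn{-D^2/2} followed by eigendecomposition), via [stats::cmdscale()].
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; axes are ordered by decreasing eigenvalue. Negative
#' eigenvalues (non-Euclidean distances) are reported verbatim, and the
#' proportion of variance explained is computed over the positive eigenvalues
#' only.
#'
#' @param dist Distance matrix (see [validate_distance_matrix()]).
#' @return List with `coordinates` (samples x axes matrix), `eigenvalues`
#'   (all, non-increasing) and `proportion_explained` (one entry per
#'   returned axis).
#' @export
pcoa <- function(dist) {
  validate_distance_matrix(dist)
  n <- nrow(dist)
  if (n < 2L) {
    return(list(coordinates = matrix(0, n, 0, dimnames = list(rownames(dist), NULL)),
                eigenvalues = numeric(0), proportion_explained = numeric(0)))
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dist), k = n - 1L, eig = TRUE))
  coords <- fit$points
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  n_axes <- ncol(coords)
  prop <- if (length(pos) > 0L) {
    head_axes <- seq_len(min(n_axes, length(pos)))
    eig[head_axes] / sum(pos)
  } else numeric(0)
  rownames(coords) <- rownames(dist)
  colnames(coords) <- if (n_axes > 0L) paste0("PCo", seq_len(n_axes)) else NULL
  list(coordinates = coords, eigenvalues = eig, proportion_explained = prop)
}
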