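# Isolation-by-distance analysis: uncorrected genetic distances from an
# alignment, great-circle geographic distances between georeferenced sites,
# global Mantel test, and a Mantel correlogram over Sturge's-rule distance
# classes with Bonferroni correction.

#' Uncorrected genetic distance (p-distance) matrix
#'
#' Pairwise proportion of differing sites between aligned sequences, with
#' pairwise deletion: only columns where both sequences carry an unambiguous
#' base (A, C, G, T or U; U is treated as T) are compared for that pair.
#' `complete_deletion = TRUE` instead drops every column with a gap or
#' ambiguity in any sequence before comparing.
#'
#' @param aln Named character vector of equal-length sequences (see
#'   [read_fasta_alignment()]).
#' @param complete_deletion Use complete instead of pairwise deletion.
#' @return Symmetric distance matrix of p-distances in \[0, 1\].
#' @examples
#' genetic_distance_matrix(c(a = "ACGT", b = "ACGA"))  # 0.25
#' @export
genetic_distance_matrix <- function(aln, complete_deletion = FALSE) {
  validate_alignment(aln)
  n <- length(aln)
  if (n < 2L) cryodiv_stop("format_error", "need at least 2 sequences")
  chars <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  chars[chars == "U"] <- "T"
  ok <- chars == "A" | chars == "C" | chars == "G" | chars == "T"
  if (complete_deletion) {
    keep <- colSums(ok) == n
    if (!any(keep))
      cryodiv_stop("comparability_error", "no alignment column is unambiguous in all sequences")
    chars <- chars[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  labels <- names(aln)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      comp <- ok[i, ] & ok[j, ]
      n_comp <- sum(comp)
      if (n_comp == 0L)
        cryodiv_stop("comparability_error",
                     paste0("no comparable sites between '", labels[i], "' and '",
                            labels[j], "'"))
      d[i, j] <- d[j, i] <- sum(chars[i, comp] != chars[j, comp]) / n_comp
    }
  }
  d
}

#' Great-circle geographic distance matrix between sequences
#'
#' Haversine distance in kilometres between the sites of every sequence
#' pair; sequences from the same site are at distance 0.
#'
#' @param sites Site table data frame (`site_id`, `lat`, `lon`; see
#'   [read_sites()]).
#' @param membership Named character vector mapping each sequence id to a
#'   `site_id`.
#' @param radius_km Earth radius in km. Default 6371.0088 (mean radius);
#'   6378.388 (international ellipsoid equatorial radius) is a common
#'   alternative in older geographic-distance routines.
#' @return Symmetric distance matrix (km) labelled by sequence id.
#' @export
geographic_distance_matrix <- function(sites, membership, radius_km = 6371.0088) {
  validate_sites(sites)
  seq_ids <- names(membership)
  if (is.null(seq_ids) || anyDuplicated(seq_ids))
    cryodiv_stop("mapping_error", "membership must be a uniquely named vector")
  unknown <- setdiff(unique(membership), sites$site_id)
  if (length(unknown) > 0L)
    cryodiv_stop("mapping_error",
                 paste0("site(s) not in table: ", paste(unknown, collapse = ", ")))
  coords <- as.matrix(sites[, c("lon", "lat")])
  rownames(coords) <- sites$site_id
  # site-by-site distances, then expanded to sequences
  ns <- nrow(sites)
  site_d <- matrix(0, ns, ns, dimnames = list(sites$site_id, sites$site_id))
  if (ns > 1L) {
    for (i in seq_len(ns - 1L)) {
      site_d[i, (i + 1L):ns] <-
        geosphere::distHaversine(coords[i, , drop = FALSE],
                                 coords[(i + 1L):ns, , drop = FALSE],
                                 r = radius_km)
    }
    site_d <- site_d + t(site_d)
  }
  site_of <- as.character(membership[seq_ids])
  d <- site_d[site_of, site_of, drop = FALSE]
  dimnames(d) <- list(seq_ids, seq_ids)
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation \eqn{r_M} between the \eqn{n(n-1)/2} unordered-pair
#' entries of two distance matrices over the same labels, with significance
#' by simultaneous row/column permutation of one matrix and the add-one
#' convention \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}
#' (positive tail; negative and two-sided tails available). With
#' `exhaustive = TRUE` all `n!` permutations are enumerated and the p-value
#' is exact.
#'
#' @param dx,dy Distance matrices with identical labels.
#' @param n_permutations Number of random permutations (default 999; the
#'   classical isolation-by-distance setting uses 1000).
#' @param seed Integer seed for the permutation draw.
#' @param tail `"positive"` (default), `"negative"` or `"two-sided"`.
#' @param exhaustive Enumerate all permutations (`n <= 8`) for an exact p.
#' @return List with `r`, `p`, `n_permutations`, `tail`.
#' @export
mantel <- function(dx, dy, n_permutations = 999L, seed = 1L,
                   tail = c("positive", "negative", "two-sided"),
                   exhaustive = FALSE) {
  tail <- match.arg(tail)
  validate_distance_matrix(dx)
  validate_distance_matrix(dy)
  if (!identical(rownames(dx), rownames(dy)))
    cryodiv_stop("format_error", "distance matrices must share identical labels")
  n <- nrow(dx)
  if (n < 3L) cryodiv_stop("design_error", "Mantel test needs n >= 3")
  vx <- lower_vec(dx)
  vy <- lower_vec(dy)
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0)
    cryodiv_stop("degenerate_error", "zero variance among pairwise distances")
  r_obs <- stats::cor(vx, vy)
  perm_r <- function(idx) stats::cor(lower_vec(dx[idx, idx]), vy)
  if (exhaustive) {
    perms <- all_perms(n)
    r_perm <- apply(perms, 2L, perm_r)
    tail_count <- switch(tail,
      positive = mean(r_perm >= r_obs - 1e-12),
      negative = mean(r_perm <= r_obs + 1e-12),
      `two-sided` = mean(abs(r_perm) >= abs(r_obs) - 1e-12))
    p_val <- tail_count
    n_perm <- ncol(perms)
  } else {
    set.seed(seed)
    r_perm <- replicate(n_permutations, perm_r(sample.int(n)))
    exceed <- switch(tail,
      positive = sum(r_perm >= r_obs - 1e-12),
      negative = sum(r_perm <= r_obs + 1e-12),
      `two-sided` = sum(abs(r_perm) >= abs(r_obs) - 1e-12))
    p_val <- (1 + exceed) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  list(r = r_obs, p = p_val, n_permutations = n_perm, tail = tail)
}

#' Sturge's rule for the number of distance classes
#'
#' \eqn{k = \lceil 1 + \log_2 m \rceil} for `m` observations (here, the
#' number of unordered sequence pairs). For the 4560 pairs of a 96-sequence
#' analysis this gives 14 classes.
#'
#' @param n_pairs Number of observations, `>= 1`.
#' @return Integer number of classes.
#' @examples
#' sturges_classes(4560)  # 14
#' @export
sturges_classes <- function(n_pairs) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || is.na(n_pairs) || n_pairs < 1)
    cryodiv_stop("format_error", "n_pairs must be a single integer >= 1")
  as.integer(ceiling(1 + log2(n_pairs)))
}

#' Mantel correlogram over Sturge's-rule distance classes
#'
#' Partitions the geographic distances into `k = sturges_classes(m)`
#' equal-width classes over (0, max\] (same-site pairs, distance 0, fall in
#' class 1 so classes cover all pairs). For each class a Mantel test is run
#' between the genetic distances and the binary class-membership model
#' matrix; the class statistic is the *negative* of that Mantel correlation,
#' so a positive value means pairs inside the class are more genetically
#' similar than average (positive spatial autocorrelation). Per-class
#' p-values are one-tailed in the direction of the observed statistic and
#' Bonferroni-corrected globally (`p_bonferroni = min(1, k * p_raw)`).
#'
#' @param d_gen,d_geo Genetic and geographic distance matrices with
#'   identical labels.
#' @param n_permutations Permutations per class (default 999).
#' @param seed Integer seed.
#' @param alpha Significance level applied to the corrected p (default
#'   0.05).
#' @return Data frame with one row per class: `class`, `lower_km`,
#'   `upper_km`, `midpoint_km`, `n_pairs`, `r`, `p_raw`, `p_bonferroni`,
#'   `significant`. Classes containing no pairs (or all pairs) have `NA`
#'   statistics and are flagged non-significant.
#' @export
mantel_correlogram <- function(d_gen, d_geo, n_permutations = 999L, seed = 1L,
                               alpha = 0.05) {
  validate_distance_matrix(d_gen)
  validate_distance_matrix(d_geo)
  if (!identical(rownames(d_gen), rownames(d_geo)))
    cryodiv_stop("format_error", "distance matrices must share identical labels")
  n <- nrow(d_gen)
  if (n < 4L) cryodiv_stop("design_error", "correlogram needs n >= 4")
  v_gen <- lower_vec(d_gen)
  v_geo <- lower_vec(d_geo)
  m <- length(v_geo)
  k <- sturges_classes(m)
  width <- max(v_geo) / k
  if (width == 0) cryodiv_stop("degenerate_error", "all geographic distances are zero")
  cls <- pmin(k, pmax(1L, ceiling(v_geo / width)))   # right-closed bins; 0 -> class 1
  membership <- vapply(seq_len(k), function(j) as.numeric(cls == j),
                       numeric(m))
  counts <- colSums(membership)
  testable <- counts > 0 & counts < m
  # observed class statistics: sign-flipped correlation with membership
  sd_gen <- stats::sd(v_gen)
  r_obs <- rep(NA_real_, k)
  if (sd_gen > 0)
    r_obs[testable] <- -suppressWarnings(
      as.numeric(stats::cor(v_gen, membership[, testable, drop = FALSE])))
  # shared permutation stream: permute the genetic matrix, test all classes
  set.seed(seed)
  exceed_pos <- exceed_neg <- rep(0L, k)
  if (any(testable) && sd_gen > 0) {
    memb_t <- membership[, testable, drop = FALSE]
    for (b in seq_len(n_permutations)) {
      idx <- sample.int(n)
      r_p <- -as.numeric(stats::cor(lower_vec(d_gen[idx, idx]), memb_t))
      ro <- r_obs[testable]
      exceed_pos[testable] <- exceed_pos[testable] + (r_p >= ro - 1e-12)
      exceed_neg[testable] <- exceed_neg[testable] + (r_p <= ro + 1e-12)
    }
  }
  p_raw <- rep(NA_real_, k)
  for (j in which(testable)) {
    exceed <- if (!is.na(r_obs[j]) && r_obs[j] >= 0) exceed_pos[j] else exceed_neg[j]
    p_raw[j] <- (1 + exceed) / (1 + n_permutations)
  }
  p_bonf <- pmin(1, k * p_raw)
  data.frame(
    class = seq_len(k),
    lower_km = (seq_len(k) - 1) * width,
    upper_km = seq_len(k) * width,
    midpoint_km = (seq_len(k) - 0.5) * width,
    n_pairs = as.integer(counts),
    r = r_obs,
    p_raw = p_raw,
    p_bonferroni = p_bonf,
    significant = !is.na(p_bonf) & p_bonf <= alpha
  )
}

#' Full isolation-by-distance analysis
#'
#' Chains [genetic_distance_matrix()], [geographic_distance_matrix()], the
#' global [mantel()] test and the [mantel_correlogram()].
#'
#' @param aln Named character vector of aligned sequences.
#' @param sites Site table data frame (`site_id`, `lat`, `lon`).
#' @param membership Named character vector mapping sequence ids to site
#'   ids.
#' @param n_permutations Permutations for the Mantel test and per
#'   correlogram class (default 1000, the classical setting).
#' @param radius_km Earth radius in km (see
#'   [geographic_distance_matrix()]).
#' @param seed Integer seed.
#' @return List with `mantel` (global test), `correlogram` (per-class data
#'   frame), the two distance matrices, and `metadata` (n_sequences,
#'   n_sites, n_pairs, max_distance_km, k_classes).
#' @export
ibd_analysis <- function(aln, sites, membership, n_permutations = 1000L,
                         radius_km = 6371.0088, seed = 1L) {
  validate_alignment(aln)
  if (!all(names(aln) %in% names(membership)))
    cryodiv_stop("mapping_error", "every sequence needs a site membership")
  membership <- membership[names(aln)]
  d_gen <- genetic_distance_matrix(aln)
  d_geo <- geographic_distance_matrix(sites, membership, radius_km = radius_km)
  d_geo <- d_geo[rownames(d_gen), rownames(d_gen)]
  global <- mantel(d_geo, d_gen, n_permutations = n_permutations, seed = seed,
                   tail = "positive")
  corr <- mantel_correlogram(d_gen, d_geo, n_permutations = n_permutations,
                             seed = seed)
  list(
    mantel = global,
    correlogram = corr,
    genetic_distances = d_gen,
    geographic_distances = d_geo,
    metadata = list(
      n_sequences = length(aln),
      n_sites = length(unique(membership)),
      n_pairs = n_pairs(d_gen),
      max_distance_km = max(d_geo),
      k_classes = nrow(corr)
    )
  )
}
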