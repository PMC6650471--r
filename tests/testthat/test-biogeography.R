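# p-distances, geographic distances, Mantel tests and the correlogram

test_that("p-distance handles identity, mismatches and pairwise deletion", {
  expect_equal(genetic_distance_matrix(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(genetic_distance_matrix(c(a = "ACGT", b = "ACGA"))["a", "b"], 0.25)
  # gap and ambiguity columns are dropped per pair
  d <- genetic_distance_matrix(c(a = "AC-TN", b = "ACGTA"))
  expect_equal(d["a", "b"], 0)           # only 3 comparable sites, all equal
  d2 <- genetic_distance_matrix(c(a = "AC-TA", b = "ACGTT"))
  expect_equal(d2["a", "b"], 1 / 4)
  # U is treated as T (rRNA alignments)
  expect_equal(genetic_distance_matrix(c(a = "ACGU", b = "ACGT"))["a", "b"], 0)
  expect_error(genetic_distance_matrix(c(a = "NN--", b = "AC--")),
               class = "cryodiv_comparability_error")
})

test_that("p-distances agree with ape::dist.dna under pairwise deletion", {
  set.seed(31)
  n <- 8; L <- 120
  mat <- matrix(sample(c("a", "c", "g", "t"), n * L, replace = TRUE), n, L)
  mat[sample(length(mat), 40)] <- "-"
  aln <- setNames(apply(mat, 1, paste, collapse = ""), paste0("q", 1:n))
  got <- genetic_distance_matrix(aln)
  bin <- ape::as.DNAbin(strsplit(tolower(aln), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(got, ref[rownames(got), colnames(got)], tolerance = 1e-12)
})

test_that("geographic distances reproduce closed-form great-circle values", {
  sites <- data.frame(site_id = c("np", "sp", "eq0", "eq1"),
                      lat = c(90, -90, 0, 0), lon = c(0, 0, 0, 1),
                      stringsAsFactors = FALSE)
  mem <- setNames(sites$site_id, paste0("s_", sites$site_id))
  d <- geographic_distance_matrix(sites, mem)
  expect_equal(d["s_np", "s_sp"], pi * 6371.0088, tolerance = 1e-6)    # 20015.1 km
  expect_equal(d["s_eq0", "s_eq1"], pi * 6371.0088 / 180, tolerance = 1e-6)  # 111.195
  # same site -> 0
  mem2 <- setNames(c("np", "np"), c("x", "y"))
  expect_equal(geographic_distance_matrix(sites, mem2)["x", "y"], 0)
  expect_error(geographic_distance_matrix(sites, setNames("atlantis", "z")),
               class = "cryodiv_mapping_error")
})

test_that("Mantel statistic hits its closed-form cases", {
  d <- random_euclidean_dist(6)
  res <- mantel(d, d, n_permutations = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)   # identity always ties itself: minimum add-one p
  # affine increasing transform leaves r = 1
  d2 <- 2.5 * d + 0.3; diag(d2) <- 0
  expect_equal(mantel(d, d2, 99, 1)$r, 1)
  # symmetry in the arguments
  set.seed(2); dy <- random_euclidean_dist(6)
  dimnames(dy) <- dimnames(d)
  expect_equal(mantel(d, dy, 9, 1)$r, mantel(dy, d, 9, 1)$r)
  # degenerate: constant distances
  dz <- matrix(1, 6, 6, dimnames = dimnames(d)); diag(dz) <- 0
  expect_error(mantel(d, dz, 9, 1), class = "cryodiv_degenerate_error")
})

test_that("Mantel r matches vegan on random instances", {
  for (seed in 1:4) {
    set.seed(seed)
    dx <- random_euclidean_dist(9)
    dy <- random_euclidean_dist(9)
    dimnames(dy) <- dimnames(dx)
    got <- mantel(dx, dy, n_permutations = 49, seed = seed)
    ref <- vegan::mantel(as.dist(dx), as.dist(dy), permutations = 49)
    expect_equal(got$r, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$r, naive_mantel_r(dx, dy), tolerance = 1e-12)
  }
})

test_that("exhaustive Mantel p equals exact enumeration for n <= 6", {
  for (n in c(4, 5, 6)) {
    set.seed(n)
    dx <- random_euclidean_dist(n)
    dy <- random_euclidean_dist(n)
    dimnames(dy) <- dimnames(dx)
    res <- mantel(dx, dy, exhaustive = TRUE)
    r_all <- vapply(perms_of(n), function(p) {
      naive_mantel_r(dx[p, p], dy)
    }, numeric(1))
    expect_equal(res$p, mean(r_all >= res$r - 1e-12))
    expect_identical(res$n_permutations, as.integer(factorial(n)))
  }
})

test_that("Sturge's rule gives the documented class counts", {
  expect_identical(sturges_classes(1), 1L)
  expect_identical(sturges_classes(2), 2L)
  expect_identical(sturges_classes(4560), 14L)
  expect_identical(sturges_classes(1326), 12L)   # ceil(1 + log2(1326))
})

test_that("correlogram classes partition all pairs and apply Bonferroni", {
  sites <- simulate_transect_sites(n_sites = 8, step_km = 600)
  sim <- simulate_ibd_sequences(sites, seqs_per_site = 3, seq_length = 400,
                                beta = 5e-5, site_noise = 0.001, seed = 5)
  d_gen <- genetic_distance_matrix(sim$alignment)
  d_geo <- geographic_distance_matrix(sites, sim$membership)
  corr <- mantel_correlogram(d_gen, d_geo, n_permutations = 199, seed = 5)
  n <- nrow(d_gen)
  expect_identical(sum(corr$n_pairs), as.integer(n * (n - 1) / 2))
  expect_identical(nrow(corr), as.integer(sturges_classes(n * (n - 1) / 2)))
  ok <- !is.na(corr$p_raw)
  expect_equal(corr$p_bonferroni[ok], pmin(1, nrow(corr) * corr$p_raw[ok]))
  expect_true(all(!corr$significant[!ok]))
  # strong isolation by distance: the shortest-distance class is positively
  # autocorrelated (pairs in it are more similar than average)
  expect_gt(corr$r[1], 0)
  expect_true(corr$significant[1])
  expect_equal(corr$midpoint_km, (corr$lower_km + corr$upper_km) / 2)
})

test_that("ibd_analysis chains the full pipeline with consistent metadata", {
  sites <- simulate_transect_sites(n_sites = 6, step_km = 800)
  sim <- simulate_ibd_sequences(sites, seqs_per_site = 2, seq_length = 300,
                                beta = 5e-5, site_noise = 0.001, seed = 9)
  res <- ibd_analysis(sim$alignment, sites, sim$membership,
                      n_permutations = 99, seed = 2)
  expect_identical(res$metadata$n_sequences, 12L)
  expect_identical(res$metadata$n_sites, 6L)
  expect_identical(res$metadata$n_pairs, 66)
  expect_identical(res$metadata$k_classes, nrow(res$correlogram))
  expect_identical(res$metadata$k_classes, as.integer(sturges_classes(66)))
  expect_gt(res$mantel$r, 0)
  # all sequences from one site -> zero-variance geographic matrix
  one_site <- sites[1, , drop = FALSE]
  mem <- setNames(rep(one_site$site_id, 4), paste0("w", 1:4))
  aln <- sim$alignment[1:4]
  names(aln) <- names(mem)
  expect_error(ibd_analysis(aln, one_site, mem, n_permutations = 9),
               class = "cryodiv_degenerate_error")
})
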