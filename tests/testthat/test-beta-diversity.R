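# Weighted UniFrac, ANOSIM and PCoA

test_that("weighted UniFrac reproduces the two-tip worked example", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  tab <- matrix(c(10L, 0L, 0L, 10L), 2, 2,
                dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_equal(weighted_unifrac(tab, tr, "s1", "s2"), 2)
  expect_equal(weighted_unifrac(tab, tr, "s1", "s2", normalized = TRUE), 1)
  # identical samples -> 0
  tab2 <- rbind(s1 = c(A = 3L, B = 5L), s2 = c(A = 3L, B = 5L))
  expect_equal(weighted_unifrac(tab2, tr, "s1", "s2"), 0)
})

test_that("UniFrac errors on missing tips and empty samples", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  tab <- matrix(c(1L, 1L, 2L, 1L), 2, 2,
                dimnames = list(c("s1", "s2"), c("A", "C")))
  expect_error(weighted_unifrac(tab, tr, "s1", "s2"),
               class = "cryodiv_label_error")
})

test_that("UniFrac matrix equals the pairwise op and respects its bounds", {
  for (seed in 1:5) {
    inst <- random_table_and_tree(n_samples = 4, n_otus = 8, seed = seed)
    m_raw <- unifrac_matrix(inst$table, inst$tree)
    m_nrm <- unifrac_matrix(inst$table, inst$tree, normalized = TRUE)
    expect_silent(validate_distance_matrix(m_raw))
    expect_true(all(m_nrm >= 0 & m_nrm <= 1 + 1e-12))
    for (i in 1:3) {
      for (j in (i + 1):4) {
        a <- rownames(inst$table)[i]; b <- rownames(inst$table)[j]
        expect_equal(m_raw[a, b],
                     weighted_unifrac(inst$table, inst$tree, a, b))
        expect_equal(m_nrm[a, b],
                     weighted_unifrac(inst$table, inst$tree, a, b, normalized = TRUE))
      }
    }
  }
  # duplicated samples give a zero entry
  inst <- random_table_and_tree(seed = 99)
  tab <- inst$table
  tab["s2", ] <- tab["s1", ]
  expect_equal(unifrac_matrix(tab, inst$tree)["s1", "s2"], 0)
})

test_that("UniFrac agrees with the phyloseq reference implementation", {
  skip_if_not_installed("phyloseq")
  for (seed in c(2, 5)) {
    inst <- random_table_and_tree(n_samples = 5, n_otus = 10, seed = seed)
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(inst$table, taxa_are_rows = FALSE),
      phyloseq::phy_tree(inst$tree))
    ref_raw <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = FALSE))
    ref_nrm <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
    ord <- rownames(inst$table)
    expect_equal(unifrac_matrix(inst$table, inst$tree),
                 ref_raw[ord, ord], tolerance = 1e-10)
    expect_equal(unifrac_matrix(inst$table, inst$tree, normalized = TRUE),
                 ref_nrm[ord, ord], tolerance = 1e-10)
  }
})

test_that("ANOSIM attains its extreme and null statistic values", {
  labs <- paste0("s", 1:4)
  groups <- setNames(c("g1", "g1", "g2", "g2"), labs)
  # all between-distances exceed all within-distances -> R = 1
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.2
  d[1, 3] <- d[3, 1] <- d[1, 4] <- d[4, 1] <- 0.9
  d[2, 3] <- d[3, 2] <- d[2, 4] <- d[4, 2] <- 0.8
  res <- suppressWarnings(anosim(d, groups, n_permutations = 99, seed = 1))
  expect_equal(res$R, 1)
  # all distances equal -> mid-ranks identical -> R = 0
  d0 <- matrix(0.5, 4, 4, dimnames = list(labs, labs)); diag(d0) <- 0
  expect_equal(suppressWarnings(anosim(d0, groups, 99, 1))$R, 0)
})

test_that("ANOSIM matches the naive statistic and vegan on random instances", {
  set.seed(14)
  for (i in 1:5) {
    d <- random_euclidean_dist(8)
    groups <- setNames(rep(c("a", "b"), each = 4), rownames(d))
    res <- suppressWarnings(anosim(d, groups, n_permutations = 49, seed = i))
    expect_equal(res$R, naive_anosim_R(d, groups[rownames(d)]))
    ref <- vegan::anosim(as.dist(d), groups[rownames(d)], permutations = 49)
    expect_equal(res$R, unname(ref$statistic), tolerance = 1e-12)
    # rank-based: invariant under monotone transformation of distances
    res2 <- suppressWarnings(anosim(sqrt(d), groups, 49, i))
    expect_equal(res2$R, res$R)
  }
})

test_that("exhaustive ANOSIM p equals exact enumeration over relabelings", {
  set.seed(4)
  d <- random_euclidean_dist(4)
  g <- setNames(c("x", "x", "y", "y"), rownames(d))
  res <- suppressWarnings(anosim(d, g, exhaustive = TRUE))
  r_all <- vapply(perms_of(4), function(p)
    naive_anosim_R(d, unname(g[rownames(d)])[p]), numeric(1))
  expect_equal(res$p, mean(r_all >= res$R - 1e-12))
  expect_identical(res$n_permutations, 24L)
})

test_that("ANOSIM rejects degenerate designs", {
  d <- random_euclidean_dist(4)
  expect_error(suppressWarnings(
    anosim(d, setNames(c("a", "a", "a", "b"), rownames(d)), 9, 1)),
    class = "cryodiv_design_error")
  expect_error(suppressWarnings(
    anosim(d, setNames(rep("a", 4), rownames(d)), 9, 1)),
    class = "cryodiv_design_error")
})

test_that("PCoA recovers closed-form and planar configurations", {
  # two points at distance d -> one axis at +/- d/2
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  res <- pcoa(d)
  expect_equal(unname(sort(res$coordinates[, 1])), c(-1.5, 1.5))
  # planar point set: distances are Euclidean, configuration is recovered
  # up to rotation/reflection
  set.seed(8)
  pts <- matrix(rnorm(14), 7, 2)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("p", 1:7), paste0("p", 1:7))
  res2 <- pcoa(dm)
  proc <- vegan::procrustes(pts, res2$coordinates[, 1:2], symmetric = FALSE)
  expect_lt(sum(proc$residuals^2), 1e-8)
  # eigenvalues ordered, proportions over positive eigenvalues
  expect_true(all(diff(res2$eigenvalues) <= 1e-8))
  expect_lte(sum(res2$proportion_explained), 1 + 1e-8)
  # all-zero distances -> all eigenvalues 0
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(abs(pcoa(z)$eigenvalues) < 1e-12))
})
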