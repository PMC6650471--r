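# Generator contracts: determinism, domain invariants, and closed-form
# parameter recovery

test_that("all generators are deterministic under a fixed seed", {
  a <- simulate_otu_table(n_samples_per_group = 3, n_otus = 40, seed = 5)
  b <- simulate_otu_table(n_samples_per_group = 3, n_otus = 40, seed = 5)
  expect_identical(a, b)

  t1 <- simulate_random_tree(8, seed = 3)
  t2 <- simulate_random_tree(8, seed = 3)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  sites <- simulate_transect_sites(5, 400)
  s1 <- simulate_ibd_sequences(sites, 2, 200, seed = 11)
  s2 <- simulate_ibd_sequences(sites, 2, 200, seed = 11)
  expect_identical(s1, s2)

  m1 <- simulate_match_table(50, seed = 2)
  m2 <- simulate_match_table(50, seed = 2)
  expect_identical(m1, m2)
})

test_that("simulated OTU tables satisfy the domain invariants", {
  sim <- simulate_otu_table(n_samples_per_group = 4, n_otus = 60, seed = 1)
  expect_silent(validate_otu_table(sim$table))
  expect_identical(sort(names(sim$groups)), sort(rownames(sim$table)))
  expect_identical(unname(table(sim$groups))[1], 4L)
  expect_true(all(rowSums(sim$table) == 5000))
  expect_true(all(sim$affected_otus %in% colnames(sim$table)))
})

test_that("random trees are rooted cherries at n = 2 with positive lengths", {
  tr <- simulate_random_tree(2, seed = 1)
  expect_identical(length(tr$tip.label), 2L)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length > 0))
  tr2 <- simulate_random_tree(20, seed = 4)
  expect_true(all(tr2$edge.length > 0))
})

test_that("transect sites are equally spaced at the requested step", {
  sites <- simulate_transect_sites(n_sites = 6, step_km = 500)
  expect_silent(validate_sites(sites))
  d <- geographic_distance_matrix(
    sites, setNames(sites$site_id, sites$site_id))
  steps <- diag(d[-1, -nrow(d), drop = FALSE])
  expect_equal(unname(steps), rep(500, 5), tolerance = 1e-6)
})

test_that("beta = 0 with no noise gives identical sequences", {
  sites <- simulate_transect_sites(5, 400)
  sim <- simulate_ibd_sequences(sites, 2, 300, beta = 0, site_noise = 0, seed = 3)
  expect_identical(length(unique(sim$alignment)), 1L)
  d <- genetic_distance_matrix(sim$alignment)
  expect_true(all(d == 0))
})

test_that("endpoint divergence follows the 1 - exp(-beta * L) expectation", {
  sites <- simulate_transect_sites(n_sites = 6, step_km = 700)
  L <- 5 * 700
  beta <- 4e-5
  expected <- 1 - exp(-beta * L)
  seq_len_bp <- 500
  reps <- 30
  obs <- vapply(seq_len(reps), function(i) {
    sim <- simulate_ibd_sequences(sites, seqs_per_site = 1, seq_length = seq_len_bp,
                                  beta = beta, site_noise = 0, seed = i)
    genetic_distance_matrix(sim$alignment)[1, 6]
  }, numeric(1))
  # per-site divergence is Bernoulli(expected) over seq_len_bp sites
  se <- sqrt(expected * (1 - expected) / (seq_len_bp * reps))
  expect_lt(abs(mean(obs) - expected), 4 * se + 0.002)  # small back-mutation slack
})

test_that("excessive divergence raises a saturation error", {
  sites <- simulate_transect_sites(10, 2000)
  expect_error(simulate_ibd_sequences(sites, 1, 100, beta = 1e-3),
               class = "cryodiv_saturation_error")
})

test_that("global Mantel r increases with the generator slope", {
  sites <- simulate_transect_sites(n_sites = 5, step_km = 600)
  betas <- c(0, 2e-5, 1e-4)
  reps <- 15
  mean_r <- vapply(betas, function(b) {
    rs <- vapply(seq_len(reps), function(i) {
      sim <- simulate_ibd_sequences(sites, seqs_per_site = 2, seq_length = 250,
                                    beta = b, site_noise = 0.002,
                                    seed = 1000 + i)
      d_gen <- genetic_distance_matrix(sim$alignment)
      d_geo <- geographic_distance_matrix(sites, sim$membership)
      if (sd(d_gen[lower.tri(d_gen)]) == 0) return(0)
      mantel(d_geo, d_gen, n_permutations = 9, seed = i)$r
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("match-table generator plants classes inside their identity bands", {
  all_novel <- simulate_match_table(
    n_otus = 80,
    class_mix = c(cryophilic = 0, non_cryophilic = 0,
                  polythermal_cosmopolitan = 0, subnovel = 0, novel = 1,
                  unclassified = 0),
    seed = 6)
  expect_true(all(all_novel$matches$best_identity_pct >= 88.5 &
                    all_novel$matches$best_identity_pct < 95.5))
  expect_true(all(all_novel$true_classes == "novel"))
  # generated tables pass the consuming module's validation
  sim <- simulate_match_table(120, seed = 9)
  expect_silent(validate_match_table(sim$matches))
  # no planted identity sits on a decision boundary
  expect_false(any(sim$matches$best_identity_pct %in% c(97, 95.5, 88.5)))
})
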