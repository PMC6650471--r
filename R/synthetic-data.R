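# Seeded generators that emulate the pipeline's inputs with known ground
# truth: grouped OTU count tables, random rooted trees, transect alignments
# with a tunable isolation-by-distance slope, and database-match tables
# with planted endemicity classes. Every generator is a pure function of
# its arguments and seed.

#' Simulate a grouped OTU count table
#'
#' Per-OTU base intensities are lognormal(`mu`, `sigma`); in one group
#' (default `"ice"`, vs `"soil"`) a random subset of OTUs is shifted by the
#' factor `exp(group_effect)`. Counts are a per-sample multinomial draw of
#' `depth` reads from the normalized intensities, so `group_effect = 0`
#' makes the two groups exchangeable.
#'
#' @param n_samples_per_group Samples per group (default 6).
#' @param n_otus Number of OTUs (default 200).
#' @param mu,sigma Lognormal parameters of the base abundances (defaults 0,
#'   1.5 — a typical steeply uneven amplicon abundance distribution).
#' @param group_effect Log-fold shift applied to affected OTUs in the first
#'   group (default 2; 0 gives the exchangeable null).
#' @param affected_fraction Fraction of OTUs shifted (default 0.2).
#' @param depth Reads per sample (default 5000).
#' @param group_labels Two group names (default `c("ice", "soil")`).
#' @param seed Integer seed.
#' @return List with `table` (integer count matrix), `groups` (named
#'   character vector sample -> group) and `affected_otus` (character
#'   vector; the ground truth).
#' @export
simulate_otu_table <- function(n_samples_per_group = 6L, n_otus = 200L,
                               mu = 0, sigma = 1.5, group_effect = 2,
                               affected_fraction = 0.2, depth = 5000L,
                               group_labels = c("ice", "soil"), seed = 1L) {
  if (group_effect < 0) cryodiv_stop("format_error", "group_effect must be >= 0")
  set.seed(seed)
  otu_ids <- sprintf("OTU_%03d", seq_len(n_otus))
  base <- stats::rlnorm(n_otus, meanlog = mu, sdlog = sigma)
  n_aff <- round(affected_fraction * n_otus)
  affected <- sort(sample.int(n_otus, n_aff))
  shifted <- base
  shifted[affected] <- shifted[affected] * exp(group_effect)
  samples <- c(paste0(group_labels[1L], "_", seq_len(n_samples_per_group)),
               paste0(group_labels[2L], "_", seq_len(n_samples_per_group)))
  groups <- stats::setNames(rep(group_labels, each = n_samples_per_group), samples)
  counts <- matrix(0L, nrow = length(samples), ncol = n_otus,
                   dimnames = list(samples, otu_ids))
  for (s in samples) {
    p <- if (groups[[s]] == group_labels[1L]) shifted else base
    counts[s, ] <- as.integer(stats::rmultinom(1L, size = depth, prob = p / sum(p)))
  }
  list(table = counts, groups = groups, affected_otus = otu_ids[affected])
}

#' Simulate a random rooted tree
#'
#' Random coalescent topology with exponential inter-node times, via
#' [ape::rcoal()]. Tip labels follow the `OTU_###` convention of
#' [simulate_otu_table()].
#'
#' @param n_tips Number of tips, `>= 2`.
#' @param seed Integer seed.
#' @return Rooted `"phylo"` tree with positive branch lengths.
#' @export
simulate_random_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2L) cryodiv_stop("format_error", "need at least 2 tips")
  set.seed(seed)
  tree <- ape::rcoal(n_tips, tip.label = sprintf("OTU_%03d", seq_len(n_tips)))
  validate_tree(tree)
}

#' Lay out sites along a transect
#'
#' Equally spaced sites along a meridian, a convenient geometry for
#' isolation-by-distance simulations: consecutive sites are `step_km`
#' apart and the full transect spans `(n_sites - 1) * step_km`.
#'
#' @param n_sites Number of sites (default 25, the scale of a global
#'   cryosphere survey).
#' @param step_km Spacing between consecutive sites in km (default 750, for
#'   an ~18,000 km global-scale transect).
#' @param lon Longitude of the meridian (default 0).
#' @return Site table data frame (`site_id`, `lat`, `lon`).
#' @export
simulate_transect_sites <- function(n_sites = 25L, step_km = 750, lon = 0) {
  if (n_sites < 2L) cryodiv_stop("format_error", "need at least 2 sites")
  step_deg <- step_km / (pi * 6371.0088 / 180)   # km per degree of latitude
  lat0 <- -(n_sites - 1L) * step_deg / 2
  lats <- lat0 + (seq_len(n_sites) - 1L) * step_deg
  if (any(lats < -90 | lats > 90))
    cryodiv_stop("range_error", "transect does not fit on the sphere; reduce step_km or n_sites")
  data.frame(site_id = sprintf("site_%02d", seq_len(n_sites)),
             lat = lats, lon = lon, stringsAsFactors = FALSE)
}

#' Simulate sequences with isolation by distance along a transect
#'
#' Stepping-stone mutation accumulation: sites are visited in table order; a
#' master sequence mutates between consecutive sites with per-site
#' substitution probability `1 - exp(-beta * d_km)` (substituting to a
#' uniformly chosen different base), so the expected p-distance between
#' sites separated by `L` km along the transect is approximately
#' `1 - exp(-beta * L)`. Each sequence then receives independent noise
#' substitutions at per-site probability `site_noise`, emulating
#' within-site sequence variation.
#'
#' @param sites Site table data frame in transect order (`site_id`, `lat`,
#'   `lon`), `>= 3` sites with distinct coordinates.
#' @param seqs_per_site Sequences sampled per site: a single integer or a
#'   vector of length `nrow(sites)` (default 4).
#' @param seq_length Alignment length in bp (default 800, a long-read 16S
#'   fragment).
#' @param beta Isolation-by-distance slope, expected substitutions per site
#'   per km (default 2e-6: ~3.5% end-to-end divergence on an 18,000 km
#'   transect, the "slight but significant" regime typical of cryosphere
#'   taxa).
#' @param site_noise Per-site probability of an independent noise
#'   substitution per sequence (default 0.002).
#' @param radius_km Earth radius used for inter-site distances.
#' @param seed Integer seed.
#' @return List with `alignment` (named character vector) and `membership`
#'   (named character vector sequence id -> site id).
#' @export
simulate_ibd_sequences <- function(sites, seqs_per_site = 4L, seq_length = 800L,
                                   beta = 2e-6, site_noise = 0.002,
                                   radius_km = 6371.0088, seed = 1L) {
  validate_sites(sites)
  if (nrow(sites) < 3L) cryodiv_stop("format_error", "need at least 3 sites")
  if (beta < 0 || site_noise < 0)
    cryodiv_stop("format_error", "beta and site_noise must be >= 0")
  if (length(seqs_per_site) == 1L) seqs_per_site <- rep(seqs_per_site, nrow(sites))
  if (length(seqs_per_site) != nrow(sites))
    cryodiv_stop("format_error", "seqs_per_site must have one entry per site")
  bases <- c("A", "C", "G", "T")
  coords <- as.matrix(sites[, c("lon", "lat")])
  seg_km <- if (nrow(sites) > 1L)
    geosphere::distHaversine(coords[-nrow(sites), , drop = FALSE],
                             coords[-1L, , drop = FALSE], r = radius_km)
  else numeric(0)
  total_km <- sum(seg_km)
  if (1 - exp(-beta * total_km) > 0.75)
    cryodiv_stop("saturation_error",
                 paste0("expected end-to-end divergence ",
                        signif(1 - exp(-beta * total_km), 3),
                        " exceeds 0.75; reduce beta or the transect length"))
  set.seed(seed)
  mutate <- function(seq_chars, p_sub) {
    hit <- which(stats::runif(length(seq_chars)) < p_sub)
    for (i in hit)
      seq_chars[i] <- sample(setdiff(bases, seq_chars[i]), 1L)
    seq_chars
  }
  master <- sample(bases, seq_length, replace = TRUE)
  aln <- character(0)
  membership <- character(0)
  current <- master
  for (s in seq_len(nrow(sites))) {
    if (s > 1L) current <- mutate(current, 1 - exp(-beta * seg_km[s - 1L]))
    for (rseq in seq_len(seqs_per_site[s])) {
      sid <- paste0(sites$site_id[s], "_seq", rseq)
      aln[sid] <- paste(mutate(current, site_noise), collapse = "")
      membership[sid] <- sites$site_id[s]
    }
  }
  list(alignment = aln, membership = membership)
}

#' Simulate a database-match table with planted endemicity classes
#'
#' Draws per-OTU best-hit identities uniformly inside each category's
#' identity interval (keeping a 0.1 margin away from the 97 / 95.5 / 88.5
#' boundaries so recovery is unambiguous) and environment label sets
#' consistent with the category. The default class mix reflects a typical
#' high-altitude periglacial bacterial community: most OTUs cosmopolitan,
#' a small endemic fraction.
#'
#' @param n_otus Number of OTUs (default 66).
#' @param class_mix Named numeric vector of category proportions over
#'   cryophilic, non_cryophilic, polythermal_cosmopolitan, subnovel, novel,
#'   unclassified; must sum to 1.
#' @param n_seq_lambda Mean of the (shifted) Poisson draw for
#'   `n_sequences`; every OTU gets at least 2 sequences so all are
#'   classifiable. Default 3.
#' @param seed Integer seed.
#' @return List with `matches` (match table data frame) and `true_classes`
#'   (named character vector otu_id -> planted category).
#' @export
simulate_match_table <- function(n_otus = 66L,
                                 class_mix = c(cryophilic = 0.10,
                                               non_cryophilic = 0.11,
                                               polythermal_cosmopolitan = 0.70,
                                               subnovel = 0.045,
                                               novel = 0.045,
                                               unclassified = 0),
                                 n_seq_lambda = 3, seed = 1L) {
  if (!all(names(class_mix) %in% .endemicity_categories))
    cryodiv_stop("vocabulary_error", "unknown category in class_mix")
  if (abs(sum(class_mix) - 1) > 1e-8)
    cryodiv_stop("format_error", "class_mix proportions must sum to 1")
  set.seed(seed)
  cats <- sample(names(class_mix), n_otus, replace = TRUE, prob = class_mix)
  eps <- 0.1   # margin away from the decision boundaries
  identity <- vapply(cats, function(k) {
    switch(k,
           cryophilic = , non_cryophilic = , polythermal_cosmopolitan =
             stats::runif(1, 97 + eps, 100),
           subnovel = stats::runif(1, 95.5 + eps, 97 - eps),
           novel = stats::runif(1, 88.5 + eps, 95.5 - eps),
           unclassified = stats::runif(1, 70, 88.5 - eps))
  }, numeric(1), USE.NAMES = FALSE)
  envs <- vapply(cats, function(k) {
    switch(k,
           cryophilic = "cold",
           non_cryophilic = "temperate",
           polythermal_cosmopolitan = "cold;temperate",
           "")
  }, character(1), USE.NAMES = FALSE)
  otu_ids <- sprintf("OTU_%03d", seq_len(n_otus))
  matches <- data.frame(
    otu_id = otu_ids,
    n_sequences = 2L + stats::rpois(n_otus, n_seq_lambda - 2),
    best_identity_pct = round(identity, 2),
    match_environments = envs,
    stringsAsFactors = FALSE
  )
  validate_match_table(matches)
  list(matches = matches, true_classes = stats::setNames(cats, otu_ids))
}
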