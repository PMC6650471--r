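# Independent oracles: deliberately naive re-implementations used only to
# check the package's optimized code paths. They share no code with R/.

# all permutations of 1..n as a list (plain recursive construction)
perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in perms_of(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub + (sub >= pos), pos, after = pos - 1L)
    }
  }
  out
}

# naive greedy average-linkage: recompute every cluster-pair mean from the
# raw matrix at each step; merge the smallest mean while it is <= cutoff
brute_force_average_linkage <- function(d, cutoff) {
  labels <- rownames(d)
  parts <- lapply(seq_along(labels), function(i) i)
  repeat {
    if (length(parts) == 1L) break
    best_avg <- Inf
    best_pair <- NULL
    for (a in seq_along(parts)) {
      for (b in seq_along(parts)) {
        if (a >= b) next
        avg <- mean(d[parts[[a]], parts[[b]]])
        key <- sort(c(min(labels[parts[[a]]]), min(labels[parts[[b]]])))
        if (avg < best_avg - 1e-15 ||
            (abs(avg - best_avg) <= 1e-15 && !is.null(best_pair) &&
             (key[1] < best_pair$key[1] ||
              (key[1] == best_pair$key[1] && key[2] < best_pair$key[2])))) {
          best_avg <- avg
          best_pair <- list(a = a, b = b, key = key)
        }
      }
    }
    if (best_avg > cutoff) break
    parts[[best_pair$a]] <- c(parts[[best_pair$a]], parts[[best_pair$b]])
    parts[[best_pair$b]] <- NULL
  }
  # return as a membership vector numbered by smallest member index
  parts <- parts[order(vapply(parts, min, integer(1)))]
  out <- integer(length(labels))
  for (k in seq_along(parts)) out[parts[[k]]] <- k
  names(out) <- labels
  out
}

# partitions agree up to cluster relabeling
same_partition <- function(a, b) {
  identical(as.integer(match(a, unique(a))), as.integer(match(b, unique(b))))
}

# naive ANOSIM R computed straight from the definition
naive_anosim_R <- function(d, g) {
  n <- nrow(d)
  vals <- c()
  within <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, d[i, j])
      within <- c(within, g[i] == g[j])
    }
  }
  rk <- rank(vals)
  (mean(rk[!within]) - mean(rk[within])) / (length(vals) / 2)
}

# Mantel r computed straight from the definition over explicit pair loops
naive_mantel_r <- function(dx, dy) {
  n <- nrow(dx)
  vx <- c(); vy <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vx <- c(vx, dx[i, j])
      vy <- c(vy, dy[i, j])
    }
  }
  cor(vx, vy)
}

# random symmetric distance matrix from points in Euclidean space
random_euclidean_dist <- function(n, dim = 3) {
  pts <- matrix(runif(n * dim), n)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}

# small random OTU table + matching random tree for UniFrac checks
random_table_and_tree <- function(n_samples = 4, n_otus = 8, seed = 1) {
  set.seed(seed)
  tab <- matrix(rpois(n_samples * n_otus, 5) + 1L, n_samples, n_otus,
                dimnames = list(paste0("s", seq_len(n_samples)),
                                sprintf("OTU_%03d", seq_len(n_otus))))
  storage.mode(tab) <- "integer"
  tree <- ape::rcoal(n_otus, tip.label = sprintf("OTU_%03d", seq_len(n_otus)))
  list(table = tab, tree = tree)
}
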