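# Per-sample alpha diversity: Shannon diversity, bias-corrected Chao1
# richness, Berger-Parker dominance, Good's coverage and Faith's
# phylogenetic diversity, plus a per-group summary over an OTU table.

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \log p_i} over OTUs with positive counts, with
#' \eqn{p_i = N_i / N}. Natural logarithm by default.
#'
#' @param counts Non-negative integer vector with at least one positive
#'   entry.
#' @param base Logarithm base; default `exp(1)` (nats).
#' @return Shannon index, `>= 0`.
#' @examples
#' shannon(c(3, 3, 3, 3))  # log(4)
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimator (bias-corrected)
#'
#' \eqn{S_{chao1} = S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}, where
#' \eqn{F_1} and \eqn{F_2} are the numbers of singleton and doubleton OTUs.
#' The bias-corrected form remains defined when no doubletons are observed.
#'
#' @param counts Non-negative integer vector with at least one positive
#'   entry.
#' @return Estimated richness, always `>=` observed richness.
#' @examples
#' chao1(c(1, 1, 2, 5))  # 4.5
#' @export
chao1 <- function(counts) {
  counts <- check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Berger-Parker dominance index
#'
#' \eqn{d = N_{max} / N}: the fraction of all reads belonging to the most
#' abundant OTU.
#'
#' @param counts Non-negative integer vector with at least one positive
#'   entry.
#' @return Dominance in `(0, 1]`.
#' @export
berger_parker <- function(counts) {
  counts <- check_counts(counts)
  max(counts) / sum(counts)
}

#' Good's coverage estimator
#'
#' \eqn{C = 1 - F_1 / N}: the estimated probability that the next read drawn
#' belongs to an already-observed OTU (\eqn{F_1} singletons, \eqn{N} reads).
#'
#' @param counts Non-negative integer vector with at least one positive
#'   entry.
#' @return Coverage in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  counts <- check_counts(counts)
  1 - sum(counts == 1) / sum(counts)
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the present tips
#' to the root of `tree` (rooted variant, the default) or spanning only the
#' present tips (`include_root = FALSE`).
#'
#' @param present_otus Character vector of tip labels present in the sample.
#'   May be empty (PD is then 0).
#' @param tree Rooted `"phylo"` tree with branch lengths.
#' @param include_root Include the path from the tips' most recent common
#'   ancestor up to the root? Default `TRUE`.
#' @return Phylogenetic diversity in branch-length units, `>= 0`.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:2);")
#' faith_pd(c("A", "B"), tr)  # 3
#' faith_pd("A", tr)          # 1
#' @export
faith_pd <- function(present_otus, tree, include_root = TRUE) {
  tree <- validate_tree(tree)
  present_otus <- unique(as.character(present_otus))
  if (length(present_otus) == 0L) return(0)
  missing <- setdiff(present_otus, tree$tip.label)
  if (length(missing) > 0L)
    cryodiv_stop("label_error",
                 paste0("tip(s) not in tree: ", paste(missing, collapse = ", ")))
  n_tip <- length(tree$tip.label)
  tip_idx <- match(present_otus, tree$tip.label)
  # mark every node on a path from a present tip to the root
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  marked <- logical(max(tree$edge))
  for (tip in tip_idx) {
    v <- tip
    while (v != 0L && !marked[v]) {
      marked[v] <- TRUE
      v <- parent_of[v]
    }
  }
  keep <- marked[tree$edge[, 2L]]
  if (!include_root && length(tip_idx) >= 1L) {
    # drop the chain of marked edges above the MRCA: these are edges whose
    # child has exactly one marked child-side subtree containing tips
    mrca <- if (length(tip_idx) == 1L) tip_idx else ape::getMRCA(tree, tip_idx)
    v <- mrca
    drop_children <- integer(0)
    while (parent_of[v] != 0L) {
      drop_children <- c(drop_children, v)
      v <- parent_of[v]
    }
    keep <- keep & !(tree$edge[, 2L] %in% drop_children)
  }
  sum(tree$edge.length[keep])
}

#' Per-sample and per-group alpha diversity summary
#'
#' Computes observed OTUs, Shannon, Chao1, Berger-Parker, Good's coverage
#' and Faith's PD for every sample of an OTU table, then unweighted group
#' means (e.g. ice vs soil).
#'
#' @param table Integer count matrix, rows = samples, columns = OTUs.
#' @param tree Rooted `"phylo"` tree whose tips include every OTU with a
#'   positive count; `NULL` to skip Faith's PD.
#' @param groups Named character vector mapping every sample to a group
#'   label.
#' @return List with `per_sample` (one row per sample) and `group_means`
#'   (one row per group) data frames.
#' @export
alpha_summary <- function(table, tree = NULL, groups) {
  validate_otu_table(table)
  samples <- rownames(table)
  missing <- setdiff(samples, names(groups))
  if (length(missing) > 0L)
    cryodiv_stop("grouping_error",
                 paste0("sample(s) without a group: ", paste(missing, collapse = ", ")))
  per <- do.call(rbind, lapply(samples, function(s) {
    x <- table[s, ]
    data.frame(
      sample_id = s,
      group = unname(groups[[s]]),
      observed_otus = sum(x > 0),
      shannon = shannon(x),
      chao1 = chao1(x),
      berger_parker = berger_parker(x),
      goods_coverage = goods_coverage(x),
      faith_pd = if (is.null(tree)) NA_real_ else
        faith_pd(colnames(table)[x > 0], tree),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per) <- NULL
  num <- c("observed_otus", "shannon", "chao1", "berger_parker",
           "goods_coverage", "faith_pd")
  means <- stats::aggregate(per[num], by = list(group = per$group), FUN = mean)
  list(per_sample = per, group_means = means)
}
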