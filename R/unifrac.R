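# Weighted UniFrac: phylogenetic dissimilarity between two communities,
# weighting each branch of a shared rooted tree by the difference in
# relative abundance of the reads descending from it.

# per-sample counts accumulated onto every node of the tree (postorder);
# rows = nodes (tips + internals), columns = samples
node_count_matrix <- function(table, tree) {
  n_tip <- length(tree$tip.label)
  miss <- setdiff(colnames(table)[colSums(table) > 0], tree$tip.label)
  if (length(miss) > 0L)
    cryodiv_stop("label_error",
                 paste0("OTU(s) not in tree: ", paste(miss, collapse = ", ")))
  tr <- stats::reorder(tree, "postorder")
  nodes <- matrix(0, nrow = max(tr$edge), ncol = nrow(table),
                  dimnames = list(NULL, rownames(table)))
  hit <- match(tree$tip.label, colnames(table))
  ok <- !is.na(hit)
  nodes[which(ok), ] <- t(table[, hit[ok], drop = FALSE])
  for (e in seq_len(nrow(tr$edge)))
    nodes[tr$edge[e, 1L], ] <- nodes[tr$edge[e, 1L], ] + nodes[tr$edge[e, 2L], ]
  list(tree = tr, nodes = nodes)
}

# root-to-tip branch length per tip (preorder accumulation)
root_to_tip_depths <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  depth <- numeric(max(tr$edge))
  for (e in rev(seq_len(nrow(tr$edge))))   # reverse postorder = preorder
    depth[tr$edge[e, 2L]] <- depth[tr$edge[e, 1L]] + tr$edge.length[e]
  depth[seq_along(tree$tip.label)]
}

unifrac_from_nodes <- function(pre, depths, table, a, b, normalized) {
  ta <- sum(table[a, ]); tb <- sum(table[b, ])
  if (ta == 0) cryodiv_stop("empty_sample_error", paste0("sample '", a, "' has no reads"))
  if (tb == 0) cryodiv_stop("empty_sample_error", paste0("sample '", b, "' has no reads"))
  child <- pre$tree$edge[, 2L]
  raw <- sum(pre$tree$edge.length *
               abs(pre$nodes[child, a] / ta - pre$nodes[child, b] / tb))
  if (!normalized) return(raw)
  tips <- seq_along(pre$tree$tip.label)
  denom <- sum(depths * (pre$nodes[tips, a] / ta + pre$nodes[tips, b] / tb))
  if (denom == 0) return(0)
  raw / denom
}

#' Weighted UniFrac between two samples
#'
#' Raw weighted UniFrac is \eqn{\sum_i b_i |A_i/A_T - B_i/B_T|} over all
#' branches \eqn{i} of the tree, where \eqn{b_i} is the branch length and
#' \eqn{A_i} the number of sample-A reads descending from the branch. The
#' normalized variant divides by \eqn{\sum_j d_j (A_j/A_T + B_j/B_T)} over
#' tips \eqn{j}, with \eqn{d_j} the root-to-tip branch length, scaling the
#' value into \[0, 1\]. The raw (non-normalized) form is the default; raw
#' values can exceed 1 on deep trees.
#'
#' @param table Integer count matrix, rows = samples, columns = OTUs. Every
#'   OTU with a positive count in either sample must be a tip of `tree`.
#' @param tree Rooted `"phylo"` tree with branch lengths.
#' @param sample_a,sample_b Row names of the two samples to compare.
#' @param normalized Divide by the abundance-weighted root-to-tip
#'   normalizer? Default `FALSE`.
#' @return A single non-negative dissimilarity.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1);")
#' m <- matrix(c(10L, 0L, 0L, 10L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("A", "B")))
#' weighted_unifrac(m, tr, "s1", "s2")                     # 2
#' weighted_unifrac(m, tr, "s1", "s2", normalized = TRUE)  # 1
#' @export
weighted_unifrac <- function(table, tree, sample_a, sample_b, normalized = FALSE) {
  validate_otu_table(table)
  tree <- validate_tree(tree)
  for (s in c(sample_a, sample_b))
    if (!s %in% rownames(table))
      cryodiv_stop("label_error", paste0("no sample named '", s, "'"))
  pre <- node_count_matrix(table, tree)
  depths <- if (normalized) root_to_tip_depths(tree) else NULL
  unifrac_from_nodes(pre, depths, table, sample_a, sample_b, normalized)
}

#' Pairwise weighted UniFrac distance matrix
#'
#' Applies [weighted_unifrac()] to every unordered sample pair of an OTU
#' table.
#'
#' @inheritParams weighted_unifrac
#' @return Symmetric distance matrix over the samples of `table`.
#' @export
unifrac_matrix <- function(table, tree, normalized = FALSE) {
  validate_otu_table(table)
  tree <- validate_tree(tree)
  pre <- node_count_matrix(table, tree)
  depths <- if (normalized) root_to_tip_depths(tree) else NULL
  samples <- rownames(table)
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        d[i, j] <- d[j, i] <-
          unifrac_from_nodes(pre, depths, table, samples[i], samples[j], normalized)
      }
    }
  }
  d
}
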