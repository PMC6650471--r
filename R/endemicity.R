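# Threshold-rule environmental classification of OTUs from database-match
# summaries. An OTU whose best database hit is at or above 97% identity is
# non-endemic, and is sub-classified by the environments of its >= 97% hits:
# all perennially cold -> cryophilic; all temperate -> non-cryophilic; both
# -> polythermal/cosmopolitan. Below 97% the OTU is endemic: subnovel in
# [95.5, 97), novel in [88.5, 95.5); below 88.5 it is left unclassified.

.endemicity_categories <- c("cryophilic", "non_cryophilic",
                            "polythermal_cosmopolitan", "subnovel", "novel",
                            "unclassified")

category_tier <- function(category) {
  switch(category,
         cryophilic = , non_cryophilic = , polythermal_cosmopolitan = "non_endemic",
         subnovel = , novel = "endemic",
         "unclassified")
}

#' Keep only classifiable OTUs
#'
#' Retains OTUs represented by at least `min_seqs` sequences (default 2;
#' singleton OTUs are too likely to be artifacts to classify).
#'
#' @param matches Match table data frame (see [read_match_table()]).
#' @param min_seqs Minimum `n_sequences` to retain.
#' @return The filtered match table.
#' @export
filter_classifiable <- function(matches, min_seqs = 2L) {
  validate_match_table(matches)
  matches[matches$n_sequences >= min_seqs, , drop = FALSE]
}

#' Classify one OTU by best-hit identity and match environments
#'
#' @param best_identity_pct Best database-hit identity, in \[0, 100\].
#' @param match_environments Character vector of environment labels
#'   (`"cold"`, `"temperate"`) for all hits at >= 97% identity; may be empty
#'   when the best identity is below 97.
#' @return List with `category` (one of cryophilic, non_cryophilic,
#'   polythermal_cosmopolitan, subnovel, novel, unclassified) and `tier`
#'   (non_endemic / endemic / unclassified). The 97 boundary is assigned
#'   non-endemic and 95.5 / 88.5 are lower-closed, so the categories
#'   partition the identity line.
#' @examples
#' classify_otu(98.2, c("cold", "temperate"))  # polythermal_cosmopolitan
#' classify_otu(96.0, character(0))            # subnovel
#' @export
classify_otu <- function(best_identity_pct, match_environments = character(0)) {
  if (!is.numeric(best_identity_pct) || length(best_identity_pct) != 1L ||
      is.na(best_identity_pct) || best_identity_pct < 0 || best_identity_pct > 100)
    cryodiv_stop("range_error", "best_identity_pct must be a single value in [0, 100]")
  envs <- unique(as.character(match_environments))
  envs <- envs[nzchar(envs)]
  bad <- setdiff(envs, .match_env_vocab)
  if (length(bad) > 0L)
    cryodiv_stop("vocabulary_error",
                 paste0("unknown environment label(s): ", paste(bad, collapse = ", ")))
  id <- best_identity_pct
  if (id >= 97) {
    if (length(envs) == 0L)
      cryodiv_stop("data_error",
                   "non-endemic OTU (identity >= 97%) with no match environments")
    category <- if (all(envs == "cold")) "cryophilic"
      else if (all(envs == "temperate")) "non_cryophilic"
      else "polythermal_cosmopolitan"
  } else if (id >= 95.5) {
    category <- "subnovel"
  } else if (id >= 88.5) {
    category <- "novel"
  } else {
    cryodiv_warn(paste0("identity ", id, "% below 88.5%: OTU left unclassified"))
    category <- "unclassified"
  }
  list(category = category, tier = category_tier(category))
}

#' Classify a whole match table
#'
#' Applies [filter_classifiable()] then [classify_otu()] per OTU, and
#' tabulates the result.
#'
#' @param matches Match table data frame (see [read_match_table()]).
#' @param min_seqs Minimum `n_sequences` for an OTU to be classified.
#' @return List with `per_otu` (data frame: otu_id, best_identity_pct,
#'   category, tier), `counts` (named integer vector over all categories),
#'   `n_endemic`, `n_non_endemic`, `n_unclassified` and
#'   `pct_cosmopolitan_of_non_endemic` (in \[0, 100\]; `NaN` when there are
#'   no non-endemic OTUs).
#' @export
classify_dataset <- function(matches, min_seqs = 2L) {
  kept <- filter_classifiable(matches, min_seqs = min_seqs)
  envs <- split_environments(kept$match_environments)
  if (nrow(kept) == 0L) {
    per <- data.frame(otu_id = character(0), best_identity_pct = numeric(0),
                      category = character(0), tier = character(0),
                      stringsAsFactors = FALSE)
  } else {
    cls <- suppressWarnings(
      lapply(seq_len(nrow(kept)), function(i)
        classify_otu(kept$best_identity_pct[i], envs[[i]]))
    )
    per <- data.frame(
      otu_id = kept$otu_id,
      best_identity_pct = kept$best_identity_pct,
      category = vapply(cls, `[[`, character(1), "category"),
      tier = vapply(cls, `[[`, character(1), "tier"),
      stringsAsFactors = FALSE
    )
  }
  counts <- vapply(.endemicity_categories,
                   function(k) sum(per$category == k), integer(1))
  n_non_endemic <- sum(per$tier == "non_endemic")
  list(
    per_otu = per,
    counts = counts,
    n_endemic = sum(per$tier == "endemic"),
    n_non_endemic = n_non_endemic,
    n_unclassified = sum(per$tier == "unclassified"),
    pct_cosmopolitan_of_non_endemic =
      100 * counts[["polythermal_cosmopolitan"]] / n_non_endemic
  )
}
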