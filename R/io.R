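# Readers and writers for the plain-text formats the pipeline touches:
# FASTA alignments, Newick trees, TSV OTU tables, CSV site tables and TSV
# database-match tables.  Domain objects are deliberately plain R structures
# (named character vectors, integer matrices, data frames, ape "phylo"
# trees) so they compose with the wider ecosystem.
#
# Conventions: all tables are UTF-8; '#'-prefixed lines are comments and are
# skipped; TSV for matrices and match tables, CSV for site coordinates.

# ---- alignment ------------------------------------------------------------

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format. Residues are
#' uppercased; record order is preserved. The result is a named character
#' vector of equal-length sequences (the package's alignment representation).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are sequence ids, values are
#'   equal-length uppercase sequence strings.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
#' read_fasta_alignment(f)
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) cryodiv_stop("format_error", paste0("file not found: ", path))
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  if (length(recs) == 0L) cryodiv_stop("format_error", "FASTA file contains no records")
  aln <- toupper(vapply(recs, `[[`, character(1), 1L))
  names(aln) <- vapply(recs, function(r) attr(r, "name"), character(1))
  validate_alignment(aln)
  aln
}

#' Write an alignment to FASTA
#'
#' @param aln Named character vector of equal-length sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  validate_alignment(aln)
  seqinr::write.fasta(as.list(unname(aln)), names = names(aln), file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Validate an alignment object
#'
#' Checks that `aln` is a named character vector of equal-length sequences
#' with unique ids. Signals a classed error otherwise.
#'
#' @param aln Candidate alignment.
#' @return `aln`, invisibly.
#' @export
validate_alignment <- function(aln) {
  if (!is.character(aln) || length(aln) == 0L)
    cryodiv_stop("format_error", "alignment must be a non-empty character vector")
  ids <- names(aln)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    cryodiv_stop("format_error", "alignment sequences must all be named")
  if (anyDuplicated(ids))
    cryodiv_stop("format_error",
                 paste0("duplicate sequence ids: ",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  lens <- nchar(aln)
  if (length(unique(lens)) > 1L) {
    bad <- ids[lens != lens[1L]][1L]
    cryodiv_stop("alignment_error",
                 paste0("unequal sequence lengths (record '", bad, "' has ",
                        nchar(aln[[bad]]), " columns, expected ", lens[1L], ")"))
  }
  if (lens[1L] < 1L) cryodiv_stop("alignment_error", "alignment length must be >= 1")
  invisible(aln)
}

# ---- OTU table ------------------------------------------------------------

#' Read an OTU count table
#'
#' Reads a tab-separated table whose header row holds OTU ids and whose first
#' column holds sample ids. Counts must be non-negative integers. Lines
#' starting with `#` are ignored.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix, rows = samples, columns = OTUs, with dimnames.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) cryodiv_stop("format_error", paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) < 2L) cryodiv_stop("format_error", "OTU table has no data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  otu_ids <- header[-1L]
  if (length(otu_ids) == 0L) cryodiv_stop("format_error", "OTU table has no OTU columns")
  body <- cells[-1L]
  ncol_expect <- length(header)
  ragged <- lengths(body) != ncol_expect
  if (any(ragged))
    cryodiv_stop("format_error",
                 paste0("ragged row (", lengths(body)[ragged][1L], " fields, expected ",
                        ncol_expect, ")"))
  sample_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(sample_ids)) cryodiv_stop("format_error", "duplicate sample ids")
  if (anyDuplicated(otu_ids)) cryodiv_stop("format_error", "duplicate OTU ids")
  raw <- t(vapply(body, function(r) r[-1L], character(length(otu_ids))))
  if (length(otu_ids) == 1L) raw <- matrix(raw, ncol = 1L)
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num)) cryodiv_stop("format_error", "non-numeric cell in OTU table")
  if (any(num < 0)) cryodiv_stop("format_error", "negative count in OTU table")
  if (any(num != round(num))) cryodiv_stop("format_error", "non-integer count in OTU table")
  counts <- matrix(as.integer(num), nrow = length(sample_ids),
                   dimnames = list(sample_ids, otu_ids))
  validate_otu_table(counts)
  counts
}

#' Write an OTU count table as TSV
#'
#' @param table Integer matrix, rows = samples, columns = OTUs.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  validate_otu_table(table)
  df <- data.frame(sample_id = rownames(table), table, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate an OTU count table
#'
#' @param table Candidate matrix of counts, rows = samples, columns = OTUs.
#' @return `table`, invisibly.
#' @export
validate_otu_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    cryodiv_stop("format_error", "OTU table must be a numeric matrix")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    cryodiv_stop("format_error", "OTU table must have sample and OTU dimnames")
  if (anyDuplicated(rownames(table)) || anyDuplicated(colnames(table)))
    cryodiv_stop("format_error", "OTU table labels must be unique")
  if (anyNA(table) || any(table < 0) || any(table != round(table)))
    cryodiv_stop("format_error", "OTU counts must be non-negative integers")
  if (nrow(table) > 0L && any(rowSums(table) == 0))
    cryodiv_stop("format_error",
                 paste0("sample with no positive counts: ",
                        rownames(table)[rowSums(table) == 0][1L]))
  invisible(table)
}

# ---- tree -----------------------------------------------------------------

#' Read a rooted Newick tree
#'
#' Wraps [ape::read.tree()] and validates the result: the tree must be rooted,
#' tip labels unique, branch lengths non-negative. A missing branch length is
#' set to 0 with a warning (Faith's PD and UniFrac require lengths; a silent
#' default would bias branch-length sums).
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) cryodiv_stop("format_error", paste0("file not found: ", path))
  tree <- tryCatch(ape::read.tree(path), error = function(e)
    cryodiv_stop("format_error", paste0("not parseable as Newick: ", conditionMessage(e))))
  if (is.null(tree)) cryodiv_stop("format_error", "not parseable as Newick")
  validate_tree(tree)
}

#' Write a tree to Newick
#'
#' @param tree A `"phylo"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate a rooted tree with branch lengths
#'
#' @param tree Candidate `"phylo"` object.
#' @return The tree (possibly with missing branch lengths zero-filled),
#'   invisibly usable.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) cryodiv_stop("format_error", "tree must be a 'phylo' object")
  if (!ape::is.rooted(tree)) cryodiv_stop("format_error", "tree must be rooted")
  if (anyDuplicated(tree$tip.label)) cryodiv_stop("format_error", "duplicate tip labels")
  if (is.null(tree$edge.length)) {
    cryodiv_warn("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    cryodiv_warn("missing branch lengths treated as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) cryodiv_stop("format_error", "negative branch length")
  tree
}

# ---- geographic sites -----------------------------------------------------

#' Read a site coordinate table
#'
#' Reads a CSV file with columns `site_id`, `lat`, `lon` (decimal degrees).
#' Latitudes must lie in \[-90, 90\] and longitudes in (-180, 180\]. Use
#' [ddm_to_decimal()] to convert degrees-decimal-minutes field notation.
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns `site_id`, `lat`, `lon`.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) cryodiv_stop("format_error", paste0("file not found: ", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("site_id", "lat", "lon")
  if (!all(need %in% names(df)))
    cryodiv_stop("format_error", "site table must have columns site_id, lat, lon")
  df <- df[, need]
  df$site_id <- as.character(df$site_id)
  validate_sites(df)
  df
}

#' Write a site coordinate table as CSV
#'
#' @param sites Data frame with columns `site_id`, `lat`, `lon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  validate_sites(sites)
  utils::write.csv(sites[, c("site_id", "lat", "lon")], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a site table
#'
#' @param sites Candidate data frame with `site_id`, `lat`, `lon` columns.
#' @return `sites`, invisibly.
#' @export
validate_sites <- function(sites) {
  if (anyDuplicated(sites$site_id)) cryodiv_stop("format_error", "duplicate site ids")
  if (anyNA(sites$lat) || anyNA(sites$lon))
    cryodiv_stop("format_error", "missing coordinate")
  if (any(sites$lat < -90 | sites$lat > 90))
    cryodiv_stop("range_error", "latitude outside [-90, 90]")
  if (any(sites$lon <= -180 | sites$lon > 180))
    cryodiv_stop("range_error", "longitude outside (-180, 180]")
  invisible(sites)
}

#' Convert degrees-decimal-minutes to decimal degrees
#'
#' Parses coordinate strings in the field-notebook style `"S 03 04.839"`
#' (hemisphere letter, whole degrees, decimal minutes; the trailing prime is
#' optional). South and west are returned negative.
#'
#' @param x Character vector of degrees-decimal-minutes strings.
#' @return Numeric vector of decimal degrees.
#' @examples
#' ddm_to_decimal("S 03 04.839")   # Kilimanjaro summit latitude, about -3.0807
#' ddm_to_decimal("E 037 21.628")
#' @export
ddm_to_decimal <- function(x) {
  vapply(x, function(s) {
    s <- gsub("[′']", "", trimws(s))
    m <- regmatches(s, regexec("^([NSEW])\\s*([0-9]+)\\s+([0-9]+(?:\\.[0-9]+)?)$",
                               s, ignore.case = TRUE))[[1L]]
    if (length(m) != 4L)
      cryodiv_stop("format_error", paste0("cannot parse coordinate: '", s, "'"))
    hemi <- toupper(m[2L])
    val <- as.numeric(m[3L]) + as.numeric(m[4L]) / 60
    if (hemi %in% c("S", "W")) val <- -val
    val
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- match table ----------------------------------------------------------

.match_env_vocab <- c("cold", "temperate")

#' Read an OTU database-match table
#'
#' Reads a TSV file with columns `otu_id`, `n_sequences`, `best_identity_pct`
#' and `match_environments` (semicolon-separated labels from
#' `{cold, temperate}`; may be empty when the best identity is below 97%).
#' This is the input of the endemicity classifier; it summarises, per OTU,
#' the best database hit identity and the environments of all hits at >= 97%
#' identity.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `otu_id` (character), `n_sequences`
#'   (integer), `best_identity_pct` (numeric), `match_environments`
#'   (character, semicolon-separated).
#' @export
read_match_table <- function(path) {
  if (!file.exists(path)) cryodiv_stop("format_error", paste0("file not found: ", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = c(match_environments = "character"))
  need <- c("otu_id", "n_sequences", "best_identity_pct", "match_environments")
  if (!all(need %in% names(df)))
    cryodiv_stop("format_error",
                 "match table must have columns otu_id, n_sequences, best_identity_pct, match_environments")
  df <- df[, need]
  df$otu_id <- as.character(df$otu_id)
  df$match_environments[is.na(df$match_environments)] <- ""
  validate_match_table(df)
  df
}

#' Write an OTU match table as TSV
#'
#' @param matches Match table data frame (see [read_match_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(matches, path) {
  validate_match_table(matches)
  utils::write.table(matches[, c("otu_id", "n_sequences", "best_identity_pct",
                                 "match_environments")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a match table
#'
#' @param matches Candidate match table data frame.
#' @return `matches`, invisibly.
#' @export
validate_match_table <- function(matches) {
  if (anyDuplicated(matches$otu_id)) cryodiv_stop("format_error", "duplicate OTU ids")
  if (anyNA(matches$n_sequences) || any(matches$n_sequences < 1) ||
      any(matches$n_sequences != round(matches$n_sequences)))
    cryodiv_stop("format_error", "n_sequences must be integers >= 1")
  if (anyNA(matches$best_identity_pct) ||
      any(matches$best_identity_pct < 0 | matches$best_identity_pct > 100))
    cryodiv_stop("range_error", "best_identity_pct must lie in [0, 100]")
  envs <- split_environments(matches$match_environments)
  bad <- setdiff(unique(unlist(envs)), .match_env_vocab)
  if (length(bad) > 0L)
    cryodiv_stop("vocabulary_error",
                 paste0("unknown environment label(s): ", paste(bad, collapse = ", "),
                        " (allowed: ", paste(.match_env_vocab, collapse = ", "), ")"))
  hi <- matches$best_identity_pct >= 97
  if (any(hi & lengths(envs) == 0L))
    cryodiv_stop("data_error",
                 "OTU with best identity >= 97% must have at least one match environment")
  invisible(matches)
}

# split semicolon-joined environment labels into a list of character vectors
split_environments <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(v) unique(trimws(v[nzchar(trimws(v))])))
}

# ---- distance matrices (PHYLIP) -------------------------------------------

#' Read a PHYLIP distance matrix
#'
#' Reads square or lower-triangle PHYLIP format (first line: number of taxa;
#' then one row per taxon: label followed by distances).
#'
#' @param path Path to a PHYLIP distance file.
#' @return Symmetric numeric matrix with zero diagonal and label dimnames.
#' @export
read_phylip_dist <- function(path) {
  if (!file.exists(path)) cryodiv_stop("format_error", paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) cryodiv_stop("format_error", "bad PHYLIP taxon count")
  if (length(lines) != n + 1L) cryodiv_stop("format_error", "PHYLIP row count mismatch")
  rows <- strsplit(trimws(lines[-1L]), "[ \t]+")
  labels <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(labels)) cryodiv_stop("format_error", "duplicate labels")
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])))
  if (any(vapply(vals, anyNA, logical(1)))) cryodiv_stop("format_error", "non-numeric distance")
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (all(lengths(vals) == n)) {                     # square
    for (i in seq_len(n)) m[i, ] <- vals[[i]]
  } else if (all(lengths(vals) == seq_len(n) - 1L)) { # lower triangle
    for (i in seq_len(n)) if (i > 1L) m[i, seq_len(i - 1L)] <- vals[[i]]
    m <- m + t(m)
  } else {
    cryodiv_stop("format_error", "PHYLIP rows are neither square nor lower-triangular")
  }
  validate_distance_matrix(m)
  m
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d Symmetric numeric matrix with label dimnames.
#' @param path Output file path.
#' @param digits Number of significant digits to print.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path, digits = 10) {
  validate_distance_matrix(d)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(as.character(nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(rownames(d)[i], format(d[i, ], digits = digits, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}
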