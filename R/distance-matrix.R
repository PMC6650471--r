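# The distance matrix is the common currency of beta diversity and the
# Mantel machinery: a symmetric non-negative numeric matrix with zero
# diagonal and unique label dimnames.

#' Validate a distance matrix
#'
#' Checks symmetry (within 1e-12), a zero diagonal, non-negativity and the
#' presence of unique labels. NaN/NA entries are rejected.
#'
#' @param d Candidate numeric matrix.
#' @return `d`, invisibly.
#' @export
validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    cryodiv_stop("format_error", "distance matrix must be a square numeric matrix")
  if (anyNA(d)) cryodiv_stop("data_error", "NA/NaN entries in distance matrix")
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    cryodiv_stop("format_error", "distance matrix needs unique row labels")
  if (!identical(rownames(d), colnames(d)))
    cryodiv_stop("format_error", "distance matrix row/column labels differ")
  if (any(abs(d - t(d)) > 1e-12))
    cryodiv_stop("format_error", "distance matrix is not symmetric")
  if (any(diag(d) != 0))
    cryodiv_stop("format_error", "distance matrix diagonal must be exactly 0")
  if (any(d < 0)) cryodiv_stop("format_error", "negative distances")
  invisible(d)
}

# lower-triangle vector of unordered pair values, column-major (the pair
# ordering shared by stats::dist)
lower_vec <- function(d) d[lower.tri(d)]

# number of unordered pairs represented in a distance matrix
n_pairs <- function(d) {
  n <- nrow(d)
  n * (n - 1L) / 2L
}
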