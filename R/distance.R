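#' Longest-common-subsequence length
#'
#' Length of the longest subsequence common to `x` and `y`: states that occur
#' in the same order in both sequences without having to occupy consecutive
#' positions. Compound states (such as `"RT"`) are atomic symbols -- there is
#' no partial credit between overlapping states.
#'
#' @param x,y state vectors (character or anything comparable with `==`).
#' @return nonnegative integer.
#' @export
lcs_length <- function(x, y) {
  if (!length(x) || !length(y)) return(0L)
  alphabet <- unique(c(x, y))
  lcs_length_cpp(match(x, alphabet), match(y, alphabet))
}

#' LCS dissimilarity between two state sequences
#'
#' `d(x, y) = |x| + |y| - 2 * lcs_length(x, y)`. On sequences of fixed length
#' this is a metric: nonnegative, zero iff the sequences are equal, symmetric,
#' and satisfying the triangle inequality.
#'
#' @inheritParams lcs_length
#' @return nonnegative integer.
#' @export
lcs_distance <- function(x, y) {
  length(x) + length(y) - 2L * lcs_length(x, y)
}

dist_kind <- function(m) attr(m, "dist_kind") %||% "raw"

new_distance_matrix <- function(values, labels, kind, denominator = NULL) {
  dimnames(values) <- list(labels, labels)
  attr(values, "dist_kind") <- kind
  if (!is.null(denominator)) attr(values, "denominator") <- denominator
  values
}

#' Pairwise LCS distance matrix for one dimension
#'
#' Computes the symmetric matrix of LCS dissimilarities between all patients'
#' sequences of one dimension. Identical sequences are collapsed before the
#' dynamic-programming pass and the matrix expanded afterwards, so cost
#' scales with the number of distinct trajectories. All arithmetic is exact
#' integer arithmetic.
#'
#' @param states character state matrix (patients x intervals) from
#'   [encode_dimension()].
#' @return numeric distance matrix (kind `"raw"`) with patient-id dimnames.
#' @export
pairwise_distances <- function(states) {
  if (is.null(dim(states)) || !is.matrix(states))
    stop("states must be a patients x intervals matrix", call. = FALSE)
  n <- nrow(states)
  key <- do.call(paste, c(as.data.frame(states, stringsAsFactors = FALSE),
                          sep = "\r"))
  uk <- unique(key)
  idx <- match(key, uk)
  u <- states[match(uk, key), , drop = FALSE]
  alphabet <- unique(as.vector(u))
  ucodes <- matrix(match(u, alphabet), nrow(u), ncol(u))
  du <- lcs_pairwise_cpp(ucodes)
  values <- matrix(as.numeric(du[idx, idx, drop = FALSE]), n, n)
  new_distance_matrix(values, rownames(states), "raw")
}

#' Min-max normalization of a distance matrix
#'
#' Rescales a raw per-dimension matrix onto a common `[0, 1]` scale before
#' pooling, so that quarterly dimensions (maximum possible distance 24) and
#' the annual dimension (maximum 6) contribute comparably. The minimum of the
#' rescaling is fixed at 0 -- the theoretical minimum of a dissimilarity --
#' because subtracting a positive observed minimum would destroy the zero
#' diagonal; entries are divided by the maximum observed off-diagonal entry
#' (`denominator = "observed"`, the default) or by the theoretical maximum
#' `2 * sequence length` (`denominator = "theoretical"`, for sensitivity
#' analysis).
#'
#' @param m raw distance matrix from [pairwise_distances()].
#' @param denominator `"observed"` or `"theoretical"`.
#' @param sequence_length required when `denominator = "theoretical"`.
#' @return normalized distance matrix (kind `"normalized"`); an all-zero
#'   matrix is returned unchanged with a degenerate-dimension warning.
#' @export
minmax_normalize <- function(m, denominator = c("observed", "theoretical"),
                             sequence_length = NULL) {
  denominator <- match.arg(denominator)
  if (denominator == "observed") {
    dmax <- max(m)
    if (dmax == 0) {
      warning("degenerate dimension: all distances are zero; returning zero matrix",
              call. = FALSE)
      return(new_distance_matrix(m, rownames(m), "normalized", denominator = 0))
    }
  } else {
    if (is.null(sequence_length))
      stop("sequence_length is required for theoretical-max normalization",
           call. = FALSE)
    dmax <- 2 * sequence_length
  }
  new_distance_matrix(m / dmax, rownames(m), "normalized", denominator = dmax)
}

#' Pool normalized per-dimension matrices
#'
#' Entrywise sum of the normalized matrices; with `D` dimensions the pooled
#' entries lie in `[0, D]`.
#'
#' @param matrices list of normalized distance matrices with identical label
#'   order.
#' @return pooled distance matrix (kind `"pooled"`).
#' @export
pool_distances <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  labels <- rownames(matrices[[1]])
  for (m in matrices[-1]) {
    if (!identical(rownames(m), labels))
      stop("distance matrices have mismatching labels", call. = FALSE)
  }
  pooled <- Reduce(`+`, matrices)
  new_distance_matrix(pooled, labels, "pooled")
}

#' Write a distance matrix as labeled CSV with a JSON manifest
#'
#' @param m distance matrix.
#' @param path CSV output path; the manifest is written next to it.
#' @return invisibly, the CSV path.
#' @export
write_distance_matrix <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = TRUE)
  manifest <- list(kind = dist_kind(m),
                   denominator = attr(m, "denominator"),
                   n = nrow(m))
  jsonlite::write_json(manifest, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
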