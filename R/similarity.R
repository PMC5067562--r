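#' Pairwise Hamming distance matrix
#'
#' The Hamming distance between two equal-length binary vectors is the
#' fraction of positions at which they differ; between two subjects it is
#' the proportion of items on which their (binary) responses disagree.
#' Computed across subjects (rows) or items (columns), optionally
#' restricted to a named item subset.
#'
#' @param tbl A binarized response table ([binarize_responses()]).
#' @param axis `"subjects"` (default) or `"items"`.
#' @param items Optional character vector of item columns to restrict to.
#' @return Symmetric numeric matrix with entries in \[0, 1\], zero
#'   diagonal, and axis IDs as dimnames.
#' @export
hamming_matrix <- function(tbl, axis = c("subjects", "items"), items = NULL) {
  axis <- match.arg(axis)
  assert_binary_table(tbl)
  if (!is.null(items)) {
    if (length(items) == 0) {
      abort("`items` must be a nonempty subset of the item columns.",
            class = "eyestrat_parameter_error")
    }
    bad <- setdiff(items, item_columns(tbl))
    if (length(bad) > 0) {
      abort(sprintf("Unknown item(s): %s.", paste(bad, collapse = ", ")),
            class = "eyestrat_parameter_error")
    }
  } else {
    items <- item_columns(tbl)
  }
  x <- as.matrix(tbl[, items])
  rownames(x) <- tbl$subject_id
  if (axis == "items") x <- t(x)
  m <- ncol(x)
  mismatch <- x %*% (1 - t(x))
  d <- (mismatch + t(mismatch)) / m
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

assert_distance_like <- function(d, call = rlang::caller_env()) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort("Expected a square distance matrix.",
          class = "eyestrat_validation_error", call = call)
  }
  if (max(abs(d - t(d))) > 1e-10) {
    abort("Distance matrix must be symmetric.",
          class = "eyestrat_validation_error", call = call)
  }
  if (min(d) < -1e-12 || max(d) > 1 + 1e-12) {
    abort("Distance entries must lie in [0, 1].",
          class = "eyestrat_validation_error", call = call)
  }
  invisible(d)
}

#' Topological overlap from a distance matrix
#'
#' Converts pairwise distances into the (unsigned) topological overlap
#' similarity used in weighted network analysis. With adjacency
#' \eqn{a_{ij} = 1 - d_{ij}} (zero diagonal), connectivity
#' \eqn{k_i = \sum_{u \ne i} a_{iu}} and shared-neighbor sum
#' \eqn{\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}}:
#' \deqn{TOM_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
#'   \quad TOM_{ii} = 1.}
#' Two nodes have high topological overlap when they are similar to each
#' other *and* similar to the same neighbors, which makes the measure less
#' susceptible to noise than the raw pairwise similarity.
#'
#' @param d Symmetric distance matrix with entries in \[0, 1\] and zero
#'   diagonal (e.g. from [hamming_matrix()]).
#' @return A `tom_matrix`: the TOM with unit diagonal and entries in
#'   \[0, 1\], carrying the adjacency and connectivities as attributes
#'   `adjacency` and `connectivity` for audit.
#' @seealso [tom_dissimilarity()]
#' @export
topological_overlap <- function(d) {
  assert_distance_like(d)
  a <- 1 - d
  diag(a) <- 0
  k <- rowSums(a)
  ell <- a %*% a              # diag(a) = 0, so u = i, j terms vanish
  kmin <- outer(k, k, pmin)
  tom <- (ell + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(d)
  structure(tom, adjacency = a, connectivity = k, class = "tom_matrix")
}

#' @export
print.tom_matrix <- function(x, ...) {
  cat(sprintf("<topological overlap matrix: %d x %d>\n", nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Topological overlap dissimilarity
#'
#' The complement `1 - TOM`, a proper dissimilarity (zero diagonal) fed to
#' hierarchical clustering.
#'
#' @param tom A `tom_matrix` from [topological_overlap()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
tom_dissimilarity <- function(tom) {
  stopifnot(inherits(tom, "tom_matrix"))
  d <- 1 - unclass(tom)
  diag(d) <- 0
  attr(d, "adjacency") <- NULL
  attr(d, "connectivity") <- NULL
  d
}

#' Long-format view of a similarity or distance matrix
#'
#' @param x A square matrix (e.g. from [hamming_matrix()] or
#'   [topological_overlap()]).
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `value`, one row per cell.
#' @method tidy tom_matrix
#' @export
tidy.tom_matrix <- function(x, ...) {
  m <- unclass(x)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tibble::tibble(
    from = rep(ids, times = ncol(m)),
    to = rep(ids, each = nrow(m)),
    value = as.vector(m)
  )
}
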