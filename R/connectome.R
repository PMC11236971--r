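#' Generate a synthetic structural connectome
#'
#' Draws a symmetric, zero-diagonal adjacency matrix from a stochastic block
#' model whose blocks are the functional systems of `labels`: region pairs
#' within the same system are connected with probability `p_in`, pairs in
#' different systems with probability `p_out`. Edge weights are positive
#' integers (streamline-count semantics) drawn from 1 + Poisson(4); the
#' pipeline only uses the binarized view (weight > `sc_threshold`).
#'
#' @param labels A `parcellation` data.frame.
#' @param p_in,p_out Within-/between-system edge probabilities,
#'   `0 <= p_out <= p_in <= 1`.
#' @param seed RNG seed.
#' @return A `structural_connectome` list with elements `adjacency`
#'   (N x N symmetric numeric matrix, zero diagonal) and `sc_threshold`
#'   (default binarization threshold, 0).
#' @export
generate_structural_connectome <- function(labels, p_in, p_out, seed = 1L) {
  validate_parcellation(labels)
  check_prob(p_in, "p_in")
  check_prob(p_out, "p_out")
  if (p_out > p_in) stopf("'p_out' must not exceed 'p_in'")
  n <- nrow(labels)
  sys <- system_index(labels)

  adj <- with_seed(seed, {
    a <- matrix(0, n, n)
    ut <- which(upper.tri(a), arr.ind = TRUE)
    same <- sys[ut[, 1L]] == sys[ut[, 2L]]
    p <- ifelse(same, p_in, p_out)
    present <- stats::runif(nrow(ut)) < p
    w <- ifelse(present, 1 + stats::rpois(nrow(ut), 4), 0)
    a[ut] <- w
    a + t(a)
  })
  structural_connectome(adj, sc_threshold = 0)
}

#' Construct a structural connectome object
#'
#' Wraps a nonnegative symmetric adjacency matrix (zero diagonal) with the
#' threshold used for its binarized view: a structural edge i-j is present iff
#' `adjacency[i, j] > sc_threshold`.
#'
#' @param adjacency N x N nonnegative symmetric numeric matrix.
#' @param sc_threshold Binarization threshold (default 0: any positive
#'   weight is an edge).
#' @return A `structural_connectome` object.
#' @export
structural_connectome <- function(adjacency, sc_threshold = 0) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stopf("adjacency must be square, got %d x %d", nrow(adjacency),
          ncol(adjacency))
  if (any(!is.finite(adjacency)) || any(adjacency < 0))
    stopf("adjacency must be finite and nonnegative")
  if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 1e-8)))
    stopf("adjacency must be symmetric")
  diag(adjacency) <- 0
  structure(list(adjacency = adjacency, sc_threshold = sc_threshold),
            class = "structural_connectome")
}

#' Binarized view of a structural connectome
#'
#' @param sc A `structural_connectome` (or plain matrix, taken as already
#'   weighted with threshold 0).
#' @param sc_threshold Optional override of the stored threshold.
#' @return Logical N x N matrix, symmetric with `FALSE` diagonal.
#' @export
binarize_sc <- function(sc, sc_threshold = NULL) {
  if (is.matrix(sc)) sc <- structural_connectome(sc)
  thr <- sc_threshold %||% sc$sc_threshold
  b <- sc$adjacency > thr
  diag(b) <- FALSE
  b
}

#' @export
print.structural_connectome <- function(x, ...) {
  b <- binarize_sc(x)
  n <- nrow(b)
  cat(sprintf(
    "Structural connectome: %d regions, %d edges (density %.3f), sc_threshold %g\n",
    n, sum(b) / 2, sum(b) / (n * (n - 1)), x$sc_threshold))
  invisible(x)
}
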