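#' Construct a weighted brain network
#'
#' A `weighted_network` holds one subject's symmetric, non-negative weighted
#' adjacency matrix together with its region labels. Edge weights are
#' dimensionless connection strengths (mean fractional anisotropy along the
#' tracts joining two regions in the intended application); the binary
#' adjacency is implied: an edge exists wherever the weight is strictly
#' positive.
#'
#' @param weights Numeric n x n matrix; symmetric, zero diagonal, all entries
#'   finite and >= 0. Asymmetry up to `tol` is repaired by averaging the two
#'   triangles; larger asymmetry is an error.
#' @param labels Character vector of region names, one per node. Defaults to
#'   dimnames of `weights` or `"V1"..."Vn"`.
#' @param tol Numeric tolerance for symmetry and zero-diagonal checks.
#' @return An object of class `weighted_network`: a list with elements
#'   `weights` (matrix), `labels` (character), `n` (node count).
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.5; w[2, 3] <- w[3, 2] <- 0.5
#' net <- weighted_network(w)
#' net$n
#' @export
weighted_network <- function(weights, labels = NULL, tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("`weights` must be square (got ", n, " x ", ncol(weights), ")",
         call. = FALSE)
  if (n < 2) stop("a network needs at least 2 nodes", call. = FALSE)
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("`weights` contains NA, NaN or infinite entries", call. = FALSE)
  if (any(weights < 0))
    stop("`weights` contains negative entries", call. = FALSE)
  asym <- max(abs(weights - t(weights)))
  if (asym > tol)
    stop("`weights` is asymmetric beyond tolerance (max |w_ij - w_ji| = ",
         format(asym), ")", call. = FALSE)
  if (asym > 0) weights <- (weights + t(weights)) / 2
  if (max(abs(diag(weights))) > tol)
    stop("`weights` must have a zero diagonal", call. = FALSE)
  diag(weights) <- 0
  if (is.null(labels)) labels <- rownames(weights) %||% paste0("V", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("label count (", length(labels), ") does not match node count (",
         n, ")", call. = FALSE)
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, n = n),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("<weighted_network> ", x$n, " nodes, ", m, " edges (density ",
      sprintf("%.3f", m / (x$n * (x$n - 1) / 2)), ")\n", sep = "")
  cat("  weight range: [", sprintf("%.4g", min(x$weights[x$weights > 0])),
      ", ", sprintf("%.4g", max(x$weights)), "] on present edges\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.weighted_network <- function(x, ...) x$weights

#' Edge density of a network
#'
#' Fraction of node pairs joined by a positive-weight edge.
#'
#' @param net A [weighted_network()].
#' @return A number in \[0, 1\].
#' @export
edge_density <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights[upper.tri(net$weights)]
  mean(w > 0)
}

#' Bundled AAL-90 region labels
#'
#' Region names of the 90-region automated anatomical labeling parcellation
#' (78 cortical + 12 subcortical regions, cerebellum excluded), in the
#' conventional left/right interleaved order.
#'
#' @return Character vector of length 90.
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.txt", package = "connstat",
                      mustWork = TRUE)
  readLines(path)
}
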