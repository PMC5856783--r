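# Containers for samples of labeled networks on a fixed node set.
#
# Internally a sample is stored as an l x E matrix X whose rows are subjects and
# whose columns are the upper-triangle entries of the adjacency matrix, in
# column-major order ((1,2), (1,3), (2,3), (1,4), ...). All statistics in the
# package decompose over these edge columns, which is what makes the restricted
# (subnetwork) searches cheap.

#' Endpoints of the upper-triangle edge ordering
#'
#' Node pairs (i < j) in the column-major upper-triangle order used throughout
#' the package to vectorize adjacency matrices.
#'
#' @param n Number of nodes.
#' @return A list with integer vectors `i` and `j` of length `n * (n - 1) / 2`.
#' @keywords internal
edge_ends <- function(n) {
  idx <- arrayInd(which(upper.tri(diag(n))), c(n, n))
  list(i = idx[, 1L], j = idx[, 2L])
}

upper_vec <- function(m) m[upper.tri(m)]

# rebuild a symmetric zero-diagonal matrix from its upper-triangle vector
unflatten_edges <- function(x, nodes) {
  n <- length(nodes)
  m <- matrix(0, n, n, dimnames = list(nodes, nodes))
  m[upper.tri(m)] <- x
  m + t(m)
}

validate_adjacency <- function(a, who = "matrix", weighted_ok = TRUE,
                               tol = 1e-8) {
  if (!is.matrix(a) || !is.numeric(a) || nrow(a) != ncol(a)) {
    stop(who, " must be a square numeric matrix", call. = FALSE)
  }
  if (nrow(a) < 2L) stop(who, " must have at least 2 nodes", call. = FALSE)
  if (anyNA(a)) stop(who, " contains missing values", call. = FALSE)
  asym <- abs(a - t(a))
  if (max(asym) > tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s is not symmetric (entry [%d, %d] differs from [%d, %d] by %.3g)",
                 who, bad[1L], bad[2L], bad[2L], bad[1L], max(asym)),
         call. = FALSE)
  }
  if (any(abs(diag(a)) > tol)) {
    stop(who, " must have a zero diagonal (no self-loops)", call. = FALSE)
  }
  if (any(a < 0 | a > 1)) {
    stop(who, " has entries outside [0, 1]; weighted networks must be scaled to [0, 1]",
         call. = FALSE)
  }
  if (!weighted_ok && any(a != 0 & a != 1)) {
    stop(who, " must be binary for this operation", call. = FALSE)
  }
  invisible(a)
}

node_labels_of <- function(a, n) {
  lb <- rownames(a)
  if (is.null(lb)) lb <- colnames(a)
  if (is.null(lb)) lb <- paste0("v", seq_len(n))
  if (anyDuplicated(lb)) stop("node labels must be unique", call. = FALSE)
  lb
}

#' Create a sample of networks on a common node set
#'
#' Bundles a set of undirected labeled networks (adjacency matrices that are
#' symmetric, hollow, with entries in \[0, 1\]) observed on the same ordered
#' node set. Binary samples enable the analytic calibration of the test
#' statistic; weighted samples are supported everywhere a permutation
#' calibration is available.
#'
#' @param x A list of n-by-n adjacency matrices, or a 3-D array with dimensions
#'   n, n, l (one slice per subject).
#' @param nodes Optional character vector of node labels; defaults to the
#'   dimnames of the first matrix or `v1..vn`.
#' @param ids Optional subject identifiers (defaults to `s1..sl`).
#' @return An object of class `network_sample` with fields `nodes`, `ids`,
#'   `X` (subjects-by-edges matrix) and `binary`.
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' empty <- matrix(0, 3, 3)
#' ns <- network_sample(list(empty, tri))
#' variability(ns)
#' @export
network_sample <- function(x, nodes = NULL, ids = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- lapply(seq_len(dim(x)[3L]), function(k) x[, , k])
  }
  if (!is.list(x) || length(x) < 1L) {
    stop("`x` must be a non-empty list of adjacency matrices or a 3-D array",
         call. = FALSE)
  }
  n <- nrow(x[[1L]])
  if (is.null(nodes)) nodes <- node_labels_of(x[[1L]], n)
  if (length(nodes) != n || anyDuplicated(nodes)) {
    stop("`nodes` must be ", n, " unique labels", call. = FALSE)
  }
  X <- matrix(NA_real_, length(x), n * (n - 1L) / 2L)
  for (k in seq_along(x)) {
    a <- x[[k]]
    if (nrow(a) != n) {
      stop("network ", k, " has ", nrow(a), " nodes; expected ", n,
           " (all members must share the node set)", call. = FALSE)
    }
    lb <- rownames(a)
    if (!is.null(lb) && !identical(lb, as.character(nodes))) {
      if (setequal(lb, nodes)) {
        a <- a[nodes, nodes]
      } else {
        stop("network ", k, " is labeled with a different node set", call. = FALSE)
      }
    }
    validate_adjacency(a, who = paste0("network ", k))
    X[k, ] <- upper_vec(a)
  }
  if (is.null(ids)) ids <- paste0("s", seq_along(x))
  structure(
    list(nodes = as.character(nodes), ids = as.character(ids), X = X,
         binary = all(X == 0 | X == 1)),
    class = "network_sample"
  )
}

new_sample_from_edges <- function(X, nodes, ids = paste0("s", seq_len(nrow(X)))) {
  structure(
    list(nodes = nodes, ids = ids, X = X, binary = all(X == 0 | X == 1)),
    class = "network_sample"
  )
}

#' @export
length.network_sample <- function(x) nrow(x$X)

#' @export
print.network_sample <- function(x, ...) {
  cat(sprintf("<network_sample> %d networks on %d nodes (%s)\n",
              nrow(x$X), length(x$nodes),
              if (x$binary) "binary" else "weighted"))
  invisible(x)
}

#' Extract one member network as an adjacency matrix
#'
#' @param x A `network_sample` or `grouped_sample`.
#' @param k Member index.
#' @return A labeled n-by-n adjacency matrix.
#' @export
member_matrix <- function(x, k) {
  s <- as_network_sample(x)
  stopifnot(k >= 1L, k <= nrow(s$X))
  unflatten_edges(s$X[k, ], s$nodes)
}

as_network_sample <- function(x) {
  if (inherits(x, "grouped_sample")) x$sample
  else if (inherits(x, "network_sample")) x
  else network_sample(x)
}

#' Partition a network sample into groups
#'
#' Attaches group membership to a [network_sample()], defining the m
#' subpopulations compared by [network_anova()]. Group order follows first
#' appearance in `groups`; every group must contain at least two networks
#' (the finite-sample bias factor n_i / (n_i - 1) of the test statistic is
#' undefined otherwise).
#'
#' @param x A `network_sample`, or anything [network_sample()] accepts.
#' @param groups Vector of group labels, one per member network.
#' @return An object of class `grouped_sample` with fields `sample`, `groups`
#'   (factor) and `sizes`.
#' @examples
#' lay <- default_layout("scalp16")
#' mod <- geometric_model(lay, lambda_planted = c(1, 0.8, 0.6))
#' gx <- geometric_grouped_sample(mod, K = 10, seed = 1)
#' gx
#' @export
grouped_sample <- function(x, groups = NULL) {
  if (inherits(x, "grouped_sample")) {
    if (!is.null(groups)) x <- grouped_sample(x$sample, groups)
    return(x)
  }
  s <- as_network_sample(x)
  if (is.null(groups)) stop("`groups` is required", call. = FALSE)
  if (length(groups) != nrow(s$X)) {
    stop("`groups` must have one label per network (", nrow(s$X), ")",
         call. = FALSE)
  }
  if (anyNA(groups)) stop("`groups` contains missing labels", call. = FALSE)
  f <- factor(groups, levels = unique(as.character(groups)))
  sizes <- as.integer(table(f))
  if (nlevels(f) < 2L) stop("at least two groups are required", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 networks (got sizes ",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  }
  structure(list(sample = s, groups = f, sizes = sizes),
            class = "grouped_sample")
}

#' @export
print.grouped_sample <- function(x, ...) {
  cat(sprintf("<grouped_sample> %d networks on %d nodes in %d groups (%s)\n",
              nrow(x$sample$X), length(x$sample$nodes), nlevels(x$groups),
              paste(levels(x$groups), "=", x$sizes, collapse = ", ")))
  invisible(x)
}
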