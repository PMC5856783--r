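# Metric-space primitives: edit distance, mean network, average distance,
# variability.

coerce_matrix <- function(a, who) {
  if (inherits(a, "mean_network")) a <- unclass(a)
  validate_adjacency(a, who = who)
  a
}

check_same_nodes <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    stop("networks are defined on node sets of different size (",
         nrow(a), " vs ", nrow(b), ")", call. = FALSE)
  }
  la <- rownames(a); lb <- rownames(b)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    stop("networks are labeled with different node sets", call. = FALSE)
  }
}

#' Edit distance between two labeled networks
#'
#' The number of links that must be added or removed to turn one network into
#' the other: the L1 distance between adjacency matrices, summed over unordered
#' node pairs. For weighted networks (entries in \[0, 1\]) the same sum of
#' absolute entry differences is used.
#'
#' @param a,b Adjacency matrices (symmetric, zero diagonal, entries in
#'   \[0, 1\]) on the same node set; a `mean_network` is accepted.
#' @return A nonnegative scalar; an integer count for binary inputs.
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' edit_distance(matrix(0, 3, 3), tri) # 3
#' @export
edit_distance <- function(a, b) {
  a <- coerce_matrix(a, "`a`"); b <- coerce_matrix(b, "`b`")
  check_same_nodes(a, b)
  sum(abs(upper_vec(a) - upper_vec(b)))
}

#' Mean network of a sample
#'
#' The entrywise average of the adjacency matrices: a weighted network whose
#' (i, j) entry is the proportion of sample members carrying link (i, j) (the
#' plug-in estimate of the link probability p_ij).
#'
#' @param x A `network_sample` or `grouped_sample` (the pooled sample is used),
#'   or anything [network_sample()] accepts.
#' @return An n-by-n matrix of class `mean_network`.
#' @export
mean_network <- function(x) {
  s <- as_network_sample(x)
  m <- unflatten_edges(colMeans(s$X), s$nodes)
  class(m) <- c("mean_network", class(m))
  m
}

#' @export
print.mean_network <- function(x, ...) {
  cat("<mean_network> on", nrow(x), "nodes\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Average distance of a sample around a network
#'
#' The mean edit distance between the members of a sample and a fixed network
#' `h`, which may be weighted (e.g. a [mean_network()]).
#'
#' @param x A `network_sample` (or coercible).
#' @param h A network to measure distances around.
#' @return A nonnegative scalar.
#' @export
average_distance <- function(x, h) {
  s <- as_network_sample(x)
  h <- coerce_matrix(h, "`h`")
  if (nrow(h) != length(s$nodes)) {
    stop("`h` is defined on ", nrow(h), " nodes; the sample has ",
         length(s$nodes), call. = FALSE)
  }
  lh <- rownames(h)
  if (!is.null(lh) && !identical(lh, s$nodes)) {
    if (setequal(lh, s$nodes)) h <- h[s$nodes, s$nodes]
    else stop("`h` is labeled with a different node set", call. = FALSE)
  }
  hv <- upper_vec(h)
  mean(abs(sweep(s$X, 2L, hv)) %*% rep(1, length(hv)))
}

#' Network variability of a sample
#'
#' The average edit distance of the sample members around the sample's mean
#' network. For binary samples this equals `2 * sum p(1 - p)` over the
#' entries p of the mean network, so the statistic simultaneously measures
#' spread and link-probability heterogeneity.
#'
#' @param x A `network_sample` (or coercible).
#' @return A nonnegative scalar.
#' @export
variability <- function(x) {
  s <- as_network_sample(x)
  average_distance(s, mean_network(s))
}
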