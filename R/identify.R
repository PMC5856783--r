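# Identification: locating the node subset (and approximately the link set)
# expressing the largest group differences, by minimizing the restricted T.
#
# Both the observed statistic S and the analytic calibration a^2 are sums of
# per-edge quantities, so the T statistic of any induced subnetwork is
#   T(V') = sum_{e within V'} s_e / sqrt(sum_{e within V'} v_e),
# with both vectors computed once. Exhaustive search over all subsets of a
# size then reduces to one matrix product against a cached node-membership
# matrix. Under the permutation calibration the per-edge statistics are
# retained for every permutation replicate, so the restricted a is the SD of
# the restricted permuted sums - i.e. a is recalibrated on each subset, which
# keeps the T_j sequence comparable across sizes.

.membership_cache <- new.env(parent = emptyenv())

combn_membership <- function(n, j) {
  key <- paste0(n, ":", j)
  hit <- .membership_cache[[key]]
  if (!is.null(hit)) return(hit)
  cmb <- combn(n, j)
  C <- ncol(cmb)
  M <- matrix(0, n, C)
  M[as.vector(cmb) + rep.int((seq_len(C) - 1L) * n, rep.int(j, C))] <- 1
  # cache only moderate sizes to bound memory
  if (n * C <= 4e6) .membership_cache[[key]] <- M
  M
}

# Build the per-edge decomposition used by all search routines.
edge_decomposition <- function(gx, spec) {
  s <- edge_statistic(gx$sample$X, gx$groups)
  n <- length(gx$sample$nodes)
  dec <- list(s = s, nodes = gx$sample$nodes, n = n, ep = edge_ends(n),
              method = spec$method)
  if (spec$method == "analytic") {
    if (!gx$sample$binary) {
      stop("the analytic calibration requires binary networks; ",
           "use calibration(\"permutation\")", call. = FALSE)
    }
    dec$v <- edge_var_asymptotic(colMeans(gx$sample$X), gx$sizes)
  } else {
    dec$Sperm <- permuted_edge_statistics(gx$sample$X, gx$groups,
                                          spec$permutations, spec$seed)
  }
  dec
}

# indices of edges with both endpoints inside `nodes_idx`
edges_within <- function(dec, nodes_idx) {
  which(dec$ep$i %in% nodes_idx & dec$ep$j %in% nodes_idx)
}

# T for one edge subset; +Inf when the restricted calibration is degenerate
restricted_T_edges <- function(dec, eidx) {
  if (length(eidx) == 0L) return(Inf)
  a2 <- if (dec$method == "analytic") {
    sum(dec$v[eidx])
  } else {
    var(rowSums(dec$Sperm[, eidx, drop = FALSE]))
  }
  if (!is.finite(a2) || a2 <= 0) return(Inf)
  sum(dec$s[eidx]) / sqrt(a2)
}

#' T statistic restricted to a subnetwork or link set
#'
#' Recomputes the network ANOVA statistic on induced subnetworks: in node mode
#' only the listed nodes and the links among them are kept; in link mode only
#' the listed links are kept. The calibration constant a is recalibrated on
#' the restricted data, so restricted values are comparable across subsets.
#'
#' @inheritParams network_anova
#' @param nodes Character vector of node labels (size at least 2), or `NULL`.
#' @param links Two-column matrix or data frame of node-label pairs, or `NULL`.
#'   Exactly one of `nodes` and `links` must be given.
#' @return The restricted T value.
#' @export
restricted_statistic <- function(x, groups = NULL, nodes = NULL, links = NULL,
                                 calibration = netanova::calibration()) {
  gx <- grouped_sample(x, groups)
  spec <- as_calibration(calibration)
  if (is.null(nodes) == is.null(links)) {
    stop("give exactly one of `nodes` or `links`", call. = FALSE)
  }
  dec <- edge_decomposition(gx, spec)
  if (!is.null(nodes)) {
    idx <- match(nodes, dec$nodes)
    if (anyNA(idx)) {
      stop("unknown node label(s): ",
           paste(nodes[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    if (length(idx) < 2L) stop("`nodes` must name at least 2 nodes", call. = FALSE)
    eidx <- edges_within(dec, idx)
  } else {
    eidx <- match_link_indices(dec, links)
  }
  val <- restricted_T_edges(dec, eidx)
  if (!is.finite(val)) {
    stop("calibration failed on the restricted data ",
         "(no retained link shows any variation)", call. = FALSE)
  }
  val
}

match_link_indices <- function(dec, links) {
  links <- as.matrix(links)
  if (ncol(links) != 2L || nrow(links) < 1L) {
    stop("`links` must be a two-column matrix of node pairs", call. = FALSE)
  }
  ia <- match(links[, 1L], dec$nodes)
  ib <- match(links[, 2L], dec$nodes)
  if (anyNA(ia) || anyNA(ib)) stop("`links` names unknown nodes", call. = FALSE)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  if (any(lo == hi)) stop("`links` contains self-loops", call. = FALSE)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) stop("`links` contains duplicate pairs", call. = FALSE)
  match(key, paste(dec$ep$i, dec$ep$j))
}

# --- search strategies ------------------------------------------------------

# exhaustive minimum over all subsets of size j (analytic or permutation)
exhaustive_min <- function(dec, j, chunk = 20000L) {
  n <- dec$n
  M <- combn_membership(n, j)
  total <- ncol(M)
  best <- Inf; best_col <- NA_integer_
  Smat <- unflatten_edges(dec$s, dec$nodes)
  Vmat <- if (dec$method == "analytic") unflatten_edges(dec$v, dec$nodes)
  for (lo in seq(1L, total, by = chunk)) {
    hi <- min(lo + chunk - 1L, total)
    Mc <- M[, lo:hi, drop = FALSE]
    Ssub <- colSums(Mc * (Smat %*% Mc)) / 2
    if (dec$method == "analytic") {
      Asub <- colSums(Mc * (Vmat %*% Mc)) / 2
    } else {
      Z <- Mc[dec$ep$i, , drop = FALSE] * Mc[dec$ep$j, , drop = FALSE]
      SS <- dec$Sperm %*% Z
      B <- nrow(SS)
      Asub <- (colSums(SS^2) - colSums(SS)^2 / B) / (B - 1)
    }
    Tv <- ifelse(Asub > 0, Ssub / sqrt(Asub), Inf)
    k <- which.min(Tv)   # first minimum = lexicographically smallest subset
    if (length(k) && Tv[k] < best) {
      best <- Tv[k]; best_col <- lo + k - 1L
    }
  }
  idx <- which(M[, best_col] > 0)
  list(nodes = idx, value = best)
}

# greedy forward growth from the best pair + single-node swap hill climbing
greedy_min <- function(dec, j) {
  n <- dec$n
  pair <- exhaustive_min(dec, 2L)
  cur <- pair$nodes
  while (length(cur) < j) {
    cand <- setdiff(seq_len(n), cur)
    vals <- vapply(cand, function(u) {
      restricted_T_edges(dec, edges_within(dec, c(cur, u)))
    }, numeric(1L))
    cur <- sort(c(cur, cand[which.min(vals)]))
  }
  cur_val <- restricted_T_edges(dec, edges_within(dec, cur))
  repeat {
    improved <- FALSE
    for (u in cur) {
      outs <- setdiff(seq_len(n), cur)
      vals <- vapply(outs, function(v) {
        restricted_T_edges(dec, edges_within(dec, c(setdiff(cur, u), v)))
      }, numeric(1L))
      k <- which.min(vals)
      if (length(k) && vals[k] < cur_val) {
        cur <- sort(c(setdiff(cur, u), outs[k]))
        cur_val <- vals[k]
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(nodes = cur, value = cur_val)
}

search_size <- function(dec, j, strategy, budget) {
  use_exhaustive <- switch(strategy,
    exhaustive = TRUE,
    greedy = FALSE,
    auto = choose(dec$n, j) <= budget
  )
  res <- if (use_exhaustive) exhaustive_min(dec, j) else greedy_min(dec, j)
  res$strategy <- if (use_exhaustive) "exhaustive" else "greedy"
  res
}

#' Best subnetwork of a given size
#'
#' Finds the node subset of size `j` minimizing the restricted T statistic.
#' All subsets are enumerated when their number is within `budget`
#' (lexicographic tie-breaking); otherwise a deterministic greedy forward
#' selection from the best pair, refined by single-node swap hill climbing,
#' is used.
#'
#' @inheritParams network_anova
#' @param j Subnetwork size (between 2 and the number of nodes).
#' @param strategy `"auto"`, `"exhaustive"` or `"greedy"`.
#' @param budget Maximum number of subset evaluations for exhaustive search.
#' @return A list with `nodes` (character labels), `value` (the minimal T_j)
#'   and `strategy`.
#' @export
best_subnetwork_of_size <- function(x, j, groups = NULL,
                                    strategy = c("auto", "exhaustive", "greedy"),
                                    budget = 2e5,
                                    calibration = netanova::calibration()) {
  gx <- grouped_sample(x, groups)
  strategy <- match.arg(strategy)
  n <- length(gx$sample$nodes)
  if (j < 2L || j > n) stop("`j` must be between 2 and ", n, call. = FALSE)
  dec <- edge_decomposition(gx, as_calibration(calibration))
  res <- search_size(dec, as.integer(j), strategy, budget)
  list(nodes = dec$nodes[res$nodes], value = res$value,
       strategy = res$strategy)
}

#' Per-size minima of the restricted statistic
#'
#' Computes the sequence T_2, T_3, ..., T_jmax of minimal restricted
#' statistics over subnetworks of each size, together with the minimizing node
#' sets, and applies the change-point selection rule of [select_size()]: the
#' selected size is the largest j whose step T_j - T_{j-1} drops below -g.
#'
#' @inheritParams best_subnetwork_of_size
#' @param j_max Largest subnetwork size to examine (default: all nodes).
#' @param g Positive stopping threshold of the selection rule.
#' @return An object of class `subnetwork_path`: a tibble `path` with columns
#'   `j`, `statistic`, `nodes` (list column) and `strategy`, the selected size
#'   `j_selected` (`NA` if no size qualifies), `nodes_selected`, and `g`.
#' @examples
#' lay <- default_layout("scalp16")
#' mod <- geometric_model(lay, lambda_planted = c(1, 0.5, 0.3))
#' gx <- geometric_grouped_sample(mod, K = 60, seed = 3)
#' sp <- subnetwork_path(gx, j_max = 10)
#' sp$j_selected
#' @export
subnetwork_path <- function(x, groups = NULL, j_max = NULL, g = 0.25,
                            strategy = c("auto", "exhaustive", "greedy"),
                            budget = 2e5,
                            calibration = netanova::calibration()) {
  gx <- grouped_sample(x, groups)
  strategy <- match.arg(strategy)
  n <- length(gx$sample$nodes)
  if (is.null(j_max)) j_max <- n
  if (j_max < 3L || j_max > n) stop("`j_max` must be in 3..", n, call. = FALSE)
  dec <- edge_decomposition(gx, as_calibration(calibration))
  sizes <- 2:j_max
  res <- lapply(sizes, function(j) search_size(dec, j, strategy, budget))
  path <- tibble::tibble(
    j = sizes,
    statistic = vapply(res, `[[`, numeric(1L), "value"),
    nodes = lapply(res, function(r) dec$nodes[r$nodes]),
    strategy = vapply(res, `[[`, character(1L), "strategy")
  )
  out <- structure(list(path = path, g = g, n_nodes = n,
                        j_selected = NA_integer_, nodes_selected = NULL),
                   class = "subnetwork_path")
  js <- select_size(out, g = g)
  out$j_selected <- js
  if (!is.na(js)) out$nodes_selected <- path$nodes[[match(js, path$j)]]
  out
}

#' Change-point selection of the subnetwork size
#'
#' Applies the stopping rule: the selected size is the largest j (at least 3)
#' such that T_j - T_{j-1} < -g. When no size qualifies the result is `NA`,
#' read as "no identifiable subnetwork". `g` is a user choice that should
#' shrink with sample size; 0.25 is the default used throughout.
#'
#' @param path A `subnetwork_path` object (or its `path` tibble with columns
#'   `j` and `statistic`, for consecutive sizes starting at 2).
#' @param g Positive threshold.
#' @return The selected size as an integer, or `NA_integer_`.
#' @examples
#' p <- tibble::tibble(j = 2:6, statistic = c(0, -0.5, -0.9, -1.2, -1.3))
#' select_size(p, g = 0.25) # 5
#' @export
select_size <- function(path, g = 0.25) {
  tb <- if (inherits(path, "subnetwork_path")) path$path else path
  stopifnot(is.numeric(g), length(g) == 1L, g > 0)
  jj <- tb$j
  if (jj[1L] != 2L || !identical(as.integer(jj), seq(2L, max(jj)))) {
    stop("`path` must contain consecutive sizes starting at 2", call. = FALSE)
  }
  drops <- diff(tb$statistic)            # T_j - T_{j-1} for j = 3..j_max
  qual <- jj[-1L][drops < -g]
  if (length(qual) == 0L) NA_integer_ else as.integer(max(qual))
}

#' @export
print.subnetwork_path <- function(x, ...) {
  cat(sprintf("<subnetwork_path> sizes 2..%d on %d nodes (g = %g)\n",
              max(x$path$j), x$n_nodes, x$g))
  if (is.na(x$j_selected)) {
    cat("  no identifiable subnetwork (no step below -g)\n")
  } else {
    cat(sprintf("  selected size %d: {%s}, T = %.3f\n", x$j_selected,
                paste(x$nodes_selected, collapse = ", "),
                x$path$statistic[match(x$j_selected, x$path$j)]))
  }
  invisible(x)
}

#' Approximate minimizing link set
#'
#' Greedy forward/backward search for the set of links minimizing the
#' restricted statistic (link mode). The space of link subsets is far too
#' large for enumeration, which is why subnetwork (node) search is the
#' recommended identification route; this procedure is documented as
#' approximate.
#'
#' @inheritParams best_subnetwork_of_size
#' @param budget Maximum number of candidate evaluations.
#' @return An object of class `link_set`: a tibble `links` (columns `node_a`,
#'   `node_b`), the objective `statistic`, the number of `evaluations`, and
#'   `no_signal` flagging a best value above the one-sided 5% critical value
#'   (no convincing link-level signal).
#' @export
best_link_set <- function(x, groups = NULL, budget = 2e5,
                          calibration = netanova::calibration()) {
  gx <- grouped_sample(x, groups)
  dec <- edge_decomposition(gx, as_calibration(calibration))
  E <- length(dec$s)
  evals <- 0L
  single_T <- vapply(seq_len(E), function(e) restricted_T_edges(dec, e),
                     numeric(1L))
  evals <- evals + E
  cur <- which.min(single_T)
  cur_val <- single_T[cur]
  repeat {
    improved <- FALSE
    # forward
    cand <- setdiff(which(is.finite(single_T)), cur)
    if (length(cand) && evals < budget) {
      vals <- vapply(cand, function(e) restricted_T_edges(dec, c(cur, e)),
                     numeric(1L))
      evals <- evals + length(cand)
      k <- which.min(vals)
      if (vals[k] < cur_val) {
        cur <- sort(c(cur, cand[k])); cur_val <- vals[k]; improved <- TRUE
      }
    }
    # backward
    if (length(cur) > 1L && evals < budget) {
      vals <- vapply(cur, function(e) restricted_T_edges(dec, setdiff(cur, e)),
                     numeric(1L))
      evals <- evals + length(cur)
      k <- which.min(vals)
      if (vals[k] < cur_val) {
        cur <- setdiff(cur, cur[k]); cur_val <- vals[k]; improved <- TRUE
      }
    }
    if (!improved || evals >= budget) break
  }
  structure(list(
    links = tibble::tibble(node_a = dec$nodes[dec$ep$i[cur]],
                           node_b = dec$nodes[dec$ep$j[cur]]),
    statistic = cur_val,
    evaluations = evals,
    no_signal = cur_val > qnorm(0.05)
  ), class = "link_set")
}

#' @export
print.link_set <- function(x, ...) {
  cat(sprintf("<link_set> %d links, T = %.3f%s\n", nrow(x$links), x$statistic,
              if (x$no_signal) " (no significant link-level signal)" else ""))
  print(x$links, ...)
  invisible(x)
}
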