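# From per-subject correlation matrices to binary networks, the W3
# threshold-robustness statistic with its resampling null, and the Psi
# difference network.

#' Bundle per-subject correlation matrices
#'
#' @param x List of symmetric correlation matrices (unit diagonal, entries in
#'   \[-1, 1\]) on a common node set, or a 3-D array.
#' @param nodes Optional node labels.
#' @param ids Optional subject identifiers.
#' @return An object of class `correlation_sample`.
#' @export
correlation_sample <- function(x, nodes = NULL, ids = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- lapply(seq_len(dim(x)[3L]), function(k) x[, , k])
  }
  if (!is.list(x) || length(x) < 1L) {
    stop("`x` must be a non-empty list of correlation matrices", call. = FALSE)
  }
  n <- nrow(x[[1L]])
  if (is.null(nodes)) nodes <- node_labels_of(x[[1L]], n)
  for (k in seq_along(x)) {
    s <- x[[k]]
    if (!is.matrix(s) || nrow(s) != n || ncol(s) != n) {
      stop("correlation matrix ", k, " is not ", n, "x", n, call. = FALSE)
    }
    if (anyNA(s)) stop("correlation matrix ", k, " contains NA", call. = FALSE)
    if (max(abs(s - t(s))) > 1e-8) {
      stop("correlation matrix ", k, " is not symmetric", call. = FALSE)
    }
    if (any(abs(s) > 1 + 1e-8)) {
      stop("correlation matrix ", k, " has entries outside [-1, 1]", call. = FALSE)
    }
    if (any(abs(diag(s) - 1) > 1e-8)) {
      stop("correlation matrix ", k, " must have a unit diagonal", call. = FALSE)
    }
  }
  if (is.null(ids)) ids <- paste0("s", seq_along(x))
  structure(list(nodes = as.character(nodes), ids = as.character(ids),
                 matrices = lapply(x, unname)),
            class = "correlation_sample")
}

#' @export
print.correlation_sample <- function(x, ...) {
  cat(sprintf("<correlation_sample> %d subjects, %d nodes\n",
              length(x$matrices), length(x$nodes)))
  invisible(x)
}

#' @export
length.correlation_sample <- function(x) length(x$matrices)

#' Correlation matrices from per-subject time series
#'
#' Convenience Pearson wrapper: each element of `x` is a time-by-node matrix;
#' its column correlation matrix becomes one subject of a
#' [correlation_sample()].
#'
#' @param x List of numeric matrices (rows = time points, columns = nodes).
#' @param ids Optional subject identifiers.
#' @return A `correlation_sample`.
#' @export
correlation_from_timeseries <- function(x, ids = NULL) {
  mats <- lapply(x, stats::cor)
  correlation_sample(mats, nodes = colnames(x[[1L]]), ids = ids)
}

#' Threshold a correlation matrix at a fixed correlation value
#'
#' Positive thresholds keep links with correlation at or above `rho`; negative
#' thresholds keep links with correlation at or below `rho`. The diagonal is
#' ignored. `rho = 0` is rejected as the branch would be ambiguous.
#'
#' @param sigma A correlation matrix.
#' @param rho Nonzero threshold in (-1, 1).
#' @return A binary adjacency matrix.
#' @export
threshold_fixed_rho <- function(sigma, rho) {
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma))
  if (!is.numeric(rho) || length(rho) != 1L || rho == 0) {
    stop("`rho` must be a single nonzero value (the sign selects the branch)",
         call. = FALSE)
  }
  a <- if (rho > 0) (sigma >= rho) else (sigma <= rho)
  a <- a * 1
  diag(a) <- 0
  dimnames(a) <- dimnames(sigma)
  a
}

#' Threshold a correlation matrix to a fixed number of links
#'
#' Keeps exactly `L` links: the `L` largest correlations on the positive
#' branch, or the `L` most negative on the negative branch. Ties are broken
#' by absolute value (larger first) and then by lexicographic pair order, so
#' the result is deterministic and has exactly `L` links regardless of ties.
#'
#' @param sigma A correlation matrix.
#' @param L Number of links (1 to n(n-1)/2).
#' @param branch `"positive"` or `"negative"`.
#' @return A binary adjacency matrix with exactly `L` links.
#' @export
threshold_fixed_links <- function(sigma, L, branch = c("positive", "negative")) {
  branch <- match.arg(branch)
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma))
  n <- nrow(sigma)
  E <- n * (n - 1L) / 2L
  if (!is.numeric(L) || length(L) != 1L || L < 1L || L > E) {
    stop("`L` must be between 1 and ", E, call. = FALSE)
  }
  v <- upper_vec(sigma)
  ep <- edge_ends(n)
  ord <- if (branch == "positive") {
    order(-v, -abs(v), ep$i, ep$j)
  } else {
    order(v, -abs(v), ep$i, ep$j)
  }
  keep <- ord[seq_len(L)]
  av <- numeric(E)
  av[keep] <- 1
  a <- matrix(0, n, n, dimnames = dimnames(sigma))
  a[upper.tri(a)] <- av
  a + t(a)
}

#' Grids of thresholds for the robustness analysis
#'
#' The four branches scanned by [t_over_grid()]: positive and negative
#' correlation thresholds, and positive- and negative-branch link counts.
#' Defaults use 10 points per branch, correlation thresholds spanning 0.05 to
#' 0.5 (mirrored for the negative branch); when `L_plus` / `L_minus` are
#' `NULL` they are resolved at use to 10 link counts spanning 5% to 50% of all
#' node pairs.
#'
#' @param rho_plus Increasing grid of positive correlation thresholds.
#' @param rho_minus Decreasing grid of negative correlation thresholds.
#' @param L_plus,L_minus Increasing grids of link counts, or `NULL`.
#' @return An object of class `threshold_grid`.
#' @export
threshold_grid <- function(rho_plus = seq(0.05, 0.5, length.out = 10),
                           rho_minus = -rho_plus,
                           L_plus = NULL, L_minus = NULL) {
  stopifnot(all(rho_plus > 0), !is.unsorted(rho_plus),
            all(rho_minus < 0), !is.unsorted(rev(rho_minus)))
  if (!is.null(L_plus)) stopifnot(all(L_plus >= 1), !is.unsorted(L_plus))
  if (!is.null(L_minus)) stopifnot(all(L_minus >= 1), !is.unsorted(L_minus))
  structure(list(rho_plus = rho_plus, rho_minus = rho_minus,
                 L_plus = L_plus, L_minus = L_minus),
            class = "threshold_grid")
}

resolve_grid <- function(grid, n) {
  E <- n * (n - 1L) / 2L
  default_L <- unique(pmax(1L, round(seq(0.05, 0.5, length.out = 10) * E)))
  if (is.null(grid$L_plus)) grid$L_plus <- default_L
  if (is.null(grid$L_minus)) grid$L_minus <- default_L
  grid
}

# binary subject-by-edge matrices for every grid point (networks do not depend
# on the grouping, so resampling reuses them)
grid_networks <- function(corrs, grid) {
  n <- length(corrs$nodes)
  grid <- resolve_grid(grid, n)
  flat <- function(net) upper_vec(net)
  build <- function(criterion, branch, values) {
    lapply(values, function(val) {
      X <- t(vapply(corrs$matrices, function(s) {
        flat(switch(criterion,
          rho = threshold_fixed_rho(s, val),
          links = threshold_fixed_links(s, val, branch)
        ))
      }, numeric(n * (n - 1L) / 2L)))
      list(criterion = criterion, branch = branch, value = val, X = X)
    })
  }
  c(build("rho", "positive", grid$rho_plus),
    build("rho", "negative", grid$rho_minus),
    build("links", "positive", grid$L_plus),
    build("links", "negative", grid$L_minus))
}

grid_t_values <- function(points, nodes, grp, spec) {
  vapply(points, function(pt) {
    gx <- grouped_sample(new_sample_from_edges(pt$X, nodes), grp)
    tryCatch(network_anova(gx, calibration = spec)$statistic,
             error = function(e) NA_real_)
  }, numeric(1L))
}

#' T statistic across thresholding grids
#'
#' Builds, for every grid point of all four branches, the per-subject binary
#' networks and runs [network_anova()], tracing how the group comparison
#' behaves as the thresholding criterion varies. Grid points whose networks
#' are degenerate (calibration impossible) yield `NA`.
#'
#' @param corrs A [correlation_sample()].
#' @param groups Group labels, one per subject.
#' @param grid A [threshold_grid()].
#' @param calibration A [calibration()] specification.
#' @return A tibble of class `grid_t` with columns `criterion` ("rho" or
#'   "links"), `branch`, `value` and `statistic`.
#' @export
t_over_grid <- function(corrs, groups, grid = threshold_grid(),
                        calibration = netanova::calibration()) {
  stopifnot(inherits(corrs, "correlation_sample"))
  spec <- as_calibration(calibration)
  pts <- grid_networks(corrs, grid)
  tv <- grid_t_values(pts, corrs$nodes, groups, spec)
  out <- tibble::tibble(
    criterion = vapply(pts, `[[`, character(1L), "criterion"),
    branch = vapply(pts, `[[`, character(1L), "branch"),
    value = vapply(pts, `[[`, numeric(1L), "value"),
    statistic = tv
  )
  class(out) <- c("grid_t", class(out))
  out
}

#' W3 threshold-robustness statistic
#'
#' Counts, in each of the four thresholding branches, the grid points whose T
#' statistic falls below the cutoff (default -3, where a standard normal
#' leaves probability 0.00135), and takes the minimum count across branches.
#' A large W3 means the group difference is detected robustly no matter how
#' the networks are built from the correlation matrices.
#'
#' @param tvalues A `grid_t` tibble from [t_over_grid()].
#' @param cutoff Cutoff on T (default -3).
#' @return An object of class `w3_result` with per-branch counts `deltas` and
#'   the minimum `w3`.
#' @export
w3_statistic <- function(tvalues, cutoff = -3) {
  stopifnot(all(c("criterion", "branch", "statistic") %in% names(tvalues)))
  key <- interaction(tvalues$criterion, tvalues$branch, drop = FALSE)
  deltas <- vapply(split(tvalues$statistic, key), function(tv) {
    sum(tv < cutoff, na.rm = TRUE)
  }, numeric(1L))
  wanted <- c("rho.positive", "rho.negative", "links.positive", "links.negative")
  deltas <- deltas[wanted]
  names(deltas) <- c("rho_plus", "rho_minus", "links_plus", "links_minus")
  structure(list(deltas = deltas, w3 = min(deltas), cutoff = cutoff),
            class = "w3_result")
}

#' @export
print.w3_result <- function(x, ...) {
  cat(sprintf("W3 = %d  (deltas: %s; cutoff T < %g)\n", x$w3,
              paste(names(x$deltas), "=", x$deltas, collapse = ", "),
              x$cutoff))
  invisible(x)
}

#' Resampling null distribution of W3
#'
#' Re-partitions the subjects into groups of the observed sizes (label
#' permutation without replacement by default; optionally a with-replacement
#' bootstrap of subjects) and recomputes W3 for each replicate, yielding an
#' empirical null distribution and a p-value for the observed statistic.
#' The thresholded networks are built once and reused, since they do not
#' depend on the grouping.
#'
#' @inheritParams t_over_grid
#' @param B Number of resamples.
#' @param seed Optional integer seed.
#' @param replace Resample subjects with replacement instead of permuting
#'   labels.
#' @param cutoff Cutoff passed to [w3_statistic()].
#' @return An object of class `w3_null`: the observed `w3_result`, the vector
#'   `null` of resampled W3 values, and the empirical `p_value` (fraction of
#'   resamples at or above the observed W3).
#' @export
bootstrap_w3_null <- function(corrs, groups, grid = threshold_grid(),
                              B = 1000L, seed = NULL, replace = FALSE,
                              cutoff = -3,
                              calibration = netanova::calibration()) {
  stopifnot(inherits(corrs, "correlation_sample"), B >= 1L)
  spec <- as_calibration(calibration)
  grp <- factor(groups, levels = unique(as.character(groups)))
  pts <- grid_networks(corrs, grid)
  as_grid_tbl <- function(tv) {
    tibble::tibble(
      criterion = vapply(pts, `[[`, character(1L), "criterion"),
      branch = vapply(pts, `[[`, character(1L), "branch"),
      statistic = tv
    )
  }
  observed <- w3_statistic(
    as_grid_tbl(grid_t_values(pts, corrs$nodes, grp, spec)), cutoff)
  run <- function() {
    vapply(seq_len(B), function(b) {
      if (replace) {
        idx <- sample(length(grp), replace = TRUE)
        pts_b <- lapply(pts, function(pt) {
          pt$X <- pt$X[idx, , drop = FALSE]; pt
        })
        w3_statistic(as_grid_tbl(grid_t_values(pts_b, corrs$nodes, grp, spec)),
                     cutoff)$w3
      } else {
        w3_statistic(as_grid_tbl(grid_t_values(pts, corrs$nodes, sample(grp),
                                               spec)),
                     cutoff)$w3
      }
    }, numeric(1L))
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(
    observed = observed,
    null = null,
    p_value = mean(null >= observed$w3),
    B = B, replace = replace, seed = seed
  ), class = "w3_null")
}

#' @export
print.w3_null <- function(x, ...) {
  cat(sprintf("W3 resampling null (B = %d, %s): observed W3 = %d, p = %.4g\n",
              x$B, if (x$replace) "bootstrap" else "label permutation",
              x$observed$w3, x$p_value))
  invisible(x)
}

#' Difference network across group means
#'
#' The weighted network of mean absolute deviations of the group mean networks
#' from their across-group average: Psi(i, j) = mean over groups of
#' |M_group(i, j) - M_bar(i, j)|. Entries are zero exactly where all group
#' means agree, so Psi highlights where the means differ.
#'
#' @param means List of group mean networks ([mean_network()] objects or plain
#'   matrices on the same node set).
#' @return A weighted adjacency matrix (class `mean_network`).
#' @export
psi_network <- function(means) {
  stopifnot(is.list(means), length(means) >= 2L)
  mats <- lapply(means, function(m) unclass(m))
  n <- nrow(mats[[1L]])
  if (!all(vapply(mats, function(m) nrow(m) == n && ncol(m) == n, logical(1L)))) {
    stop("all mean networks must share the node set", call. = FALSE)
  }
  mbar <- Reduce(`+`, mats) / length(mats)
  psi <- Reduce(`+`, lapply(mats, function(m) abs(m - mbar))) / length(mats)
  diag(psi) <- 0
  class(psi) <- c("mean_network", class(psi))
  psi
}

#' Split subjects into Low / Medium / High tertile groups
#'
#' Orders a per-subject covariate and cuts at the 33.3% and 66.7% percentiles
#' (left-continuous sample quantiles), assigning boundary ties to the lower
#' group. Group sizes are close to a third of the sample except under heavy
#' ties.
#'
#' @param values Numeric covariate, one value per subject.
#' @return A factor with levels `Low`, `Medium`, `High`.
#' @examples
#' table(group_by_tertiles(1:9))
#' @export
group_by_tertiles <- function(values) {
  stopifnot(is.numeric(values))
  if (anyNA(values)) stop("`values` contains NA", call. = FALSE)
  q <- quantile(values, c(1 / 3, 2 / 3), type = 1L, names = FALSE)
  lab <- ifelse(values <= q[1L], "Low",
                ifelse(values <= q[2L], "Medium", "High"))
  f <- factor(lab, levels = c("Low", "Medium", "High"))
  if (sum(table(f) > 0L) < 2L) {
    stop("covariate is too heavily tied (or constant): no tertile grouping exists",
         call. = FALSE)
  }
  f
}
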