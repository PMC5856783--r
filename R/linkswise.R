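# The comparator "links test": per-link m-sample proportion comparisons with
# Benjamini-Hochberg control and a global decision.

#' Per-link p-values for equal link proportions
#'
#' For every unordered node pair, tests homogeneity of the link-presence
#' proportion across the m groups with a chi-square test on the m-by-2 table
#' of (present, absent) counts, without continuity correction. Pairs whose
#' link is present in every network or absent from every network carry no
#' information about group differences and receive p = 1 by convention
#' (flagged in the `degenerate` column).
#'
#' @inheritParams network_anova
#' @return A tibble with columns `node_a`, `node_b`, one proportion column per
#'   group (`prop_<group>`), `p_value` and `degenerate`.
#' @export
per_link_pvalues <- function(x, groups = NULL) {
  gx <- grouped_sample(x, groups)
  if (!gx$sample$binary) {
    stop("the links test requires binary networks", call. = FALSE)
  }
  X <- gx$sample$X
  sizes <- gx$sizes
  m <- length(sizes)
  grp <- as.integer(gx$groups)
  counts <- matrix(vapply(seq_len(m),
                          function(i) colSums(X[grp == i, , drop = FALSE]),
                          numeric(ncol(X))),
                   ncol = m)                              # E x m
  phat <- colSums(X)                                      # pooled presence count
  p_pool <- phat / sum(sizes)
  degenerate <- p_pool <= 0 | p_pool >= 1
  # chi-square homogeneity: sum_i (k_i - n_i p)^2 / (n_i p (1 - p)), df = m - 1
  expct <- outer(p_pool, sizes)
  denom <- p_pool * (1 - p_pool)
  stat <- rowSums((counts - expct)^2 / outer(denom, sizes))
  pv <- pchisq(stat, df = m - 1L, lower.tail = FALSE)
  pv[degenerate] <- 1
  ep <- edge_ends(length(gx$sample$nodes))
  out <- tibble::tibble(
    node_a = gx$sample$nodes[ep$i],
    node_b = gx$sample$nodes[ep$j]
  )
  props <- counts / rep(sizes, each = nrow(counts))
  colnames(props) <- paste0("prop_", levels(gx$groups))
  out <- dplyr::bind_cols(out, tibble::as_tibble(props))
  out$p_value <- pv
  out$degenerate <- degenerate
  out
}

#' Benjamini-Hochberg selection
#'
#' Declares significant all hypotheses with p-value at or below the largest
#' order statistic p_(j) satisfying p_(j) <= j / m * alpha (boundary cases
#' count as significant). Implemented via [stats::p.adjust()]; the tests
#' cross-check the printed step-up rule directly.
#'
#' @param pvalues Numeric vector of p-values.
#' @param alpha Control level.
#' @return A logical vector marking the significant entries.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.04), alpha = 0.05) # all TRUE
#' @export
benjamini_hochberg <- function(pvalues, alpha = 0.05) {
  stopifnot(is.numeric(pvalues), all(pvalues >= 0 & pvalues <= 1))
  if (length(pvalues) == 0L) return(logical(0L))
  p.adjust(pvalues, method = "BH") <= alpha
}

#' Link-wise comparison of network groups (the links test)
#'
#' The comparator procedure: per-link proportion tests with
#' Benjamini-Hochberg control at level `alpha`, declaring the groups
#' different when at least one link is significant. Only node pairs with
#' non-degenerate tables enter the multiplicity; degenerate links are never
#' significant.
#'
#' @inheritParams network_anova
#' @param alpha Control level of the BH procedure.
#' @return An object of class `link_test`: the per-link tibble `table` (with a
#'   `significant` column), `alpha`, the number of informative links
#'   `n_tests`, and `global_reject`.
#' @export
links_test <- function(x, groups = NULL, alpha = 0.05) {
  tb <- per_link_pvalues(x, groups)
  keep <- !tb$degenerate
  tb$significant <- FALSE
  tb$significant[keep] <- benjamini_hochberg(tb$p_value[keep], alpha)
  structure(list(
    table = tb,
    alpha = alpha,
    n_tests = sum(keep),
    global_reject = any(tb$significant)
  ), class = "link_test")
}

#' @export
print.link_test <- function(x, ...) {
  cat(sprintf("Links test: %d informative links, BH at alpha = %g\n",
              x$n_tests, x$alpha))
  cat(sprintf("  %d significant link(s); groups declared %s\n",
              sum(x$table$significant),
              if (x$global_reject) "DIFFERENT" else "not different"))
  invisible(x)
}
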