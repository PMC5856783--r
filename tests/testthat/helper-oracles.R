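# Independent oracles and small fixture builders. Everything here is a direct
# transcription of the defining formulas, deliberately naive, and shares no
# code with the package internals it checks.

# random binary symmetric hollow adjacency matrix
random_adjacency <- function(n, p = 0.5) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

random_sample_mats <- function(l, n, p = 0.5) {
  replicate(l, random_adjacency(n, p), simplify = FALSE)
}

# naive edit distance: loop over unordered pairs
oracle_edit_distance <- function(a, b) {
  n <- nrow(a)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + abs(a[i, j] - b[i, j])
  }
  s
}

# naive transcription of the unnormalized statistic from its definition
oracle_S <- function(mats, grp) {
  grp <- factor(grp, levels = unique(as.character(grp)))
  m <- nlevels(grp)
  n <- length(mats)
  sizes <- as.integer(table(grp))
  mean_mat <- function(ms) Reduce(`+`, ms) / length(ms)
  dbar <- function(ms, h) mean(vapply(ms, oracle_edit_distance, 0, b = h))
  S <- 0
  for (i in seq_len(m)) {
    ms_i <- mats[as.integer(grp) == i]
    Mi <- mean_mat(ms_i)
    S <- S + sqrt(sizes[i]) *
      (sizes[i] / (sizes[i] - 1) * dbar(ms_i, Mi) -
         n / (n - 1) * dbar(mats, Mi))
  }
  sqrt(m) * S
}

# the three printed steps of the BH procedure
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) / m * alpha)
  if (length(ok) == 0) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

# induced subnetwork of an adjacency matrix
induce_nodes <- function(a, keep) a[keep, keep, drop = FALSE]

# grouped sample built from a list of matrices
make_grouped <- function(mats, grp) grouped_sample(network_sample(mats), grp)

# small planted two-group model on n nodes: groups differ on links among
# `planted` nodes only
planted_sample <- function(n, planted, K, p_base = 0.3, p_alt = 0.8,
                          seed = NULL) {
  build <- function() {
    mk <- function(p_in) {
      a <- random_adjacency(n, p_base)
      idx <- utils::combn(planted, 2)
      for (k in seq_len(ncol(idx))) {
        v <- rbinom(1, 1, p_in)
        a[idx[1, k], idx[2, k]] <- v
        a[idx[2, k], idx[1, k]] <- v
      }
      a
    }
    mats <- c(replicate(K, mk(p_base), simplify = FALSE),
              replicate(K, mk(p_alt), simplify = FALSE))
    make_grouped(mats, rep(c("g1", "g2"), each = K))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
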