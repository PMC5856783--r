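# Correlation thresholding, the W3 robustness statistic, Psi, and tertiles.

sigma3 <- matrix(c(1, 0.9, 0.4,
                   0.9, 1, -0.8,
                   0.4, -0.8, 1), 3, 3,
                 dimnames = list(letters[1:3], letters[1:3]))

# correlated time series generator: subjects share block structure whose
# strength scales with `effect`
make_corr_sample <- function(n_sub, n_nodes, effect = 0, t_len = 80,
                             seed = NULL) {
  build <- function() {
    lapply(seq_len(n_sub), function(s) {
      z <- matrix(rnorm(t_len * n_nodes), t_len, n_nodes)
      if (effect > 0) {
        common <- rnorm(t_len)
        half <- seq_len(ceiling(n_nodes / 2))
        z[, half] <- z[, half] + effect * common
      }
      stats::cor(z)
    })
  }
  mats <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  correlation_sample(mats)
}

test_that("fixed-rho thresholding keeps the correct branch", {
  expect_equal(sum(threshold_fixed_rho(sigma3, 0.5)) / 2, 1)
  expect_identical(threshold_fixed_rho(sigma3, 0.5)["a", "b"], 1)
  neg <- threshold_fixed_rho(sigma3, -0.5)
  expect_identical(neg["b", "c"], 1)
  expect_equal(sum(neg) / 2, 1)
  expect_equal(sum(threshold_fixed_rho(sigma3, 0.95)), 0)
  expect_error(threshold_fixed_rho(sigma3, 0), "nonzero")
})

test_that("fixed-links thresholding returns exactly L links with deterministic ties", {
  one <- threshold_fixed_links(sigma3, 1, "positive")
  expect_identical(one["a", "b"], 1)
  expect_equal(sum(one) / 2, 1)
  expect_identical(threshold_fixed_links(sigma3, 1, "negative")["b", "c"], 1)
  expect_equal(sum(threshold_fixed_links(sigma3, 3, "positive")) / 2, 3)
  expect_error(threshold_fixed_links(sigma3, 4, "positive"), "between 1 and 3")
  # heavy ties: all off-diagonal correlations equal
  tied <- matrix(0.5, 4, 4); diag(tied) <- 1
  for (L in 1:6) {
    expect_equal(sum(threshold_fixed_links(tied, L, "positive")) / 2, L)
  }
  # deterministic under ties: repeated calls agree
  expect_identical(threshold_fixed_links(tied, 3, "positive"),
                   threshold_fixed_links(tied, 3, "positive"))
})

test_that("thresholded networks are nested along each branch", {
  cs <- make_corr_sample(4, 8, effect = 0.5, seed = 281)
  for (s in cs$matrices) {
    rhos <- c(0.1, 0.2, 0.35, 0.5)
    nets <- lapply(rhos, function(r) threshold_fixed_rho(s, r))
    for (k in 2:4) expect_true(all(nets[[k]] <= nets[[k - 1]]))
    Ls <- c(2, 5, 9, 14)
    netsL <- lapply(Ls, function(L) threshold_fixed_links(s, L, "positive"))
    for (k in 2:4) expect_true(all(netsL[[k - 1]] <= netsL[[k]]))
  }
})

test_that("W3 is the minimum of the four branch counts", {
  tv <- tibble::tibble(
    criterion = rep(c("rho", "rho", "links", "links"), each = 10),
    branch = rep(c("positive", "negative", "positive", "negative"), each = 10),
    value = rep(1:10, 4),
    statistic = c(rep(-4, 10), rep(-4, 10),
                  c(rep(-4, 9), 0), c(rep(-4, 9), 0))
  )
  w <- w3_statistic(tv)
  expect_identical(unname(w$deltas), c(10, 10, 9, 9))
  expect_identical(w$w3, 9)
  # all T in (-2, 2) -> W3 = 0
  tv$statistic <- runif(40, -1.9, 1.9)
  expect_identical(w3_statistic(tv)$w3, 0)
  # one branch null, others extreme -> the minimum dominates
  tv$statistic <- ifelse(tv$criterion == "rho" & tv$branch == "positive",
                         0, -10)
  expect_identical(w3_statistic(tv)$w3, 0)
})

test_that("t_over_grid scans all four branches and flags degenerate points", {
  cs <- make_corr_sample(36, 8, effect = 0.8, seed = 291)
  grp <- rep(c("L", "M", "H"), each = 12)
  tg <- t_over_grid(cs, grp)
  expect_identical(nrow(tg), 40L)
  expect_setequal(unique(tg$criterion), c("rho", "links"))
  expect_setequal(unique(tg$branch), c("positive", "negative"))
  expect_true(any(is.finite(tg$statistic)))
  expect_s3_class(autoplot(tg), "ggplot")
})

test_that("the W3 resampling null has mode zero and is seed-reproducible", {
  cs <- make_corr_sample(30, 8, effect = 0.6, seed = 301)
  grp <- withr::with_seed(302, sample(rep(c("L", "M", "H"), each = 10)))
  bw <- bootstrap_w3_null(cs, grp, B = 40, seed = 303)
  expect_identical(length(bw$null), 40L)
  tab <- table(bw$null)
  expect_identical(names(tab)[which.max(tab)], "0")
  bw2 <- bootstrap_w3_null(cs, grp, B = 40, seed = 303)
  expect_identical(bw$null, bw2$null)
  expect_identical(bw$observed$w3, bw2$observed$w3)
  # with-replacement variant runs and differs in general
  bw3 <- bootstrap_w3_null(cs, grp, B = 10, seed = 304, replace = TRUE)
  expect_identical(length(bw3$null), 10L)
  # degenerate single-replicate null
  expect_identical(length(bootstrap_w3_null(cs, grp, B = 1, seed = 1)$null), 1L)
})

test_that("a real grouping effect yields a larger W3 than its permutation null", {
  # subjects' block structure strengthens with the covariate; the two blocks
  # load with opposite signs so both positive and negative correlations carry
  # the effect (all four W3 branches can detect it)
  mats <- withr::with_seed(311, lapply(1:36, function(s) {
    effect <- c(0.1, 0.8, 1.6)[ceiling(s / 12)]
    z <- matrix(rnorm(60 * 8), 60, 8)
    common <- rnorm(60)
    z[, 1:4] <- z[, 1:4] + effect * common
    z[, 5:8] <- z[, 5:8] - effect * common
    stats::cor(z)
  }))
  cs <- correlation_sample(mats)
  grp <- rep(c("L", "M", "H"), each = 12)
  bw <- bootstrap_w3_null(cs, grp, B = 60, seed = 312)
  expect_gt(bw$observed$w3, 0)
  expect_lt(bw$p_value, 0.2)
})

test_that("psi highlights where group means differ", {
  m1 <- matrix(0, 3, 3); m1[1, 2] <- m1[2, 1] <- 0.2
  m2 <- matrix(0, 3, 3); m2[1, 2] <- m2[2, 1] <- 0.8
  psi <- psi_network(list(m1, m2))
  expect_equal(psi[1, 2], 0.3)
  expect_equal(sum(psi != 0), 2)
  expect_equal(unclass(psi_network(list(m2, m1))), unclass(psi))  # group order
  expect_true(all(unclass(psi_network(list(m1, m1))) == 0))
})

test_that("tertile grouping cuts at the 33% percentiles with ties downward", {
  f <- group_by_tertiles(1:9)
  expect_identical(as.character(f), rep(c("Low", "Medium", "High"), each = 3))
  # heavy ties at the cut collapse deterministically into the lower group
  v <- c(1, 1, 1, 1, 2, 3)
  f2 <- group_by_tertiles(v)
  expect_identical(as.character(f2)[1:4], rep("Low", 4))
  expect_identical(group_by_tertiles(v), group_by_tertiles(v))
  expect_error(group_by_tertiles(rep(7, 10)), "tied")
})

test_that("correlation samples validate their invariants", {
  bad <- sigma3; bad[1, 2] <- bad[2, 1] <- 2
  expect_error(correlation_sample(list(bad)), "outside")
  bad2 <- sigma3; bad2[1, 1] <- 0.5
  expect_error(correlation_sample(list(bad2)), "unit diagonal")
  ts <- withr::with_seed(321, replicate(3, matrix(rnorm(200), 50, 4),
                                        simplify = FALSE))
  cs <- correlation_from_timeseries(ts)
  expect_identical(length(cs), 3L)
  expect_equal(cs$matrices[[1]], stats::cor(ts[[1]]), ignore_attr = TRUE)
})
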