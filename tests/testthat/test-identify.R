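# Subnetwork identification: restricted statistic, per-size search, the
# change-point selection rule, and the link-set search.

test_that("restriction to the full node set reproduces the full statistic", {
  gx <- planted_sample(6, 1:3, K = 12, seed = 131)
  full <- network_anova(gx)$statistic
  expect_equal(restricted_statistic(gx, nodes = gx$sample$nodes), full)
})

test_that("restricted statistic equals the ANOVA run on induced subnetworks", {
  gx <- planted_sample(7, 1:3, K = 10, seed = 141)
  for (keep in list(1:4, c(2, 5, 6), c(1, 3, 4, 6, 7))) {
    mats <- lapply(seq_len(20), function(k) {
      unname(induce_nodes(member_matrix(gx, k), keep))
    })
    direct <- network_anova(make_grouped(mats, gx$groups))$statistic
    expect_equal(
      restricted_statistic(gx, nodes = gx$sample$nodes[keep]),
      direct, tolerance = 1e-10
    )
  }
})

test_that("exhaustive search agrees with an independent enumeration oracle", {
  gx <- planted_sample(5, 1:3, K = 15, p_base = 0.3, p_alt = 0.9, seed = 151)
  for (j in 2:4) {
    # naive oracle: restricted ANOVA on every induced subnetwork
    combos <- utils::combn(5, j)
    vals <- apply(combos, 2, function(keep) {
      mats <- lapply(seq_len(30), function(k) {
        unname(induce_nodes(member_matrix(gx, k), keep))
      })
      tryCatch(network_anova(make_grouped(mats, gx$groups))$statistic,
               error = function(e) Inf)
    })
    best <- best_subnetwork_of_size(gx, j, strategy = "exhaustive")
    expect_equal(best$value, min(vals), tolerance = 1e-10)
    expect_identical(best$nodes,
                     gx$sample$nodes[combos[, which.min(vals)]])
  }
})

test_that("exhaustive search is independent of node input order", {
  gx <- planted_sample(6, c(1, 2, 3), K = 12, seed = 161)
  perm <- c(4, 1, 6, 3, 2, 5)
  mats <- lapply(seq_len(24), function(k) {
    m <- member_matrix(gx, k)[perm, perm]
    m
  })
  gx_p <- make_grouped(mats, gx$groups)
  b1 <- best_subnetwork_of_size(gx, 3, strategy = "exhaustive")
  b2 <- best_subnetwork_of_size(gx_p, 3, strategy = "exhaustive")
  expect_equal(b1$value, b2$value)
  expect_setequal(b1$nodes, b2$nodes)
})

test_that("greedy search matches exhaustive on most small instances", {
  agree <- withr::with_seed(171, {
    vapply(1:100, function(r) {
      gx <- planted_sample(8, sample(8, 3), K = 10,
                          p_base = runif(1, 0.25, 0.5),
                          p_alt = runif(1, 0.6, 0.95))
      ex <- best_subnetwork_of_size(gx, 4, strategy = "exhaustive")
      gr <- best_subnetwork_of_size(gx, 4, strategy = "greedy")
      abs(ex$value - gr$value) < 1e-8
    }, logical(1))
  })
  expect_gte(mean(agree), 0.9)
})

test_that("size selection applies the literal max-drop rule", {
  path <- tibble::tibble(j = 2:6,
                         statistic = cumsum(c(0, -0.5, -0.4, -0.3, -0.1)))
  expect_identical(select_size(path, g = 0.25), 5L)
  incr <- tibble::tibble(j = 2:5, statistic = c(-1, -0.9, -0.8, -0.2))
  expect_identical(select_size(incr, g = 0.25), NA_integer_)
  # boundary: a drop of exactly -g does not qualify (strict inequality)
  boundary <- tibble::tibble(j = 2:4, statistic = c(0, -0.25, -0.6))
  expect_identical(select_size(boundary, g = 0.25), 4L)
  expect_identical(select_size(tibble::tibble(j = 2:4,
                                              statistic = c(0, -0.25, -0.45)),
                               g = 0.25), NA_integer_)
  expect_error(select_size(tibble::tibble(j = 3:5, statistic = 1:3)),
               "consecutive sizes")
})

test_that("appending sizes without a qualifying drop leaves the selection fixed", {
  base <- tibble::tibble(j = 2:6, statistic = c(0, -1, -1.1, -1.15, -1.18))
  extended <- dplyr::bind_rows(base,
                               tibble::tibble(j = 7:9,
                                              statistic = c(-1.19, -1.0, -0.8)))
  expect_identical(select_size(base, 0.25), select_size(extended, 0.25))
  # a new large drop at bigger j moves the selection there
  moved <- dplyr::bind_rows(base, tibble::tibble(j = 7, statistic = -1.6))
  expect_identical(select_size(moved, 0.25), 7L)
})

test_that("subnetwork_path recovers a strongly planted subnetwork", {
  gx <- planted_sample(7, 2:4, K = 60, p_base = 0.3, p_alt = 0.9, seed = 181)
  sp <- subnetwork_path(gx)
  expect_s3_class(sp, "subnetwork_path")
  expect_identical(sp$path$j, 2:7)
  expect_identical(sp$j_selected, 3L)
  expect_setequal(sp$nodes_selected, gx$sample$nodes[2:4])
  td <- tidy(sp)
  expect_true(td$selected[td$j == 3])
  expect_s3_class(autoplot(sp), "ggplot")
})

test_that("restricted search treats degenerate subsets as non-informative", {
  # nodes 5 and 6 share no varying links: all-zero block
  mats <- withr::with_seed(191, lapply(1:12, function(k) {
    a <- matrix(0, 6, 6)
    a[1:4, 1:4] <- random_adjacency(4)
    a
  }))
  gx <- make_grouped(mats, rep(1:2, each = 6))
  expect_error(restricted_statistic(gx, nodes = c("v5", "v6")), "calibration")
  # but the search simply avoids them
  b <- best_subnetwork_of_size(gx, 2, strategy = "exhaustive")
  expect_true(all(b$nodes %in% paste0("v", 1:4)))
})

test_that("permutation-calibrated search matches its own restricted statistic", {
  gx <- planted_sample(5, 1:3, K = 10, seed = 201)
  spec <- calibration("permutation", permutations = 150, seed = 7)
  b <- best_subnetwork_of_size(gx, 3, strategy = "exhaustive",
                               calibration = spec)
  expect_true(is.finite(b$value))
  # same subset re-evaluated under the same seed gives the same value
  expect_equal(restricted_statistic(gx, nodes = b$nodes, calibration = spec),
               b$value, tolerance = 1e-10)
})

test_that("link-set search recovers a single differing link (exhaustive oracle)", {
  # 3 nodes; only link (1,2) differs between groups
  withr::with_seed(211, {
    mk <- function(p12) {
      a <- matrix(0, 3, 3)
      a[1, 2] <- a[2, 1] <- rbinom(1, 1, p12)
      a[1, 3] <- a[3, 1] <- rbinom(1, 1, 0.5)
      a[2, 3] <- a[3, 2] <- rbinom(1, 1, 0.5)
      a
    }
    mats <- c(replicate(40, mk(0.05), simplify = FALSE),
              replicate(40, mk(0.95), simplify = FALSE))
  })
  gx <- make_grouped(mats, rep(1:2, each = 40))
  ls <- best_link_set(gx)
  expect_false(ls$no_signal)
  # brute force over all 7 nonempty link subsets via restricted_statistic
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  subsets <- unlist(lapply(1:3, function(k) utils::combn(3, k, simplify = FALSE)),
                    recursive = FALSE)
  vals <- vapply(subsets, function(ss) {
    lk <- do.call(rbind, lapply(pairs[ss], function(p) paste0("v", p)))
    tryCatch(restricted_statistic(gx, links = lk), error = function(e) Inf)
  }, numeric(1))
  best <- subsets[[which.min(vals)]]
  expect_equal(ls$statistic, min(vals), tolerance = 1e-10)
  expect_true(any(ls$links$node_a == "v1" & ls$links$node_b == "v2"))
  expect_identical(nrow(ls$links), length(best))
})

test_that("link-set search flags the absence of signal for identical groups", {
  withr::with_seed(221, {
    mats <- random_sample_mats(30, 4, 0.5)
  })
  gx <- make_grouped(mats, rep(1:2, each = 15))
  ls <- best_link_set(gx)
  expect_s3_class(ls, "link_set")
  expect_true(is.finite(ls$statistic))
})
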