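# Geometric random-network simulator with a planted subnetwork effect, and the
# power / type-I / identification experiment harnesses.
#
# Each unordered node pair (i, j) is linked independently with probability
# exp(-lambda * d(i, j)), where d is the Euclidean distance of a 2-D layout.
# Pairs inside the planted node subset use a group-specific decay rate, so
# groups differ only through the planted subnetwork's link probabilities.

#' Built-in 2-D node layouts
#'
#' `"scalp16"` is a 16-channel EEG-style montage on an x-y grid with unit
#' nearest-neighbour spacing (rows front to back: Fp1 Fp2 / F7 F3 F4 F8 /
#' T3 C3 C4 T4 / T5 P3 P4 T6 / O1 O2); its planted subset is the six frontal
#' electrodes, which are mutually close so the planted effect acts on short,
#' high-probability links. The montage is a synthetic stand-in for a real
#' digitized cap: coordinates are idealized, and users with true electrode
#' positions should build a layout from them via [network_layout()].
#' `"grid"` is a 4-by-4 unit grid with the top six nodes planted.
#'
#' @param name `"scalp16"` or `"grid"`.
#' @return A `network_layout`: tibble `coords` (node, x, y), distance matrix
#'   `distances`, and the `planted` node labels.
#' @export
default_layout <- function(name = c("scalp16", "grid")) {
  name <- match.arg(name)
  if (name == "scalp16") {
    coords <- tibble::tibble(
      node = c("Fp1", "Fp2", "F7", "F3", "F4", "F8", "T3", "C3", "C4", "T4",
               "T5", "P3", "P4", "T6", "O1", "O2"),
      x = c(1, 2, 0, 1, 2, 3, 0, 1, 2, 3, 0, 1, 2, 3, 1, 2),
      y = c(3, 3, 2, 2, 2, 2, 1, 1, 1, 1, 0, 0, 0, 0, -1, -1)
    )
    planted <- c("Fp1", "Fp2", "F7", "F3", "F4", "F8")
  } else {
    coords <- tibble::tibble(
      node = paste0("v", 1:16),
      x = rep(0:3, 4),
      y = rep(3:0, each = 4)
    )
    planted <- coords$node[1:6]
  }
  network_layout(coords, planted)
}

#' Build a node layout from coordinates
#'
#' @param coords Data frame with columns `node`, `x`, `y`.
#' @param planted Labels of the planted subset (may be empty).
#' @return An object of class `network_layout`.
#' @export
network_layout <- function(coords, planted = character()) {
  coords <- tibble::as_tibble(coords)
  stopifnot(all(c("node", "x", "y") %in% names(coords)),
            !anyDuplicated(coords$node), nrow(coords) >= 2L)
  if (!all(planted %in% coords$node)) {
    stop("`planted` must be a subset of the layout's nodes", call. = FALSE)
  }
  D <- as.matrix(dist(cbind(coords$x, coords$y)))
  dimnames(D) <- list(coords$node, coords$node)
  if (any(D[upper.tri(D)] <= 0)) {
    stop("layout has coincident nodes (zero pairwise distance)", call. = FALSE)
  }
  structure(list(coords = coords, distances = D,
                 planted = as.character(planted)),
            class = "network_layout")
}

#' @export
print.network_layout <- function(x, ...) {
  cat(sprintf("<network_layout> %d nodes, planted: {%s}\n",
              nrow(x$coords), paste(x$planted, collapse = ", ")))
  invisible(x)
}

#' Geometric model with a planted subnetwork effect
#'
#' Defines, for each of m groups, the link probability of every node pair:
#' `exp(-lambda_global * d)` outside the planted subset and
#' `exp(-lambda_planted[group] * d)` for pairs with both endpoints planted.
#' With all planted rates equal to the global rate the model is a null model.
#'
#' @param layout A [network_layout()].
#' @param lambda_global Positive decay rate for all pairs.
#' @param lambda_planted Vector of positive per-group decay rates for
#'   within-planted pairs; its length sets the number of groups.
#' @param planted Optional override of the layout's planted subset.
#' @return An object of class `geometric_model` carrying one link-probability
#'   matrix per group.
#' @examples
#' mod <- geometric_model(default_layout("scalp16"),
#'                        lambda_planted = c(1, 0.8, 0.6))
#' mod
#' @export
geometric_model <- function(layout, lambda_global = 1,
                            lambda_planted = c(1, 0.8, 0.6),
                            planted = NULL) {
  stopifnot(inherits(layout, "network_layout"),
            lambda_global > 0, all(lambda_planted > 0),
            length(lambda_planted) >= 1L)
  if (is.null(planted)) planted <- layout$planted
  if (!all(planted %in% layout$coords$node)) {
    stop("`planted` must be a subset of the layout's nodes", call. = FALSE)
  }
  D <- layout$distances
  inside <- rownames(D) %in% planted
  probs <- lapply(lambda_planted, function(lam) {
    P <- exp(-lambda_global * D)
    P[inside, inside] <- exp(-lam * D[inside, inside])
    diag(P) <- 0
    P
  })
  structure(list(layout = layout, lambda_global = lambda_global,
                 lambda_planted = lambda_planted, planted = planted,
                 probs = probs, n_groups = length(lambda_planted)),
            class = "geometric_model")
}

#' @export
print.geometric_model <- function(x, ...) {
  cat(sprintf(
    "<geometric_model> %d nodes, %d groups; lambda_global = %g, planted {%s} with lambda = %s\n",
    nrow(x$layout$coords), x$n_groups, x$lambda_global,
    paste(x$planted, collapse = ", "),
    paste(x$lambda_planted, collapse = "/")))
  invisible(x)
}

sample_edges <- function(pvec, K) {
  matrix(rbinom(K * length(pvec), 1L, rep(pvec, each = K)), K, length(pvec))
}

#' Draw networks from one group of a geometric model
#'
#' @param model A [geometric_model()].
#' @param group Group index (1-based).
#' @param K Number of networks to draw.
#' @param seed Optional integer seed.
#' @return A [network_sample()] of K binary networks.
#' @export
geometric_sample <- function(model, group, K, seed = NULL) {
  stopifnot(inherits(model, "geometric_model"),
            group >= 1L, group <= model$n_groups, K >= 1L)
  pvec <- upper_vec(model$probs[[group]])
  draw <- function() sample_edges(pvec, K)
  X <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_sample_from_edges(X, rownames(model$probs[[group]]))
}

#' Draw a grouped sample from all groups of a geometric model
#'
#' @inheritParams geometric_sample
#' @param K Networks per group: a scalar or one value per group (each at
#'   least 2).
#' @return A [grouped_sample()] with groups `group1`, `group2`, ...
#' @export
geometric_grouped_sample <- function(model, K, seed = NULL) {
  stopifnot(inherits(model, "geometric_model"))
  m <- model$n_groups
  K <- rep_len(as.integer(K), m)
  stopifnot(all(K >= 2L))
  draw <- function() {
    do.call(rbind, lapply(seq_len(m), function(g) {
      sample_edges(upper_vec(model$probs[[g]]), K[g])
    }))
  }
  X <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  s <- new_sample_from_edges(X, rownames(model$probs[[1L]]))
  grouped_sample(s, rep(paste0("group", seq_len(m)), K))
}

experiment_seed <- function(seed, r) {
  if (is.null(seed)) NULL else (as.integer(seed) + 7919L * r) %% .Machine$integer.max
}

#' Power experiment for the network ANOVA and the links test
#'
#' Simulates `replicates` datasets from the model (m groups of K networks
#' each), applies [network_anova()] to every replicate and estimates the power
#' as the fraction of replicates rejecting at level `alpha` (T below the
#' lower-tail normal quantile, -1.65 at alpha = 0.05). Optionally runs the
#' comparator [links_test()] on the same data for a power comparison.
#'
#' @param model A [geometric_model()].
#' @param K Networks per group.
#' @param replicates Number of simulated datasets.
#' @param alpha Test level.
#' @param seed Optional integer seed (replicate streams derive from it).
#' @param compare_links Also run the links test per replicate.
#' @param calibration A [calibration()] specification.
#' @return An object of class `power_experiment`: per-replicate tibble
#'   `results` (columns `replicate`, `statistic`, `reject`, and `links_reject`
#'   when requested), the `power` estimate, its binomial 95% confidence
#'   interval, and the settings.
#' @export
power_experiment <- function(model, K, replicates = 500L, alpha = 0.05,
                             seed = NULL, compare_links = FALSE,
                             calibration = netanova::calibration()) {
  stopifnot(inherits(model, "geometric_model"), replicates >= 1L)
  spec <- as_calibration(calibration)
  rows <- lapply(seq_len(replicates), function(r) {
    gx <- geometric_grouped_sample(model, K, seed = experiment_seed(seed, r))
    fit <- network_anova(gx, alpha = alpha, calibration = spec)
    out <- tibble::tibble(replicate = r, statistic = fit$statistic,
                          reject = fit$reject)
    if (compare_links) {
      out$links_reject <- links_test(gx, alpha = alpha)$global_reject
    }
    out
  })
  results <- dplyr::bind_rows(rows)
  ci <- stats::binom.test(sum(results$reject), replicates)$conf.int
  structure(list(
    results = results,
    power = mean(results$reject),
    conf_int = as.numeric(ci),
    links_power = if (compare_links) mean(results$links_reject) else NULL,
    K = K, replicates = replicates, alpha = alpha, seed = seed,
    model = model
  ), class = "power_experiment")
}

#' @export
print.power_experiment <- function(x, ...) {
  cat(sprintf("Power experiment: K = %s, %d replicates, alpha = %g\n",
              paste(x$K, collapse = "/"), x$replicates, x$alpha))
  cat(sprintf("  network ANOVA power = %.3f (95%% CI %.3f-%.3f)\n",
              x$power, x$conf_int[1L], x$conf_int[2L]))
  if (!is.null(x$links_power)) {
    cat(sprintf("  links test power   = %.3f\n", x$links_power))
  }
  invisible(x)
}

#' Null-distribution experiment for the T statistic
#'
#' Simulates datasets in which every group follows the same law (the model is
#' used as given; pass a null model with equal decay rates) and summarizes the
#' T ensemble: mean, standard deviation, type-I error rate at `alpha`, and a
#' Kolmogorov-Smirnov comparison with the standard normal.
#'
#' @inheritParams power_experiment
#' @return An object of class `type1_experiment` with the per-replicate
#'   tibble `results` and summary fields `mean_t`, `sd_t`, `type1_rate`,
#'   `ks_statistic`, `ks_p_value`.
#' @export
type1_experiment <- function(model, K, replicates = 2000L, alpha = 0.05,
                             seed = NULL,
                             calibration = netanova::calibration()) {
  stopifnot(inherits(model, "geometric_model"), replicates >= 2L)
  spec <- as_calibration(calibration)
  tv <- vapply(seq_len(replicates), function(r) {
    gx <- geometric_grouped_sample(model, K, seed = experiment_seed(seed, r))
    network_anova(gx, alpha = alpha, calibration = spec)$statistic
  }, numeric(1L))
  ks <- suppressWarnings(ks.test(tv, pnorm))
  structure(list(
    results = tibble::tibble(replicate = seq_len(replicates), statistic = tv),
    mean_t = mean(tv), sd_t = sd(tv),
    type1_rate = mean(tv < qnorm(alpha)),
    ks_statistic = unname(ks$statistic), ks_p_value = ks$p.value,
    K = K, replicates = replicates, alpha = alpha, seed = seed
  ), class = "type1_experiment")
}

#' @export
print.type1_experiment <- function(x, ...) {
  cat(sprintf("Null experiment: K = %s, %d replicates\n",
              paste(x$K, collapse = "/"), x$replicates))
  cat(sprintf("  T: mean = %.3f, sd = %.3f; type-I rate at alpha = %g: %.3f\n",
              x$mean_t, x$sd_t, x$alpha, x$type1_rate))
  cat(sprintf("  KS vs N(0,1): D = %.4f, p = %.3f\n",
              x$ks_statistic, x$ks_p_value))
  invisible(x)
}

#' Identification experiment
#'
#' Simulates datasets from a planted-subnetwork model, runs the
#' [subnetwork_path()] identification with stopping threshold `g` on each, and
#' summarizes how often the selected subnetwork has the planted size and how
#' often it recovers the planted node set exactly.
#'
#' @inheritParams power_experiment
#' @param g Stopping threshold of [select_size()].
#' @param strategy,budget Search controls, as in [subnetwork_path()].
#' @return An object of class `identification_experiment`: per-replicate
#'   tibble `results` (columns `replicate`, `j_selected`, `nodes` list column,
#'   `exact`), the size histogram `size_table`, `modal_size`,
#'   `prop_planted_size` (fraction selecting exactly the planted size),
#'   `prop_exact` (fraction recovering the planted set exactly), and
#'   `prop_exact_given_size` (exact recovery among replicates selecting the
#'   planted size).
#' @export
identification_experiment <- function(model, K, replicates = 50L, g = 0.25,
                                      strategy = c("auto", "exhaustive", "greedy"),
                                      budget = 2e5, seed = NULL,
                                      calibration = netanova::calibration()) {
  stopifnot(inherits(model, "geometric_model"), replicates >= 1L)
  strategy <- match.arg(strategy)
  spec <- as_calibration(calibration)
  planted <- sort(model$planted)
  rows <- lapply(seq_len(replicates), function(r) {
    gx <- geometric_grouped_sample(model, K, seed = experiment_seed(seed, r))
    sp <- subnetwork_path(gx, g = g, strategy = strategy, budget = budget,
                          calibration = spec)
    sel <- if (is.na(sp$j_selected)) character() else sp$nodes_selected
    hit <- length(sel) > 0L && setequal(sel, planted)
    tibble::tibble(replicate = r, j_selected = sp$j_selected,
                   nodes = list(sel), exact = hit)
  })
  results <- dplyr::bind_rows(rows)
  sizes <- results$j_selected[!is.na(results$j_selected)]
  size_table <- table(factor(sizes, levels = sort(unique(sizes))))
  at_planted_size <- !is.na(results$j_selected) &
    results$j_selected == length(planted)
  structure(list(
    results = results,
    size_table = size_table,
    modal_size = if (length(sizes)) {
      as.integer(names(size_table)[which.max(size_table)])
    } else NA_integer_,
    prop_planted_size = mean(at_planted_size),
    prop_exact = mean(results$exact),
    prop_exact_given_size = if (any(at_planted_size)) {
      mean(results$exact[at_planted_size])
    } else NA_real_,
    planted = planted, K = K, replicates = replicates, g = g, seed = seed
  ), class = "identification_experiment")
}

#' @export
print.identification_experiment <- function(x, ...) {
  cat(sprintf("Identification experiment: K = %s, %d replicates, g = %g\n",
              paste(x$K, collapse = "/"), x$replicates, x$g))
  cat(sprintf("  modal selected size = %s; planted size (%d) selected in %.0f%%\n",
              x$modal_size, length(x$planted), 100 * x$prop_planted_size))
  cat(sprintf("  exact planted-set recovery: %.0f%% overall, %.0f%% given planted size\n",
              100 * x$prop_exact, 100 * x$prop_exact_given_size))
  invisible(x)
}
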