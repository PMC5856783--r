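# File I/O: dense symmetric matrices as labeled CSV, manifests of per-subject
# files, group label tables, edge lists, and JSON reports.

#' Read / write a labeled symmetric matrix as CSV
#'
#' Matrices are stored dense with a header row of node labels (the first
#' column holds the row labels), which round-trips node ordering.
#'
#' @param path File path.
#' @return `read_network_matrix()` returns a labeled numeric matrix.
#' @export
read_network_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path, call. = FALSE)
  if (nrow(m) != ncol(m) || !identical(labels, colnames(m))) {
    stop("matrix in ", path, " is not square with matching row/column labels",
         call. = FALSE)
  }
  rownames(m) <- labels
  m
}

#' @rdname read_network_matrix
#' @param m A labeled square matrix.
#' @export
write_network_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("v", seq_len(nrow(m)))
  }
  df <- tibble::as_tibble(unclass(m), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(node = rownames(m)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Load a sample of matrices from a manifest
#'
#' The manifest is a CSV with columns `subject_id` and `path` (and optionally
#' `kind`, "adjacency" or "correlation"); paths resolve relative to the
#' manifest's directory. All matrices must share the dimension and node
#' labels of the first; failures are reported per subject.
#'
#' @param manifest Path to the manifest CSV.
#' @param kind `"adjacency"` (default) or `"correlation"`; overrides the
#'   manifest's `kind` column.
#' @return A [network_sample()] or [correlation_sample()].
#' @export
load_sample <- function(manifest, kind = NULL) {
  mf <- readr::read_csv(manifest, col_types = readr::cols(), progress = FALSE)
  if (!all(c("subject_id", "path") %in% names(mf))) {
    stop("manifest needs columns `subject_id` and `path`", call. = FALSE)
  }
  if (anyDuplicated(mf$subject_id)) {
    stop("duplicate subject_id in manifest", call. = FALSE)
  }
  if (is.null(kind)) {
    kind <- if ("kind" %in% names(mf)) unique(mf$kind) else "adjacency"
  }
  kind <- match.arg(kind, c("adjacency", "correlation"))
  base <- dirname(normalizePath(manifest))
  mats <- vector("list", nrow(mf))
  for (k in seq_len(nrow(mf))) {
    p <- mf$path[k]
    if (!file.path_is_absolute(p)) p <- file.path(base, p)
    if (!file.exists(p)) {
      stop("subject ", mf$subject_id[k], ": file not found (", mf$path[k], ")",
           call. = FALSE)
    }
    mats[[k]] <- tryCatch({
      m <- read_network_matrix(p)
      if (kind == "adjacency") {
        validate_adjacency(m, who = "matrix")
      } else {
        correlation_sample(list(m))
      }
      m
    }, error = function(e) {
      stop("subject ", mf$subject_id[k], ": ", conditionMessage(e),
           call. = FALSE)
    })
    if (k > 1L && !identical(dim(mats[[k]]), dim(mats[[1L]]))) {
      stop("subject ", mf$subject_id[k], ": dimension ",
           nrow(mats[[k]]), " differs from ", nrow(mats[[1L]]), call. = FALSE)
    }
  }
  if (kind == "adjacency") {
    network_sample(mats, ids = mf$subject_id)
  } else {
    correlation_sample(mats, ids = mf$subject_id)
  }
}

file.path_is_absolute <- function(p) grepl("^(/|[A-Za-z]:)", p)

#' Read group labels for a sample
#'
#' @param path CSV with columns `subject_id` and `group`.
#' @param ids Subject identifiers, in sample order, that the labels must cover.
#' @return A factor of group labels aligned with `ids`.
#' @export
read_group_labels <- function(path, ids) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop("group file needs columns `subject_id` and `group`", call. = FALSE)
  }
  idx <- match(ids, df$subject_id)
  if (anyNA(idx)) {
    stop("no group label for subject(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  factor(df$group[idx], levels = unique(as.character(df$group[idx])))
}

#' Convert an adjacency matrix to a tidy edge list
#'
#' @param m A labeled square matrix.
#' @param drop_zero Drop absent links.
#' @return A tibble with columns `node_a`, `node_b`, `weight`.
#' @export
as_edge_list <- function(m, drop_zero = TRUE) {
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  labels <- if (is.null(rownames(m))) paste0("v", seq_len(nrow(m))) else rownames(m)
  ep <- edge_ends(nrow(m))
  out <- tibble::tibble(node_a = labels[ep$i], node_b = labels[ep$j],
                        weight = upper_vec(m))
  if (drop_zero) out <- out[out$weight != 0, ]
  out
}

report_data <- function(x) UseMethod("report_data")

#' @export
report_data.network_anova <- function(x) {
  list(type = "network_anova",
       statistic = x$statistic, a = x$a, S = x$S, p_value = x$p_value,
       alpha = x$alpha, reject = x$reject,
       calibration = x$calibration$method,
       m = x$m, n_total = x$n_total, n_nodes = x$n_nodes,
       small_sample = x$small_sample,
       groups = x$group_summary)
}

#' @export
report_data.subnetwork_path <- function(x) {
  list(type = "subnetwork_path",
       g = x$g, j_selected = x$j_selected,
       nodes_selected = as.list(x$nodes_selected),
       path = tibble::tibble(j = x$path$j, statistic = x$path$statistic,
                             strategy = x$path$strategy,
                             nodes = vapply(x$path$nodes, paste,
                                            character(1L), collapse = ",")))
}

#' @export
report_data.link_test <- function(x) {
  list(type = "link_test", alpha = x$alpha, n_tests = x$n_tests,
       global_reject = x$global_reject, table = x$table)
}

#' @export
report_data.w3_null <- function(x) {
  list(type = "w3_null", w3 = x$observed$w3,
       deltas = as.list(x$observed$deltas), p_value = x$p_value, B = x$B,
       resampling = if (x$replace) "bootstrap" else "permutation",
       null = as.numeric(x$null))
}

#' @export
report_data.power_experiment <- function(x) {
  list(type = "power_experiment", power = x$power,
       conf_int = x$conf_int, links_power = x$links_power,
       K = x$K, replicates = x$replicates, alpha = x$alpha, seed = x$seed)
}

#' Write a machine-readable JSON report
#'
#' Serializes a fitted result (`network_anova`, `subnetwork_path`,
#' `link_test`, `w3_null` or `power_experiment`) with a schema version and the
#' package version, floats at full precision.
#'
#' @param x A result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  payload <- list(
    schema = "netanova/1",
    package_version = as.character(utils::packageVersion("netanova")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    result = report_data(x)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
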