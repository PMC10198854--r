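#' Assemble a z-scored tumor-microenvironment parameter panel
#'
#' Joins per-sample score tables (and optionally TMB) into one panel, then
#' z-scores each parameter across samples. Typical parameters: immune and
#' stromal scores, TAM/MDSC/Treg and exhausted-T scores, the TLS score, an
#' IFN-gamma signature, TMB and a malignant-cell score.
#'
#' @param score_tables A long score tibble (`sample_id`, `signature`,
#'   `score`), a list of them, or a wide tibble (`sample_id` + numeric
#'   columns).
#' @param tmb_table Optional tibble `sample_id`, `tmb`, joined as parameter
#'   `"TMB"`.
#' @param imputation `"drop_samples"` (default; samples with any missing
#'   parameter are dropped) or `"mean"` (missing cells imputed with the
#'   parameter mean before scaling).
#' @param min_shared Minimum fraction of samples every input must share with
#'   the first (default 0.9).
#' @return A `tme_panel` tibble: `sample_id` + one z-scored column per
#'   parameter; attributes `raw` (pre-scaling values) and `parameters`.
#' @export
build_tme_panel <- function(score_tables, tmb_table = NULL,
                            imputation = c("drop_samples", "mean"),
                            min_shared = 0.9) {
  imputation <- match.arg(imputation)
  wide <- panel_wide(score_tables)
  if (!is.null(tmb_table)) {
    stop_if_not_cols(tmb_table, c("sample_id", "tmb"), "TMB table")
    tt <- tibble::tibble(sample_id = tmb_table$sample_id, TMB = as.numeric(tmb_table$tmb))
    shared <- length(intersect(wide$sample_id, tt$sample_id)) /
      max(nrow(wide), nrow(tt))
    if (shared < min_shared) {
      abort(sprintf("inputs share only %.0f%% of samples (< %.0f%% required)",
                    100 * shared, 100 * min_shared))
    }
    wide <- dplyr::inner_join(wide, tt, by = "sample_id")
  }
  params <- setdiff(names(wide), "sample_id")
  if (length(params) < 2L) abort("a TME panel needs at least 2 parameters")
  if (imputation == "drop_samples") {
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  } else {
    for (p in params) {
      v <- wide[[p]]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      wide[[p]] <- v
    }
  }
  keep <- vapply(params, function(p) sd(wide[[p]]) > 0, logical(1))
  if (!all(keep)) {
    warn(sprintf("constant parameter(s) excluded: %s",
                 paste(params[!keep], collapse = ", ")))
    params <- params[keep]
    if (length(params) < 2L) abort("fewer than 2 non-constant parameters remain")
  }
  raw <- wide[, c("sample_id", params)]
  z <- raw
  for (p in params) z[[p]] <- as.numeric(scale(raw[[p]]))
  attr(z, "raw") <- raw
  attr(z, "parameters") <- params
  class(z) <- c("tme_panel", class(z))
  z
}

panel_wide <- function(score_tables) {
  if (is.data.frame(score_tables)) {
    if (all(c("sample_id", "signature", "score") %in% names(score_tables))) {
      wide <- tidyr::pivot_wider(
        score_tables[, c("sample_id", "signature", "score")],
        names_from = "signature", values_from = "score")
      return(wide)
    }
    stop_if_not_cols(score_tables, "sample_id", "panel table")
    return(tibble::as_tibble(score_tables))
  }
  if (is.list(score_tables)) {
    wides <- lapply(score_tables, panel_wide)
    return(Reduce(function(a, b) dplyr::inner_join(a, b, by = "sample_id"), wides))
  }
  abort("score_tables must be a data frame or a list of score tables")
}

#' Complete-linkage hierarchical TME classes
#'
#' Agglomerative clustering of samples on the z-scored panel (Euclidean
#' distance, complete linkage via `stats::hclust`, the procedure the
#' original classification used), cut to exactly `k` clusters. Labels are
#' renumbered so that cluster `k` has the highest mean of the TLS parameter
#' (when one is present), making "cluster 5 = TLS-highest" stable across
#' runs.
#'
#' @param panel A `tme_panel` ([build_tme_panel()]).
#' @param k Number of classes (default 5).
#' @param linkage Agglomeration method (default and convention: "complete").
#' @param metric Distance metric (default "euclidean").
#' @param tls_param Panel column used to order labels (default: a column
#'   named "TLS" if present, else merge order).
#' @return Tibble `sample_id`, `cluster` (integer 1..k); attributes `hclust`
#'   (the full tree), `merge` (tibble child1/child2/height), `k`, `linkage`,
#'   `metric`.
#' @export
hierarchical_clusters <- function(panel, k = 5L, linkage = "complete",
                                  metric = "euclidean", tls_param = NULL) {
  params <- attr(panel, "parameters") %||% setdiff(names(panel), "sample_id")
  m <- as.matrix(panel[, params, drop = FALSE])
  rownames(m) <- panel$sample_id
  if (k > nrow(m)) abort("k cannot exceed the number of samples")
  hc <- hclust(dist(m, method = metric), method = linkage)
  cl <- cutree(hc, k = k)
  tls_param <- tls_param %||% (if ("TLS" %in% params) "TLS" else NULL)
  if (!is.null(tls_param) && tls_param %in% params) {
    means <- tapply(panel[[tls_param]], cl, mean)
    relabel <- setNames(rank(means, ties.method = "first"), names(means))
    cl <- unname(relabel[as.character(cl)])
  }
  out <- tibble::tibble(sample_id = panel$sample_id, cluster = as.integer(cl))
  attr(out, "hclust") <- hc
  attr(out, "merge") <- tibble::tibble(child1 = hc$merge[, 1L],
                                       child2 = hc$merge[, 2L],
                                       height = hc$height)
  attr(out, "k") <- as.integer(k)
  attr(out, "linkage") <- linkage
  attr(out, "metric") <- metric
  class(out) <- c("tme_clusters", class(out))
  out
}

#' Characterize and compare TME classes
#'
#' Per-cluster mean z-score of every panel parameter, and — when a clinical
#' table is supplied — a k-group log-rank test plus per-cluster Kaplan-Meier
#' curves.
#'
#' @param panel A `tme_panel`.
#' @param assignment Cluster assignment ([hierarchical_clusters()]).
#' @param clinical Optional clinical tibble.
#' @return List of class `tme_profile`: `profile` (tibble cluster,
#'   parameter, mean_z, n), `logrank` (or NULL), `km` (or NULL).
#' @export
characterize_clusters <- function(panel, assignment, clinical = NULL) {
  params <- attr(panel, "parameters") %||% setdiff(names(panel), "sample_id")
  df <- dplyr::inner_join(panel, assignment, by = "sample_id")
  if (nrow(df) == 0L) abort("panel and assignment share no samples")
  if (any(table(df$cluster) == 0L)) abort("empty cluster after joining")
  long <- tidyr::pivot_longer(df[, c("cluster", params)], -"cluster",
                              names_to = "parameter", values_to = "z")
  profile <- dplyr::summarise(long, mean_z = mean(.data$z), n = dplyr::n(),
                              .by = c("cluster", "parameter"))
  profile <- dplyr::arrange(profile, .data$cluster, .data$parameter)
  lr <- km <- NULL
  if (!is.null(clinical)) {
    groups <- tibble::tibble(sample_id = df$sample_id,
                             group = paste0("c", df$cluster))
    if (length(unique(groups$group)) >= 2L) {
      lr <- logrank_test(clinical, groups)
    }
    km <- km_estimate(clinical, groups)
  }
  structure(list(profile = profile, logrank = lr, km = km),
            class = "tme_profile")
}
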