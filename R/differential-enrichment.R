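#' Two-group differential expression with fold-change filter
#'
#' Per gene: a Wilcoxon rank-sum (default) or Welch t test on the log2
#' values, and a fold change computed on linear-scale group means. A gene is
#' called up (or down) only when both the p-value and the absolute fold
#' change pass their thresholds; `|FC| > 1.5` corresponds to
#' `|log2FC| > log2(1.5)`.
#'
#' @param expr An [expression_matrix()].
#' @param group_labels Tibble `sample_id`, `group` with exactly two groups,
#'   each of size >= 2. The first group (factor level or alphabetical order)
#'   is the numerator of the fold change.
#' @param test `"wilcoxon"` or `"welch"`.
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @return Tibble per gene: `gene_id`, `log2_fc`, `statistic`, `p_value`,
#'   `q_value` (BH), `direction` in {up, down, ns}; attribute `groups`.
#' @export
differential_expression <- function(expr, group_labels,
                                    test = c("wilcoxon", "welch"),
                                    fc_threshold = 1.5, p_threshold = 0.05) {
  test <- match.arg(test)
  stop_if_not_cols(group_labels, c("sample_id", "group"), "group labels")
  gl <- group_labels[!is.na(group_labels$group), , drop = FALSE]
  gl <- gl[gl$sample_id %in% colnames(expr), , drop = FALSE]
  lev <- if (is.factor(gl$group)) intersect(levels(gl$group), unique(as.character(gl$group)))
         else sort(unique(as.character(gl$group)))
  if (length(lev) != 2L) abort("differential expression needs exactly two groups")
  ia <- gl$sample_id[gl$group == lev[1L]]
  ib <- gl$sample_id[gl$group == lev[2L]]
  if (length(ia) < 2L || length(ib) < 2L) abort("each group needs at least 2 samples")
  lv <- expr_log2(expr)
  lin <- expr_linear(expr)
  la <- lv[, ia, drop = FALSE]
  lb <- lv[, ib, drop = FALSE]
  log2_fc <- unname(log2(rowMeans(lin[, ia, drop = FALSE]) /
                           rowMeans(lin[, ib, drop = FALSE])))
  res <- vapply(seq_len(nrow(lv)), function(i) {
    x <- la[i, ]
    y <- lb[i, ]
    if (diff(range(c(x, y))) == 0) return(c(NA_real_, 1))
    ht <- if (test == "wilcoxon") {
      suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    } else {
      t.test(x, y)
    }
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2))
  p <- res[2L, ]
  q <- p.adjust(p, method = "BH")
  direction <- ifelse(p < p_threshold & log2_fc > log2(fc_threshold), "up",
                      ifelse(p < p_threshold & log2_fc < -log2(fc_threshold),
                             "down", "ns"))
  out <- tibble::tibble(gene_id = rownames(lv), log2_fc = unname(log2_fc),
                        statistic = res[1L, ], p_value = p, q_value = q,
                        direction = direction)
  attr(out, "groups") <- lev
  attr(out, "thresholds") <- c(fc = fc_threshold, p = p_threshold)
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the overlap between the query list and the set within the
#' universe, `P(X >= k)`, with Benjamini-Hochberg adjustment across sets.
#' Sets are kept when the overlap has at least `min_overlap` genes and the
#' mode's significance rule holds: GO mode keeps FDR < 0.05, pathway mode
#' keeps raw p < 0.05.
#'
#' @param query_genes Character vector of query genes (e.g. DEGs). Genes not
#'   in the universe are dropped with a warning.
#' @param universe_genes Character vector of universe genes.
#' @param gene_sets Gene-set tibble or named list; sets are intersected with
#'   the universe.
#' @param min_overlap Minimum overlap size to keep a set (default 5).
#' @param mode `"go"` (FDR < 0.05) or `"pathway"` (p < 0.05).
#' @return Tibble per set: `set`, `overlap` (list-column), `k`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `q_value`, `kept`.
#' @export
ora_enrichment <- function(query_genes, universe_genes, gene_sets,
                           min_overlap = 5L, mode = c("go", "pathway")) {
  mode <- match.arg(mode)
  universe <- unique(universe_genes)
  if (length(universe) == 0L) abort("the universe must be non-empty")
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warn(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- intersect(query, universe)
  }
  gene_sets <- as_gene_sets(gene_sets)
  N <- length(universe)
  n <- length(query)
  res <- purrr::pmap(gene_sets, function(set, description, genes) {
    gs <- intersect(unique(genes), universe)
    K <- length(gs)
    ov <- intersect(query, gs)
    k <- length(ov)
    p <- if (n == 0L || K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = set, overlap = list(ov), k = k, set_size = K,
                   query_size = n, universe_size = N, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  sig <- if (mode == "go") out$q_value < 0.05 else out$p_value < 0.05
  out$kept <- out$k >= min_overlap & sig
  attr(out, "mode") <- mode
  attr(out, "min_overlap") <- min_overlap
  out
}
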