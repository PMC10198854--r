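#' The 13-chemokine TLS signature
#'
#' Chemokine genes whose coordinated over-expression marks tertiary lymphoid
#' structure formation in head and neck squamous cell carcinoma. BCL6, a
#' member of earlier TLS marker panels, is deliberately absent: its expression
#' does not track the remaining genes in HNSCC (see
#' [check_signature_coherence()] for the corresponding diagnostic).
#'
#' @return Character vector of 13 gene symbols.
#' @export
tls_signature_genes <- function() {
  c("CCL2", "CCL3", "CCL4", "CCL5", "CCL18", "CCL19", "CCL21",
    "CXCL9", "CXCL10", "CXCL11", "CXCL13", "CXCR4", "LAMP3")
}

#' Compute the TLS signature score per sample
#'
#' The score is the geometric mean of the linear-scale signature-gene values,
#' computed as the arithmetic mean of `log2(v + 1)` and reported in log2
#' units. The `+1` shift keeps all-zero samples finite; for an input already
#' on the `log2p1` scale the stored values are averaged directly.
#'
#' @param expr An [expression_matrix()].
#' @param signature Character vector of signature gene ids (default the
#'   13-chemokine TLS set).
#' @param name Signature name recorded in the output.
#' @param min_present Minimum fraction of the signature that must be present
#'   in `expr` (default 0.7); below it the call errors.
#' @return A score tibble with columns `sample_id`, `signature`, `score`, and
#'   attributes `method`, `genes_used`, `genes_missing`.
#' @examples
#' m <- matrix(7, nrow = 13, ncol = 2,
#'             dimnames = list(tls_signature_genes(), c("s1", "s2")))
#' compute_tls_score(expression_matrix(m, "linear"))  # log2(8) = 3 for both
#' @export
compute_tls_score <- function(expr, signature = tls_signature_genes(),
                              name = "TLS", min_present = 0.7) {
  marker_score_impl(expr, signature, name, min_present, method = "geometric_mean")
}

marker_score_impl <- function(expr, signature, name, min_present, method) {
  present <- intersect(signature, rownames(expr))
  missing <- setdiff(signature, rownames(expr))
  if (length(present) == 0L) {
    abort(sprintf("no gene of signature '%s' is present in the expression matrix", name))
  }
  if (length(present) / length(signature) < min_present) {
    abort(sprintf("only %d/%d genes of signature '%s' are present (< %.0f%% required)",
                  length(present), length(signature), name, 100 * min_present))
  }
  if (length(missing) > 0L) {
    warn(sprintf("signature '%s': %d gene(s) missing from the expression matrix: %s",
                 name, length(missing), paste(missing, collapse = ", ")))
  }
  lv <- expr_log2(expr)[present, , drop = FALSE]
  out <- tibble::tibble(sample_id = colnames(expr),
                        signature = name,
                        score = unname(colMeans(lv)))
  attr(out, "method") <- method
  attr(out, "genes_used") <- present
  attr(out, "genes_missing") <- missing
  out
}

#' Stratify samples into TLS classes by score quartiles
#'
#' Two dialects are supported. `three_class` (default for survival curves):
#' scores strictly above the third quartile are TLS-hi, strictly below the
#' first quartile TLS-low, the rest TLS-inter. `two_class_q3` (the literal
#' Methods rule): strictly above Q3 is hi, everything else low. Quartiles use
#' the type-7 (linear interpolation) convention.
#'
#' @param scores A score tibble ([compute_tls_score()]); when several
#'   signatures are present, `signature` selects one.
#' @param mode `"three_class"` or `"two_class_q3"`.
#' @param signature Signature name to stratify on (default: the only one).
#' @return Tibble `sample_id`, `score`, `tls_class` (factor) with attributes
#'   `thresholds` (named Q1/Q3) and `mode`.
#' @export
stratify_by_quartile <- function(scores, mode = c("three_class", "two_class_q3"),
                                 signature = NULL) {
  mode <- match.arg(mode)
  stop_if_not_cols(scores, c("sample_id", "score"), "score table")
  if ("signature" %in% names(scores)) {
    sigs <- unique(scores$signature)
    signature <- signature %||% sigs[[1L]]
    scores <- scores[scores$signature == signature, , drop = FALSE]
  }
  if (nrow(scores) < 4L) abort("quartile stratification needs at least 4 scored samples")
  s <- scores$score
  q <- quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
  if (diff(range(s)) == 0) {
    warn("constant scores: every sample falls in a single class")
  }
  cls <- if (mode == "two_class_q3") {
    factor(ifelse(s > q[2L], "hi", "low"), levels = c("hi", "low"))
  } else {
    factor(ifelse(s > q[2L], "TLS-hi", ifelse(s < q[1L], "TLS-low", "TLS-inter")),
           levels = c("TLS-hi", "TLS-inter", "TLS-low"))
  }
  out <- tibble::tibble(sample_id = scores$sample_id, score = s, tls_class = cls)
  attr(out, "thresholds") <- c(Q1 = q[1L], Q3 = q[2L])
  attr(out, "mode") <- mode
  attr(out, "quantile_type") <- 7L
  out
}

#' Compare scores between two groups
#'
#' Wilcoxon rank-sum (exact when sample sizes permit and no ties, otherwise
#' normal approximation with tie correction — the `stats::wilcox.test`
#' convention) or Welch two-sample t test, one- or two-sided.
#'
#' @param scores Score tibble with `sample_id` and `score`.
#' @param group_labels Tibble with `sample_id` and `group`; exactly two
#'   non-empty groups after joining.
#' @param test `"wilcoxon"` or `"t"`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (first group
#'   relative to second, groups ordered by level/alphabetically).
#' @return One-row tibble: groups, sizes, medians, statistic, p_value.
#' @export
compare_score_by_group <- function(scores, group_labels,
                                   test = c("wilcoxon", "t"),
                                   alternative = "two.sided") {
  test <- match.arg(test)
  stop_if_not_cols(scores, c("sample_id", "score"), "score table")
  stop_if_not_cols(group_labels, c("sample_id", "group"), "group labels")
  df <- dplyr::inner_join(scores, group_labels, by = "sample_id")
  df <- df[!is.na(df$group), , drop = FALSE]
  lev <- if (is.factor(df$group)) intersect(levels(df$group), unique(as.character(df$group)))
         else sort(unique(df$group))
  if (length(lev) != 2L) abort("exactly two non-empty groups are required")
  x <- df$score[df$group == lev[1L]]
  y <- df$score[df$group == lev[2L]]
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be non-empty")
  if (diff(range(c(x, y))) == 0) {
    warn("constant scores in both groups: p = 1")
    stat <- NA_real_
    p <- 1
  } else if (test == "wilcoxon") {
    ht <- suppressWarnings(wilcox.test(x, y, alternative = alternative))
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- t.test(x, y, alternative = alternative)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble::tibble(group1 = lev[1L], group2 = lev[2L],
                 n1 = length(x), n2 = length(y),
                 median1 = median(x), median2 = median(y),
                 statistic = stat, p_value = p,
                 test = test, alternative = alternative)
}

#' Flag signature genes discordant with the rest of the signature
#'
#' For each signature gene, computes the Pearson correlation of its log2
#' expression with the leave-one-out signature score; genes with negative
#' correlation are flagged as candidates for exclusion (the rule under which
#' BCL6 was dropped from the TLS panel).
#'
#' @inheritParams compute_tls_score
#' @return Tibble `gene_id`, `r`, `flagged`.
#' @export
check_signature_coherence <- function(expr, signature = tls_signature_genes()) {
  present <- intersect(signature, rownames(expr))
  if (length(present) < 3L) abort("coherence check needs at least 3 signature genes present")
  lv <- expr_log2(expr)[present, , drop = FALSE]
  r <- vapply(seq_along(present), function(i) {
    loo <- colMeans(lv[-i, , drop = FALSE])
    if (sd(lv[i, ]) == 0 || sd(loo) == 0) return(NA_real_)
    cor(lv[i, ], loo)
  }, numeric(1))
  tibble::tibble(gene_id = present, r = r, flagged = !is.na(r) & r < 0)
}
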