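#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample independently, genes are ranked by decreasing expression
#' (ties receive their average rank). Walking down the ranked list, the
#' enrichment score is the sum over positions of the difference between the
#' weighted in-set empirical CDF — weights are `rank^alpha`, with the
#' highest-expressed gene holding rank G — and the unweighted out-of-set CDF.
#' The score depends on the expression vector only through its ranks, so it
#' is invariant under any strictly monotone per-sample transform.
#'
#' @param expr An [expression_matrix()].
#' @param gene_sets Gene-set tibble ([read_gmt()]) or a named list of gene-id
#'   vectors. After intersection with the expressed genes, each set must be a
#'   proper non-empty subset.
#' @param alpha Rank-weighting exponent (> 0), default 0.25.
#' @param normalize If `TRUE`, divide each set's scores by the max-minus-min
#'   of the score across samples. Off by default: normalization couples
#'   samples and breaks single-sample semantics.
#' @return Score tibble: `sample_id`, `signature`, `score`.
#' @export
ssgsea_score <- function(expr, gene_sets, alpha = 0.25, normalize = FALSE) {
  if (alpha <= 0) abort("alpha must be positive")
  gene_sets <- as_gene_sets(gene_sets)
  genes <- rownames(expr)
  G <- length(genes)
  sets <- setNames(gene_sets$genes, gene_sets$set)
  sets <- lapply(sets, intersect, y = genes)
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0L) {
      abort(sprintf("gene set '%s' shares no genes with the expression matrix", nm))
    }
    if (length(sets[[nm]]) == G) {
      abort(sprintf("gene set '%s' covers every expressed gene (empty complement)", nm))
    }
  }
  vals <- unclass(expr)
  inset <- lapply(sets, function(g) genes %in% g)
  out <- purrr::map(colnames(expr), function(s) {
    v <- vals[, s]
    r <- rank(v, ties.method = "average")      # highest expression -> rank G
    ord <- order(v, decreasing = TRUE)
    es <- vapply(names(sets), function(nm) {
      ins <- inset[[nm]][ord]
      w <- (r[ord]^alpha) * ins
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!ins) / (G - sum(ins))
      sum(p_in - p_out)
    }, numeric(1))
    tibble::tibble(sample_id = s, signature = names(sets), score = unname(es))
  })
  res <- dplyr::bind_rows(out)
  if (normalize) {
    res <- dplyr::mutate(res,
      score = .data$score / (max(.data$score) - min(.data$score)),
      .by = "signature")
  }
  attr(res, "method") <- "ssgsea"
  attr(res, "alpha") <- alpha
  res
}

#' Marker-mean gene-set scores
#'
#' MCP-counter-style scoring: per sample and set, the arithmetic mean of the
#' markers' `log2(v + 1)` values. For the 13-gene TLS set this equals
#' [compute_tls_score()] exactly.
#'
#' @inheritParams ssgsea_score
#' @param min_present Minimum fraction of each set required to be present.
#' @return Score tibble: `sample_id`, `signature`, `score`.
#' @export
marker_mean_score <- function(expr, gene_sets, min_present = 0) {
  gene_sets <- as_gene_sets(gene_sets)
  res <- purrr::pmap(gene_sets, function(set, description, genes) {
    marker_score_impl(expr, genes, set, min_present, method = "marker_mean")
  })
  out <- dplyr::bind_rows(res)
  attr(out, "method") <- "marker_mean"
  out
}

#' Correlate two score tables
#'
#' Pairwise Spearman or Pearson correlation between the signatures of two
#' score tables over their shared samples, with two-sided p-values from the
#' t approximation. Pairs with fewer than 5 shared complete observations are
#' reported as NA.
#'
#' @param table_a,table_b Score tibbles (`sample_id`, `signature`, `score`).
#' @param method `"spearman"` or `"pearson"`.
#' @return Long tibble: `signature_a`, `signature_b`, `estimate`, `p_value`,
#'   `n`.
#' @export
score_correlation <- function(table_a, table_b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  wa <- score_wide(table_a)
  wb <- score_wide(table_b)
  shared <- intersect(rownames(wa), rownames(wb))
  if (length(shared) == 0L) abort("the two score tables share no samples")
  wa <- wa[shared, , drop = FALSE]
  wb <- wb[shared, , drop = FALSE]
  grid <- expand.grid(signature_a = colnames(wa), signature_b = colnames(wb),
                      stringsAsFactors = FALSE)
  res <- purrr::pmap(grid, function(signature_a, signature_b) {
    x <- wa[, signature_a]
    y <- wb[, signature_b]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 5L) {
      return(tibble::tibble(signature_a = signature_a, signature_b = signature_b,
                            estimate = NA_real_, p_value = NA_real_, n = n))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method, exact = FALSE))
    tibble::tibble(signature_a = signature_a, signature_b = signature_b,
                   estimate = unname(ct$estimate), p_value = ct$p.value, n = n)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "method") <- method
  out
}

# long score tibble -> samples x signatures matrix
score_wide <- function(scores) {
  stop_if_not_cols(scores, c("sample_id", "signature", "score"), "score table")
  wide <- tidyr::pivot_wider(scores[, c("sample_id", "signature", "score")],
                             names_from = "signature", values_from = "score")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}
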