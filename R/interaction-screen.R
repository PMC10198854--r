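#' Fit the per-gene TLS-interaction hazard model
#'
#' The model relates the hazard to `a*F + b*V + d*F*V` (plus a baseline
#' absorbed into the Cox baseline hazard, where the generating model's
#' intercept `c` lives): `F` is the focal score (TLS level) and `V` a gene's
#' expression. Both are z-standardized before fitting so `d` is comparable
#' across genes. A positive `d` means higher expression of the gene weakens
#' the association between the TLS level and better survival; a negative `d`
#' strengthens it.
#'
#' @param clinical Clinical tibble.
#' @param focal_scores Score tibble (`sample_id`, `score`) — typically the
#'   TLS score.
#' @param gene_values Named numeric vector (names = sample ids) of the gene's
#'   expression, or a one-row slice of an [expression_matrix()].
#' @param gene_id Label recorded in the output.
#' @param robust Use Lin-Wei robust standard errors (default TRUE; see
#'   [screen_genes()]).
#' @return One-row tibble: `gene_id`, `a`, `b`, `d`, their standard errors
#'   and Wald p-values, `converged`.
#' @export
fit_interaction_model <- function(clinical, focal_scores, gene_values,
                                  gene_id = "gene", robust = TRUE) {
  clinical <- validate_clinical(clinical)
  f <- align_scores(focal_scores, clinical$sample_id)
  v <- gene_values[clinical$sample_id]
  if (anyNA(v)) abort("gene expression is missing for some clinical samples")
  if (sd(v) < 1e-8) abort(sprintf("gene '%s' has near-zero variance", gene_id))
  fz <- as.numeric(scale(f))
  vz <- as.numeric(scale(v))
  X <- cbind(F = fz, V = vz, `F:V` = fz * vz)
  rownames(X) <- clinical$sample_id
  fit <- cox_fit(clinical, X, robust = robust)
  se <- if (robust && !is.null(fit$robust_se)) fit$robust_se else fit$se
  est <- fit$coefficients
  pv <- 2 * pnorm(-abs(est / se))
  tibble::tibble(gene_id = gene_id,
                 a = est[[1L]], b = est[[2L]], d = est[[3L]],
                 se_a = se[[1L]], se_b = se[[2L]], se_d = se[[3L]],
                 p_a = pv[[1L]], p_b = pv[[2L]], p_d = pv[[3L]],
                 converged = fit$converged)
}

align_scores <- function(focal_scores, sample_ids) {
  stop_if_not_cols(focal_scores, c("sample_id", "score"), "focal score table")
  idx <- match(sample_ids, focal_scores$sample_id)
  if (anyNA(idx)) abort("focal scores are missing for some clinical samples")
  setNames(focal_scores$score[idx], sample_ids)
}

#' Screen every gene for modulation of the TLS-survival association
#'
#' Applies [fit_interaction_model()] gene by gene, adjusts the interaction
#' p-values with Benjamini-Hochberg across genes, and classifies genes
#' passing both thresholds by the sign of `d`: `enhancer` (d < 0, the gene
#' strengthens the protective TLS association) or `reducer` (d > 0, it
#' weakens it); everything else is `null`. The raw-p-only preset
#' (`fdr_threshold = 1`) mirrors filtering on the interaction p-value alone.
#'
#' @param clinical Clinical tibble.
#' @param focal_scores Score tibble (`sample_id`, `score`).
#' @param expr An [expression_matrix()]; every row is tested. Genes with
#'   near-zero variance (SD < 1e-8) are skipped with a warning.
#' @param p_threshold Raw p-value threshold on `d` (default 0.05).
#' @param fdr_threshold BH threshold on `d` (default 1 = off).
#' @param robust Use Lin-Wei robust standard errors for the Wald tests
#'   (default TRUE). The per-gene model is a working model — other genes act
#'   on the hazard too — so sandwich variance keeps the null p-values
#'   calibrated under that unexplained heterogeneity.
#' @return A `tls_screen` tibble: per gene `a`, `b`, `d`, `se_d`, `p_d`,
#'   `q_d`, `class`, `converged`; attributes `thresholds` and `counts`.
#' @export
screen_genes <- function(clinical, focal_scores, expr,
                         p_threshold = 0.05, fdr_threshold = 1.0,
                         robust = TRUE) {
  if (p_threshold <= 0 || p_threshold > 1 || fdr_threshold <= 0 || fdr_threshold > 1) {
    abort("thresholds must lie in (0, 1]")
  }
  clinical <- validate_clinical(clinical)
  f <- align_scores(focal_scores, clinical$sample_id)
  lv <- expr_log2(expr)[, clinical$sample_id, drop = FALSE]
  sds <- apply(lv, 1L, sd)
  skip <- sds < 1e-8
  if (any(skip)) {
    warn(sprintf("%d near-constant gene(s) skipped", sum(skip)))
  }
  genes <- rownames(lv)[!skip]
  if (length(genes) == 0L) abort("no genes with non-zero variance to screen")
  fz <- as.numeric(scale(f))
  surv <- clinical[, c("sample_id", "time", "event")]
  fits <- purrr::map(genes, function(g) {
    vz <- as.numeric(scale(lv[g, ]))
    X <- cbind(F = fz, V = vz, `F:V` = fz * vz)
    rownames(X) <- clinical$sample_id
    fit <- tryCatch(suppressWarnings(cox_fit(surv, X, robust = robust)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(gene_id = g, a = NA_real_, b = NA_real_, d = NA_real_,
                            se_d = NA_real_, p_d = NA_real_, converged = FALSE))
    }
    se <- if (robust && !is.null(fit$robust_se)) fit$robust_se else fit$se
    est <- fit$coefficients
    tibble::tibble(gene_id = g, a = est[[1L]], b = est[[2L]], d = est[[3L]],
                   se_d = se[[3L]],
                   p_d = 2 * pnorm(-abs(est[[3L]] / se[[3L]])),
                   converged = fit$converged)
  })
  res <- dplyr::bind_rows(fits)
  if (!any(res$converged)) abort("no interaction fit converged")
  res$q_d <- NA_real_
  ok <- res$converged & is.finite(res$p_d)
  res$q_d[ok] <- p.adjust(res$p_d[ok], method = "BH")
  pass <- ok & res$p_d <= p_threshold & res$q_d <= fdr_threshold
  res$class <- ifelse(!pass, "null", ifelse(res$d < 0, "enhancer", "reducer"))
  res$class[!res$converged] <- NA_character_
  attr(res, "thresholds") <- c(p = p_threshold, fdr = fdr_threshold)
  attr(res, "counts") <- table(factor(res$class, levels = c("enhancer", "reducer", "null")))
  class(res) <- c("tls_screen", class(res))
  res
}

#' Aggregate score over a screened modulator gene class
#'
#' Per sample, the mean z-standardized log2 expression over the genes of the
#' requested class.
#'
#' @param expr An [expression_matrix()].
#' @param screen_result A `tls_screen` ([screen_genes()]).
#' @param direction `"enhancer"` or `"reducer"`.
#' @return Score tibble (`sample_id`, `signature`, `score`).
#' @export
modulator_score <- function(expr, screen_result, direction = c("enhancer", "reducer")) {
  direction <- match.arg(direction)
  genes <- screen_result$gene_id[!is.na(screen_result$class) &
                                   screen_result$class == direction]
  genes <- intersect(genes, rownames(expr))
  if (length(genes) == 0L) {
    abort(sprintf("no gene of class '%s' in the screen result", direction))
  }
  lv <- expr_log2(expr)[genes, , drop = FALSE]
  z <- t(scale(t(lv)))
  tibble::tibble(sample_id = colnames(expr),
                 signature = paste0("modulator_", direction),
                 score = unname(colMeans(z)))
}
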