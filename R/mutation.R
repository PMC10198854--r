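#' Tumor mutational burden per sample
#'
#' TMB is the raw count of nonsynonymous records per sample (no per-megabase
#' normalization); duplicated (sample, gene, class) records count once, and
#' roster samples without any record get count 0.
#'
#' @param maf MAF tibble (`sample_id`, `gene_id`, `variant_classification`).
#' @param cohort_samples Character vector: the full sample roster.
#' @param nonsyn_classes Classes counted as nonsynonymous
#'   ([default_nonsyn_classes()]).
#' @return Tibble `sample_id`, `tmb`.
#' @export
compute_tmb <- function(maf, cohort_samples,
                        nonsyn_classes = default_nonsyn_classes()) {
  if (length(cohort_samples) == 0L) abort("the cohort roster must be non-empty")
  if (length(nonsyn_classes) == 0L) abort("nonsyn_classes must be non-empty")
  stop_if_not_cols(maf, c("sample_id", "gene_id", "variant_classification"), "MAF table")
  rec <- dplyr::distinct(maf, .data$sample_id, .data$gene_id,
                         .data$variant_classification)
  rec <- rec[rec$variant_classification %in% nonsyn_classes, , drop = FALSE]
  counts <- table(factor(rec$sample_id, levels = unique(cohort_samples)))
  tibble::tibble(sample_id = names(counts), tmb = as.integer(counts))
}

#' Per-gene mutation frequency by group
#'
#' A sample counts as mutated in a gene when it carries at least one
#' nonsynonymous record for it (binary status; multi-hit samples count once).
#' When exactly two groups are present, a two-sided Fisher exact test per
#' gene with BH adjustment across genes is added.
#'
#' @param maf MAF tibble.
#' @param group_labels Tibble `sample_id`, `group`; the group table defines
#'   the sample roster (its sizes are the frequency denominators).
#' @param nonsyn_classes Classes counted as nonsynonymous.
#' @return Long tibble: `gene_id`, `group`, `n_mutated`, `group_size`,
#'   `frequency`; with exactly two groups, `p_value` and `q_value` columns
#'   (repeated across the gene's rows) are appended.
#' @export
mutation_frequency_by_group <- function(maf, group_labels,
                                        nonsyn_classes = default_nonsyn_classes()) {
  stop_if_not_cols(maf, c("sample_id", "gene_id", "variant_classification"), "MAF table")
  stop_if_not_cols(group_labels, c("sample_id", "group"), "group labels")
  gl <- group_labels[!is.na(group_labels$group), , drop = FALSE]
  gl$group <- as.character(gl$group)
  sizes <- table(gl$group)
  if (any(sizes == 0L) || nrow(gl) == 0L) abort("every group must be non-empty")
  rec <- maf[maf$variant_classification %in% nonsyn_classes, , drop = FALSE]
  rec <- dplyr::distinct(rec, .data$sample_id, .data$gene_id)
  rec <- dplyr::inner_join(rec, gl, by = "sample_id")
  genes <- sort(unique(rec$gene_id))
  grid <- tidyr::expand_grid(gene_id = genes, group = names(sizes))
  cnt <- dplyr::count(rec, .data$gene_id, .data$group, name = "n_mutated")
  out <- dplyr::left_join(grid, cnt, by = c("gene_id", "group"))
  out$n_mutated[is.na(out$n_mutated)] <- 0L
  out$group_size <- as.integer(sizes[out$group])
  out$frequency <- out$n_mutated / out$group_size
  if (length(sizes) == 2L && length(genes) > 0L) {
    g1 <- names(sizes)[1L]
    g2 <- names(sizes)[2L]
    tests <- vapply(genes, function(g) {
      a <- out$n_mutated[out$gene_id == g & out$group == g1]
      b <- out$n_mutated[out$gene_id == g & out$group == g2]
      tab <- matrix(c(a, sizes[[g1]] - a, b, sizes[[g2]] - b), nrow = 2L)
      fisher.test(tab)$p.value
    }, numeric(1))
    qv <- p.adjust(tests, method = "BH")
    out$p_value <- tests[out$gene_id]
    out$q_value <- qv[out$gene_id]
  }
  out
}

#' Split a cohort into TMB-high and TMB-low groups
#'
#' `median` split: strictly above the median is TMB-hi, the rest TMB-low.
#' `quartile` split: strictly above Q3 is TMB-hi, strictly below Q1 TMB-low,
#' the rest TMB-inter. Quantiles are type-7, consistent with the TLS score
#' stratification.
#'
#' @param tmb Tibble `sample_id`, `tmb` ([compute_tmb()]).
#' @param clinical Optional clinical tibble; when given, the output is
#'   restricted to its samples.
#' @param split `"median"` or `"quartile"`.
#' @return Tibble `sample_id`, `tmb`, `group`; attribute `thresholds`.
#' @export
tmb_survival_groups <- function(tmb, clinical = NULL, split = c("median", "quartile")) {
  split <- match.arg(split)
  stop_if_not_cols(tmb, c("sample_id", "tmb"), "TMB table")
  if (!is.null(clinical)) {
    tmb <- tmb[tmb$sample_id %in% clinical$sample_id, , drop = FALSE]
  }
  x <- tmb$tmb
  if (diff(range(x)) == 0) {
    warn("constant TMB: every sample falls in a single class")
  }
  if (split == "median") {
    thr <- c(median = median(x))
    grp <- ifelse(x > thr, "TMB-hi", "TMB-low")
  } else {
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    thr <- c(Q1 = q[1L], Q3 = q[2L])
    grp <- ifelse(x > q[2L], "TMB-hi", ifelse(x < q[1L], "TMB-low", "TMB-inter"))
  }
  out <- tibble::tibble(sample_id = tmb$sample_id, tmb = x, group = grp)
  attr(out, "thresholds") <- thr
  out
}
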