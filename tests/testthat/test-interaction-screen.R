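# shared small cohort with one planted protective factor and one modulator
make_screen_cohort <- function(n = 600, seed = 2, d_genes = c(MODN01 = -0.5)) {
  spec <- cohort_spec(
    n_samples = n, n_genes = 60, seed = seed,
    hazard_coeffs = list(a = -0.7, b = setNames(numeric(0), character(0)),
                         d = d_genes, c = log(0.1)))
  sim <- simulate_expression(spec)
  clin <- simulate_survival(sim$latent_tls, sim$expression,
                            spec$hazard_coeffs, 0.25, seed = seed)
  list(spec = spec, sim = sim, clin = clin,
       scores = compute_tls_score(sim$expression))
}

test_that("a planted interaction gene is recovered with the right sign", {
  co <- make_screen_cohort()
  v <- unclass(co$sim$expression)["MODN01", ]
  fit <- fit_interaction_model(co$clin, co$scores, v, "MODN01")
  expect_lt(fit$d, 0)
  expect_lt(fit$p_d, 0.05)
  # protective focal score: a-hat negative
  expect_lt(fit$a, 0)

  # V identical to F: collinear design must error, never misreport
  f_as_gene <- setNames(co$scores$score, co$scores$sample_id)
  expect_error(fit_interaction_model(co$clin, co$scores, f_as_gene, "self"),
               "collinear")
  # near-constant gene refused
  const <- setNames(rep(2, nrow(co$clin)), co$clin$sample_id)
  expect_error(fit_interaction_model(co$clin, co$scores, const, "flat"),
               "variance")
})

test_that("null interaction p-values are uniform on a clean cohort", {
  spec <- clean_spec(n_samples = 600, n_genes = 220, seed = 6)
  sim <- simulate_expression(spec)
  clin <- simulate_survival(sim$latent_tls, sim$expression,
                            spec$hazard_coeffs, 0.25, seed = 6)
  scores <- compute_tls_score(sim$expression)
  scr <- screen_genes(clin, scores, sim$expression)
  nulls <- scr[!scr$gene_id %in% tls_signature_genes(), ]
  expect_gte(nrow(nulls), 200L)
  expect_lt(abs(mean(nulls$d)), 0.05)
  ks <- suppressWarnings(ks.test(nulls$p_d, "punif"))
  expect_lt(unname(ks$statistic), 1.358 / sqrt(nrow(nulls)))  # 5% critical value
})

test_that("screen classification follows thresholds, sign rules and order invariance", {
  co <- make_screen_cohort(n = 400, seed = 9,
                           d_genes = c(MODN01 = -0.5, MODP01 = 0.5))
  scr <- screen_genes(co$clin, co$scores, co$sim$expression,
                      p_threshold = 0.05, fdr_threshold = 1)
  expect_equal(scr$class[scr$gene_id == "MODN01"], "enhancer")
  expect_equal(scr$class[scr$gene_id == "MODP01"], "reducer")
  counts <- attr(scr, "counts")
  expect_equal(sum(counts), sum(!is.na(scr$class)))

  # threshold degeneracy: everything converged is classified by sign
  all_in <- screen_genes(co$clin, co$scores, co$sim$expression,
                         p_threshold = 1, fdr_threshold = 1)
  conv <- all_in[all_in$converged, ]
  expect_true(all(conv$class == ifelse(conv$d < 0, "enhancer", "reducer")))

  # gene and sample order invariance
  ex_shuf <- co$sim$expression[sample(nrow(co$sim$expression)),
                               sample(ncol(co$sim$expression))]
  scr2 <- screen_genes(co$clin, co$scores, ex_shuf,
                       p_threshold = 0.05, fdr_threshold = 1)
  merged <- dplyr::inner_join(as.data.frame(scr)[, c("gene_id", "d", "p_d")],
                              as.data.frame(scr2)[, c("gene_id", "d", "p_d")],
                              by = "gene_id")
  expect_equal(merged$d.x, merged$d.y, tolerance = 1e-10)

  # constant focal score: degenerate, not silently misclassified
  flat <- tibble::tibble(sample_id = co$scores$sample_id, score = 1)
  expect_error(suppressWarnings(screen_genes(co$clin, flat, co$sim$expression)))
})

test_that("modulator scores aggregate screened classes faithfully", {
  co <- make_screen_cohort(n = 400, seed = 9,
                           d_genes = c(MODN01 = -0.5, MODP01 = 0.5))
  scr <- screen_genes(co$clin, co$scores, co$sim$expression)
  enh <- modulator_score(co$sim$expression, scr, "enhancer")
  genes_enh <- scr$gene_id[!is.na(scr$class) & scr$class == "enhancer"]
  if (length(genes_enh) == 1L) {
    # single-gene class: score equals that gene's standardized expression
    z <- as.numeric(scale(unclass(co$sim$expression)[genes_enh, ]))
    expect_equal(enh$score, z)
  }
  expect_equal(nrow(enh), ncol(co$sim$expression))

  # enhancer and reducer summaries are near-orthogonal by construction
  red <- modulator_score(co$sim$expression, scr, "reducer")
  expect_lt(abs(cor(enh$score, red$score)), 0.15)

  none <- scr
  none$class[none$class == "reducer"] <- "null"
  expect_error(modulator_score(co$sim$expression, none, "reducer"), "no gene")
})
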