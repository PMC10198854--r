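test_that("TLS score equals the log2 geometric mean with +1 shift", {
  # all 13 genes at linear value 7 -> log2(8) = 3
  m <- matrix(7, nrow = 13, ncol = 2)
  ex <- toy_expr(m, genes = tls_signature_genes(), samples = c("a", "b"))
  sc <- compute_tls_score(ex)
  expect_equal(sc$score, c(3, 3))

  # two genes at linear 1 and 7 -> (log2 2 + log2 8) / 2 = 2
  m2 <- matrix(c(1, 7), nrow = 2, ncol = 1)
  ex2 <- toy_expr(m2, genes = c("CCL2", "CCL3"))
  sc2 <- suppressWarnings(compute_tls_score(ex2, c("CCL2", "CCL3"), min_present = 1))
  expect_equal(sc2$score, 2)

  # order invariance over genes and samples
  spec <- cohort_spec(n_samples = 30, n_genes = 40, seed = 8)
  ex3 <- simulate_expression(spec)$expression
  s1 <- compute_tls_score(ex3)
  shuf <- ex3[sample(nrow(ex3)), sample(ncol(ex3))]
  s2 <- compute_tls_score(shuf)
  merged <- dplyr::inner_join(s1, s2, by = "sample_id")
  expect_equal(merged$score.x, merged$score.y)

  # missing-gene policy: proceeds at >= 70%, errors below, warns when missing
  ex4 <- ex3[setdiff(rownames(ex3), c("CCL2", "CCL3")), ]
  expect_warning(compute_tls_score(ex4), "missing")
  ex5 <- ex3[tls_signature_genes()[1:5], ]
  expect_error(compute_tls_score(ex5), "70%")
})

test_that("doubling a sample's signature genes raises its score by at most one log2 unit", {
  set.seed(2)
  m <- matrix(runif(13 * 4, 5, 50), nrow = 13)
  ex <- toy_expr(m, genes = tls_signature_genes())
  base <- compute_tls_score(ex)$score
  m2 <- m
  m2[, 1] <- m2[, 1] * 2
  doubled <- compute_tls_score(toy_expr(m2, genes = tls_signature_genes()))$score
  expect_lt(doubled[1] - base[1], 1)
  expect_gt(doubled[1] - base[1], 0.9)  # values >> 1, nearly exact
  expect_equal(doubled[-1], base[-1])

  # large values: exactly 1 in the limit
  m3 <- matrix(2^20, 13, 1)
  ex3 <- toy_expr(m3, genes = tls_signature_genes())
  ex4 <- toy_expr(m3 * 2, genes = tls_signature_genes())
  expect_equal(compute_tls_score(ex4)$score - compute_tls_score(ex3)$score, 1,
               tolerance = 1e-5)
})

test_that("quartile stratification follows the type-7 thresholds in both modes", {
  sc <- tibble::tibble(sample_id = paste0("p", 1:8), signature = "TLS", score = 1:8)
  two <- stratify_by_quartile(sc, mode = "two_class_q3")
  expect_equal(unname(attr(two, "thresholds")["Q3"]), 6.25)
  expect_setequal(two$sample_id[two$tls_class == "hi"], c("p7", "p8"))

  three <- stratify_by_quartile(sc, mode = "three_class")
  thr <- attr(three, "thresholds")
  expect_equal(unname(thr), c(2.75, 6.25))
  expect_setequal(three$sample_id[three$tls_class == "TLS-low"], c("p1", "p2"))
  expect_setequal(three$sample_id[three$tls_class == "TLS-hi"], c("p7", "p8"))
  expect_equal(sum(three$tls_class == "TLS-inter"), 4L)
  expect_equal(nrow(three), 8L)

  # degenerate input: all equal scores -> single class, with a warning
  flat <- tibble::tibble(sample_id = paste0("p", 1:6), score = rep(2, 6))
  expect_warning(res <- stratify_by_quartile(flat, mode = "two_class_q3"),
                 "constant")
  expect_true(all(res$tls_class == "low"))
  expect_error(stratify_by_quartile(flat[1:3, ]), "at least 4")
})

test_that("score captures the latent TLS factor on the default cohort structure", {
  spec <- cohort_spec(n_samples = 400, n_genes = 60, seed = 21)
  sim <- simulate_expression(spec)
  sc <- compute_tls_score(sim$expression)
  expect_gt(cor(sc$score, sim$latent_tls, method = "spearman"), 0.9)
})

test_that("two-group score comparisons match exact rank-sum probabilities", {
  sc <- tibble::tibble(sample_id = paste0("p", 1:6), score = c(1, 2, 3, 4, 5, 6))
  gl <- groups_tbl(sc$sample_id, rep(c("a", "b"), each = 3))  # a = {1,2,3}
  res <- compare_score_by_group(sc, gl, test = "wilcoxon", alternative = "less")
  expect_equal(res$p_value, 1 / 20)  # exact enumeration over C(6,3) arrangements

  tied <- tibble::tibble(sample_id = paste0("p", 1:4), score = rep(5, 4))
  gl2 <- groups_tbl(tied$sample_id, c("a", "a", "b", "b"))
  expect_warning(res2 <- compare_score_by_group(tied, gl2), "constant")
  expect_equal(res2$p_value, 1)

  # response-linked cohort: CR scores exceed PD scores by construction
  f <- setNames(rnorm(200), sprintf("s%03d", 1:200))
  resp <- simulate_response(f, response_shift = 2, seed = 3)
  sc3 <- tibble::tibble(sample_id = names(f), score = as.numeric(f))
  gl3 <- groups_tbl(resp$sample_id, as.character(resp$response))
  gl3 <- gl3[gl3$group %in% c("CR", "PD"), ]
  res3 <- compare_score_by_group(sc3, gl3)
  expect_gt(res3$median1, res3$median2)  # CR before PD alphabetically
  expect_error(compare_score_by_group(sc3, gl3[gl3$group == "CR", ]),
               "two non-empty groups")
})

test_that("signature coherence flags a gene anti-correlated with the rest", {
  set.seed(5)
  f <- rnorm(120)
  m <- rbind(t(sapply(1:5, function(i) 4 + f + rnorm(120, sd = 0.3))),
             4 - f + rnorm(120, sd = 0.3))
  ex <- toy_expr(m, scale = "log2p1", genes = c(paste0("ok", 1:5), "BCL6like"))
  rep <- check_signature_coherence(ex, rownames(ex))
  expect_true(rep$flagged[rep$gene_id == "BCL6like"])
  expect_false(any(rep$flagged[rep$gene_id != "BCL6like"]))
})
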