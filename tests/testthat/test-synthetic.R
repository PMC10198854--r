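test_that("expression simulation is seed-deterministic and respects the latent factor", {
  spec <- cohort_spec(n_samples = 50, n_genes = 30, seed = 4)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(unclass(a$expression), unclass(b$expression))
  expect_identical(a$latent_tls, b$latent_tls)

  # null effect: signature genes uncorrelated with the factor on average
  rs <- unlist(lapply(1:50, function(s) {
    sp <- cohort_spec(n_samples = 40, n_genes = 20, tls_effect = 0, seed = s)
    sim <- simulate_expression(sp)
    lv <- unclass(sim$expression)
    vapply(intersect(tls_signature_genes(), rownames(lv)),
           function(g) cor(lv[g, ], sim$latent_tls), numeric(1))
  }))
  expect_lt(abs(mean(rs)), 0.05)

  # analytic correlation r = effect / sqrt(effect^2 + noise^2) ~ 0.894
  sp <- cohort_spec(n_samples = 400, n_genes = 50, tls_effect = 1,
                    noise_sd = 0.5, seed = 9)
  sim <- simulate_expression(sp)
  lv <- unclass(sim$expression)
  r_sig <- vapply(tls_signature_genes(), function(g) cor(lv[g, ], sim$latent_tls),
                  numeric(1))
  expect_true(all(r_sig > 0.8))
  expect_equal(mean(r_sig), 1 / sqrt(1 + 0.5^2), tolerance = 0.05)

  expect_error(cohort_spec(n_genes = 5), "smaller than the signature")
})

test_that("survival times follow the null exponential law and recover coefficients", {
  # all coefficients zero: times are exponential(exp(c))
  spec <- clean_spec(n_samples = 2000, a = 0, seed = 3, censoring_rate = 0)
  sim <- simulate_expression(spec)
  clin <- simulate_survival(sim$latent_tls, sim$expression,
                            spec$hazard_coeffs, 0, seed = 3)
  expect_true(all(clin$event == 1))
  ks <- suppressWarnings(ks.test(clin$time, "pexp", rate = exp(log(0.1))))
  # 1% critical value for the KS statistic at n = 2000
  expect_lt(unname(ks$statistic), 1.63 / sqrt(2000))

  # protective focal coefficient recovered within +/- 0.15 at n = 1000
  spec <- clean_spec(n_samples = 1000, a = -0.7, seed = 11)
  sim <- simulate_expression(spec)
  clin <- simulate_survival(sim$latent_tls, sim$expression,
                            spec$hazard_coeffs, 0.25, seed = 11)
  fit <- cox_fit(clin, tibble::tibble(sample_id = names(sim$latent_tls),
                                      f = as.numeric(sim$latent_tls)))
  expect_equal(unname(fit$coefficients), -0.7, tolerance = 0.15 / 0.7)

  expect_error(simulate_survival(sim$latent_tls, sim$expression,
                                 spec$hazard_coeffs, 1.0), "censoring_rate")
})

test_that("mutation simulation hits its per-group frequencies", {
  groups <- groups_tbl(sprintf("s%03d", 1:1000),
                       rep(c("A", "B"), each = 500))
  freqs <- tibble::tibble(group = c("A", "A", "B", "B"),
                          gene_id = c("X", "Y", "X", "Y"),
                          frequency = c(1.0, 0.22, 0.0, 0.10))
  maf <- simulate_mutations(groups, freqs, seed = 2)
  # frequency 1 means every group-A sample carries an X record
  x_a <- unique(maf$sample_id[maf$gene_id == "X"])
  expect_setequal(x_a, groups$sample_id[groups$group == "A"])
  fy <- function(g) {
    length(unique(maf$sample_id[maf$gene_id == "Y" &
      maf$sample_id %in% groups$sample_id[groups$group == g]])) / 500
  }
  expect_equal(fy("A"), 0.22, tolerance = 0.04 / 0.22)
  expect_equal(fy("B"), 0.10, tolerance = 0.04 / 0.10)

  # zero frequency everywhere: empty table
  freqs0 <- dplyr::mutate(freqs, frequency = 0)
  expect_equal(nrow(simulate_mutations(groups, freqs0, seed = 2)), 0L)
  expect_error(simulate_mutations(groups, dplyr::mutate(freqs, frequency = 2)),
               "\\[0, 1\\]")
})

test_that("ordinal response labels track the latent factor", {
  f <- setNames(rnorm(5000), sprintf("s%04d", 1:5000))
  base <- c(CR = 0.10, PR = 0.20, SD = 0.30, PD = 0.40)
  r0 <- simulate_response(f, response_shift = 0, response_base = base, seed = 6)
  freq <- as.numeric(table(r0$response) / 5000)
  expect_true(all(abs(freq - base) < 0.03))

  # stochastic dominance: CR group has larger mean latent factor than PD
  dominates <- vapply(1:20, function(s) {
    fs <- setNames(rnorm(300), sprintf("s%03d", 1:300))
    r <- simulate_response(fs, response_shift = 2, seed = s)
    mean(fs[r$response == "CR"]) > mean(fs[r$response == "PD"])
  }, logical(1))
  expect_true(all(dominates))

  one <- simulate_response(setNames(0.3, "only"), 1, seed = 1)
  expect_equal(nrow(one), 1L)
})

test_that("a full cohort is internally consistent and byte-stable", {
  spec <- cohort_spec(n_samples = 80, n_genes = 60, seed = 5)
  co <- simulate_cohort(spec)
  ids <- colnames(co$expression)
  expect_identical(co$clinical$sample_id, ids)
  expect_identical(names(co$latent_tls), ids)
  expect_true(all(co$maf$sample_id %in% ids))
  expect_identical(co$truth, spec)

  co2 <- simulate_cohort(spec)
  expect_identical(co$clinical, co2$clinical)
  expect_identical(co$maf, co2$maf)
  expect_identical(unclass(co$expression), unclass(co2$expression))
})
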