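test_that("Kaplan-Meier product-limit values match hand computation", {
  clin <- toy_clinical(time = 1:5, event = c(0, 1, 1, 0, 1))
  km <- km_estimate(clin)
  s_at <- function(t) km$survival[km$time == t]
  expect_equal(s_at(1), 1)        # censoring only
  expect_equal(s_at(2), 0.75)     # 3/4
  expect_equal(s_at(3), 0.5)      # x 2/3
  expect_equal(s_at(5), 0)        # x 0/1

  # all censored: flat at 1
  expect_warning(flat <- km_estimate(toy_clinical(1:4, rep(0, 4))), "no events")
  expect_true(all(flat$survival == 1))

  # simultaneous death of everyone: S drops to 0 at that time
  all_die <- km_estimate(toy_clinical(rep(3, 6), rep(1, 6)))
  expect_equal(all_die$survival, 0)

  # no censoring: KM equals the empirical survival function
  set.seed(1)
  t <- sample(100, 30)
  km2 <- km_estimate(toy_clinical(t, rep(1, 30)))
  emp <- vapply(km2$time, function(x) mean(t > x), numeric(1))
  expect_equal(km2$survival, emp)

  # S is non-increasing and within [0, 1]
  expect_true(all(diff(km2$survival) <= 0))
  expect_true(all(km2$survival >= 0 & km2$survival <= 1))
})

test_that("log-rank matches a brute-force O/E/V accumulation and symmetries", {
  # fully separated groups
  clin <- toy_clinical(c(1, 2, 3, 4, 5, 6), rep(1, 6))
  gl <- groups_tbl(clin$sample_id, rep(c("A", "B"), each = 3))
  res <- logrank_test(clin, gl)
  ref <- brute_logrank_2g(clin$time, clin$event, gl$group)
  expect_equal(res$statistic, ref, tolerance = 1e-9)

  # random fixtures against the brute-force oracle
  set.seed(8)
  for (i in 1:5) {
    n <- 40
    clin2 <- toy_clinical(round(rexp(n, 0.1), 1) + 0.1, rbinom(n, 1, 0.7))
    gl2 <- groups_tbl(clin2$sample_id, sample(c("A", "B"), n, TRUE))
    expect_equal(logrank_test(clin2, gl2)$statistic,
                 brute_logrank_2g(clin2$time, clin2$event, gl2$group),
                 tolerance = 1e-9)
  }

  # identical groups: chi-square 0, p = 1
  dup <- toy_clinical(c(1:5, 1:5), rep(c(0, 1, 1, 0, 1), 2),
                      ids = paste0("p", 1:10))
  gdup <- groups_tbl(dup$sample_id, rep(c("A", "B"), each = 5))
  same <- logrank_test(dup, gdup)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  # invariance to strictly increasing time relabeling
  relab <- dup
  relab$time <- exp(relab$time)
  expect_equal(logrank_test(relab, gdup)$statistic, same$statistic)

  # observed and expected totals balance; df = k - 1 for 3 groups
  clin3 <- toy_clinical(round(rexp(30, 0.2), 2) + 0.01, rbinom(30, 1, 0.8),
                        ids = paste0("q", 1:30))
  gl3 <- groups_tbl(clin3$sample_id, rep(c("A", "B", "C"), each = 10))
  res3 <- logrank_test(clin3, gl3)
  counts <- attr(res3, "counts")
  expect_equal(sum(counts$observed), sum(counts$expected), tolerance = 1e-9)
  expect_equal(res3$df, 2L)
})

test_that("log-rank equals the squared Cox score statistic for a binary group", {
  set.seed(42)
  for (i in 1:10) {
    n <- 50
    clin <- toy_clinical(rexp(n, 0.1), rbinom(n, 1, 0.7))  # continuous: no ties
    g <- rbinom(n, 1, 0.5)
    gl <- groups_tbl(clin$sample_id, ifelse(g == 1, "hi", "lo"))
    lr <- logrank_test(clin, gl)
    sc <- cox_score_test(clin, tibble::tibble(sample_id = clin$sample_id, g = g))
    expect_equal(lr$statistic, sc$statistic, tolerance = 1e-6)
  }
})

test_that("Cox fits agree with an established implementation under Efron ties", {
  skip_if_not_installed("survival")
  set.seed(12)
  # 20-subject fixture with heavy ties
  clin <- toy_clinical(time = rep(c(2, 5, 7, 9), each = 5),
                       event = rbinom(20, 1, 0.75))
  X <- tibble::tibble(sample_id = clin$sample_id,
                      x1 = rnorm(20), x2 = rbinom(20, 1, 0.4))
  fit <- cox_fit(clin, X)
  ref <- survival::coxph(survival::Surv(clin$time, clin$event) ~ X$x1 + X$x2,
                         ties = "efron")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  expect_equal(unname(fit$loglik["final"]), ref$loglik[2], tolerance = 1e-4)

  fitb <- cox_fit(clin, X, ties = "breslow")
  refb <- survival::coxph(survival::Surv(clin$time, clin$event) ~ X$x1 + X$x2,
                          ties = "breslow")
  expect_equal(unname(fitb$coefficients), unname(coef(refb)), tolerance = 1e-4)

  # robust sandwich variance against coxph(robust = TRUE) on untied data
  clin2 <- toy_clinical(rexp(50, 0.1), rbinom(50, 1, 0.7))
  X2 <- tibble::tibble(sample_id = clin2$sample_id, z = rnorm(50))
  fr <- cox_fit(clin2, X2, robust = TRUE)
  rr <- survival::coxph(survival::Surv(clin2$time, clin2$event) ~ X2$z,
                        robust = TRUE)
  expect_equal(unname(fr$robust_se), unname(sqrt(diag(rr$var))), tolerance = 1e-8)
})

test_that("Cox estimates behave under symmetry, shifts and rescaling", {
  # duplicated data with opposite arms: beta ~ 0
  dup <- toy_clinical(c(1:6, 1:6), rep(c(1, 1, 0, 1, 0, 1), 2),
                      ids = paste0("p", 1:12))
  arm <- tibble::tibble(sample_id = dup$sample_id, g = rep(c(0, 1), each = 6))
  fit <- cox_fit(dup, arm)
  expect_lt(abs(unname(fit$coefficients)), 1e-6)

  set.seed(3)
  clin <- toy_clinical(rexp(80, 0.1), rbinom(80, 1, 0.8))
  x <- rnorm(80)
  f0 <- cox_fit(clin, tibble::tibble(sample_id = clin$sample_id, x = x))
  # shift invariance
  f1 <- cox_fit(clin, tibble::tibble(sample_id = clin$sample_id, x = x + 100))
  expect_equal(unname(f0$coefficients), unname(f1$coefficients), tolerance = 1e-8)
  expect_equal(unname(f0$loglik), unname(f1$loglik), tolerance = 1e-8)
  # scale equivariance
  f2 <- cox_fit(clin, tibble::tibble(sample_id = clin$sample_id, x = 3 * x))
  expect_equal(unname(f0$coefficients), 3 * unname(f2$coefficients),
               tolerance = 1e-8)

  # loglik at optimum is at least the null loglik
  expect_gte(f0$loglik[["final"]], f0$loglik[["null"]])

  # parameter recovery: true log-hazard 0.7 at n = 500
  set.seed(77)
  z <- rnorm(500)
  t_ev <- rexp(500, rate = exp(0.7 * z) * 0.1)
  cens <- rexp(500, 0.03)
  clin5 <- toy_clinical(pmin(t_ev, cens), as.numeric(t_ev <= cens),
                        ids = sprintf("r%03d", 1:500))
  f5 <- cox_fit(clin5, tibble::tibble(sample_id = clin5$sample_id, z = z))
  expect_gt(unname(f5$coefficients), 0.55)
  expect_lt(unname(f5$coefficients), 0.85)

  # binary covariate sign agrees with which KM curve is lower
  gl <- groups_tbl(clin5$sample_id, ifelse(z > 0, "hiZ", "loZ"))
  km <- km_estimate(clin5, gl)
  min_s <- tapply(km$survival, km$group, min)
  expect_true(min_s[["hiZ"]] < min_s[["loZ"]])  # consistent with beta > 0

  # degenerate covariates
  cc <- tibble::tibble(sample_id = clin$sample_id, x = x, const = 1)
  expect_warning(fc <- cox_fit(clin, cc), "constant")
  expect_equal(unname(fc$coefficients), unname(f0$coefficients), tolerance = 1e-10)
  col <- tibble::tibble(sample_id = clin$sample_id, x = x, x2 = 2 * x)
  expect_error(cox_fit(clin, col), "collinear")
})

test_that("univariate and multivariate screens produce coherent hazard tables", {
  spec <- clean_spec(n_samples = 300, seed = 14, n_genes = 20)
  sim <- simulate_expression(spec)
  clin <- simulate_survival(sim$latent_tls, sim$expression,
                            spec$hazard_coeffs, 0.25, seed = 14)
  covs <- tibble::tibble(sample_id = clin$sample_id,
                         tls = as.numeric(sim$latent_tls),
                         stage = sample(c("I", "II", "III"), 300, TRUE))

  # single binary covariate: univariate equals multivariate
  single <- tibble::tibble(sample_id = clin$sample_id,
                           arm = rbinom(300, 1, 0.5))
  both <- survival_screen(clin, single)
  uni <- both[both$mode == "univariate", ]
  multi <- both[both$mode == "multivariate", ]
  expect_equal(uni$hr, multi$hr, tolerance = 1e-10)

  res <- survival_screen(clin, covs)
  expect_true(all(res$conf_low <= res$hr & res$hr <= res$conf_high))
  # protective latent factor detected in both modes
  tls_rows <- res[res$covariate == "tls", ]
  expect_true(all(tls_rows$hr < 1))
  expect_true(all(tls_rows$p_value < 0.05))
  # reference coding: stage contributes (levels - 1) terms per mode
  expect_equal(sum(res$covariate == "stage" & res$mode == "multivariate"), 2L)
})
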