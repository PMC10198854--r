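# in-code fixtures and independent oracles shared across test files

toy_expr <- function(values, scale = "linear",
                     genes = sprintf("g%d", seq_len(nrow(values))),
                     samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, scale = scale)
}

toy_clinical <- function(time, event, ids = sprintf("p%d", seq_along(time))) {
  tibble::tibble(sample_id = ids, time = time, event = event)
}

groups_tbl <- function(ids, group) tibble::tibble(sample_id = ids, group = group)

# adjusted Rand index, written independently of any clustering code
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# best bijective matching of clusters to references by profile correlation
# (brute force over permutations; k <= 6)
best_profile_match <- function(profiles, centers) {
  k <- nrow(centers)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- -Inf
  best_cors <- NULL
  for (p in perms(seq_len(k))) {
    cors <- vapply(seq_len(k), function(i) cor(profiles[i, ], centers[p[i], ]),
                   numeric(1))
    if (sum(cors) > best) {
      best <- sum(cors)
      best_cors <- cors
    }
  }
  best_cors
}

# restricted mean survival per group from a km_estimate tibble (area under
# the step curve up to a shared horizon); robust summary of which curve is low
km_rmst <- function(km, horizon = min(tapply(km$time, km$group, max))) {
  vapply(split(km, km$group), function(g) {
    tt <- c(0, g$time[g$time <= horizon], horizon)
    ss <- c(1, g$survival[g$time <= horizon])
    sum(diff(tt) * ss)
  }, numeric(1))
}

# brute-force log-rank O/E/V accumulation, independent of logrank_test()
brute_logrank_2g <- function(time, event, group) {
  gl <- sort(unique(group))
  stopifnot(length(gl) == 2L)
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & group == gl[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == gl[1])
    o <- o + d1
    e <- e + n1 * d / n
    if (n > 1) v <- v + d * (n - d) / (n - 1) * n1 / n * (1 - n1 / n)
  }
  (o - e)^2 / v
}

# brute-force ssGSEA running sum, independent of ssgsea_score()
brute_ssgsea <- function(values, set_genes, alpha) {
  r <- rank(values, ties.method = "average")
  ord <- order(values, decreasing = TRUE)
  ins <- names(values)[ord] %in% set_genes
  w <- r[ord]^alpha * ins
  tot_w <- sum(w)
  n_out <- sum(!ins)
  es <- 0
  p_in <- 0
  p_out <- 0
  for (i in seq_along(values)) {
    p_in <- p_in + w[i] / tot_w
    p_out <- p_out + (!ins[i]) / n_out
    es <- es + p_in - p_out
  }
  es
}

# exact upper-tail hypergeometric by summation, independent of phyper
brute_hyper_upper <- function(k, N, K, n) {
  sum(vapply(k:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# a small cohort spec without planted interaction genes (clean hazard)
clean_spec <- function(n_samples, n_genes = 30, a = -0.7, seed = 1,
                       censoring_rate = 0.25, ...) {
  cohort_spec(
    n_samples = n_samples, n_genes = n_genes, seed = seed,
    censoring_rate = censoring_rate,
    hazard_coeffs = list(a = a, b = setNames(numeric(0), character(0)),
                         d = setNames(numeric(0), character(0)), c = log(0.1)),
    ...)
}
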