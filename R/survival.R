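#' Kaplan-Meier product-limit estimate
#'
#' Survival curves per group with Greenwood standard errors. Subjects
#' censored at an event time are counted at risk at that time (standard
#' right-continuity convention).
#'
#' @param clinical Clinical tibble with `sample_id`, `time`, `event`.
#' @param group_labels Optional tibble `sample_id`, `group`; one pooled curve
#'   when omitted.
#' @return A `km_estimate` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `std_err` (Greenwood SE of S), one row per
#'   distinct observed time per group.
#' @export
km_estimate <- function(clinical, group_labels = NULL) {
  clinical <- validate_clinical(clinical)
  df <- join_groups(clinical, group_labels)
  any_event <- sum(df$event) > 0
  if (!any_event) warn("no events observed: all curves are flat at 1")
  res <- lapply(split(df, df$group), function(g) {
    tt <- sort(unique(g$time))
    n_event <- vapply(tt, function(t) sum(g$time == t & g$event == 1), numeric(1))
    n_censor <- vapply(tt, function(t) sum(g$time == t & g$event == 0), numeric(1))
    n_risk <- vapply(tt, function(t) sum(g$time >= t), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    # Greenwood: var(S) = S^2 * sum d / (n (n - d))
    gw <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0))
    std_err <- surv * sqrt(gw)
    if (any_event && sum(g$event) == 0) warn(sprintf("group '%s' has no events: flat curve", g$group[1L]))
    tibble::tibble(group = g$group[1L], time = tt, n_risk = n_risk,
                   n_event = n_event, n_censor = n_censor,
                   survival = surv, std_err = std_err)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("km_estimate", class(out))
  out
}

join_groups <- function(clinical, group_labels) {
  if (is.null(group_labels)) {
    clinical$group <- "all"
    return(clinical)
  }
  stop_if_not_cols(group_labels, c("sample_id", "group"), "group labels")
  df <- dplyr::inner_join(clinical, group_labels[, c("sample_id", "group")],
                          by = "sample_id")
  df <- df[!is.na(df$group), , drop = FALSE]
  if (nrow(df) == 0L) abort("no samples remain after joining group labels")
  df$group <- as.character(df$group)
  df
}

#' Log-rank test across two or more groups
#'
#' At each distinct event time, the expected event count per group is the
#' hypergeometric mean and the variance-covariance the hypergeometric
#' variance; the chi-square statistic is the quadratic form over the first
#' k - 1 groups (for two groups this is the familiar `(O - E)^2 / V`).
#'
#' @inheritParams km_estimate
#' @param group_labels Tibble `sample_id`, `group` with >= 2 groups.
#' @return One-row tibble `statistic`, `df`, `p_value`, with attribute
#'   `counts`: per-group `n`, `observed`, `expected`.
#' @export
logrank_test <- function(clinical, group_labels) {
  clinical <- validate_clinical(clinical)
  df <- join_groups(clinical, group_labels)
  groups <- sort(unique(df$group))
  k <- length(groups)
  if (k < 2L) abort("log-rank test needs at least two groups")
  if (sum(df$event) == 0) abort("log-rank test needs at least one event")
  gidx <- match(df$group, groups)
  ev_times <- sort(unique(df$time[df$event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- df$time >= t
    n_j <- sum(at_risk)
    n_gj <- tabulate(gidx[at_risk], nbins = k)
    d_j <- sum(df$time == t & df$event == 1)
    d_gj <- tabulate(gidx[df$time == t & df$event == 1], nbins = k)
    O <- O + d_gj
    E <- E + n_gj * d_j / n_j
    if (n_j > 1) {
      fac <- d_j * (n_j - d_j) / (n_j - 1)
      p <- n_gj / n_j
      V <- V + fac * (diag(p, k) - tcrossprod(p, p) * 1) * 1
    }
  }
  if (all(tabulate(gidx, nbins = k) == 0)) abort("empty group")
  idx <- seq_len(k - 1L)
  d_vec <- (O - E)[idx]
  Vsub <- V[idx, idx, drop = FALSE]
  qr_v <- qr(Vsub)
  if (qr_v$rank < length(idx)) {
    stat <- as.numeric(t(d_vec) %*% pseudo_inverse(Vsub) %*% d_vec)
  } else {
    stat <- as.numeric(t(d_vec) %*% solve(Vsub, d_vec))
  }
  out <- tibble::tibble(statistic = stat, df = k - 1L,
                        p_value = pchisq(stat, df = k - 1L, lower.tail = FALSE))
  attr(out, "counts") <- tibble::tibble(
    group = groups, n = tabulate(gidx, nbins = k), observed = O, expected = E)
  out
}

#' Cox partial-likelihood score test at beta = 0
#'
#' The quadratic form `U' I^{-1} U` of the score and observed information at
#' the null. For a single binary group covariate this equals the two-group
#' log-rank chi-square (exactly so when event times are untied).
#'
#' @inheritParams cox_fit
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @export
cox_score_test <- function(clinical, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  clinical <- validate_clinical(clinical)
  X <- covariate_matrix(clinical$sample_id, covariates)
  dsn <- cox_design(clinical$time, clinical$event, X, ties)
  d <- cox_partial(dsn, numeric(ncol(X)))
  stat <- as.numeric(t(d$score) %*% solve(d$info, d$score))
  tibble::tibble(statistic = stat, df = ncol(X),
                 p_value = pchisq(stat, df = ncol(X), lower.tail = FALSE))
}

# Per-subject score residuals at beta (Breslow risk-set weighting; exact
# when event times are untied). Substrate of the Lin-Wei robust variance.
cox_score_residuals <- function(dsn, beta) {
  Xo <- dsn$Xo
  n <- dsn$n
  p <- dsn$p
  eta <- as.numeric(Xo %*% beta)
  eta <- eta - mean(eta)
  w <- exp(eta)
  cw <- rev_cumsum(w)
  cwx <- apply(Xo * w, 2L, rev_cumsum)
  if (p == 1L) cwx <- matrix(cwx, ncol = 1L)
  fi <- dsn$fi
  d_cnt <- dsn$d_cnt
  S0 <- cw[fi]
  M <- cwx[fi, , drop = FALSE] / S0          # risk-set mean at each event time
  # cumulative hazard-increment sums over event times <= each subject's time
  dk_S0 <- d_cnt / S0
  A_ev <- cumsum(dk_S0)
  B_ev <- apply(M * dk_S0, 2L, cumsum)
  if (p == 1L) B_ev <- matrix(B_ev, ncol = 1L)
  # index of the last distinct event time <= each sorted subject time
  pos <- findInterval(dsn$tt, dsn$ev_times)
  A <- c(0, A_ev)[pos + 1L]
  B <- rbind(0, B_ev)[pos + 1L, , drop = FALSE]
  # event part: x_i - mean at the subject's own event time
  ev_at <- match(dsn$tt, dsn$ev_times)       # NA for censored-only times
  Mi <- matrix(0, n, p)
  has <- !is.na(ev_at) & dsn$ss == 1
  Mi[has, ] <- M[ev_at[has], , drop = FALSE]
  resid <- dsn$ss * (Xo - Mi) - w * (Xo * A - B)
  resid
}

# Moore-Penrose pseudo-inverse via SVD (degenerate log-rank designs only)
pseudo_inverse <- function(m, tol = 1e-12) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1L]
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the Efron (default) or Breslow partial
#' likelihood, written from first principles. Standard errors come from the
#' inverse observed information; confidence intervals are Wald
#' (`exp(beta +/- 1.96 se)`). Step-halving guards against log-likelihood
#' decreases; non-convergence (monotone likelihood / separation) returns a
#' flagged fit with a warning rather than an error.
#'
#' @param clinical Clinical tibble (`sample_id`, `time`, `event`).
#' @param covariates Tibble with `sample_id` plus numeric covariate columns,
#'   or a numeric matrix with sample rownames. Constant columns are dropped
#'   with a warning; collinear columns raise an error naming them.
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter,tol Newton-Raphson controls; convergence when the maximum
#'   absolute score falls below `tol`.
#' @param robust Also compute the Lin-Wei robust (sandwich) variance from
#'   score residuals. Appropriate when the model is a working model — e.g. a
#'   marginal per-gene screen in which other genes also act on the hazard.
#'   With tied event times the residuals use Breslow risk-set weighting.
#' @return A `cox_fit` object; see [tidy.cox_fit()] and [glance.cox_fit()].
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_samples = 120, n_genes = 20))
#' covar <- tibble::tibble(sample_id = names(cohort$latent_tls),
#'                         tls = as.numeric(cohort$latent_tls))
#' fit <- cox_fit(cohort$clinical, covar)
#' tidy(fit)
#' @export
cox_fit <- function(clinical, covariates, ties = c("efron", "breslow"),
                    max_iter = 50L, tol = 1e-9, robust = FALSE) {
  ties <- match.arg(ties)
  clinical <- validate_clinical(clinical)
  X <- covariate_matrix(clinical$sample_id, covariates)
  keep <- apply(X, 2L, function(v) sd(v) > 0)
  if (!all(keep)) {
    warn(sprintf("constant covariate(s) dropped: %s",
                 paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0L) abort("no non-constant covariates to fit")
  if (sum(clinical$event) == 0) abort("Cox fit needs at least one event")
  qx <- qr(scale(X, center = TRUE, scale = FALSE))
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    abort(sprintf("collinear covariate(s): %s", paste(dep, collapse = ", ")))
  }

  dsn <- cox_design(clinical$time, clinical$event, X, ties)
  p <- ncol(X)
  beta <- numeric(p)
  ll0 <- cox_partial(dsn, beta)$loglik
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- cox_partial(dsn, beta)
    if (max(abs(d$score)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(d$info, d$score), error = function(e) {
      abort("singular information matrix: covariates are collinear")
    })
    # step-halving if the partial log-likelihood would decrease
    h <- 1
    repeat {
      beta_new <- beta + h * step
      ll_new <- cox_partial(dsn, beta_new)$loglik
      if (is.finite(ll_new) && ll_new >= d$loglik - 1e-12) break
      h <- h / 2
      if (h < 1e-10) break
    }
    beta <- beta_new
    if (iter >= max_iter) break
  }
  if (!converged) {
    warn("Cox fit did not converge (possible monotone likelihood / separation)")
  }
  d <- cox_partial(dsn, beta)
  vcov <- tryCatch(solve(d$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  rvar <- NULL
  rse <- NULL
  if (robust && all(is.finite(vcov))) {
    resid <- cox_score_residuals(dsn, beta)
    rvar <- vcov %*% crossprod(resid) %*% vcov
    rse <- sqrt(diag(rvar))
  }
  structure(list(
    coefficients = setNames(as.numeric(beta), colnames(X)),
    se = setNames(se, colnames(X)),
    robust_se = if (!is.null(rse)) setNames(rse, colnames(X)) else NULL,
    var = vcov,
    robust_var = rvar,
    loglik = c(null = ll0, final = d$loglik),
    score = d$score,
    n = nrow(X), n_event = sum(clinical$event),
    iter = iter, converged = converged, ties = ties
  ), class = "cox_fit")
}

# align covariates to the clinical sample order
covariate_matrix <- function(sample_ids, covariates) {
  if (is.matrix(covariates)) {
    if (is.null(rownames(covariates))) {
      if (nrow(covariates) != length(sample_ids)) {
        abort("covariate matrix without rownames must match the clinical row count")
      }
      rownames(covariates) <- sample_ids
    }
    miss <- setdiff(sample_ids, rownames(covariates))
    if (length(miss) > 0L) abort("covariate matrix is missing samples")
    X <- covariates[sample_ids, , drop = FALSE]
  } else {
    stop_if_not_cols(covariates, "sample_id", "covariate table")
    idx <- match(sample_ids, covariates$sample_id)
    if (anyNA(idx)) abort("covariate table is missing samples")
    X <- as.matrix(covariates[idx, setdiff(names(covariates), "sample_id"),
                              drop = FALSE])
  }
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) abort("covariates must be finite")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

# precompute the sorted event-time structure shared by every evaluation of
# the partial likelihood for one data set
cox_design <- function(time, status, X, ties) {
  ord <- order(time)
  tt <- time[ord]
  ss <- status[ord]
  Xo <- X[ord, , drop = FALSE]
  p <- ncol(X)
  n <- length(tt)
  ev_idx <- which(ss == 1)
  ev_t <- tt[ev_idx]                       # sorted
  grp <- rle(ev_t)
  ev_times <- grp$values
  d_cnt <- grp$lengths
  grp_end <- cumsum(d_cnt)
  grp_start <- grp_end - d_cnt + 1L
  # rows (in sorted order) of the events at each distinct event time
  ev_rows <- lapply(seq_along(ev_times),
                    function(k) ev_idx[grp_start[k]:grp_end[k]])
  # first sorted position with time >= each distinct event time
  fi <- findInterval(ev_times, tt, left.open = TRUE) + 1L
  pair_i <- rep(seq_len(p), times = p)
  pair_j <- rep(seq_len(p), each = p)
  upper <- which(pair_i <= pair_j)
  list(tt = tt, ss = ss, Xo = Xo, n = n, p = p, ties = ties,
       ev_times = ev_times, d_cnt = d_cnt, ev_rows = ev_rows, fi = fi,
       pair_i = pair_i[upper], pair_j = pair_j[upper], upper = upper)
}

# partial log-likelihood, score vector and observed information at beta.
# Untied event times are handled fully vectorized; tied times get the Efron
# (or Breslow) correction in a short loop.
cox_partial <- function(dsn, beta) {
  Xo <- dsn$Xo
  n <- dsn$n
  p <- dsn$p
  ties <- dsn$ties
  eta <- as.numeric(Xo %*% beta)
  eta <- eta - mean(eta)          # numerical safeguard; PL is shift-invariant
  w <- exp(eta)

  # reverse cumulative sums: risk-set aggregates at each position
  cw <- rev_cumsum(w)
  wX <- Xo * w
  cwx <- apply(wX, 2L, rev_cumsum)
  if (p == 1L) cwx <- matrix(cwx, ncol = 1L)
  cwxx <- vapply(seq_along(dsn$pair_i), function(k) {
    rev_cumsum(wX[, dsn$pair_i[k]] * Xo[, dsn$pair_j[k]])
  }, numeric(n))
  if (is.null(dim(cwxx))) cwxx <- matrix(cwxx, nrow = n)

  fi <- dsn$fi
  d_cnt <- dsn$d_cnt

  loglik <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  sym_idx <- matrix(0L, p, p)
  sym_idx[cbind(dsn$pair_i, dsn$pair_j)] <- seq_along(dsn$pair_i)
  sym_idx[cbind(dsn$pair_j, dsn$pair_i)] <- seq_along(dsn$pair_i)
  expand_sym <- function(v) matrix(v[sym_idx], p, p)

  untied <- d_cnt == 1L
  if (any(untied)) {
    idx <- fi[untied]
    S0 <- cw[idx]
    S1 <- cwx[idx, , drop = FALSE]
    S2 <- cwxx[idx, , drop = FALSE]
    ev_rows <- unlist(dsn$ev_rows[untied])
    loglik <- loglik + sum(eta[ev_rows]) - sum(log(S0))
    U <- S1 / S0
    score <- score + colSums(Xo[ev_rows, , drop = FALSE]) - colSums(U)
    info <- info + expand_sym(colSums(S2 / S0)) - crossprod(U)
  }
  for (k in which(!untied)) {
    idx <- fi[k]
    dset <- dsn$ev_rows[[k]]
    m <- length(dset)
    S0r <- cw[idx]; S1r <- cwx[idx, ]; S2r <- expand_sym(cwxx[idx, ])
    wt <- w[dset]
    S0t <- sum(wt)
    S1t <- colSums(Xo[dset, , drop = FALSE] * wt)
    S2t <- crossprod(Xo[dset, , drop = FALSE] * sqrt(wt))
    loglik <- loglik + sum(eta[dset])
    score <- score + colSums(Xo[dset, , drop = FALSE])
    for (l in seq_len(m) - 1L) {
      frac <- if (ties == "efron") l / m else 0
      S0s <- S0r - frac * S0t
      S1s <- S1r - frac * S1t
      S2s <- S2r - frac * S2t
      loglik <- loglik - log(S0s)
      u <- S1s / S0s
      score <- score - u
      info <- info + S2s / S0s - tcrossprod(u)
    }
  }
  list(loglik = loglik, score = score, info = info)
}
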