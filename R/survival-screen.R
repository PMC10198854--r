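#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Cox fit into a coefficient table
#'
#' @param x A `cox_fit`.
#' @param conf_level Wald confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (log HR), `std_error`, `hr`,
#'   `conf_low`, `conf_high`, `statistic` (Wald z), `p_value`.
#' @export
tidy.cox_fit <- function(x, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- x$coefficients
  se <- x$se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    hr = exp(unname(est)),
    conf_low = exp(unname(est) - z * unname(se)),
    conf_high = exp(unname(est) + z * unname(se)),
    statistic = unname(est / se),
    p_value = 2 * pnorm(-abs(unname(est / se)))
  )
}

#' One-row summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return Tibble: `n`, `n_event`, `loglik_null`, `loglik`, `iterations`,
#'   `converged`, `ties`.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event,
                 loglik_null = unname(x$loglik["null"]),
                 loglik = unname(x$loglik["final"]),
                 iterations = x$iter, converged = x$converged, ties = x$ties)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, %s in %d iteration(s)\n",
              x$n, x$n_event, x$ties,
              if (x$converged) "converged" else "NOT converged", x$iter))
  print(tidy(x))
  invisible(x)
}

#' Univariate / multivariate Cox screening over a covariate table
#'
#' Builds a forest-plot-ready hazard-ratio table. Character or factor
#' covariates are expanded to reference-coded indicators (reference = first
#' level, alphabetical unless the column is already a factor). In univariate
#' mode each covariate (with all its levels) is fit alone; in multivariate
#' mode all covariates enter jointly. Benjamini-Hochberg adjusted p-values
#' are reported across the univariate fits.
#'
#' @param clinical Clinical tibble.
#' @param covariates Tibble `sample_id` + covariate columns (numeric, factor
#'   or character).
#' @param mode `"both"` (default), `"univariate"` or `"multivariate"`.
#' @param ties Passed to [cox_fit()].
#' @return Tibble: `mode`, `covariate`, `term`, `hr`, `conf_low`,
#'   `conf_high`, `p_value`, `q_value` (univariate only), `n`, `n_event`.
#' @export
survival_screen <- function(clinical, covariates,
                            mode = c("both", "univariate", "multivariate"),
                            ties = "efron") {
  mode <- match.arg(mode)
  clinical <- validate_clinical(clinical)
  stop_if_not_cols(covariates, "sample_id", "covariate table")
  vars <- setdiff(names(covariates), "sample_id")
  if (length(vars) == 0L) abort("no covariates supplied")
  blocks <- lapply(vars, function(v) expand_covariate(covariates, v))
  names(blocks) <- vars

  fit_block <- function(X) {
    df <- dplyr::inner_join(clinical, X, by = "sample_id")
    cox_fit(df[, c("sample_id", "time", "event")],
            df[, c("sample_id", setdiff(names(X), "sample_id"))], ties = ties)
  }
  rows <- list()
  if (mode %in% c("both", "univariate")) {
    uni <- purrr::imap(blocks, function(X, v) {
      fit <- fit_block(X)
      td <- tidy(fit)
      td$covariate <- v
      td$n <- fit$n
      td$n_event <- fit$n_event
      td
    })
    uni <- dplyr::bind_rows(uni)
    uni$mode <- "univariate"
    uni$q_value <- p.adjust(uni$p_value, method = "BH")
    rows <- c(rows, list(uni))
  }
  if (mode %in% c("both", "multivariate")) {
    joint <- Reduce(function(a, b) dplyr::inner_join(a, b, by = "sample_id"), blocks)
    fit <- fit_block(joint)
    td <- tidy(fit)
    term_var <- unlist(lapply(names(blocks), function(v) {
      setNames(rep(v, ncol(blocks[[v]]) - 1L), setdiff(names(blocks[[v]]), "sample_id"))
    }))
    td$covariate <- unname(term_var[td$term])
    td$n <- fit$n
    td$n_event <- fit$n_event
    td$mode <- "multivariate"
    td$q_value <- NA_real_
    rows <- c(rows, list(td))
  }
  out <- dplyr::bind_rows(rows)
  out[, c("mode", "covariate", "term", "estimate", "std_error", "hr",
          "conf_low", "conf_high", "p_value", "q_value", "n", "n_event")]
}

# reference-code one covariate column into indicator columns
expand_covariate <- function(covariates, v) {
  x <- covariates[[v]]
  out <- tibble::tibble(sample_id = covariates$sample_id)
  if (is.numeric(x)) {
    out[[v]] <- x
    return(out)
  }
  f <- if (is.factor(x)) droplevels(x) else factor(x)
  lev <- levels(f)
  if (length(lev) < 2L) {
    out[[v]] <- rep(0, nrow(out))  # constant; cox_fit will drop it with a warning
    return(out)
  }
  for (l in lev[-1L]) out[[paste0(v, "=", l)]] <- as.numeric(f == l)
  out
}
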