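#' Specify a synthetic HNSCC-like cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a latent per-sample TLS factor drives correlated over-expression
#' of the signature chemokines; survival times follow an exponential
#' distribution whose log rate is the linear hazard
#' `a*F + sum(b_g*V_g) + sum(d_g*F*V_g) + c` (F the latent factor, V_g the
#' centered log2 expression of gene g); mutations occur with group-dependent
#' per-gene frequencies; and ordinal immunotherapy response labels
#' (CR/PR/SD/PD) follow a cumulative-logit model on the latent factor.
#'
#' The default cohort has 600 samples and 500 genes: the 13 signature
#' chemokines, 20 "MODN" genes with interaction coefficient d = -0.5
#' (strengthening the TLS-survival association), 20 "MODP" genes with
#' d = +0.5 (weakening it), six driver genes carrying the reported
#' TLS-hi/TLS-low mutation-frequency contrasts, and unstructured filler genes.
#'
#' @param n_samples,n_genes Cohort dimensions. `n_genes` must cover the
#'   signature and every gene named in the coefficient/frequency maps.
#' @param signature_genes Gene ids of the TLS signature (default: the
#'   13-chemokine set, [tls_signature_genes()]).
#' @param tls_effect Log2 expression shift of each signature gene per unit of
#'   the latent factor.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param baseline_log2 Baseline log2 expression of every gene.
#' @param hazard_coeffs List with entries `a` (focal-factor coefficient),
#'   `b` (named per-gene main effects), `d` (named per-gene interaction
#'   effects) and `c` (baseline log hazard).
#' @param censoring_rate Target fraction of right-censored subjects in [0, 1).
#' @param mutation_freqs Tibble with columns `group`, `gene_id`, `frequency`.
#' @param response_shift Cumulative-logit slope of response on the latent
#'   factor (>= 0; larger values concentrate CR among TLS-high samples).
#' @param response_base Baseline response probabilities (sum to 1) used when
#'   `response_shift = 0`.
#' @param seed Integer seed that fully determines all draws.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 600L,
                        n_genes = 500L,
                        signature_genes = tls_signature_genes(),
                        tls_effect = 1,
                        noise_sd = 0.5,
                        baseline_log2 = 4,
                        hazard_coeffs = NULL,
                        censoring_rate = 0.25,
                        mutation_freqs = NULL,
                        response_shift = 1,
                        response_base = c(CR = 0.10, PR = 0.20, SD = 0.30, PD = 0.40),
                        seed = 20220913L) {
  if (n_samples < 1L || n_genes < 1L) abort("n_samples and n_genes must be positive")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) abort("censoring_rate must lie in [0, 1)")
  if (response_shift < 0) abort("response_shift must be >= 0")
  if (abs(sum(response_base) - 1) > 1e-8) abort("response_base must sum to 1")

  gene_ids <- default_gene_ids(n_genes, signature_genes)
  if (is.null(hazard_coeffs)) {
    modn <- grep("^MODN", gene_ids, value = TRUE)
    modp <- grep("^MODP", gene_ids, value = TRUE)
    hazard_coeffs <- list(
      a = -0.7,
      b = setNames(numeric(0), character(0)),
      d = c(setNames(rep(-0.5, length(modn)), modn),
            setNames(rep(0.5, length(modp)), modp)),
      c = log(0.1)
    )
  }
  if (is.null(mutation_freqs)) {
    mutation_freqs <- default_mutation_freqs()
    mutation_freqs <- mutation_freqs[mutation_freqs$gene_id %in% gene_ids, , drop = FALSE]
  }

  known <- unique(c(names(hazard_coeffs$b), names(hazard_coeffs$d)))
  if (!all(known %in% gene_ids)) {
    abort(sprintf("hazard coefficient gene(s) absent from the cohort: %s",
                  paste(setdiff(known, gene_ids), collapse = ", ")))
  }
  if (!all(mutation_freqs$gene_id %in% gene_ids)) {
    abort("mutation_freqs names gene(s) absent from the cohort")
  }
  if (any(mutation_freqs$frequency < 0 | mutation_freqs$frequency > 1)) {
    abort("mutation frequencies must lie in [0, 1]")
  }

  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    gene_ids = gene_ids, signature_genes = signature_genes,
    tls_effect = tls_effect, noise_sd = noise_sd, baseline_log2 = baseline_log2,
    hazard_coeffs = hazard_coeffs, censoring_rate = censoring_rate,
    mutation_freqs = mutation_freqs, response_shift = response_shift,
    response_base = response_base, seed = as.integer(seed)
  ), class = "cohort_spec")
}

default_gene_ids <- function(n_genes, signature_genes) {
  drivers <- c("MUC16", "DNAH5", "PKHD1L1", "NSD1", "COL11A1", "CASP8")
  named <- c(signature_genes,
             sprintf("MODN%02d", 1:20), sprintf("MODP%02d", 1:20), drivers)
  named <- unique(named)
  if (n_genes < length(signature_genes)) {
    abort("n_genes is smaller than the signature")
  }
  if (n_genes <= length(named)) return(named[seq_len(max(n_genes, length(signature_genes)))])
  c(named, sprintf("G%04d", seq_len(n_genes - length(named))))
}

# per-gene mutation frequencies by TLS group, echoing the reported driver-gene
# contrasts between TLS-hi and TLS-low tumors
default_mutation_freqs <- function() {
  tibble::tibble(
    group = rep(c("TLS-hi", "TLS-low"), each = 6L),
    gene_id = rep(c("MUC16", "DNAH5", "PKHD1L1", "NSD1", "COL11A1", "CASP8"), 2L),
    frequency = c(0.22, 0.21, 0.19, 0.15, 0.12, 0.10,
                  0.17, 0.14, 0.12, 0.08, 0.06, 0.22)
  )
}

#' Simulate the expression layer of a cohort
#'
#' Draws the latent TLS factor standard-normal, then sets each signature
#' gene's log2 value to `baseline + tls_effect * factor + noise` and every
#' other gene to `baseline + noise`.
#'
#' @param spec A [cohort_spec()].
#' @return List with `expression` (an [expression_matrix()], scale `"log2p1"`)
#'   and `latent_tls` (named numeric).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(child_seed(spec$seed, 1L), {
    n <- spec$n_samples
    sample_ids <- sprintf("S%04d", seq_len(n))
    f <- setNames(rnorm(n), sample_ids)
    m <- matrix(rnorm(spec$n_genes * n, sd = spec$noise_sd),
                nrow = spec$n_genes, ncol = n,
                dimnames = list(spec$gene_ids, sample_ids))
    m <- m + spec$baseline_log2
    sig <- intersect(spec$signature_genes, spec$gene_ids)
    m[sig, ] <- m[sig, ] + spec$tls_effect * rep(f, each = length(sig))
    m[m < 0] <- 0  # log2(TPM+1) cannot be negative
    list(expression = expression_matrix(m, scale = "log2p1"), latent_tls = f)
  })
}

#' Simulate survival under the linear hazard model
#'
#' Event times are exponential with per-sample rate
#' `exp(a*F + sum(b_g*V_g) + sum(d_g*F*V_g) + c)` where `F` is the latent
#' factor and `V_g` the centered log2 expression of gene `g`; the intercept
#' `c` is the baseline log hazard. Censoring is independent exponential with
#' its rate tuned so the expected censored fraction matches
#' `censoring_rate`.
#'
#' @param latent_tls Named numeric latent factor per sample.
#' @param expression An [expression_matrix()] covering the coefficient genes.
#' @param hazard_coeffs,censoring_rate See [cohort_spec()].
#' @param seed Integer seed.
#' @return A clinical tibble (`sample_id`, `time`, `event`).
#' @export
simulate_survival <- function(latent_tls, expression, hazard_coeffs,
                              censoring_rate = 0.25, seed = 1L) {
  if (censoring_rate < 0 || censoring_rate >= 1) abort("censoring_rate must lie in [0, 1)")
  sample_ids <- names(latent_tls)
  stopifnot(identical(sample_ids, colnames(expression)))
  lv <- expr_log2(expression)
  lp <- hazard_coeffs$a * latent_tls + hazard_coeffs$c
  bg <- names(hazard_coeffs$b)
  dg <- names(hazard_coeffs$d)
  if (!all(c(bg, dg) %in% rownames(lv))) {
    abort("hazard coefficient gene(s) absent from the expression matrix")
  }
  center <- function(g) lv[g, ] - mean(lv[g, ])
  for (g in bg) lp <- lp + hazard_coeffs$b[[g]] * center(g)
  for (g in dg) lp <- lp + hazard_coeffs$d[[g]] * latent_tls * center(g)
  rate <- exp(lp)
  with_seed(child_seed(seed, 2L), {
    t_event <- rexp(length(rate), rate = rate)
    if (censoring_rate == 0) {
      time <- t_event
      event <- rep(1, length(rate))
    } else {
      # P(censored | rate_i) = mu / (mu + rate_i); tune mu to the target mean
      f <- function(mu) mean(mu / (mu + rate)) - censoring_rate
      mu <- uniroot(f, lower = 1e-12, upper = 1e12, tol = 1e-12)$root
      t_cens <- rexp(length(rate), rate = mu)
      time <- pmin(t_event, t_cens)
      event <- as.numeric(t_event <= t_cens)
    }
    tibble::tibble(sample_id = sample_ids, time = time, event = event)
  })
}

#' Simulate a MAF-like mutation table with group-dependent frequencies
#'
#' Each (sample, gene) pair mutates independently with its group's frequency;
#' mutated records are emitted with class `"Missense_Mutation"`.
#'
#' @param sample_groups Tibble with columns `sample_id` and `group`.
#' @param mutation_freqs Tibble with columns `group`, `gene_id`, `frequency`.
#' @param seed Integer seed.
#' @return A MAF tibble (`sample_id`, `gene_id`, `variant_classification`).
#' @export
simulate_mutations <- function(sample_groups, mutation_freqs, seed = 1L) {
  stop_if_not_cols(sample_groups, c("sample_id", "group"), "sample_groups")
  stop_if_not_cols(mutation_freqs, c("group", "gene_id", "frequency"), "mutation_freqs")
  if (any(mutation_freqs$frequency < 0 | mutation_freqs$frequency > 1)) {
    abort("mutation frequencies must lie in [0, 1]")
  }
  if (nrow(mutation_freqs) == 0L) {
    return(tibble::tibble(sample_id = character(), gene_id = character(),
                          variant_classification = character()))
  }
  miss <- setdiff(unique(sample_groups$group), unique(mutation_freqs$group))
  if (length(miss) > 0L) {
    abort(sprintf("no mutation frequencies declared for group(s): %s",
                  paste(miss, collapse = ", ")))
  }
  with_seed(child_seed(seed, 3L), {
    grid <- dplyr::inner_join(sample_groups, mutation_freqs, by = "group",
                              relationship = "many-to-many")
    hit <- runif(nrow(grid)) < grid$frequency
    tibble::tibble(sample_id = grid$sample_id[hit],
                   gene_id = grid$gene_id[hit],
                   variant_classification = rep("Missense_Mutation", sum(hit)))
  })
}

#' Simulate ordinal immunotherapy response labels
#'
#' Labels are drawn from a cumulative-logit (proportional-odds) model whose
#' linear predictor is `response_shift * latent_tls`: a latent logistic
#' utility is cut at the baseline quantiles so that, at shift 0, label
#' frequencies match `response_base`, and larger latent factors shift mass
#' toward CR.
#'
#' @inheritParams simulate_survival
#' @param response_shift Slope (>= 0) of the ordinal model.
#' @param response_base Baseline probabilities for CR, PR, SD, PD.
#' @return Tibble with `sample_id` and `response` (factor CR/PR/SD/PD).
#' @export
simulate_response <- function(latent_tls, response_shift = 1,
                              response_base = c(CR = 0.10, PR = 0.20, SD = 0.30, PD = 0.40),
                              seed = 1L) {
  if (response_shift < 0) abort("response_shift must be >= 0")
  # cutpoints on the PD < SD < PR < CR utility axis
  cum <- cumsum(response_base[c("PD", "SD", "PR")])
  cuts <- qlogis(cum)
  with_seed(child_seed(seed, 4L), {
    u <- response_shift * latent_tls + rlogis(length(latent_tls))
    lab <- cut(u, breaks = c(-Inf, cuts, Inf),
               labels = c("PD", "SD", "PR", "CR"), right = TRUE)
    tibble::tibble(sample_id = names(latent_tls),
                   response = factor(as.character(lab),
                                     levels = c("CR", "PR", "SD", "PD")))
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs all four generator stages from one spec and seed: expression with the
#' latent TLS factor, exponential survival under the linear hazard model,
#' group-dependent mutations (groups taken from the two-class quartile
#' stratification of the computed TLS score, so the planted frequency
#' contrasts line up with the analysis' own TLS-hi/TLS-low split) and ordinal
#' response labels.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_cohort`: `expression`, `latent_tls`,
#'   `clinical` (with the response column), `maf`, `tls_group`, and `truth`
#'   (the spec).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  ex <- simulate_expression(spec)
  clinical <- simulate_survival(ex$latent_tls, ex$expression,
                                spec$hazard_coeffs, spec$censoring_rate,
                                seed = spec$seed)
  scores <- compute_tls_score(ex$expression, spec$signature_genes)
  strata <- stratify_by_quartile(scores, mode = "two_class_q3")
  groups <- tibble::tibble(
    sample_id = strata$sample_id,
    group = ifelse(strata$tls_class == "hi", "TLS-hi", "TLS-low"))
  maf <- simulate_mutations(groups, spec$mutation_freqs, seed = spec$seed)
  resp <- simulate_response(ex$latent_tls, spec$response_shift,
                            spec$response_base, seed = spec$seed)
  clinical <- dplyr::left_join(clinical, resp, by = "sample_id")
  structure(list(expression = ex$expression, latent_tls = ex$latent_tls,
                 clinical = clinical, maf = maf, tls_group = groups,
                 truth = spec),
            class = "synthetic_cohort")
}

#' Simulate a planted-archetype tumor-microenvironment panel
#'
#' Five archetypes mirror the five TME classes the clustering stage is meant
#' to recover: (1) immune desert, (2) immune-low / TMB-high, (3) immune-high
#' stromal-high, (4) stromal-high immune desert (worst prognosis), and (5)
#' immune-high TLS-high (best prognosis). Samples are drawn around the
#' archetype centers with isotropic Gaussian noise, and exponential survival
#' times follow per-archetype log hazards so archetype 4 carries the largest
#' hazard and archetype 5 the smallest.
#'
#' @param n_per_class Samples per archetype.
#' @param within_sd Within-archetype SD around each center.
#' @param censoring_rate Target censored fraction.
#' @param seed Integer seed.
#' @return List with `panel` (tibble: sample_id + 6 raw TME parameters),
#'   `labels` (tibble: sample_id, archetype), `clinical`, and `centers`.
#' @export
simulate_tme_archetypes <- function(n_per_class = 50L, within_sd = 0.5,
                                    censoring_rate = 0.2, seed = 1L) {
  params <- c("immune", "suppressive", "stromal", "TMB", "TLS", "malignant")
  centers <- rbind(
    c(-1.5, -1.5, -1.0, -1.5, -1.5,  1.5),  # 1 immune desert
    c(-0.5, -0.5, -1.0,  1.5, -1.5,  1.5),  # 2 immune-low, TMB-high
    c( 1.5,  1.5,  1.5, -1.5,  1.5, -1.0),  # 3 immune-high, stromal-high
    c(-1.5, -1.5,  1.5, -1.5, -1.5,  0.0),  # 4 stromal-high immune desert
    c( 1.5,  1.5,  0.0,  1.5,  1.5, -1.5)   # 5 immune-high, TLS-high
  )
  colnames(centers) <- params
  log_hazard <- c(0.3, 0.0, -0.3, 0.9, -0.9) + log(0.1)
  n <- 5L * n_per_class
  with_seed(child_seed(seed, 5L), {
    arche <- rep(1:5, each = n_per_class)
    x <- centers[arche, ] + matrix(rnorm(n * length(params), sd = within_sd),
                                   nrow = n)
    sample_ids <- sprintf("T%04d", seq_len(n))
    rate <- exp(log_hazard[arche])
    t_event <- rexp(n, rate)
    if (censoring_rate > 0) {
      f <- function(mu) mean(mu / (mu + rate)) - censoring_rate
      mu <- uniroot(f, lower = 1e-12, upper = 1e12, tol = 1e-12)$root
      t_cens <- rexp(n, mu)
      time <- pmin(t_event, t_cens)
      event <- as.numeric(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1, n)
    }
    panel <- tibble::as_tibble(as.data.frame(x))
    names(panel) <- params
    panel <- dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), panel)
    list(panel = panel,
         labels = tibble::tibble(sample_id = sample_ids, archetype = arche),
         clinical = tibble::tibble(sample_id = sample_ids, time = time,
                                   event = event),
         centers = centers)
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d genes, %d mutation records\n",
              ncol(x$expression), nrow(x$expression), nrow(x$maf)))
  invisible(x)
}
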