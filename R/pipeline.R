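#' Build a pipeline configuration
#'
#' A flat list of stage parameters for [run_pipeline()]. Inputs are either a
#' synthetic cohort (`simulate = TRUE`, drawn from [cohort_spec()] with
#' `seed`) or paths to an expression TSV, clinical TSV and MAF TSV.
#'
#' @param simulate Generate the cohort instead of reading files.
#' @param expression,clinical,maf Input paths (when `simulate = FALSE`).
#' @param expression_scale Declared scale of the expression input.
#' @param signature Signature gene ids (default the 13-chemokine TLS set).
#' @param stratify_mode Quartile stratification dialect.
#' @param screen_p,screen_fdr Interaction-screen thresholds.
#' @param deg_fc,deg_p Differential-expression thresholds.
#' @param ora_mode,ora_min_overlap Over-representation settings.
#' @param gene_sets_gmt Optional GMT path for enrichment; when absent, the
#'   signature and the screened modulator gene lists are used as sets.
#' @param cluster_k Number of TME classes.
#' @param seed Global seed; every stochastic stage derives its child seed
#'   from it.
#' @param n_samples,n_genes Cohort size when simulating.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE,
                            expression = NULL, clinical = NULL, maf = NULL,
                            expression_scale = "log2p1",
                            signature = tls_signature_genes(),
                            stratify_mode = "two_class_q3",
                            screen_p = 0.05, screen_fdr = 1.0,
                            deg_fc = 1.5, deg_p = 0.05,
                            ora_mode = "pathway", ora_min_overlap = 5L,
                            gene_sets_gmt = NULL,
                            cluster_k = 5L,
                            seed = 17L,
                            n_samples = 600L, n_genes = 500L) {
  cfg <- list(simulate = isTRUE(simulate), expression = expression,
              clinical = clinical, maf = maf,
              expression_scale = expression_scale, signature = signature,
              stratify_mode = stratify_mode, screen_p = screen_p,
              screen_fdr = screen_fdr, deg_fc = deg_fc, deg_p = deg_p,
              ora_mode = ora_mode, ora_min_overlap = as.integer(ora_min_overlap),
              gene_sets_gmt = gene_sets_gmt, cluster_k = as.integer(cluster_k),
              seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (!cfg$simulate) {
    for (f in c("expression", "clinical", "maf")) {
      if (is.null(cfg[[f]])) abort(sprintf("config needs an input path for '%s'", f))
      if (!file.exists(cfg[[f]])) abort(sprintf("input file not found: %s", cfg[[f]]))
    }
  }
  if (!is.null(cfg$gene_sets_gmt) && !file.exists(cfg$gene_sets_gmt)) {
    abort(sprintf("gene-set GMT not found: %s", cfg$gene_sets_gmt))
  }
  stopifnot(cfg$screen_p > 0, cfg$screen_p <= 1,
            cfg$screen_fdr > 0, cfg$screen_fdr <= 1,
            cfg$deg_fc >= 1, cfg$deg_p > 0, cfg$deg_p <= 1,
            cfg$cluster_k >= 2L)
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return [read_pipeline_config()]: a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @return [write_pipeline_config()]: `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the eight analysis stages in dependency order — score, stratify,
#' survival, interaction screen, differential expression, enrichment,
#' mutation, TME classification — on a simulated or ingested cohort, writing
#' every result as TSV under `out_dir` and returning a manifest with content
#' hashes. Outputs carry no timestamps, so a re-run from the same config and
#' seed is byte-identical.
#'
#' @param config A `pipeline_config` (or path to its YAML).
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage progress to stderr.
#' @return Manifest tibble: `stage`, `output`, `md5`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(s) if (verbose) message("[tlstme] stage: ", s)
  manifest <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, output = name, md5 = unname(tools::md5sum(path)))
  }

  log_stage("input")
  if (config$simulate) {
    cohort <- simulate_cohort(cohort_spec(
      n_samples = config$n_samples, n_genes = config$n_genes,
      signature_genes = config$signature, seed = config$seed))
    expr <- cohort$expression
    clinical <- cohort$clinical
    maf <- cohort$maf
    emit("input", "expression.tsv", function(p) write_expression_matrix(expr, p))
    emit("input", "clinical.tsv", function(p) write_clinical(clinical, p))
    emit("input", "maf.tsv", function(p) write_maf(maf, p))
  } else {
    expr <- read_expression_matrix(config$expression, scale = config$expression_scale)
    clinical <- read_clinical(config$clinical)
    maf <- read_maf(config$maf)
    shared <- intersect(colnames(expr), clinical$sample_id)
    expr <- expr[, shared]
    clinical <- clinical[clinical$sample_id %in% shared, , drop = FALSE]
  }

  log_stage("score")
  scores <- compute_tls_score(expr, config$signature)
  emit("score", "scores.tsv", function(p) write_tsv_prov(scores, p, "TLS scores"))

  log_stage("stratify")
  strata <- stratify_by_quartile(scores, mode = config$stratify_mode)
  strata_groups <- tibble::tibble(sample_id = strata$sample_id,
                                  group = as.character(strata$tls_class))
  emit("stratify", "strata.tsv", function(p) write_tsv_prov(strata, p, "TLS strata"))

  log_stage("survival")
  lr <- logrank_test(clinical, strata_groups)
  km <- km_estimate(clinical, strata_groups)
  emit("survival", "km.tsv", function(p) write_tsv_prov(km, p, "Kaplan-Meier estimate"))
  emit("survival", "logrank.tsv", function(p) write_tsv_prov(lr, p, "log-rank test"))

  log_stage("screen")
  screen <- suppressWarnings(
    screen_genes(clinical, scores, expr,
                 p_threshold = config$screen_p, fdr_threshold = config$screen_fdr))
  emit("screen", "screen.tsv", function(p) write_tsv_prov(screen, p, "interaction screen"))

  log_stage("differential")
  two_class <- if (config$stratify_mode == "two_class_q3") strata_groups else {
    tibble::tibble(sample_id = strata$sample_id,
                   group = ifelse(strata$tls_class == "TLS-hi", "hi", "low"))
  }
  deg <- differential_expression(expr, two_class,
                                 fc_threshold = config$deg_fc,
                                 p_threshold = config$deg_p)
  emit("differential", "deg.tsv", function(p) write_tsv_prov(deg, p, "differential expression"))

  log_stage("enrichment")
  sets <- if (!is.null(config$gene_sets_gmt)) {
    read_gmt(config$gene_sets_gmt)
  } else {
    ls <- list(TLS13 = intersect(config$signature, rownames(expr)))
    for (cls in c("enhancer", "reducer")) {
      g <- screen$gene_id[!is.na(screen$class) & screen$class == cls]
      if (length(g) > 0L) ls[[paste0("screen_", cls)]] <- g
    }
    as_gene_sets(ls)
  }
  query <- deg$gene_id[deg$direction != "ns"]
  ora <- ora_enrichment(query, rownames(expr), sets,
                        min_overlap = config$ora_min_overlap,
                        mode = config$ora_mode)
  ora_flat <- ora
  ora_flat$overlap <- vapply(ora$overlap, paste, "", collapse = ",")
  emit("enrichment", "ora.tsv", function(p) write_tsv_prov(ora_flat, p, "over-representation"))

  log_stage("mutation")
  tmb <- compute_tmb(maf, clinical$sample_id)
  mf_groups <- two_class
  mutfreq <- mutation_frequency_by_group(maf, mf_groups)
  emit("mutation", "tmb.tsv", function(p) write_tsv_prov(tmb, p, "tumor mutational burden"))
  emit("mutation", "mutfreq.tsv", function(p) write_tsv_prov(mutfreq, p, "mutation frequencies"))

  log_stage("classify")
  panel_scores <- dplyr::bind_rows(
    scores,
    suppressWarnings(safe_modulator(expr, screen, "enhancer")),
    suppressWarnings(safe_modulator(expr, screen, "reducer"))
  )
  panel <- build_tme_panel(panel_scores, tmb_table = tmb)
  k_eff <- min(config$cluster_k, nrow(panel))
  clusters <- hierarchical_clusters(panel, k = k_eff)
  profile <- characterize_clusters(panel, clusters, clinical)
  emit("classify", "clusters.tsv", function(p) write_tsv_prov(clusters, p, "TME classes"))
  emit("classify", "cluster_profile.tsv",
       function(p) write_tsv_prov(profile$profile, p, "TME class profiles"))
  emit("classify", "dendrogram.tsv",
       function(p) write_tsv_prov(attr(clusters, "merge"), p, "merge history"))

  out <- dplyr::bind_rows(manifest)
  emit2 <- file.path(out_dir, "manifest.tsv")
  write_tsv_prov(out, emit2, "run manifest")
  out
}

safe_modulator <- function(expr, screen, direction) {
  tryCatch(modulator_score(expr, screen, direction),
           error = function(e) NULL)
}
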