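#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample identifiers and
#' whose first column holds gene identifiers. Lines starting with `#` are
#' ignored. The scale of the values is declared by the caller, never inferred.
#'
#' @param path Path to the TSV file.
#' @param scale Declared scale of the stored values ("linear" or "log2p1").
#' @return An [expression_matrix()] with samples in file column order.
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  raw <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) abort("expression TSV needs a gene-id column plus >= 1 sample column")
  gid <- raw[[1L]]
  if (anyDuplicated(gid)) {
    abort(sprintf("duplicate gene row(s) in %s: %s", path,
                  paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("non-numeric expression value '%s' at gene row %d, sample column %d",
                  vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L]))
  }
  if (anyNA(num)) abort("expression matrix contains missing values")
  dimnames(num) <- list(gid, colnames(vals))
  expression_matrix(num, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tlstme expression matrix; scale=%s", expr_scale(x)), con)
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(unclass(x), 1L, fmt_num)
  if (is.null(dim(body))) body <- matrix(body, nrow = 1L)  # single-sample case
  lines <- paste(rownames(x), apply(t(body), 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard MSigDB dialect: one set per line, `name<TAB>description<TAB>gene...`.
#' Empty lines are skipped; duplicate genes within a set are dropped with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `set` (name), `description`, and a list-column
#'   `genes`; one row per gene set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0L) {
    abort(sprintf("GMT line %d has fewer than 3 fields (name, description, >= 1 gene)",
                  short[1L]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate gene-set name(s): %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  genes <- lapply(fields, function(f) {
    g <- f[-c(1L, 2L)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warn(sprintf("gene set '%s' contains duplicated genes; de-duplicated", f[[1L]]))
      g <- unique(g)
    }
    g
  })
  tibble::tibble(set = nm,
                 description = vapply(fields, `[[`, "", 2L),
                 genes = genes)
}

#' Write a gene-set collection to GMT
#'
#' @param sets Tibble as returned by [read_gmt()], or a named list of gene-id
#'   vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- as_gene_sets(sets)
  lines <- purrr::pmap_chr(sets, function(set, description, genes) {
    paste(c(set, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

# normalize a named list of gene vectors to the tibble representation
as_gene_sets <- function(sets) {
  if (is.data.frame(sets)) {
    stop_if_not_cols(sets, c("set", "genes"), "gene-set collection")
    if (!"description" %in% names(sets)) sets$description <- ""
    return(sets[, c("set", "description", "genes")])
  }
  if (is.list(sets) && !is.null(names(sets))) {
    return(tibble::tibble(set = names(sets),
                          description = rep("", length(sets)),
                          genes = unname(lapply(sets, as.character))))
  }
  abort("gene sets must be a tibble with columns set/description/genes or a named list")
}

#' Read a clinical table from TSV
#'
#' Mandatory columns `sample_id`, `time` (positive follow-up time, one unit
#' throughout a table) and `event` (1 = event observed, 0 = right-censored).
#' Any further columns are carried along as covariates; a `response` column is
#' validated against the immunotherapy response vocabulary CR/PR/SD/PD.
#'
#' @param path Path to the TSV file.
#' @return A tibble with typed, validated columns.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  validate_clinical(tibble::as_tibble(df))
}

validate_clinical <- function(df) {
  stop_if_not_cols(df, c("sample_id", "time", "event"), "clinical table")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("duplicate sample_id(s) in clinical table: %s",
                  paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  }
  df$time <- as.numeric(df$time)
  df$event <- as.numeric(df$event)
  if (anyNA(df$time) || anyNA(df$event)) {
    abort("clinical time/event must not be missing")
  }
  bad <- df$sample_id[df$time <= 0]
  if (length(bad) > 0L) {
    abort(sprintf("non-positive follow-up time for sample(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!all(df$event %in% c(0, 1))) {
    bad <- df$sample_id[!df$event %in% c(0, 1)]
    abort(sprintf("event indicator outside {0,1} for sample(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if ("response" %in% names(df)) {
    lev <- c("CR", "PR", "SD", "PD")
    vals <- df$response[!is.na(df$response)]
    if (!all(vals %in% lev)) {
      abort(sprintf("response values outside {CR, PR, SD, PD}: %s",
                    paste(unique(setdiff(vals, lev)), collapse = ", ")))
    }
    df$response <- factor(df$response, levels = lev)
  }
  df
}

#' Write a clinical table to TSV
#'
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  write_tsv_prov(clinical, path, "clinical table")
}

#' Default variant-classification vocabularies
#'
#' The nonsynonymous classes follow the MAF standard and are the classes
#' counted into tumor mutational burden.
#'
#' @return Character vector of variant classification labels.
#' @export
default_nonsyn_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
    "Splice_Site", "Translation_Start_Site")
}

#' @rdname default_nonsyn_classes
#' @export
default_synonymous_classes <- function() {
  c("Silent", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "RNA", "IGR")
}

#' Read a minimal MAF-like mutation table
#'
#' A three-column projection of the MAF standard: sample, gene and variant
#' classification (header match is case-insensitive; `Tumor_Sample_Barcode` /
#' `Hugo_Symbol` / `Variant_Classification` synonyms are accepted). Fully
#' duplicated records are collapsed with a warning; records whose class is not
#' in the declared vocabulary are retained with class `"other"` and a warning.
#'
#' @param path Path to the TSV file.
#' @param nonsyn_vocabulary Recognised nonsynonymous classes.
#' @param synonymous_vocabulary Recognised synonymous/non-coding classes.
#' @return A tibble with columns `sample_id`, `gene_id`, `variant_classification`.
#' @export
read_maf <- function(path,
                     nonsyn_vocabulary = default_nonsyn_classes(),
                     synonymous_vocabulary = default_synonymous_classes()) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands, what) {
    hit <- which(nm %in% cands)
    if (length(hit) == 0L) abort(sprintf("MAF table is missing a %s column", what))
    hit[1L]
  }
  out <- tibble::tibble(
    sample_id = as.character(df[[pick(c("sample", "sample_id", "tumor_sample_barcode"), "sample")]]),
    gene_id = as.character(df[[pick(c("gene", "gene_id", "hugo_symbol"), "gene")]]),
    variant_classification = as.character(
      df[[pick(c("variant_classification", "class", "variant_class"), "variant classification")]])
  )
  validate_maf(out, nonsyn_vocabulary, synonymous_vocabulary)
}

validate_maf <- function(maf, nonsyn_vocabulary = default_nonsyn_classes(),
                         synonymous_vocabulary = default_synonymous_classes()) {
  if (nrow(maf) > 0L) {
    dup <- duplicated(maf)
    if (any(dup)) {
      warn(sprintf("%d fully duplicated MAF record(s) collapsed", sum(dup)))
      maf <- maf[!dup, , drop = FALSE]
    }
    vocab <- c(nonsyn_vocabulary, synonymous_vocabulary, "other")
    unknown <- !maf$variant_classification %in% vocab
    if (any(unknown)) {
      warn(sprintf("unknown variant classification(s) retained as 'other': %s",
                   paste(unique(maf$variant_classification[unknown]), collapse = ", ")))
      maf$variant_classification[unknown] <- "other"
    }
  }
  tibble::as_tibble(maf)
}

#' Write a MAF-like table to TSV
#'
#' @param maf MAF tibble (see [read_maf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path) {
  write_tsv_prov(maf, path, "MAF-like mutation table")
}

# shared TSV writer: provenance comment + header + numeric formatting that
# round-trips within 1e-12
write_tsv_prov <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tlstme %s", what), con)
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- fmt_num(df[[j]])
    if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
    df[[j]][is.na(df[[j]])] <- "NA"
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  }
  invisible(path)
}
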