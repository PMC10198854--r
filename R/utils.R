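#' @importFrom rlang %||% abort warn .data
#' @importFrom stats quantile setNames p.adjust phyper pchisq pnorm qlogis
#'   rnorm rexp runif rbinom rlogis cor cor.test wilcox.test t.test
#'   fisher.test ks.test hclust cutree dist median sd var uniroot
#' @importFrom utils head read.delim write.table
#' @importFrom tools md5sum
NULL

# reverse cumulative sum: out[i] = sum(x[i:n])
rev_cumsum <- function(x) {
  if (length(x) == 0L) return(x)
  rev(cumsum(rev(x)))
}

# format numbers for TSV output with enough digits that a write-read cycle
# reproduces the IEEE double exactly
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

stop_if_not_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# derive a stage-specific child seed from a global seed; keeps results
# reproducible when a stage is re-run in isolation
child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
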