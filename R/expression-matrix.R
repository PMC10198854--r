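#' Construct a gene-by-sample expression matrix
#'
#' The expression container used throughout the package: a numeric matrix with
#' genes as rows and samples as columns, carrying a declared scale. The scale
#' is never inferred from the values; bulk RNA-seq abundance arrives either as
#' linear TPM-like values (`"linear"`) or already log-transformed as
#' `log2(x + 1)` (`"log2p1"`), and downstream scoring depends on knowing which.
#'
#' @param values Numeric matrix, genes x samples, with unique non-empty
#'   dimnames. All values must be finite; under `scale = "linear"` they must
#'   also be non-negative.
#' @param scale Declared scale of `values`: `"linear"` or `"log2p1"`.
#' @return An `expr_matrix`: the validated matrix with a `scale` attribute.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' expression_matrix(m, scale = "linear")
#' @export
expression_matrix <- function(values, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples)")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    abort("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(gid)) {
    abort(sprintf("duplicate gene identifier(s): %s",
                  paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  }
  if (anyDuplicated(sid)) {
    abort(sprintf("duplicate sample identifier(s): %s",
                  paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  if (!all(is.finite(values))) {
    abort("expression values must all be finite")
  }
  if (scale == "linear" && any(values < 0)) {
    abort("negative expression values are invalid under scale = \"linear\"")
  }
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  print(head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE], 5L))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
expr_scale <- function(x) attr(x, "scale") %||% "linear"

# matrix of log2(v + 1) values whatever the declared scale
expr_log2 <- function(x) {
  v <- unclass(x)
  attr(v, "scale") <- NULL
  if (expr_scale(x) == "linear") log2(v + 1) else v
}

# matrix of linear-scale values
expr_linear <- function(x) {
  v <- unclass(x)
  attr(v, "scale") <- NULL
  if (expr_scale(x) == "linear") v else 2^v - 1
}

# subsetting keeps the class and scale when the result is still a matrix
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    structure(out, scale = attr(x, "scale"),
              class = c("expr_matrix", class(out)))
  } else {
    out
  }
}
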