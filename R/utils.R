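#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used for printed report
#' tables (R's `round()` rounds half to even, which turns 0.9715 into 0.971
#' rather than the conventional 0.972). A tiny representation tolerance keeps
#' values that are exact halves in decimal, but slightly below in binary,
#' rounding up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.9715, 3)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# rank descending with deterministic tie-break on a secondary key (usually the
# variety/gene identifier) so reported ranks are a stable permutation of 1..n
rank_desc <- function(x, tie_key) {
  ord <- order(-x, tie_key)
  rk <- integer(length(x))
  rk[ord] <- seq_along(x)
  rk
}

# validate that `df` has the named columns; abort with the offenders otherwise
check_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "droughtrank_schema_error")
  }
  invisible(df)
}

# convert an expression table (gene id column + one column per sample) to a
# numeric matrix with gene rownames
expr_as_matrix <- function(expr, gene_col = "gene") {
  check_columns(expr, gene_col, "expression table")
  genes <- as.character(expr[[gene_col]])
  if (anyDuplicated(genes)) {
    abort("duplicate gene ids in expression table",
          class = "droughtrank_schema_error")
  }
  m <- as.matrix(expr[setdiff(names(expr), gene_col)])
  if (!is.numeric(m)) {
    abort("expression values must be numeric", class = "droughtrank_schema_error")
  }
  if (any(!is.finite(m))) {
    abort("expression values must be finite", class = "droughtrank_schema_error")
  }
  rownames(m) <- genes
  m
}

# upper-triangle (off-diagonal) vector of a square symmetric matrix
upper_tri_vec <- function(m) m[upper.tri(m)]
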