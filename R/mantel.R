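#' Mantel permutation test between two distance matrices
#'
#' Correlates the off-diagonal upper triangles of two sample distance
#' matrices and assesses significance by jointly permuting the rows and
#' columns of the second matrix. The permutation p uses the add-one
#' estimator `p = (1 + #(r_perm >= r_obs)) / (n_perm + 1)` (one-sided,
#' matching the usual Mantel convention), so `p > 0` always and
#' `p >= 1 / (n_perm + 1)`. For `n <= 7` samples `exact = TRUE` enumerates
#' all `n!` permutations instead, reporting the exact proportion of
#' permutations (including the identity) whose statistic reaches the
#' observed one.
#'
#' @param dist_a,dist_b symmetric distance matrices (or `dist` objects) over
#'   the same samples, zero diagonal.
#' @param n_perm number of random permutations (ignored in exact mode).
#' @param seed integer seed for the permutations.
#' @param method correlation flavour, `"pearson"` (default) or
#'   `"spearman"`.
#' @param exact enumerate all permutations (requires <= 7 samples).
#' @return an object of class `mantel_result`: list with `r`, `p_perm`,
#'   `n_perm` (number of non-identity permutations examined), `method`,
#'   `exact`, `n_samples`.
#' @examples
#' x <- matrix(rnorm(12), 6)
#' y <- matrix(rnorm(12), 6)
#' mantel_test(dist(x), dist(y), n_perm = 99, seed = 1)
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = 1,
                        method = c("pearson", "spearman"), exact = FALSE) {
  method <- match.arg(method)
  a <- as.matrix(dist_a)
  b <- as.matrix(dist_b)
  for (m in list(a, b)) {
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
      abort("distance matrices must be square and symmetric",
            class = "droughtrank_input_error")
    }
  }
  if (nrow(a) != nrow(b)) {
    abort("distance matrices must cover the same samples",
          class = "droughtrank_input_error")
  }
  n <- nrow(a)
  if (n < 3) {
    abort("at least 3 samples are required", class = "droughtrank_input_error")
  }
  va <- upper_tri_vec(a)
  r_obs <- cor(va, upper_tri_vec(b), method = method)
  stat <- function(perm) cor(va, upper_tri_vec(b[perm, perm]), method = method)
  if (exact) {
    if (n > 7) {
      abort("exact mode enumerates n! permutations; limited to n <= 7",
            class = "droughtrank_input_error")
    }
    perms <- all_permutations(n)
    r_all <- vapply(perms, stat, numeric(1))
    p <- sum(r_all >= r_obs - 1e-12) / length(perms)
    n_used <- length(perms)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    r_null <- replicate(n_perm, stat(sample.int(n)))
    p <- (1 + sum(r_null >= r_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(
    list(r = r_obs, p_perm = p, n_perm = n_used, method = method,
         exact = exact, n_samples = n),
    class = "mantel_result"
  )
}

# all permutations of 1..n as a list of integer vectors (n <= 7 in practice)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos)
    }
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s%s): r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$method, if (x$exact) ", exact" else "", x$r, x$p_perm,
              x$n_perm, x$n_samples))
  invisible(x)
}

#' @rdname mantel_test
#' @param x a `mantel_result` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p_perm = x$p_perm, n_perm = x$n_perm,
                 method = x$method, exact = x$exact, n_samples = x$n_samples)
}

#' @rdname mantel_test
#' @exportS3Method generics::glance
glance.mantel_result <- function(x, ...) tidy(x)

#' Euclidean distance on standardized columns
#'
#' The default distance used when feeding tabular data (samples x variables)
#' to [mantel_test()]: columns are centred and scaled before Euclidean
#' distance, so variables on different scales contribute comparably.
#'
#' @param df data frame with a `sample` column plus numeric columns, or a
#'   numeric matrix with sample rownames.
#' @return a `dist` object.
#' @export
standardized_dist <- function(df) {
  if (is.data.frame(df)) {
    check_columns(df, "sample", "sample table")
    m <- as.matrix(df[setdiff(names(df), "sample")])
    rownames(m) <- df$sample
  } else {
    m <- df
  }
  zs <- scale(m)
  zs[, attr(zs, "scaled:scale") == 0] <- 0
  dist(zs)
}
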