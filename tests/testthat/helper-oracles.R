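# Independent oracles used to validate the closed-form / engine code paths.
# These are deliberately written as brute-force enumerations, separate from
# the package implementations they check.

# hypergeometric upper-tail P(X >= k) by exhaustive enumeration of all
# C(M, n) possible draws of the query from the universe
enum_hypergeom_p <- function(M, K, n, k) {
  draws <- utils::combn(M, n)          # columns are draws; set = 1..K
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# all permutations of 1..n via Heap's algorithm (iterative), independent of
# the package's recursive generator
heap_permutations <- function(n) {
  a <- seq_len(n)
  out <- list(a)
  c_counts <- integer(n)
  i <- 1L
  while (i <= n) {
    if (c_counts[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        j <- c_counts[i] + 1L
        tmp <- a[j]; a[j] <- a[i]; a[i] <- tmp
      }
      out[[length(out) + 1L]] <- a
      c_counts[i] <- c_counts[i] + 1L
      i <- 1L
    } else {
      c_counts[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# Mantel exact p by full enumeration: proportion of permutations of the
# second matrix whose upper-triangle correlation reaches the observed one
enum_mantel_p <- function(a, b) {
  ut <- function(m) m[upper.tri(m)]
  r_obs <- stats::cor(ut(a), ut(b))
  perms <- heap_permutations(nrow(a))
  r_all <- vapply(perms, function(p) stats::cor(ut(a), ut(b[p, p])),
                  numeric(1))
  mean(r_all >= r_obs - 1e-12)
}

# grey relational coefficients by direct per-cell formula evaluation on a
# normalized variety x trait matrix (reference = 1 for every trait)
manual_grey_xi <- function(norm_matrix, rho) {
  delta <- abs(norm_matrix - 1)
  dmin <- min(delta)
  dmax <- max(delta)
  xi <- matrix(NA_real_, nrow(delta), ncol(delta),
               dimnames = dimnames(delta))
  for (i in seq_len(nrow(delta))) {
    for (j in seq_len(ncol(delta))) {
      xi[i, j] <- (dmin + rho * dmax) / (delta[i, j] + rho * dmax)
    }
  }
  xi
}

# small deterministic germination count table for two varieties
fixture_counts <- function() {
  tibble::tibble(
    variety = rep(c("A", "B"), each = 6),
    treatment = rep(rep(c("control", "stress"), each = 3), 2),
    day = rep(1:3, 4),
    newly_germinated = c(10, 8, 2, 5, 4, 1,
                         12, 6, 2, 2, 1, 0),
    total_sown = 30
  )
}
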