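#' Power-transformed correlation adjacency
#'
#' Builds an unsigned weighted adjacency from an expression matrix:
#' `w(i, j) = |cor(x_i, x_j)|^beta`, diagonal zero. Expression is
#' log2(x + 1)-transformed first by default (FPKM-like abundances have heavy
#' tails). Zero-variance genes are removed with a message.
#'
#' @param expr data frame with a `gene` id column and one numeric column per
#'   sample, or a numeric matrix with gene rownames.
#' @param beta soft-thresholding power (>= 1); default 6, the usual unsigned
#'   convention.
#' @param log_transform apply `log2(x + 1)` before correlating.
#' @return a list of class `coexpression_adjacency` with `weights` (gene x
#'   gene matrix), `correlation` (signed correlations, for edge signs) and
#'   `beta`.
#' @export
correlation_adjacency <- function(expr, beta = 6, log_transform = TRUE) {
  m <- if (is.matrix(expr)) expr else expr_as_matrix(expr)
  if (ncol(m) < 3) {
    abort("at least 3 samples are required", class = "droughtrank_input_error")
  }
  if (beta < 1) {
    abort("beta must be >= 1", class = "droughtrank_input_error")
  }
  if (log_transform) m <- log2(m + 1)
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    inform(sprintf("removing %d zero-variance gene(s)", sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  r <- cor(t(m))
  w <- abs(r)^beta
  diag(w) <- 0
  diag(r) <- 0
  structure(list(weights = w, correlation = r, beta = beta),
            class = "coexpression_adjacency")
}

# module label palette, ordered by module size (largest first), mirroring the
# colour-name convention of co-expression analyses
module_palette <- function(n) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue")
  if (n <= length(pal)) pal[seq_len(n)] else c(pal, paste0("module", seq_len(n - length(pal))))
}

#' Detect co-expression modules
#'
#' Simplified module detection: average-linkage hierarchical clustering on
#' the dissimilarity `1 - w` of a power adjacency, cut into a fixed number
#' of modules. Deterministic given its inputs. Modules are labelled with
#' colour-style names ordered by decreasing size. This is deliberately a
#' transparent stand-in for full weighted co-expression pipelines
#' (soft-threshold selection, topological overlap, dynamic tree cutting are
#' intentionally out of scope); the module count is an explicit parameter.
#'
#' @param adjacency a `coexpression_adjacency` (or a symmetric weight
#'   matrix in `[0, 1]` with gene dimnames).
#' @param n_modules number of modules to cut (1..n_genes).
#' @return a tibble with columns `gene`, `module`.
#' @export
detect_modules <- function(adjacency, n_modules) {
  w <- if (inherits(adjacency, "coexpression_adjacency")) adjacency$weights else adjacency
  n <- nrow(w)
  if (n_modules < 1 || n_modules > n) {
    abort("n_modules must lie between 1 and the number of genes",
          class = "droughtrank_input_error")
  }
  if (all(w == 0) && n > 1) {
    warn("all-zero adjacency: partition is arbitrary but deterministic")
  }
  d <- stats::as.dist(1 - w)
  hc <- hclust(d, method = "average")
  cut <- cutree(hc, k = n_modules)
  sizes <- sort(table(cut), decreasing = TRUE)
  relabel <- setNames(module_palette(n_modules), names(sizes))
  tibble::tibble(
    gene = rownames(w),
    module = unname(relabel[as.character(cut)])
  )
}

#' Module eigengene
#'
#' First principal component of the standardized expression profiles of a
#' module's member genes, scaled to unit variance, with the sign fixed so
#' that its mean correlation with the member genes is non-negative. The
#' eigengene summarises module activity per sample.
#'
#' @param expr expression table or matrix as in [correlation_adjacency()].
#' @param genes character vector of member gene ids (non-empty).
#' @param log_transform apply `log2(x + 1)` before standardizing.
#' @return a named numeric vector (one value per sample).
#' @export
module_eigengene <- function(expr, genes, log_transform = TRUE) {
  m <- if (is.matrix(expr)) expr else expr_as_matrix(expr)
  if (length(genes) == 0) {
    abort("empty module", class = "droughtrank_input_error")
  }
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) absent from expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "droughtrank_input_error")
  }
  m <- m[genes, , drop = FALSE]
  if (log_transform) m <- log2(m + 1)
  z <- t(scale(t(m)))           # standardize each gene across samples
  z[is.na(z)] <- 0              # constant genes carry no signal
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  e <- pc$x[, 1]
  if (sd(e) > 0) e <- e / sd(e)
  mean_cor <- mean(apply(z, 1, function(g) {
    if (sd(g) == 0 || sd(e) == 0) 0 else cor(g, e)
  }))
  if (mean_cor < 0) e <- -e
  setNames(e, colnames(m))
}

#' Eigengenes for every module
#'
#' @param expr expression table or matrix.
#' @param assignment tibble `gene`, `module` from [detect_modules()].
#' @param log_transform apply `log2(x + 1)` first.
#' @return a tibble with columns `sample`, `module`, `eigengene`.
#' @export
module_eigengenes <- function(expr, assignment, log_transform = TRUE) {
  check_columns(assignment, c("gene", "module"), "module assignment")
  split(assignment$gene, assignment$module) |>
    purrr::imap(function(genes, mod) {
      e <- module_eigengene(expr, genes, log_transform = log_transform)
      tibble::tibble(sample = names(e), module = mod, eigengene = unname(e))
    }) |>
    purrr::list_rbind()
}

#' Module-trait correlation
#'
#' Pearson correlation (with two-sided p) between every module eigengene and
#' every sample-level trait, the heatmap behind module prioritisation.
#' Constant traits yield missing correlations with a warning.
#'
#' @param eigengenes tibble `sample`, `module`, `eigengene` from
#'   [module_eigengenes()].
#' @param traits data frame with a `sample` column and one numeric column
#'   per trait.
#' @return a tibble with columns `module`, `trait`, `r`, `pvalue`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  check_columns(eigengenes, c("sample", "module", "eigengene"), "eigengene table")
  check_columns(traits, "sample", "trait table")
  ew <- tidyr::pivot_wider(eigengenes, names_from = "module",
                           values_from = "eigengene")
  misaligned <- c(setdiff(ew$sample, traits$sample),
                  setdiff(traits$sample, ew$sample))
  if (length(misaligned) > 0) {
    abort(sprintf("samples not shared between eigengenes and traits: %s",
                  paste(unique(misaligned), collapse = ", ")),
          class = "droughtrank_alignment_error")
  }
  traits <- traits[match(ew$sample, traits$sample), ]
  trait_cols <- setdiff(names(traits), "sample")
  mod_cols <- setdiff(names(ew), "sample")
  res <- tidyr::expand_grid(module = mod_cols, trait = trait_cols) |>
    dplyr::mutate(purrr::map2_dfr(.data$module, .data$trait, function(m, tr) {
      x <- ew[[m]]; y <- traits[[tr]]
      if (sd(y) == 0 || sd(x) == 0) {
        warn(sprintf("constant values for %s/%s: correlation undefined", m, tr))
        return(tibble::tibble(r = NA_real_, pvalue = NA_real_))
      }
      ct <- cor.test(x, y)
      tibble::tibble(r = unname(ct$estimate), pvalue = ct$p.value)
    }))
  res
}

#' Hub genes by intramodular degree
#'
#' Within each module, keeps edges with weight at or above a threshold and
#' ranks genes by their count of retained intramodular edges (degree), with
#' ties broken by mean incident edge weight and then gene id. The top genes
#' per module are reported as hub genes.
#'
#' @param adjacency a `coexpression_adjacency` or weight matrix.
#' @param assignment tibble `gene`, `module`.
#' @param top_k hubs per module (default 5).
#' @param edge_threshold minimum weight for a retained edge (default 0.8).
#' @return a tibble with columns `module`, `gene`, `degree`,
#'   `mean_edge_weight`, `rank`, at most `top_k` rows per module (the whole
#'   module, with a warning, when it is smaller).
#' @export
hub_genes <- function(adjacency, assignment, top_k = 5, edge_threshold = 0.8) {
  if (top_k < 1) {
    abort("top_k must be >= 1", class = "droughtrank_input_error")
  }
  w <- if (inherits(adjacency, "coexpression_adjacency")) adjacency$weights else adjacency
  check_columns(assignment, c("gene", "module"), "module assignment")
  split(assignment$gene, assignment$module) |>
    purrr::imap(function(genes, mod) {
      if (length(genes) < top_k) {
        warn(sprintf("module %s has fewer than top_k genes; returning all", mod))
      }
      sub <- w[genes, genes, drop = FALSE]
      keep <- sub >= edge_threshold
      diag(keep) <- FALSE
      degree <- rowSums(keep)
      mean_w <- ifelse(degree > 0, rowSums(sub * keep) / pmax(degree, 1), 0)
      ord <- order(-degree, -mean_w, genes)
      tibble::tibble(
        module = mod, gene = genes[ord],
        degree = as.integer(degree[ord]),
        mean_edge_weight = mean_w[ord],
        rank = seq_along(genes)
      ) |>
        dplyr::slice_head(n = top_k)
    }) |>
    purrr::list_rbind()
}

#' Export a thresholded edge list
#'
#' Flattens an adjacency into an undirected edge table (each pair once,
#' `source < target` lexicographically) for external network tools.
#'
#' @param adjacency a `coexpression_adjacency` or weight matrix.
#' @param threshold minimum weight in `[0, 1]`.
#' @param genes optional subset of gene ids to restrict to.
#' @return a tibble with columns `source`, `target`, `weight`, `sign`
#'   (`"+"`/`"-"` from the signed correlation; `"+"` when unavailable).
#' @export
export_edge_list <- function(adjacency, threshold = 0.8, genes = NULL) {
  if (threshold < 0 || threshold > 1) {
    abort("threshold must lie in [0, 1]", class = "droughtrank_input_error")
  }
  w <- if (inherits(adjacency, "coexpression_adjacency")) adjacency$weights else adjacency
  r <- if (inherits(adjacency, "coexpression_adjacency")) adjacency$correlation else NULL
  if (!is.null(genes)) {
    w <- w[genes, genes, drop = FALSE]
    if (!is.null(r)) r <- r[genes, genes, drop = FALSE]
  }
  ids <- rownames(w)
  pairs <- which(upper.tri(w) & w >= threshold, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          weight = numeric(), sign = character()))
  }
  a <- ids[pairs[, 1]]; b <- ids[pairs[, 2]]
  src <- pmin(a, b); tgt <- pmax(a, b)
  tibble::tibble(
    source = src, target = tgt,
    weight = w[pairs],
    sign = if (is.null(r)) "+" else ifelse(r[pairs] >= 0, "+", "-")
  ) |>
    dplyr::arrange(.data$source, .data$target)
}

#' Gene-trait correlations with permutation p-values
#'
#' Correlates individual gene expression profiles (e.g. hub genes) with
#' sample-level physiological traits, attaching a permutation p-value and a
#' sign classification. Run it per variety to expose variety-specific sign
#' reversals (a tolerant variety's hubs tracking CAT positively while the
#' sensitive variety's track it negatively).
#'
#' @param expr expression table or matrix.
#' @param traits data frame with `sample` plus numeric trait columns;
#'   samples must match the expression columns.
#' @param genes gene ids to test (default: all rows of `expr`).
#' @param n_perm number of permutations for the p-value (default 999).
#' @param seed integer seed for the permutations.
#' @param method `"pearson"` or `"spearman"`.
#' @param log_transform apply `log2(x + 1)` to expression first.
#' @return a tibble with columns `gene`, `trait`, `r`, `p_perm`, `sign`.
#' @export
gene_trait_correlation <- function(expr, traits, genes = NULL, n_perm = 999,
                                   seed = 1, method = c("pearson", "spearman"),
                                   log_transform = TRUE) {
  method <- match.arg(method)
  m <- if (is.matrix(expr)) expr else expr_as_matrix(expr)
  check_columns(traits, "sample", "trait table")
  genes <- genes %||% rownames(m)
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) absent from expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "droughtrank_input_error")
  }
  misaligned <- c(setdiff(colnames(m), traits$sample),
                  setdiff(traits$sample, colnames(m)))
  if (length(misaligned) > 0) {
    abort(sprintf("samples not shared between expression and traits: %s",
                  paste(unique(misaligned), collapse = ", ")),
          class = "droughtrank_alignment_error")
  }
  traits <- traits[match(colnames(m), traits$sample), ]
  if (log_transform) m <- log2(m + 1)
  trait_cols <- setdiff(names(traits), "sample")
  ns <- ncol(m)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  perms <- replicate(n_perm, sample.int(ns), simplify = FALSE)
  tidyr::expand_grid(gene = genes, trait = trait_cols) |>
    dplyr::mutate(purrr::map2_dfr(.data$gene, .data$trait, function(g, tr) {
      x <- m[g, ]; y <- traits[[tr]]
      if (sd(x) == 0 || sd(y) == 0) {
        warn(sprintf("constant values for %s/%s: correlation undefined", g, tr))
        return(tibble::tibble(r = NA_real_, p_perm = NA_real_,
                              sign = NA_character_))
      }
      r_obs <- cor(x, y, method = method)
      r_null <- purrr::map_dbl(perms, ~ cor(x, y[.x], method = method))
      # two-sided add-one permutation p on |r|
      p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1)
      tibble::tibble(r = r_obs, p_perm = p,
                     sign = ifelse(r_obs >= 0, "positive", "negative"))
    }))
}
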