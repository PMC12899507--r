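#' Cluster varieties into tolerance groups
#'
#' Groups varieties by their stress/control relative indices using K-means on
#' standardized columns, then relabels clusters `I`, `II`, ... in order of
#' decreasing centroid mean so that group `I` is always the most tolerant and
#' labels are deterministic for a given seed and input.
#'
#' Missing cells are mean-imputed within each index column (with a warning);
#' columns with zero variance are left unscaled but centred.
#'
#' @param rel data frame with a `variety` column and one numeric column per
#'   relative index (e.g. the output of [relative_germination_indices()]).
#' @param k number of groups (>= 2, <= number of varieties).
#' @param seed integer seed controlling the K-means restarts.
#' @param nstart number of K-means restarts (default 25).
#' @return an object of class `tolerance_grouping`: a list with
#'   `assignments` (tibble `variety`, `group`, `mean_relative`),
#'   `centroids` (tibble, one row per group, on the original scale),
#'   and `k`.
#' @examples
#' rel <- tibble::tibble(
#'   variety = paste0("V", 1:6),
#'   rel_GR = c(0.9, 0.95, 0.92, 0.3, 0.25, 0.28),
#'   rel_GI = c(0.8, 0.85, 0.83, 0.2, 0.22, 0.18)
#' )
#' cluster_tolerance_groups(rel, k = 2, seed = 1)
#' @export
cluster_tolerance_groups <- function(rel, k = 4, seed = 1, nstart = 25) {
  check_columns(rel, "variety", "relative index table")
  value_cols <- setdiff(names(rel), "variety")
  if (length(value_cols) == 0) {
    abort("no index columns to cluster on", class = "droughtrank_input_error")
  }
  if (k < 1 || k > nrow(rel)) {
    abort("k must lie between 1 and the number of varieties",
          class = "droughtrank_input_error")
  }
  # deterministic row order regardless of input ordering
  rel <- dplyr::arrange(rel, .data$variety)
  x <- as.matrix(rel[value_cols])
  rownames(x) <- rel$variety
  if (anyNA(x)) {
    warn("missing relative indices mean-imputed within column")
    for (j in seq_len(ncol(x))) {
      x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0  # constant columns carry no signal
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  if (k == nrow(xs)) {
    # saturated cut: every variety is its own group
    km <- list(cluster = seq_len(k))
  } else {
    km <- suppressWarnings(kmeans(xs, centers = k, nstart = nstart,
                                  iter.max = 100))
  }
  # relabel clusters I..k by decreasing mean relative index of their centroid
  raw_means <- tapply(rowMeans(x), km$cluster, mean)
  new_order <- order(-raw_means, as.integer(names(raw_means)))
  relabel <- setNames(seq_len(k), names(raw_means)[new_order])
  group_num <- relabel[as.character(km$cluster)]
  assignments <- tibble::tibble(
    variety = rel$variety,
    group = as.roman(group_num) |> as.character() |> factor(levels = as.character(as.roman(1:k))),
    mean_relative = rowMeans(x)
  )
  centroids <- assignments |>
    dplyr::bind_cols(tibble::as_tibble(x)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols), mean),
                     .groups = "drop")
  structure(
    list(assignments = assignments, centroids = centroids, k = k, seed = seed),
    class = "tolerance_grouping"
  )
}

#' @export
print.tolerance_grouping <- function(x, ...) {
  cat(sprintf("Tolerance grouping: %d varieties in %d groups (I = most tolerant)\n",
              nrow(x$assignments), x$k))
  print(dplyr::count(x$assignments, .data$group))
  invisible(x)
}

#' @rdname cluster_tolerance_groups
#' @param x a `tolerance_grouping` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.tolerance_grouping <- function(x, ...) x$assignments

#' @rdname cluster_tolerance_groups
#' @exportS3Method generics::glance
glance.tolerance_grouping <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_varieties = nrow(x$assignments),
    seed = x$seed
  )
}
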