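#' Filter differentially expressed genes from a DE table
#'
#' Classifies genes as up- or down-regulated by a log2 fold-change magnitude
#' cut and a raw p-value cut: up when `log2fc >= lfc_cut` and `pvalue <
#' p_cut`, down when `log2fc <= -lfc_cut` and `pvalue < p_cut`. The default
#' `lfc_cut = 2` reads "log2 fold change of 2" literally (a 4-fold change);
#' use `lfc_cut = 1` for the 2-fold-change reading.
#'
#' @param table data frame with columns `gene`, `log2fc`, `pvalue` (an
#'   optional `contrast` column is preserved and filtering is applied within
#'   contrast).
#' @param lfc_cut non-negative log2 fold-change magnitude threshold.
#' @param p_cut p-value threshold, strict (`<`), in `(0, 1]`.
#' @param adjust if `TRUE`, apply Benjamini-Hochberg adjustment within each
#'   contrast and threshold the adjusted value instead of the raw p.
#' @return a tibble of the passing rows with an added `direction` column
#'   (`"up"` or `"down"`).
#' @examples
#' tab <- tibble::tibble(gene = c("a", "b", "c", "d"),
#'                       log2fc = c(3, 1, -2.5, 4),
#'                       pvalue = c(0.01, 0.01, 0.04, 0.2))
#' filter_degs(tab) # a up, c down
#' @export
filter_degs <- function(table, lfc_cut = 2, p_cut = 0.05, adjust = FALSE) {
  check_columns(table, c("gene", "log2fc", "pvalue"), "DE table")
  if (lfc_cut < 0) {
    abort("lfc_cut must be non-negative", class = "droughtrank_input_error")
  }
  if (p_cut <= 0 || p_cut > 1) {
    abort("p_cut must lie in (0, 1]", class = "droughtrank_input_error")
  }
  bad_p <- !is.finite(table$pvalue) | table$pvalue < 0 | table$pvalue > 1
  bad_l <- !is.finite(table$log2fc)
  if (any(bad_p | bad_l)) {
    abort(sprintf("malformed p-value or log2fc for gene(s): %s",
                  paste(head(table$gene[bad_p | bad_l], 5), collapse = ", ")),
          class = "droughtrank_schema_error")
  }
  if (!"contrast" %in% names(table)) table$contrast <- "contrast_1"
  dup <- table |>
    dplyr::count(.data$contrast, .data$gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate gene id(s) within contrast: %s",
                  paste(head(dup$gene, 5), collapse = ", ")),
          class = "droughtrank_schema_error")
  }
  tab <- table |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(p_test = if (adjust) p.adjust(.data$pvalue, "BH") else .data$pvalue) |>
    dplyr::ungroup()
  tab |>
    dplyr::filter(abs(.data$log2fc) >= lfc_cut, .data$p_test < p_cut,
                  # sign classification at the boundary lfc_cut = 0
                  .data$log2fc != 0 | lfc_cut > 0) |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    dplyr::select(-"p_test") |>
    tibble::as_tibble()
}

#' DEG sets per contrast
#'
#' Convenience split of a filtered DEG tibble into named lists of gene ids.
#'
#' @param degs output of [filter_degs()].
#' @return a named list (one element per contrast) of lists with `up`,
#'   `down`, and `all` (union) character vectors.
#' @export
deg_sets <- function(degs) {
  check_columns(degs, c("contrast", "gene", "direction"), "DEG table")
  split(degs, degs$contrast) |>
    purrr::map(function(d) {
      list(up = d$gene[d$direction == "up"],
           down = d$gene[d$direction == "down"],
           all = d$gene)
    })
}

#' Multi-contrast intersection and Venn regions
#'
#' Intersects two or three gene sets and reports every Venn region
#' cardinality, the device used to isolate a core stress-responsive gene set
#' shared by all variety/treatment comparisons.
#'
#' @param sets named list of >= 2 character vectors of gene ids.
#' @return a list with `shared` (character vector, the full intersection,
#'   sorted) and `regions` (tibble with one row per Venn region: a
#'   membership pattern over the input sets and its cardinality).
#' @examples
#' contrast_intersection(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' @export
contrast_intersection <- function(sets) {
  if (length(sets) < 2) {
    abort("at least 2 sets are required", class = "droughtrank_input_error")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- purrr::map(sets, unique)
  universe <- sort(unique(unlist(sets)))
  member <- purrr::map(sets, ~ universe %in% .x) |> tibble::as_tibble()
  pattern <- tidyr::expand_grid(!!!purrr::map(sets, ~ c(TRUE, FALSE)))
  counts <- purrr::map_int(seq_len(nrow(pattern)), function(i) {
    want <- unlist(pattern[i, ])
    sum(rowSums(member == matrix(want, nrow(member), length(want),
                                 byrow = TRUE)) == length(want))
  })
  regions <- dplyr::mutate(pattern, n = counts)
  shared <- universe[rowSums(as.matrix(member)) == length(sets)]
  list(shared = sort(shared), regions = regions)
}
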