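#' Grey relational analysis of a variety x trait table
#'
#' Ranks varieties by similarity to an ideal reference series. Each trait is
#' min-max normalized to `[0, 1]` respecting its direction (cost traits are
#' reversed), so the reference series is 1 for every trait. Per-cell
#' deviations `Delta(v, t) = |x(v, t) - 1|` give relational coefficients
#'
#' `xi(v, t) = (Dmin + rho * Dmax) / (Delta(v, t) + rho * Dmax)`
#'
#' with `Dmin`/`Dmax` the global extremes over all cells and `rho` the
#' distinguishing coefficient. The relational degree `gamma(v)` is the mean
#' of `xi(v, t)` over traits; varieties are ranked by descending gamma.
#'
#' If all varieties are identical (`Dmax = 0`) every gamma is 1 and a warning
#' is issued.
#'
#' @param values long data frame with columns `variety`, `trait`, `value`.
#' @param direction optional direction map as in [membership_standardize()].
#' @param rho distinguishing coefficient in `(0, 1]`; conventionally 0.5.
#' @param normalized set `TRUE` when `values` are already normalized to
#'   `[0, 1]` with 1 the ideal (skips the membership rescaling).
#' @return an object of class `grey_relation`: list with `coefficients`
#'   (tibble `variety`, `trait`, `delta`, `xi`), `degrees` (tibble `variety`,
#'   `gamma`, `rank`), `rho`, `delta_min`, `delta_max`.
#' @examples
#' vals <- tidyr::crossing(variety = c("A", "B"), trait = c("t1", "t2")) |>
#'   dplyr::mutate(value = c(1, 1, 0, 0))
#' grey_relational_degree(vals, rho = 0.5, normalized = TRUE)
#' @export
grey_relational_degree <- function(values, direction = NULL, rho = 0.5,
                                   normalized = FALSE) {
  if (rho <= 0 || rho > 1) {
    abort("rho must lie in (0, 1]", class = "droughtrank_input_error")
  }
  check_columns(values, c("variety", "trait", "value"), "trait value table")
  if (length(unique(values$variety)) < 2) {
    abort("grey relational analysis needs at least 2 varieties",
          class = "droughtrank_input_error")
  }
  norm <- if (normalized) {
    dplyr::mutate(values, membership = .data$value)
  } else {
    membership_standardize(values, direction)
  }
  norm <- dplyr::mutate(norm, delta = abs(.data$membership - 1))
  dmin <- min(norm$delta)
  dmax <- max(norm$delta)
  if (dmax == 0) {
    warn("all varieties identical to the reference series; all gamma = 1")
    norm <- dplyr::mutate(norm, xi = 1)
  } else {
    norm <- dplyr::mutate(norm,
                          xi = (dmin + rho * dmax) / (.data$delta + rho * dmax))
  }
  degrees <- norm |>
    dplyr::group_by(.data$variety) |>
    dplyr::summarise(gamma = mean(.data$xi), .groups = "drop") |>
    dplyr::mutate(rank = rank_desc(.data$gamma, .data$variety)) |>
    dplyr::arrange(.data$rank)
  structure(
    list(
      coefficients = dplyr::select(norm, "variety", "trait", "delta", "xi"),
      degrees = degrees,
      rho = rho, delta_min = dmin, delta_max = dmax
    ),
    class = "grey_relation"
  )
}

#' @export
print.grey_relation <- function(x, ...) {
  cat(sprintf("Grey relational analysis (rho = %g)\n", x$rho))
  print(x$degrees)
  invisible(x)
}

#' @rdname grey_relational_degree
#' @param x a `grey_relation` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.grey_relation <- function(x, ...) x$degrees

#' @rdname grey_relational_degree
#' @exportS3Method generics::glance
glance.grey_relation <- function(x, ...) {
  tibble::tibble(
    rho = x$rho,
    delta_min = x$delta_min,
    delta_max = x$delta_max,
    n_varieties = nrow(x$degrees)
  )
}
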