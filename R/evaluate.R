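#' Comprehensive drought-tolerance evaluation of varieties
#'
#' Runs the full comprehensive evaluation on one value per variety and trait:
#' fuzzy-membership standardization, composite D scoring and grey relational
#' ranking, and flags any disagreement between the two rankings.
#'
#' Values can be raw trait responses (e.g. the timepoint-averaged
#' stress/control ratios from [trait_responses()]) or membership values taken
#' directly from a published evaluation table; in the latter case pass
#' `values_are_memberships = TRUE` to skip restandardization.
#'
#' @param values long data frame with columns `variety`, `trait`, `value`.
#' @param direction optional trait direction map (see [trait_directions()]).
#' @param weights optional trait weights for the D score; default uniform.
#'   `weights = "grey"` derives weights from the grey relational coefficients
#'   (mean xi per trait, normalized), a common hybrid of the two methods.
#' @param rho distinguishing coefficient for the grey relational step.
#' @param values_are_memberships if `TRUE`, `value` is already a membership
#'   in `[0, 1]` with 1 ideal.
#' @return an object of class `drought_eval`: list with `membership`,
#'   `d_scores`, `grey` (a `grey_relation`), and `rank_agreement` (tibble
#'   per variety with both ranks and a `concordant` flag).
#' @examples
#' vals <- tidyr::crossing(variety = c("A", "B", "C"), trait = c("t1", "t2")) |>
#'   dplyr::mutate(value = c(5, 4, 3, 2, 1, 1.5))
#' ev <- evaluate_varieties(vals)
#' tidy(ev)
#' @export
evaluate_varieties <- function(values, direction = NULL, weights = NULL,
                               rho = 0.5, values_are_memberships = FALSE) {
  check_columns(values, c("variety", "trait", "value"), "trait value table")
  membership <- if (values_are_memberships) {
    if (any(values$value < 0 | values$value > 1)) {
      abort("membership values must lie in [0, 1]",
            class = "droughtrank_input_error")
    }
    dplyr::mutate(values, membership = .data$value)
  } else {
    membership_standardize(values, direction)
  }
  grey <- grey_relational_degree(
    dplyr::select(membership, "variety", "trait", value = "membership"),
    rho = rho, normalized = TRUE
  )
  if (identical(weights, "grey")) {
    weights <- grey$coefficients |>
      dplyr::group_by(.data$trait) |>
      dplyr::summarise(weight = mean(.data$xi), .groups = "drop")
  }
  d_scores <- composite_d(membership, weights = weights)
  agreement <- d_scores |>
    dplyr::select("variety", d_rank = "rank") |>
    dplyr::left_join(dplyr::select(grey$degrees, "variety", grey_rank = "rank"),
                     by = "variety") |>
    dplyr::mutate(concordant = .data$d_rank == .data$grey_rank)
  if (!all(agreement$concordant)) {
    inform(sprintf(
      "D-score and grey relational rankings disagree for: %s",
      paste(agreement$variety[!agreement$concordant], collapse = ", ")
    ))
  }
  structure(
    list(membership = membership, d_scores = d_scores, grey = grey,
         rank_agreement = agreement),
    class = "drought_eval"
  )
}

#' @export
print.drought_eval <- function(x, ...) {
  cat("Comprehensive drought-tolerance evaluation\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname evaluate_varieties
#' @param x a `drought_eval` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.drought_eval <- function(x, ...) {
  x$d_scores |>
    dplyr::left_join(dplyr::select(x$grey$degrees, "variety", "gamma",
                                   grey_rank = "rank"),
                     by = "variety")
}

#' @rdname evaluate_varieties
#' @exportS3Method generics::glance
glance.drought_eval <- function(x, ...) {
  tibble::tibble(
    n_varieties = nrow(x$d_scores),
    n_traits = length(unique(x$membership$trait)),
    rho = x$grey$rho,
    rankings_concordant = all(x$rank_agreement$concordant)
  )
}

#' @rdname evaluate_varieties
#' @param object a `drought_eval` object (for `autoplot`).
#' @export
autoplot.drought_eval <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("d_score", "gamma"),
                        names_to = "method", values_to = "score") |>
    dplyr::mutate(method = dplyr::recode(.data$method,
                                         d_score = "composite D",
                                         gamma = "grey relational degree"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variety, -.data$score),
    y = .data$score, fill = .data$method
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "variety", y = "score",
                  title = "Drought-tolerance evaluation") +
    ggplot2::theme_minimal()
}
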