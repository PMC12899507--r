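#' Fuzzy membership standardization of a variety x trait table
#'
#' Direction-aware min-max rescaling to `[0, 1]`. For benefit traits
#' `U = (x - min) / (max - min)`; for cost traits the scale is reversed,
#' `U = (max - x) / (max - min)`, so that a membership of 1 always marks the
#' most favourable variety for that trait.
#'
#' @param values long data frame with columns `variety`, `trait`, `value`.
#' @param direction data frame with columns `trait`, `direction`
#'   (`"benefit"` or `"cost"`), e.g. from [trait_directions()]; traits absent
#'   from it default to benefit.
#' @param on_constant what to do with a trait column whose values are all
#'   equal: `"error"` (default) or `"half"` (membership 0.5 everywhere, with
#'   a warning).
#' @return a tibble with columns `variety`, `trait`, `value`, `direction`,
#'   `xmin`, `xmax`, `membership`.
#' @examples
#' vals <- tidyr::crossing(variety = c("A", "B", "C"), trait = "t1") |>
#'   dplyr::mutate(value = c(1, 3, 5))
#' membership_standardize(vals)
#' @export
membership_standardize <- function(values, direction = NULL,
                                   on_constant = c("error", "half")) {
  on_constant <- match.arg(on_constant)
  check_columns(values, c("variety", "trait", "value"), "trait value table")
  dir_map <- if (is.null(direction)) {
    trait_directions(unique(values$trait))
  } else {
    check_columns(direction, c("trait", "direction"), "direction map")
    direction
  }
  out <- values |>
    dplyr::left_join(dir_map, by = "trait") |>
    dplyr::mutate(direction = dplyr::coalesce(.data$direction, "benefit")) |>
    dplyr::group_by(.data$trait) |>
    dplyr::mutate(xmin = min(.data$value), xmax = max(.data$value)) |>
    dplyr::ungroup()
  constant <- out$xmax == out$xmin
  if (any(constant)) {
    flat <- unique(out$trait[constant])
    if (on_constant == "error") {
      abort(sprintf("constant trait column(s): %s", paste(flat, collapse = ", ")),
            class = "droughtrank_degenerate_error")
    }
    warn(sprintf("constant trait column(s) set to membership 0.5: %s",
                 paste(flat, collapse = ", ")))
  }
  out |>
    dplyr::mutate(
      membership = dplyr::case_when(
        .data$xmax == .data$xmin ~ 0.5,
        .data$direction == "cost" ~
          (.data$xmax - .data$value) / (.data$xmax - .data$xmin),
        TRUE ~ (.data$value - .data$xmin) / (.data$xmax - .data$xmin)
      )
    )
}

#' Composite drought-resistance score (D value)
#'
#' Aggregates per-trait membership values into one score per variety as a
#' weighted convex combination `D(v) = sum_t w_t * U(v, t)`. With the default
#' uniform weights this is the arithmetic mean of the memberships. Varieties
#' are ranked by descending D (ties broken by variety identifier), and a
#' half-up 3-decimal rounding of D is reported alongside full precision for
#' comparison with printed evaluation tables.
#'
#' @param membership long data frame with columns `variety`, `trait`,
#'   `membership` (e.g. from [membership_standardize()], or membership values
#'   entered directly from a published table).
#' @param weights optional data frame with columns `trait`, `weight`
#'   (non-negative; normalized internally). Default: uniform.
#' @param digits decimals for the rounded report column (default 3).
#' @return a tibble with columns `variety`, `d_score`, `d_rounded`, `rank`,
#'   sorted by rank.
#' @examples
#' m <- tidyr::crossing(variety = c("A", "B"), trait = c("t1", "t2")) |>
#'   dplyr::mutate(membership = c(1, 0.8, 0.2, 0.4))
#' composite_d(m)
#' @export
composite_d <- function(membership, weights = NULL, digits = 3) {
  check_columns(membership, c("variety", "trait", "membership"),
                "membership table")
  if (anyNA(membership$membership)) {
    abort("membership table contains missing cells",
          class = "droughtrank_input_error")
  }
  traits <- unique(membership$trait)
  if (is.null(weights)) {
    weights <- tibble::tibble(trait = traits, weight = 1 / length(traits))
  } else {
    check_columns(weights, c("trait", "weight"), "weight table")
    if (any(weights$weight < 0)) {
      abort("weights must be non-negative", class = "droughtrank_input_error")
    }
    missing_w <- setdiff(traits, weights$trait)
    if (length(missing_w) > 0) {
      abort(sprintf("no weight for trait(s): %s", paste(missing_w, collapse = ", ")),
            class = "droughtrank_input_error")
    }
    weights <- dplyr::mutate(weights, weight = .data$weight / sum(.data$weight))
  }
  scores <- membership |>
    dplyr::left_join(weights, by = "trait") |>
    dplyr::group_by(.data$variety) |>
    dplyr::summarise(d_score = sum(.data$weight * .data$membership),
                     .groups = "drop")
  scores |>
    dplyr::mutate(
      d_rounded = round_half_up(.data$d_score, digits),
      rank = rank_desc(.data$d_score, .data$variety)
    ) |>
    dplyr::arrange(.data$rank)
}
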