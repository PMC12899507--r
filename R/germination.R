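#' Germination rate
#'
#' Percentage of sown seeds that emerged as seedlings: `GR = Ne / N * 100`,
#' where `Ne` is the number of emerged seedlings and `N` the total sown.
#'
#' @param emerged number of emerged seedlings (`Ne`).
#' @param sown total number of seeds sown (`N`); must be positive.
#' @return germination rate in percent, in `[0, 100]`.
#' @examples
#' germination_rate(27, 30)
#' @export
germination_rate <- function(emerged, sown) {
  if (any(sown <= 0)) {
    abort("total seeds sown must be positive", class = "droughtrank_input_error")
  }
  if (any(emerged < 0) || any(emerged > sown)) {
    abort("emerged count must lie in [0, sown]", class = "droughtrank_input_error")
  }
  emerged / sown * 100
}

#' Germination energy
#'
#' Early-germination vigour: the mean of the two daily counts with the most
#' newly germinated seeds (`Gt`), as a percentage of seeds sown. When only a
#' single day is recorded, `Gt` is that day's count.
#'
#' @param daily vector of newly germinated counts, one per scoring day.
#' @param sown total number of seeds sown; must be positive.
#' @return germination energy in percent.
#' @examples
#' germination_energy(c(10, 8, 2), 30) # Gt = mean(10, 8) = 9 -> 30%
#' @export
germination_energy <- function(daily, sown) {
  if (length(daily) == 0) {
    abort("at least one daily germination count is required",
          class = "droughtrank_input_error")
  }
  if (any(sown <= 0)) {
    abort("total seeds sown must be positive", class = "droughtrank_input_error")
  }
  if (any(daily < 0)) {
    abort("daily counts must be non-negative", class = "droughtrank_input_error")
  }
  top <- sort(daily, decreasing = TRUE)
  gt <- if (length(top) == 1) top else mean(top[1:2])
  gt / sown * 100
}

#' Germination index
#'
#' Speed-weighted germination total `GI = sum(Gn / Dn)` over scoring days,
#' where `Gn` seeds newly germinate on day `Dn`. Earlier germination counts
#' more.
#'
#' @param daily vector of newly germinated counts.
#' @param days scoring days (>= 1), same length as `daily`, strictly
#'   increasing.
#' @return dimensionless germination index, >= 0.
#' @examples
#' germination_index(c(5, 3, 2), c(1, 2, 4)) # 5/1 + 3/2 + 2/4 = 7
#' @export
germination_index <- function(daily, days) {
  if (length(daily) != length(days)) {
    abort("daily counts and days must have the same length",
          class = "droughtrank_input_error")
  }
  if (any(days < 1)) {
    abort("scoring days must be >= 1", class = "droughtrank_input_error")
  }
  if (any(daily < 0)) {
    abort("daily counts must be non-negative", class = "droughtrank_input_error")
  }
  sum(daily / days)
}

#' Stress-tolerance indicator (relative index)
#'
#' Ratio of a stressed measurement to its paired control: the tolerance
#' indicator applied uniformly to germination rate, energy, index, root
#' length and shoot length. Equals 1 when stress leaves the trait unchanged.
#'
#' @param stress value under stress.
#' @param control value under control; must be non-zero.
#' @param context optional label (variety/index) used in error messages.
#' @return ratio `stress / control`.
#' @examples
#' relative_index(45, 90)
#' @export
relative_index <- function(stress, control, context = NULL) {
  bad <- control == 0
  if (any(bad)) {
    abort(paste0(
      "relative index undefined: control value is zero",
      if (!is.null(context)) paste0(" (", paste(context[bad], collapse = ", "), ")")
    ), class = "droughtrank_ratio_error")
  }
  stress / control
}

#' Germination indices per variety and treatment
#'
#' Summarises a daily germination count table into the three germination
#' indices (rate, energy, index) per variety and treatment, optionally joined
#' with mean seedling root/shoot lengths.
#'
#' @param counts data frame with columns `variety`, `treatment`, `day`,
#'   `newly_germinated`, `total_sown`. `treatment` must use the values
#'   `"control"` and `"stress"`.
#' @param seedlings optional data frame with columns `variety`, `treatment`,
#'   `replicate`, `root_mm`, `shoot_mm`.
#' @return a tibble with one row per variety x treatment and columns `GR`,
#'   `GE`, `GI` (plus `root_mm`, `shoot_mm` means when `seedlings` is given).
#' @seealso [relative_germination_indices()], [cluster_tolerance_groups()]
#' @export
germination_indices <- function(counts, seedlings = NULL) {
  check_columns(counts, c("variety", "treatment", "day", "newly_germinated",
                          "total_sown"), "germination count table")
  bad_trt <- setdiff(unique(counts$treatment), c("control", "stress"))
  if (length(bad_trt) > 0) {
    abort(sprintf("unknown treatment label(s): %s", paste(bad_trt, collapse = ", ")),
          class = "droughtrank_schema_error")
  }
  out <- counts |>
    dplyr::group_by(.data$variety, .data$treatment) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      total_sown = .data$total_sown[1],
      GR = germination_rate(sum(.data$newly_germinated), .data$total_sown[1]),
      GE = germination_energy(.data$newly_germinated, .data$total_sown[1]),
      GI = germination_index(.data$newly_germinated, .data$day),
      .groups = "drop"
    )
  if (!is.null(seedlings)) {
    check_columns(seedlings, c("variety", "treatment", "root_mm", "shoot_mm"),
                  "seedling table")
    lengths <- seedlings |>
      dplyr::group_by(.data$variety, .data$treatment) |>
      dplyr::summarise(root_mm = mean(.data$root_mm),
                       shoot_mm = mean(.data$shoot_mm), .groups = "drop")
    out <- dplyr::left_join(out, lengths, by = c("variety", "treatment"))
  }
  out
}

#' Relative (stress/control) germination indices
#'
#' Converts per-treatment germination indices into stress-tolerance
#' indicators: one row per variety, each index expressed as its
#' stress/control ratio.
#'
#' @param indices output of [germination_indices()] containing both
#'   treatments for every variety.
#' @return a tibble with one row per variety and columns `rel_<index>`.
#' @export
relative_germination_indices <- function(indices) {
  check_columns(indices, c("variety", "treatment"), "indices table")
  value_cols <- setdiff(names(indices), c("variety", "treatment", "total_sown"))
  long <- indices |>
    tidyr::pivot_longer(dplyr::all_of(value_cols),
                        names_to = "index", values_to = "value") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "value")
  if (!all(c("control", "stress") %in% names(long))) {
    abort("both control and stress rows are required for every variety",
          class = "droughtrank_input_error")
  }
  long |>
    dplyr::mutate(relative = relative_index(
      .data$stress, .data$control,
      context = paste(.data$variety, .data$index)
    )) |>
    dplyr::select("variety", "index", "relative") |>
    tidyr::pivot_wider(names_from = "index", values_from = "relative",
                       names_prefix = "rel_")
}
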