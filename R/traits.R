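#' Leaf relative water content
#'
#' `RWC = (FW - DW) / (TW - DW) * 100`, where `FW` is fresh weight, `TW` the
#' saturated (turgid) weight after soaking, and `DW` the dry weight. A
#' hydration index in percent; 100 at full turgor, 0 when fully dry.
#'
#' @param fw fresh weight (g).
#' @param dw dry weight (g).
#' @param tw saturated weight (g); must exceed `dw`.
#' @return relative water content in percent.
#' @examples
#' relative_water_content(fw = 2.0, dw = 0.5, tw = 2.5)
#' @export
relative_water_content <- function(fw, dw, tw) {
  if (any(tw <= dw)) {
    abort("saturated weight must exceed dry weight",
          class = "droughtrank_input_error")
  }
  (fw - dw) / (tw - dw) * 100
}

#' Percent change of a stressed mean relative to control
#'
#' Signed percent change `(stress - control) / control * 100`; negative
#' values are declines under stress. Prose-style reports ("decreased by
#' 9.5%") correspond to the magnitude of a negative value.
#'
#' @param stress mean under stress.
#' @param control mean under control; must be non-zero.
#' @return signed percent change.
#' @examples
#' relative_change(90.5, 100) # -9.5
#' @export
relative_change <- function(stress, control) {
  if (any(control == 0)) {
    abort("percent change undefined: control mean is zero",
          class = "droughtrank_ratio_error")
  }
  (stress - control) / control * 100
}

#' The physiological trait panel and its directions
#'
#' The fourteen traits scored in a multi-timepoint drought trial, with the
#' direction each takes in a membership-function evaluation: `benefit` traits
#' indicate tolerance when high (growth, water status, osmolytes,
#' antioxidant capacity), `cost` traits indicate damage when high (MDA, a
#' lipid-peroxidation product, and REC, electrolyte leakage).
#'
#' @param traits optional character vector; defaults to the full panel.
#' @param cost_traits traits to mark as cost-direction (default MDA and REC).
#' @return a tibble with columns `trait` and `direction`.
#' @export
trait_directions <- function(traits = NULL,
                             cost_traits = c("MDA", "REC")) {
  panel <- c("plant_height", "fresh_weight", "dry_weight", "chlorophyll",
             "RWC", "REC", "MDA", "PRO", "GSH", "SOD", "POD", "SP", "SS",
             "CAT")
  traits <- traits %||% panel
  tibble::tibble(
    trait = traits,
    direction = ifelse(traits %in% cost_traits, "cost", "benefit")
  )
}

#' Summarise a replicate-level trait table
#'
#' Computes per-cell (variety x treatment x timepoint x trait) mean, SD and
#' replicate count from a long replicate-level table.
#'
#' @param raw data frame with columns `variety`, `treatment`, `timepoint_d`,
#'   `trait`, `replicate`, `value` (a `unit` column is carried through if
#'   present).
#' @param treatments allowed treatment labels (default `CK` control and
#'   `PEG` osmotic stress).
#' @return a tibble with columns `variety`, `treatment`, `timepoint_d`,
#'   `trait`, `mean`, `sd` (`NA` for single replicates), `n`.
#' @export
summarize_traits <- function(raw, treatments = c("CK", "PEG")) {
  check_columns(raw, c("variety", "treatment", "timepoint_d", "trait",
                       "replicate", "value"), "trait replicate table")
  if (nrow(raw) == 0) {
    warn("empty trait table: returning empty summary")
    return(tibble::tibble(
      variety = character(), treatment = character(),
      timepoint_d = numeric(), trait = character(),
      mean = numeric(), sd = numeric(), n = integer()
    ))
  }
  bad <- setdiff(unique(raw$treatment), treatments)
  if (length(bad) > 0) {
    abort(sprintf("unknown treatment label(s): %s", paste(bad, collapse = ", ")),
          class = "droughtrank_schema_error")
  }
  raw |>
    dplyr::group_by(.data$variety, .data$treatment, .data$timepoint_d,
                    .data$trait) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Stress/control responses per variety and trait
#'
#' Turns a trait summary into per-variety, per-trait drought responses:
#' the signed percent change and the stress/control ratio, per timepoint and
#' averaged over timepoints. The timepoint-averaged ratio is the default
#' input to the comprehensive evaluation.
#'
#' @param summary output of [summarize_traits()].
#' @param control,stress treatment labels (defaults `CK`, `PEG`).
#' @return a list with `by_timepoint` (tibble: variety, trait, timepoint_d,
#'   pct_change, ratio) and `by_variety` (tibble: variety, trait, ratio =
#'   mean over timepoints).
#' @export
trait_responses <- function(summary, control = "CK", stress = "PEG") {
  check_columns(summary, c("variety", "treatment", "timepoint_d", "trait",
                           "mean"), "trait summary")
  wide <- summary |>
    dplyr::select("variety", "treatment", "timepoint_d", "trait", "mean") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "mean")
  if (!all(c(control, stress) %in% names(wide))) {
    abort("summary must contain both control and stress treatments",
          class = "droughtrank_input_error")
  }
  by_tp <- wide |>
    dplyr::mutate(
      pct_change = relative_change(.data[[stress]], .data[[control]]),
      ratio = .data[[stress]] / .data[[control]]
    ) |>
    dplyr::select("variety", "trait", "timepoint_d", "pct_change", "ratio")
  by_var <- by_tp |>
    dplyr::group_by(.data$variety, .data$trait) |>
    dplyr::summarise(ratio = mean(.data$ratio), .groups = "drop")
  list(by_timepoint = by_tp, by_variety = by_var)
}
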