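#' Relative expression by the 2^-ddCt method
#'
#' Computes relative expression of target genes against a reference gene and
#' a calibrator condition, assuming perfect doubling per cycle. Technical
#' replicates are averaged within each biological sample first; then
#' `dCt = Ct_target - Ct_reference` per sample, `ddCt = mean dCt(condition) -
#' mean dCt(calibrator)`, and `fold = 2^-ddCt`. The biological SD of dCt is
#' propagated to a fold-change interval `2^-(ddCt +/- sd)`.
#'
#' @param ct data frame with columns `gene`, `sample`, `treatment`, `ct`
#'   (optional `bio_rep`, `tech_rep` columns; `sample` identifies the
#'   biological sample within which technical replicates are averaged).
#' @param reference_gene id of the reference gene, measured in every sample.
#' @param calibrator the calibrator condition label (e.g. `"CK"`).
#' @return a tibble with one row per gene x condition: `gene`, `treatment`,
#'   `n_samples`, `delta_ct`, `delta_ct_sd`, `ddct`, `fold`, `log2_fold`,
#'   `fold_lo`, `fold_hi`.
#' @examples
#' ct <- tibble::tibble(
#'   gene = rep(c("g1", "ref"), each = 4),
#'   sample = rep(c("c1", "c2", "t1", "t2"), 2),
#'   treatment = rep(c("CK", "CK", "PEG", "PEG"), 2),
#'   ct = c(25, 25, 22, 22, 20, 20, 20, 20)
#' )
#' delta_delta_ct(ct, reference_gene = "ref", calibrator = "CK")
#' @export
delta_delta_ct <- function(ct, reference_gene, calibrator) {
  check_columns(ct, c("gene", "sample", "treatment", "ct"), "Ct table")
  if (any(ct$ct <= 0)) {
    abort("Ct values must be positive", class = "droughtrank_input_error")
  }
  # average technical replicates within biological sample
  per_sample <- ct |>
    dplyr::group_by(.data$gene, .data$sample, .data$treatment) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- dplyr::filter(per_sample, .data$gene == reference_gene)
  targets <- dplyr::filter(per_sample, .data$gene != reference_gene)
  if (nrow(ref) == 0) {
    abort(sprintf("reference gene %s not found", reference_gene),
          class = "droughtrank_input_error")
  }
  no_ref <- setdiff(unique(targets$sample), ref$sample)
  if (length(no_ref) > 0) {
    abort(sprintf("reference gene missing in sample(s): %s",
                  paste(no_ref, collapse = ", ")),
          class = "droughtrank_input_error")
  }
  dct <- targets |>
    dplyr::left_join(dplyr::select(ref, "sample", ref_ct = "ct"), by = "sample") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ref_ct)
  cond <- dct |>
    dplyr::group_by(.data$gene, .data$treatment) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      delta_ct_sd = if (dplyr::n() > 1) sd(.data$delta_ct) else NA_real_,
      delta_ct = mean(.data$delta_ct),
      .groups = "drop"
    )
  cal <- dplyr::filter(cond, .data$treatment == calibrator)
  if (nrow(cal) == 0) {
    abort(sprintf("calibrator condition %s not found", calibrator),
          class = "droughtrank_input_error")
  }
  cond |>
    dplyr::left_join(dplyr::select(cal, "gene", cal_dct = "delta_ct"),
                     by = "gene") |>
    dplyr::mutate(
      ddct = .data$delta_ct - .data$cal_dct,
      fold = 2^-.data$ddct,
      log2_fold = -.data$ddct,
      fold_lo = 2^-(.data$ddct + dplyr::coalesce(.data$delta_ct_sd, 0)),
      fold_hi = 2^-(.data$ddct - dplyr::coalesce(.data$delta_ct_sd, 0))
    ) |>
    dplyr::select("gene", "treatment", "n_samples", "delta_ct",
                  "delta_ct_sd", "ddct", "fold", "log2_fold", "fold_lo",
                  "fold_hi")
}

#' Concordance between qPCR and RNA-seq fold changes
#'
#' Pearson correlation and fold-change sign agreement between qPCR-derived
#' and RNA-seq log2 fold changes for the genes shared by both tables. This
#' is the standard check that sequencing-derived expression trends are
#' technically reproducible.
#'
#' @param qpcr data frame with columns `gene`, `log2_fold` (e.g. the stress
#'   rows from [delta_delta_ct()]).
#' @param rnaseq data frame with columns `gene`, `log2fc`.
#' @return a one-row tibble with `n_genes`, `r`, `sign_agreement`.
#' @export
concordance_with_rnaseq <- function(qpcr, rnaseq) {
  check_columns(qpcr, c("gene", "log2_fold"), "qPCR table")
  check_columns(rnaseq, c("gene", "log2fc"), "RNA-seq table")
  shared <- dplyr::inner_join(
    dplyr::select(qpcr, "gene", "log2_fold"),
    dplyr::select(rnaseq, "gene", "log2fc"),
    by = "gene"
  )
  if (nrow(shared) < 3) {
    abort("fewer than 3 genes shared between qPCR and RNA-seq tables",
          class = "droughtrank_input_error")
  }
  tibble::tibble(
    n_genes = nrow(shared),
    r = cor(shared$log2_fold, shared$log2fc),
    sign_agreement = mean(sign(shared$log2_fold) == sign(shared$log2fc))
  )
}
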