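#' Published membership values for four oat varieties
#'
#' The fourteen-trait fuzzy membership values reported for the two
#' drought-tolerant oat varieties Muda (MD) and Mengshi No. 1 (MS) and the
#' two drought-sensitive varieties Heike (HK) and Haywire (HW) in a
#' PEG-6000 seedling drought trial. Feeding this table to [composite_d()]
#' with uniform weights reproduces the published composite D scores
#' (MD 0.966, MS 0.972, HK 0.915, HW 0.836) and ranking (MS first, MD
#' second, HK third, HW fourth).
#'
#' @return a long tibble with columns `variety`, `trait`, `membership`.
#' @examples
#' composite_d(oat_reference_memberships())
#' @export
oat_reference_memberships <- function() {
  # rows follow the published table ordering: plant height, fresh weight,
  # dry weight, chlorophyll, RWC, REC, MDA, PRO, GSH, SOD, POD, SP, SS, CAT
  traits <- c("plant_height", "fresh_weight", "dry_weight", "chlorophyll",
              "RWC", "REC", "MDA", "PRO", "GSH", "SOD", "POD", "SP", "SS",
              "CAT")
  md <- c(0.996, 0.987, 0.998, 0.997, 1, 0.996, 0.993, 0.815, 0.982, 0.998,
          0.975, 0.943, 0.971, 0.873)
  ms <- c(0.99, 0.992, 0.967, 0.995, 0.99, 0.998, 0.964, 0.937, 0.975,
          0.974, 0.997, 0.964, 0.983, 0.875)
  hk <- c(0.957, 0.998, 0.908, 0.982, 0.966, 0.972, 0.968, 0.566, 0.973,
          0.905, 0.993, 0.851, 0.984, 0.787)
  hw <- c(0.893, 0.952, 0.834, 0.947, 0.909, 0.931, 0.965, 0.333, 0.801,
          0.79, 0.872, 0.797, 0.968, 0.708)
  tibble::tibble(
    variety = rep(c("MD", "MS", "HK", "HW"), each = length(traits)),
    trait = rep(traits, times = 4),
    membership = c(md, ms, hk, hw)
  )
}
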