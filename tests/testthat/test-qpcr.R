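qpcr_fixture <- function(treat_ct = 22, ctrl_ct = 25, ref_ct = 20) {
  tibble::tibble(
    gene = rep(c("g1", "ref"), each = 4),
    sample = rep(c("c1", "c2", "t1", "t2"), 2),
    treatment = rep(c("CK", "CK", "PEG", "PEG"), 2),
    ct = c(ctrl_ct, ctrl_ct, treat_ct, treat_ct,
           ref_ct, ref_ct, ref_ct, ref_ct)
  )
}

test_that("ddCt fold changes match hand arithmetic", {
  # target drops 3 cycles relative to constant reference: fold 8
  res <- delta_delta_ct(qpcr_fixture(), reference_gene = "ref",
                        calibrator = "CK")
  peg <- dplyr::filter(res, treatment == "PEG")
  expect_equal(peg$ddct, -3)
  expect_equal(peg$fold, 8)
  expect_equal(peg$log2_fold, 3)
  # calibrator condition is exactly fold 1
  ck <- dplyr::filter(res, treatment == "CK")
  expect_equal(ck$fold, 1)
  # ddCt = 0 -> fold 1; ddCt = -1 -> fold 2
  same <- delta_delta_ct(qpcr_fixture(treat_ct = 25), "ref", "CK")
  expect_equal(dplyr::filter(same, treatment == "PEG")$fold, 1)
  dbl <- delta_delta_ct(qpcr_fixture(treat_ct = 24), "ref", "CK")
  expect_equal(dplyr::filter(dbl, treatment == "PEG")$fold, 2)
})

test_that("log2 fold is antisymmetric under swapping condition and calibrator", {
  a <- delta_delta_ct(qpcr_fixture(), "ref", calibrator = "CK")
  b <- delta_delta_ct(qpcr_fixture(), "ref", calibrator = "PEG")
  expect_equal(dplyr::filter(a, treatment == "PEG")$log2_fold,
               -dplyr::filter(b, treatment == "CK")$log2_fold)
  expect_true(all(a$fold > 0))
})

test_that("technical replicates are averaged before biological aggregation", {
  ct <- tibble::tibble(
    gene = rep(c("g1", "ref"), each = 4),
    sample = rep(c("b1", "b1", "b2", "b2"), 2),   # 2 tech reps per bio sample
    treatment = "CK",
    ct = c(24, 26, 25, 25, 20, 20, 20, 20)
  )
  res <- delta_delta_ct(ct, "ref", "CK")
  expect_equal(res$n_samples, 2L)   # biological, not technical, count
  expect_equal(res$delta_ct, 5)
})

test_that("missing reference measurements are reported by sample", {
  ct <- qpcr_fixture()
  broken <- dplyr::filter(ct, !(gene == "ref" & sample == "t1"))
  expect_error(delta_delta_ct(broken, "ref", "CK"), regexp = "t1",
               class = "droughtrank_input_error")
  expect_error(delta_delta_ct(ct, "nope", "CK"),
               class = "droughtrank_input_error")
  expect_error(delta_delta_ct(dplyr::mutate(ct, ct = -ct), "ref", "CK"),
               class = "droughtrank_input_error")
})

test_that("qPCR/RNA-seq concordance measures correlation and sign agreement", {
  qp <- tibble::tibble(gene = paste0("g", 1:6), log2_fold = c(3, -2, 1, 4, -1, 2))
  rs <- tibble::tibble(gene = paste0("g", 1:6), log2fc = qp$log2_fold)
  perfect <- concordance_with_rnaseq(qp, rs)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$sign_agreement, 1)

  flipped <- concordance_with_rnaseq(qp, dplyr::mutate(rs, log2fc = -log2fc))
  expect_equal(flipped$sign_agreement, 0)

  set.seed(81)
  noisy <- concordance_with_rnaseq(
    dplyr::mutate(qp, log2_fold = log2_fold + rnorm(6, 0, 0.2)), rs)
  expect_gt(noisy$r, 0.95)
  expect_equal(noisy$sign_agreement, 1)

  expect_error(concordance_with_rnaseq(qp[1:2, ], rs),
               class = "droughtrank_input_error")
})
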