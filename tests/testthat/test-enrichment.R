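test_that("hypergeometric p equals exhaustive enumeration on small universes", {
  # 5-member set fully contained in a query of 10 from a universe of 20
  coll <- gene_set_collection(list(S = paste0("g", 1:5)),
                              universe = paste0("g", 1:20))
  res <- hypergeometric_enrichment(paste0("g", 1:10), coll)
  expect_equal(res$k, 5)
  expect_equal(res$pvalue, 3003 / 184756)        # C(15,5)/C(20,10)
  expect_equal(res$pvalue, enum_hypergeom_p(20, 5, 10, 5))

  set.seed(51)
  for (i in 1:5) {
    M <- sample(8:14, 1)
    K <- sample(2:(M - 2), 1)
    n <- sample(2:(M - 2), 1)
    universe <- paste0("g", seq_len(M))
    coll <- gene_set_collection(list(S = paste0("g", seq_len(K))),
                                universe = universe)
    query <- sample(universe, n)
    k <- sum(query %in% paste0("g", seq_len(K)))
    res <- hypergeometric_enrichment(query, coll)
    expect_equal(res$pvalue, enum_hypergeom_p(M, K, n, k), tolerance = 1e-12)
  }
})

test_that("enrichment handles vacuous and saturated cases", {
  universe <- paste0("g", 1:10)
  coll <- gene_set_collection(list(S = paste0("g", 1:4)), universe = universe)
  # no overlap -> p = 1
  res0 <- hypergeometric_enrichment(paste0("g", 9:10), coll)
  expect_equal(res0$pvalue, 1)
  # query = universe -> k = K, p = 1
  res_full <- hypergeometric_enrichment(universe, coll)
  expect_equal(res_full$k, res_full$K)
  expect_equal(res_full$pvalue, 1)
  expect_error(hypergeometric_enrichment("g1", gene_set_collection(list())),
               class = "droughtrank_input_error")
  expect_warning(hypergeometric_enrichment(c("g1", "not_here"), coll))
})

test_that("BH adjustment satisfies q >= p and monotonicity in p-order", {
  set.seed(52)
  universe <- sprintf("g%03d", 1:200)
  sets <- purrr::map(1:15, ~ sample(universe, 20))
  names(sets) <- paste0("S", 1:15)
  coll <- gene_set_collection(sets, universe = universe)
  res <- hypergeometric_enrichment(sample(universe, 40), coll)
  expect_true(all(res$qvalue >= res$pvalue - 1e-12))
  expect_true(all(diff(res$qvalue) >= -1e-12))   # sorted by p
  expect_equal(res$qvalue, p.adjust(res$pvalue, "BH"))
})

test_that("GMT files round-trip and dialect quirks are handled", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "TERM1\tfirst set\tg1\tg2\tg3",
    "TERM2\tsecond set\tg2\tg4"
  ), path)
  coll <- read_gmt(path)
  expect_equal(length(coll$sets), 2)
  expect_equal(coll$sets$TERM1, c("g1", "g2", "g3"))
  expect_equal(coll$universe, c("g1", "g2", "g3", "g4"))

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, out)
  expect_equal(read_gmt(out)$sets, coll$sets)

  # duplicated term id: last wins, with warning
  writeLines(c("T\td\tg1", "T\td\tg2"), path)
  expect_warning(dup <- read_gmt(path))
  expect_equal(dup$sets$T, "g2")

  # empty member list dropped with warning
  writeLines(c("T1\td\tg1", "T2\td"), path)
  expect_warning(drop <- read_gmt(path))
  expect_equal(names(drop$sets), "T1")

  writeLines("just_one_field", path)
  expect_error(read_gmt(path), class = "droughtrank_parse_error")

  writeLines(character(0), path)
  expect_warning(empty <- read_gmt(path))
  expect_equal(length(empty$sets), 0)
})
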