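test_that("every simulator is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 99, n_varieties = 6,
                          tau = setNames(seq(0.1, 0.9, length.out = 6),
                                         paste0("V", 1:6)))
  expect_identical(simulate_germination(cfg), simulate_germination(cfg))
  expect_identical(simulate_traits(cfg), simulate_traits(cfg))
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_de_tables(cfg), simulate_de_tables(cfg))
  planted <- tibble::tibble(gene = paste0("G000", 1:3), log2fc = c(3, -2, 4))
  expect_identical(simulate_qpcr(cfg, planted), simulate_qpcr(cfg, planted))
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_germination(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("germination thinning responds to the planted tolerance", {
  # tau = 1: stress retention is 1, so stress equals control exactly
  cfg1 <- generator_config(seed = 5, n_varieties = 1, tau = c(V1 = 1))
  germ <- simulate_germination(cfg1)
  rel <- relative_germination_indices(germination_indices(germ$counts))
  expect_equal(rel$rel_GR, 1)
  expect_equal(rel$rel_GI, 1)

  # tau = 0: relative GR concentrates near the configured floor
  rels <- vapply(1:100, function(s) {
    cfg0 <- generator_config(seed = 1000 + s, n_varieties = 1, tau = c(V1 = 0))
    g <- simulate_germination(cfg0)
    relative_germination_indices(germination_indices(g$counts))$rel_GR
  }, numeric(1))
  expect_lt(abs(mean(rels) - 0.2), 0.03)
})

test_that("trait simulation leaves controls untouched by tolerance", {
  cfg_a <- generator_config(seed = 12, focal_tau = c(A = 0.9, B = 0.8, C = 0.3, D = 0.2))
  cfg_b <- generator_config(seed = 12, focal_tau = c(A = 0.1, B = 0.2, C = 0.6, D = 0.9))
  ck_a <- dplyr::filter(simulate_traits(cfg_a)$raw, treatment == "CK")
  ck_b <- dplyr::filter(simulate_traits(cfg_b)$raw, treatment == "CK")
  expect_equal(ck_a$value, ck_b$value)
})

test_that("noiseless traits reproduce the planted ordering exactly", {
  cfg <- generator_config(seed = 13, noise_sd = 0,
                          focal_tau = c(W = 0.9, X = 0.8, Y = 0.3, Z = 0.2))
  tr <- simulate_traits(cfg)
  resp <- trait_responses(summarize_traits(tr$raw))
  ev <- suppressMessages(evaluate_varieties(
    dplyr::rename(resp$by_variety, value = "ratio")))
  expect_equal(tidy(ev)$variety, c("W", "X", "Y", "Z"))
  expect_equal(tidy(ev)$grey_rank, 1:4)
})

test_that("planted expression modules separate within from between correlation", {
  cfg <- generator_config(seed = 14, n_genes = 120, n_modules = 4)
  sim <- simulate_expression(cfg)
  m <- log2(as.matrix(sim$expr[-1]) + 1)
  rownames(m) <- sim$expr$gene
  r <- abs(cor(t(m)))
  truth <- sim$modules$module[match(rownames(m), sim$modules$gene)]
  same <- outer(truth, truth, "==") & upper.tri(r)
  diff_mod <- outer(truth, truth, "!=") & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[diff_mod]) + 0.4)
  # sample metadata aligns with expression columns
  expect_setequal(sim$samples$sample, colnames(sim$expr)[-1])
  expect_setequal(sim$traits$sample, sim$samples$sample)
})

test_that("planted DE structure passes thresholds only where intended", {
  cfg <- generator_config(seed = 15)
  de <- simulate_de_tables(cfg)
  degs <- filter_degs(de$tables, lfc_cut = cfg$lfc_cut, p_cut = cfg$p_cut)
  sets <- deg_sets(degs)
  shared <- contrast_intersection(purrr::map(sets, "all"))$shared
  expect_setequal(shared, de$shared_genes)
  # null genes are constructed to be unable to cross the default cut
  nulls <- dplyr::anti_join(
    de$tables,
    tibble::tibble(gene = unique(c(de$shared_genes, unlist(de$specific_genes)))),
    by = "gene"
  )
  expect_lt(max(abs(nulls$log2fc)), cfg$lfc_cut)

  cfg0 <- generator_config(seed = 15, n_shared_degs = 0)
  de0 <- simulate_de_tables(cfg0)
  degs0 <- filter_degs(de0$tables, lfc_cut = 2, p_cut = 0.05)
  shared0 <- contrast_intersection(
    purrr::map(deg_sets(degs0), "all"))$shared
  expect_length(shared0, 0)
})

test_that("gene sets plant enrichment signal for the shared DEGs", {
  cfg <- generator_config(seed = 16)
  de <- simulate_de_tables(cfg)
  coll <- simulate_gene_sets(cfg, de$shared_genes)
  res <- hypergeometric_enrichment(de$shared_genes, coll)
  top3 <- res$term[1:3]
  expect_setequal(top3, c("RESP_01", "RESP_02", "RESP_03"))
  expect_true(all(res$qvalue[1:3] < 0.01))
})

test_that("noiseless qPCR recovers planted fold changes exactly", {
  cfg <- generator_config(seed = 17, qpcr_noise_sd = 0)
  planted <- tibble::tibble(gene = c("gA", "gB"), log2fc = c(3, -2))
  sim <- simulate_qpcr(cfg, planted)
  res <- delta_delta_ct(sim$ct, reference_gene = sim$reference_gene,
                        calibrator = "CK")
  peg <- dplyr::filter(res, treatment == "PEG") |> dplyr::arrange(gene)
  expect_equal(peg$log2_fold, c(3, -2))
  expect_equal(peg$fold, c(8, 0.25))
})
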