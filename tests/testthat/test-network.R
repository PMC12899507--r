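# small expression fixture with three planted blocks of correlated genes
planted_blocks <- function(n_per_block = 8, n_samples = 30, noise = 0.3,
                           seed = 61) {
  set.seed(seed)
  factors <- matrix(rnorm(3 * n_samples), 3)
  z <- do.call(rbind, purrr::map(1:3, function(b) {
    t(replicate(n_per_block, factors[b, ] + rnorm(n_samples, 0, noise)))
  }))
  rownames(z) <- sprintf("g%02d", seq_len(3 * n_per_block))
  colnames(z) <- sprintf("s%02d", seq_len(n_samples))
  list(expr = 2^(z + 6), truth = rep(1:3, each = n_per_block))
}

test_that("power adjacency transforms correlations as expected", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),      # identical profile
             c = c(1, -1, 1, -1) + 5)                   # unrelated
  adj <- correlation_adjacency(x, beta = 6, log_transform = FALSE)
  expect_equal(adj$weights["a", "b"], 1)
  expect_equal(diag(adj$weights), setNames(rep(0, 3), rownames(x)))
  expect_true(isSymmetric(adj$weights))
  expect_true(all(adj$weights >= 0 & adj$weights <= 1))
  # r = 0.5 at beta 6
  expect_equal(0.5^6, 0.015625)
  y <- rbind(a = c(0, 1), b = c(1, 0))
  expect_error(correlation_adjacency(y), class = "droughtrank_input_error")
})

test_that("module detection recovers planted blocks and degenerate cuts", {
  fix <- planted_blocks()
  adj <- correlation_adjacency(fix$expr, beta = 6)
  mods <- detect_modules(adj, n_modules = 3)
  ari <- mclust::adjustedRandIndex(mods$module, fix$truth)
  expect_gte(ari, 0.9)

  # saturation: one module per gene
  tiny <- correlation_adjacency(fix$expr[1:4, ], beta = 6)
  singletons <- detect_modules(tiny, n_modules = 4)
  expect_equal(dplyr::n_distinct(singletons$module), 4)
  expect_error(detect_modules(tiny, n_modules = 10),
               class = "droughtrank_input_error")

  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(z1 <- detect_modules(zero, n_modules = 2))
  expect_warning(z2 <- detect_modules(zero, n_modules = 2))
  expect_equal(z1, z2)   # arbitrary but deterministic
})

test_that("module eigengene summarises member activity with fixed sign", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(1, 2, 3, 4, 5),
             g3 = c(1, 2, 3, 4, 5))
  e <- module_eigengene(m, rownames(m), log_transform = FALSE)
  expect_equal(abs(cor(e, m["g1", ])), 1)
  expect_gte(cor(e, m["g1", ]), 0)         # sign convention
  expect_equal(sd(e), 1)

  # profile and its negation: PC1 explains everything, sign fixed
  m2 <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = -c(1, 2, 3, 4, 5))
  e2 <- module_eigengene(m2, rownames(m2), log_transform = FALSE)
  expect_equal(abs(cor(e2, m2["g1", ])), 1)

  expect_error(module_eigengene(m, character(0)),
               class = "droughtrank_input_error")

  # planted latent factor recovered at high SNR
  set.seed(62)
  f <- rnorm(40)
  noisy <- t(replicate(12, f + rnorm(40, 0, sqrt(var(f) / 10))))
  rownames(noisy) <- paste0("g", 1:12)
  e3 <- module_eigengene(noisy, rownames(noisy), log_transform = FALSE)
  expect_gt(abs(cor(e3, f)), 0.95)
})

test_that("module-trait correlation aligns samples and flags degenerate traits", {
  fix <- planted_blocks()
  adj <- correlation_adjacency(fix$expr)
  mods <- detect_modules(adj, n_modules = 3)
  eig <- module_eigengenes(fix$expr, mods)
  # trait equal to one eigengene
  one <- dplyr::filter(eig, module == module[1])
  traits <- tibble::tibble(sample = one$sample, mirror = one$eigengene,
                           flat = 1)
  expect_warning(mt <- module_trait_correlation(eig, traits))
  hit <- dplyr::filter(mt, trait == "mirror", module == one$module[1])
  expect_equal(hit$r, 1)
  expect_true(all(is.na(dplyr::filter(mt, trait == "flat")$r)))
  expect_error(
    module_trait_correlation(eig, dplyr::mutate(traits, sample = paste0(sample, "_x"))),
    class = "droughtrank_alignment_error"
  )
})

test_that("hub ranking follows degree with documented tie-breaks", {
  # star topology: center connected to all leaves
  genes <- c("center", "l1", "l2", "l3")
  w <- matrix(0, 4, 4, dimnames = list(genes, genes))
  w["center", c("l1", "l2", "l3")] <- 0.9
  w[c("l1", "l2", "l3"), "center"] <- 0.9
  assign <- tibble::tibble(gene = genes, module = "m1")
  hubs <- hub_genes(w, assign, top_k = 4, edge_threshold = 0.8)
  expect_equal(hubs$gene[1], "center")
  expect_equal(hubs$degree[1], 3L)

  # complete graph of equal weights: tie-break by id
  w2 <- matrix(0.9, 3, 3, dimnames = list(c("c", "a", "b"), c("c", "a", "b")))
  diag(w2) <- 0
  h2 <- hub_genes(w2, tibble::tibble(gene = c("c", "a", "b"), module = "m"),
                  top_k = 3, edge_threshold = 0.5)
  expect_equal(h2$gene, c("a", "b", "c"))

  expect_warning(
    small <- hub_genes(w2, tibble::tibble(gene = c("c", "a", "b"), module = "m"),
                       top_k = 5, edge_threshold = 0.5)
  )
  expect_equal(nrow(small), 3)
})

test_that("planted hubs with elevated correlations are recovered as rank 1", {
  recovered <- vapply(1:20, function(s) {
    set.seed(700 + s)
    n_samples <- 20
    hub_profile <- rnorm(n_samples)
    # satellites correlate strongly with the hub, weakly with each other
    sat <- t(replicate(6, hub_profile + rnorm(n_samples, 0, 0.8)))
    m <- rbind(hub = hub_profile, sat)
    rownames(m) <- c("hub", paste0("s", 1:6))
    adj <- correlation_adjacency(2^(m + 6), beta = 2)
    h <- hub_genes(adj, tibble::tibble(gene = rownames(m), module = "m"),
                   top_k = 1, edge_threshold = 0.2)
    h$gene[1] == "hub"
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
})

test_that("edge list export respects thresholds and canonical ordering", {
  genes <- c("a", "b", "c")
  w <- matrix(0, 3, 3, dimnames = list(genes, genes))
  w["a", "b"] <- w["b", "a"] <- 0.9
  w["a", "c"] <- w["c", "a"] <- 0.3
  w["b", "c"] <- w["c", "b"] <- 0.5
  edges <- export_edge_list(w, threshold = 0.4)
  expect_equal(nrow(edges), 2)
  expect_true(all(edges$source < edges$target))
  expect_equal(nrow(export_edge_list(w, threshold = 0)), 3)   # n(n-1)/2
  expect_equal(nrow(export_edge_list(w, threshold = 1)), 0)
  expect_error(export_edge_list(w, threshold = 2),
               class = "droughtrank_input_error")
})

test_that("gene-trait correlation reports sign and permutation p", {
  set.seed(63)
  n <- 12
  trait <- rnorm(n)
  m <- rbind(gpos = trait, gneg = -trait)
  colnames(m) <- paste0("s", 1:n)
  traits <- tibble::tibble(sample = colnames(m), tr = trait)
  res <- gene_trait_correlation(m, traits, n_perm = 199, seed = 2,
                                log_transform = FALSE)
  expect_equal(dplyr::filter(res, gene == "gpos")$r, 1)
  expect_equal(dplyr::filter(res, gene == "gpos")$sign, "positive")
  expect_equal(dplyr::filter(res, gene == "gneg")$r, -1)
  expect_equal(dplyr::filter(res, gene == "gneg")$sign, "negative")
  expect_true(all(res$p_perm >= 1 / 200))
})
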