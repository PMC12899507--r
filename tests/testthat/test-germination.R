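test_that("germination rate, energy and index match hand arithmetic", {
  expect_equal(germination_rate(0, 30), 0)
  expect_equal(germination_rate(30, 30), 100)
  expect_equal(germination_rate(27, 30), 90)
  expect_error(germination_rate(5, 0), class = "droughtrank_input_error")

  expect_equal(germination_energy(c(10, 8, 2), 30), 30)   # Gt = 9
  expect_equal(germination_energy(c(0, 0), 30), 0)
  expect_equal(germination_energy(15, 30), 50)            # single-day fallback
  expect_error(germination_energy(numeric(0), 30),
               class = "droughtrank_input_error")

  expect_equal(germination_index(c(5, 3, 2), c(1, 2, 4)), 7)
  expect_equal(germination_index(c(0, 0), c(1, 2)), 0)
  expect_equal(germination_index(7, 1), 7)                # day 1 identity
  expect_error(germination_index(3, 0), class = "droughtrank_input_error")
})

test_that("relative index is the stress/control ratio with scale invariance", {
  expect_equal(relative_index(45, 90), 0.5)
  expect_equal(relative_index(33, 33), 1)
  expect_equal(relative_index(0, 90), 0)
  expect_error(relative_index(5, 0, context = "A/GR"),
               class = "droughtrank_ratio_error")
  for (c_mult in c(0.1, 3, 1000)) {
    expect_equal(relative_index(45 * c_mult, 90 * c_mult), 0.5)
  }
})

test_that("indices are monotone in daily germination counts", {
  set.seed(11)
  for (i in 1:20) {
    daily <- rpois(5, 4)
    days <- sort(sample(1:10, 5))
    bumped <- daily
    j <- sample(5, 1)
    bumped[j] <- bumped[j] + 1
    expect_gte(germination_energy(bumped, 60), germination_energy(daily, 60))
    expect_gte(germination_index(bumped, days), germination_index(daily, days))
    expect_gte(germination_rate(sum(bumped), 60), germination_rate(sum(daily), 60))
  }
})

test_that("germination_indices summarises count tables per variety/treatment", {
  out <- germination_indices(fixture_counts())
  expect_equal(nrow(out), 4)
  a_ctrl <- dplyr::filter(out, variety == "A", treatment == "control")
  expect_equal(a_ctrl$GR, 20 / 30 * 100)
  expect_equal(a_ctrl$GE, mean(c(10, 8)) / 30 * 100)
  expect_equal(a_ctrl$GI, 10 / 1 + 8 / 2 + 2 / 3)
  rel <- relative_germination_indices(out)
  expect_equal(nrow(rel), 2)
  expect_equal(rel$rel_GR[rel$variety == "A"], 10 / 20)
})

test_that("K-means tolerance grouping recovers separated clouds and orders groups", {
  set.seed(7)
  n <- 10
  rel <- tibble::tibble(
    variety = sprintf("V%02d", 1:(2 * n)),
    rel_GR = c(rnorm(n, 0.9, 0.02), rnorm(n, 0.3, 0.02)),
    rel_GE = c(rnorm(n, 0.85, 0.02), rnorm(n, 0.25, 0.02)),
    rel_GI = c(rnorm(n, 0.8, 0.02), rnorm(n, 0.2, 0.02))
  )
  grp <- cluster_tolerance_groups(rel, k = 2, seed = 7)
  labels <- tidy(grp)
  expect_true(all(labels$group[1:n] == "I"))       # tolerant cloud -> group I
  expect_true(all(labels$group[(n + 1):(2 * n)] == "II"))
  # permutation invariance of assignments
  grp2 <- cluster_tolerance_groups(rel[sample(nrow(rel)), ], k = 2, seed = 7)
  expect_equal(dplyr::arrange(tidy(grp2), variety),
               dplyr::arrange(labels, variety))
})

test_that("tolerance grouping handles degenerate and saturated cases", {
  rel <- tibble::tibble(variety = c("A", "B", "C"),
                        rel_GR = c(0.5, 0.5, 0.5))
  expect_s3_class(cluster_tolerance_groups(rel, k = 1, seed = 1),
                  "tolerance_grouping")
  rel2 <- tibble::tibble(variety = c("A", "B", "C"),
                         rel_GR = c(0.9, 0.5, 0.1))
  grp <- cluster_tolerance_groups(rel2, k = 3, seed = 1)
  expect_equal(sort(as.character(tidy(grp)$group)), c("I", "II", "III"))
  expect_error(cluster_tolerance_groups(rel2, k = 5, seed = 1),
               class = "droughtrank_input_error")
})

test_that("mean relative index tracks the planted tolerance of the panel", {
  cfg <- generator_config(seed = 3)
  germ <- simulate_germination(cfg)
  idx <- germination_indices(germ$counts, germ$seedlings)
  rel <- relative_germination_indices(idx)
  mean_rel <- rowMeans(rel[, -1])
  rho <- cor(mean_rel, germ$tau[rel$variety], method = "spearman")
  expect_gt(rho, 0.9)
})
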