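# Feature-table assembly and the mixed-model comparison harness.

test_that("feature table validates shape, factors and duplicates", {
  tab <- simulate_feature_table(n_bats = 9, seed = 1)
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 27L)           # 9 bats x 3 conditions
  expect_identical(levels(tab$condition), c("single1", "group", "single2"))

  dup <- rbind(tab, transform(tab[1, ], tfm_bandwidth = tfm_bandwidth + 1))
  dup$condition <- as.character(dup$condition)
  dup$space <- as.character(dup$space)
  expect_error(build_feature_table(dup), "conflicting duplicate")

  bad <- transform(tab, condition = "weird")
  bad$condition <- "weird"
  expect_error(build_feature_table(bad), "unknown condition")

  # rows with missing responses are retained
  tab$rf_sd <- NA_real_
  expect_silent(build_feature_table(as.data.frame(tab)))
})

test_that("comparisons need at least two conditions", {
  tab <- simulate_feature_table(seed = 2)
  solo <- tab[tab$condition == "group", ]
  expect_error(compare_conditions(solo, "tfm_bandwidth"), "two flight conditions")
})

test_that("a strong group effect is detected and reported coherently", {
  tab <- simulate_feature_table(n_bats = 9, effect = 3, sigma_bat = 0.5,
                                sigma_res = 1, seed = 33)
  cmp <- compare_conditions(tab, "tfm_bandwidth")
  m <- cmp$models[[1]]
  # Wald test flags the condition effect
  expect_lt(m$wald["condition", "Pr(>Chisq)"], 0.001)
  # both group-vs-single Tukey contrasts are significant
  gs <- grepl("group", m$contrasts$contrast)
  expect_true(all(m$contrasts$p.value[gs] < 0.05))
  # adjusted p-values never undercut unadjusted ones
  expect_true(all(m$contrasts$p.value >= m$contrasts$p.unadjusted - 1e-12))
  # estimated effect near truth
  est <- m$contrasts$estimate[m$contrasts$contrast == "single1 - group"]
  expect_lt(abs(est + 3), 1)
})

test_that("model output is invariant to row order and bat relabeling", {
  tab <- simulate_feature_table(n_bats = 6, effect = 1, seed = 9)
  p1 <- compare_conditions(tab, "tfm_bandwidth")$models[[1]]$contrasts$p.value
  shuf <- tab[sample(nrow(tab)), ]
  p2 <- compare_conditions(shuf, "tfm_bandwidth")$models[[1]]$contrasts$p.value
  expect_equal(p1, p2, tolerance = 1e-8)
  relab <- tab
  relab$bat_id <- sub("bat", "animal_", relab$bat_id)
  p3 <- compare_conditions(relab, "tfm_bandwidth")$models[[1]]$contrasts$p.value
  expect_equal(p1, p3, tolerance = 1e-8)
})

test_that("rf_sd is modelled separately per flight space", {
  tab1 <- simulate_feature_table(n_bats = 6, space = "narrow",
                                 response = "rf_sd", baseline = 85,
                                 sigma_bat = 10, sigma_res = 15, seed = 4)
  tab2 <- simulate_feature_table(n_bats = 6, space = "wide",
                                 response = "rf_sd", baseline = 150,
                                 sigma_bat = 20, sigma_res = 40, seed = 5)
  tab2$bat_id <- sub("bat0", "bat1", tab2$bat_id)
  tab <- build_feature_table(rbind(as.data.frame(tab1), as.data.frame(tab2)))
  cmp <- compare_conditions(tab, "rf_sd")
  expect_true(cmp$per_space)
  expect_setequal(names(cmp$models), c("narrow", "wide"))
})
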