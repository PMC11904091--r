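test_that("the constraint gate is inclusive at the threshold and monotone", {
  expect_true(passes_constraint_gate(0.073, 0.35))
  expect_true(passes_constraint_gate(0.35, 0.35))
  expect_false(passes_constraint_gate(0.36, 0.35))
  expect_false(passes_constraint_gate(NA_real_, 0.35))  # unscored genes fail

  set.seed(7)
  loeuf <- c(runif(200, 0, 2), NA, NA)
  thresholds <- sort(runif(10, 0.05, 1.5))
  for (i in seq_len(length(thresholds) - 1L)) {
    g1 <- passes_constraint_gate(loeuf, thresholds[i])
    g2 <- passes_constraint_gate(loeuf, thresholds[i + 1L])
    expect_true(all(g2[g1]))  # lower threshold admits a subset
  }
})

test_that("inheritance-mode categories follow chromosome class and modes", {
  expect_equal(mode_category("XLR", "chrX"), "XLR")
  expect_equal(mode_category("", "autosome"), "A_other")
  expect_equal(mode_category("", "chrX"), "X_other")
  expect_equal(mode_category("AD,AR", "autosome"), "ADR")
  expect_equal(mode_category("XLD,XLR", "chrX"), "XLDR")
  expect_error(mode_category("XLD", "autosome"), "data error")
})

test_that("welch_t_test matches the textbook formula and is antisymmetric", {
  # identical groups: no signal
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # worked example against an independent hand computation
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  got <- welch_t_test(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$t_statistic, want$t, tolerance = 1e-12)
  expect_equal(got$degrees_freedom, want$df, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:40, 1), mean = runif(1, -2, 2))
    got <- welch_t_test(x, y)
    want <- welch_oracle(x, y)
    expect_equal(got$t_statistic, want$t, tolerance = 1e-10)
    expect_equal(got$degrees_freedom, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    # antisymmetry
    rev <- welch_t_test(y, x)
    expect_equal(rev$t_statistic, -got$t_statistic, tolerance = 1e-12)
    expect_equal(rev$p_value, got$p_value, tolerance = 1e-12)
  }

  expect_error(welch_t_test(1, c(1, 2)), "fewer than 2")
  degenerate <- welch_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(degenerate$t_statistic, 0)
  expect_equal(degenerate$p_value, 1)
})

test_that("null p-values are uniform: type-I error near the nominal level", {
  set.seed(2024)
  p <- replicate(1000, {
    welch_t_test(rnorm(30), rnorm(30))$p_value
  })
  alpha_hat <- mean(p < 0.05)
  # 1000 replicates: binomial 3-sigma band around 0.05 is about +/- 0.021
  expect_gt(alpha_hat, 0.05 - 0.021)
  expect_lt(alpha_hat, 0.05 + 0.021)
  # gross uniformity across the unit interval
  expect_gt(mean(p < 0.5), 0.45)
  expect_lt(mean(p < 0.5), 0.55)
})

test_that("X-linked categories score below AD in the generated constraint table", {
  cfg <- sim_config(seed = 3)
  tab <- generate_constraint_table(cfg, n_per_category = 500)$constraint
  cmp <- compare_loeuf_by_inheritance(tab)
  expect_true(all(c("XLD", "XLR", "XLDR") %in% cmp$comparisons$group_a))
  xld <- cmp$comparisons[cmp$comparisons$group_a == "XLD", ]
  expect_lt(xld$mean_a, xld$mean_b)       # XLD more constrained than AD
  expect_lt(xld$p_value, 0.001)
  xlr <- cmp$comparisons[cmp$comparisons$group_a == "XLR", ]
  expect_lt(xlr$mean_a, xlr$mean_b)
  expect_lt(xlr$p_value, 0.001)
  expect_true(all(cmp$comparisons$p_bonferroni >= cmp$comparisons$p_value))
  # per-category summary is plot-ready
  expect_true(all(c("category", "n", "n_scored", "mean_loeuf", "median_loeuf")
                  %in% names(cmp$summary)))
})

test_that("degenerate constraint tables are handled gracefully", {
  # only AD genes: empty comparison list, summary still produced
  ad_only <- mk_constraint(paste0("G", 1:5), "chr1", runif(5), "AD")
  res <- compare_loeuf_by_inheritance(ad_only)
  expect_equal(nrow(res$comparisons), 0L)
  expect_equal(res$summary$category, "AD")
  # and too few scored genes anywhere is flagged
  tiny <- mk_constraint("G1", "chr1", 0.5, "AD")
  expect_warning(compare_loeuf_by_inheritance(tiny), "fewer than 2")

  # all scores equal: every comparison is null
  flat <- rbind(mk_constraint(paste0("A", 1:5), "chr1", 0.1, "AD"),
                mk_constraint(paste0("X", 1:5), "chrX", 0.1, "XLD"))
  res <- compare_loeuf_by_inheritance(flat)
  expect_true(all(res$comparisons$p_value == 1))
  expect_true(all(res$comparisons$t_statistic == 0))
})
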