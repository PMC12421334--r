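test_that("Spearman matrix recovers perfect and null correlations", {
  df <- data.frame(sex = "woman", pcs = 1:20, faw = (1:20)^2)
  m <- spearman_matrix(df, c("pcs", "faw"))
  expect_equal(m$rho["pcs", "faw"], 1)
  set.seed(3)
  df2 <- data.frame(sex = "woman", pcs = rnorm(1000), faw = rnorm(1000))
  m2 <- spearman_matrix(df2, c("pcs", "faw"))
  expect_lt(abs(m2$rho["pcs", "faw"]), 0.08)
  # constant variable flagged undefined
  df3 <- data.frame(sex = "woman", pcs = rep(1, 10), faw = 1:10)
  expect_true(is.na(spearman_matrix(df3, c("pcs", "faw"))$rho["pcs", "faw"]))
})

test_that("tie-corrected Spearman equals the rank-formula evaluation on a tied toy", {
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 6)
  df <- data.frame(sex = "woman", pcs = x, faw = y)
  m <- spearman_matrix(df, c("pcs", "faw"))
  expect_equal(m$rho["pcs", "faw"], cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("numeric comparison selects tests and degenerates sensibly", {
  expect_error(compare_numeric(1, 1:5), "at least 2")
  same <- c(1, 2, 3, 4, 5)
  cmp <- compare_numeric(same, same)
  expect_equal(cmp$p_value, 1, tolerance = 1e-9)
  set.seed(6)
  cmp2 <- compare_numeric(rnorm(50), rnorm(50, 2), "always_normal")
  expect_identical(cmp2$test_used, "student_t")
  expect_lt(cmp2$p_value, 1e-4)
  cmp3 <- compare_numeric(rnorm(50), rnorm(50, 2), "never_normal")
  expect_identical(cmp3$test_used, "mann_whitney")
  expect_lt(cmp3$p_value, 1e-4)
})

test_that("Mann-Whitney approximation agrees with exact enumeration on small groups", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(6)
    y <- rnorm(6, 0.5)
    got <- compare_numeric(x, y, "never_normal")$p_value
    exact <- oracle_mw_exact_p(x, y)
    # continuity-corrected normal approximation vs exact enumeration
    expect_lt(abs(got - exact), 0.05)
  }
  # the exact oracle itself matches R's exact routine without ties
  x <- c(0.1, 0.9, 1.7, 2.1, 3.2, 4.4)
  y <- c(0.5, 1.1, 2.6, 3.9, 4.1, 5.3)
  expect_equal(oracle_mw_exact_p(x, y),
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("nominal comparison switches between chi-squared and Fisher correctly", {
  # no physical activity among overweight/obese: women 44/64 vs men 22/53
  cmp <- compare_nominal(matrix(c(44, 20, 22, 31), 2, byrow = TRUE))
  expect_identical(cmp$test_used, "chi2")
  expect_lt(abs(cmp$p_value - 0.003), 0.001)
  # cLBP sex ratio 164/92 vs pain-free 262/249
  cmp2 <- compare_nominal(matrix(c(164, 92, 262, 249), 2, byrow = TRUE))
  expect_identical(cmp2$test_used, "chi2")
  expect_lt(abs(cmp2$p_value - 0.001), 0.0005)
  # perfect association: decisive whichever route the expected counts pick
  cmp3 <- compare_nominal(matrix(c(10, 0, 0, 10), 2))
  expect_lt(cmp3$p_value, 1e-4)
  cmp4 <- compare_nominal(matrix(c(7, 0, 0, 7), 2))
  expect_identical(cmp4$test_used, "fisher_exact")
  expect_lt(cmp4$p_value, 1e-3)
  expect_error(compare_nominal(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
  expect_error(compare_nominal(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("2x2 chi-squared equals the squared two-proportion z statistic", {
  tab <- matrix(c(44, 20, 22, 31), 2, byrow = TRUE)
  cmp <- compare_nominal(tab)
  p1 <- tab[1, 1] / sum(tab[1, ])
  p2 <- tab[2, 1] / sum(tab[2, ])
  pp <- sum(tab[, 1]) / sum(tab)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / sum(tab[1, ]) + 1 / sum(tab[2, ])))
  expect_equal(cmp$statistic, z^2, tolerance = 1e-10)
})

test_that("gesture-interference coupling is detected at the oracle-predicted power", {
  # shift 1.0 on the 0-10 scale at n = 164, exposure ~62%: the detection
  # rate through the full generator + work-factor route must agree with an
  # independent Monte-Carlo power oracle of the same marginal design
  sig <- logical(60)
  for (s in seq_along(sig)) {
    cfg <- preset_config("women_like", seed = 300 + s,
                         gesture_shift = list(heavy_loads = c(1.0, 0)))
    co <- generate_cohort(cfg)
    wf <- work_factor_associations(co, "women")
    sig[s] <- wf$p_value[wf$factor == "gesture_heavy_loads"] < 0.05
  }
  reg <- instrument_table()
  mu <- reg$mu_women[reg$variable == "pain_interference"]
  sd_ <- reg$sd_women[reg$variable == "pain_interference"]
  set.seed(9090)
  oracle <- mean(replicate(400, {
    exposed <- rbinom(164, 1, 0.622) == 1
    y <- pmin(10, pmax(0, round(rnorm(164, mu, sd_) + exposed, 1)))
    suppressWarnings(wilcox.test(y[exposed], y[!exposed],
                                 exact = FALSE)$p.value) < 0.05
  }))
  expect_lt(abs(mean(sig) - oracle), 0.15)
  expect_gt(mean(sig), 0.4)  # the coupling is detectable, not marginal
})

test_that("a women-only gesture effect is found in women and not in men", {
  women_hits <- men_hits <- logical(20)
  for (s in 1:20) {
    cfg <- preset_config("full_cohort", seed = 500 + s,
                         gesture_shift = list(back_torsion = c(1.2, 0)))
    co <- generate_cohort(cfg)
    wfw <- work_factor_associations(co, "women")
    wfm <- work_factor_associations(co, "men")
    women_hits[s] <- wfw$p_value[wfw$factor == "gesture_back_torsion"] < 0.05
    men_hits[s] <- wfm$p_value[wfm$factor == "gesture_back_torsion"] < 0.05
  }
  expect_gt(mean(women_hits), 0.5)
  expect_lt(mean(men_hits), 0.5)
  expect_gt(mean(women_hits), mean(men_hits))
})

test_that("work-factor table flags untestable factors instead of testing them", {
  cfg <- preset_config("women_like", seed = 9, n_women = 40L)
  co <- generate_cohort(cfg)
  co$gesture_vibrations <- FALSE  # empty exposed level
  wf <- work_factor_associations(co, "women")
  row <- wf[wf$factor == "gesture_vibrations", ]
  expect_false(row$tested)
  expect_true(is.na(row$p_value))
})

test_that("sex-comparison table covers the registry variables with valid p-values", {
  cfg <- preset_config("full_cohort", seed = 44)
  co <- derive_variables(generate_cohort(cfg))
  tab <- compare_sex_groups(co, adjust = TRUE)
  expect_equal(nrow(tab), 17)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$test %in% c("student_t", "mann_whitney")))
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12))
})
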