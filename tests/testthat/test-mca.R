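test_that("indicator matrix has row sums Q and drops unseen modalities with a warning", {
  df <- data.frame(v1 = c("a", "b", "a"), v2 = c("x", "y", "z"),
                   stringsAsFactors = FALSE)
  rownames(df) <- paste0("s", 1:3)
  ind <- build_indicator(df)
  expect_equal(unname(rowSums(ind$Z)), rep(2, 3))
  expect_equal(ind$J, 5)
  # scheme-declared label never observed -> dropped with a warning
  cfg <- preset_config("women_like", seed = 41, n_women = 25L)
  co <- derive_variables(generate_cohort(cfg))
  sw <- build_scheme(co, "woman")
  coded <- apply_scheme(co, sw)
  if (!all(vapply(names(coded), function(v) {
    v == "npf" || all(sw$rules[[v]]$labels %in% coded[[v]])
  }, logical(1)))) {
    expect_warning(build_indicator(coded), "never observed")
  }
  df_na <- df
  df_na$v1[2] <- NA
  expect_error(build_indicator(df_na), "absent cells")
})

test_that("a fully coded cohort gives row sums equal to the variable count", {
  cfg <- preset_config("women_like", seed = 6)
  co <- derive_variables(generate_cohort(cfg))
  coded <- apply_scheme(co, build_scheme(co, "woman"), include_npf = FALSE)
  ind <- suppressWarnings(build_indicator(coded))
  expect_equal(ind$Q, 17)
  expect_equal(unname(rowSums(ind$Z)), rep(17, nrow(co)))
})

test_that("MCA satisfies the analytic identities", {
  coded <- random_coded_table(40, 4, seed = 2)
  ind <- build_indicator(coded)
  m <- run_mca(ind)
  expect_equal(sum(m$eigenvalues), ind$J / ind$Q - 1, tolerance = 1e-8)
  expect_equal(unname(colSums(m$modality_contrib_pct)),
               rep(100, length(m$eigenvalues)), tolerance = 1e-8)
  # per variable and axis, the mass-weighted mean modality coordinate is 0
  for (v in names(ind$variables)) {
    cols <- ind$variables[[v]]
    wm <- colSums(m$modality_coords[cols, , drop = FALSE] *
                    m$modality_mass[cols])
    expect_equal(unname(wm), rep(0, length(wm)), tolerance = 1e-8)
  }
  # transition identity: subject principal coordinate = mean of its
  # modalities' standard coordinates
  std <- sweep(m$modality_coords, 2, sqrt(m$eigenvalues), "/")
  expect_equal(unname(ind$Z %*% std / ind$Q), unname(m$subject_coords),
               tolerance = 1e-8)
})

test_that("perfectly associated variables give a unit leading eigenvalue", {
  lab <- sample(c("a", "b", "c"), 30, replace = TRUE)
  df <- data.frame(v1 = lab, v2 = paste0("r", lab), stringsAsFactors = FALSE)
  rownames(df) <- paste0("s", 1:30)
  m <- run_mca(build_indicator(df))
  expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
})

test_that("two-variable MCA eigenvalues map onto the simple CA of the cross-table", {
  skip_if_not_installed("vegan")
  set.seed(30)
  df <- data.frame(v1 = sample(c("a", "b", "c"), 30, TRUE),
                   v2 = sample(c("x", "y"), 30, TRUE),
                   stringsAsFactors = FALSE)
  rownames(df) <- paste0("s", 1:30)
  m <- run_mca(build_indicator(df))
  ca_eig <- vegan::cca(unclass(table(df$v1, df$v2)))$CA$eig
  # each indicator eigenvalue is (1 +- sqrt(lambda_CA)) / 2, plus 1/2 for
  # the dimensions the two-way CA does not span
  expected <- sort(unname(c((1 + sqrt(ca_eig)) / 2, (1 - sqrt(ca_eig)) / 2,
                            rep(0.5, length(m$eigenvalues) -
                                  2 * length(ca_eig)))),
                   decreasing = TRUE)
  expect_equal(unname(m$eigenvalues), expected, tolerance = 1e-8)
})

test_that("eigenvalues and coordinates match the reference implementation", {
  skip_if_not_installed("vegan")
  for (seed in 1:10) {
    coded <- random_coded_table(n = sample(15:50, 1), Q = sample(2:4, 1),
                                seed = seed)
    ind <- build_indicator(coded)
    m <- run_mca(ind)
    ref <- reference_mca(ind$Z)
    kk <- min(length(ref$eigenvalues), length(m$eigenvalues))
    expect_equal(unname(m$eigenvalues[seq_len(kk)]),
                 ref$eigenvalues[seq_len(kk)],
                 tolerance = 1e-6)
    eig <- ref$eigenvalues[seq_len(kk)]
    for (k in seq_len(kk)) {
      # coordinates in a (near-)degenerate eigenspace are defined only up
      # to rotation; compare well-separated axes
      gap <- min(abs(eig[k] - eig[-k]), 1)
      if (gap < 1e-7) next
      a <- m$modality_coords[, k]
      b <- ref$modality_coords[, k]
      expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-6)
    }
  }
})

test_that("Benzecri adjustment matches the closed form and flags degenerate spectra", {
  # at Q = 4 the 1/Q threshold is 0.25: the boundary eigenvalue is excluded
  expect_equal(benzecri_adjusted_rates(c(0.5, 0.25), 4), c(100, 0))
  # a flat spectrum at exactly 1/Q has no signal axis at all
  expect_warning(out <- benzecri_adjusted_rates(rep(0.25, 4), 4),
                 "no eigenvalue")
  expect_equal(out, rep(0, 4))
  expect_warning(out2 <- benzecri_adjusted_rates(c(0.5, 0.25), 2),
                 "no eigenvalue")
  expect_equal(out2, c(0, 0))
  lam <- c(0.6, 0.3, 0.2)
  adj <- ifelse(lam > 0.25, (4 / 3)^2 * (lam - 0.25)^2, 0)
  expect_equal(benzecri_adjusted_rates(lam, 4), 100 * adj / sum(adj))
  expect_error(benzecri_adjusted_rates(0.5, 1), "Q")
})

test_that("axis retention keeps leading axes above the threshold with a 2-axis floor", {
  expect_equal(select_axes(c(60.4, 7.8, 4.1, 3), 5), 2)
  expect_equal(select_axes(c(50, 30, 20), 5), 3)
  expect_equal(select_axes(c(100, 0), 5), 2)
})

test_that("axes are oriented so the anchor modality is non-negative", {
  cfg <- preset_config("women_like", seed = 19)
  co <- derive_variables(generate_cohort(cfg))
  coded <- apply_scheme(co, build_scheme(co, "woman"))
  ind <- suppressWarnings(build_indicator(coded))
  m <- run_mca(ind, orient_modality = "pain_interference=T3")
  expect_true(all(m$modality_coords["pain_interference=T3", ] >= 0))
})
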