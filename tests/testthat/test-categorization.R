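test_that("tercile cut-points balance classes and reject degenerate input", {
  expect_equal(tercile_cutpoints(1:9), c(3, 6))
  x <- c(1:9)
  cls <- cut(x, c(-Inf, 3, 6, Inf))
  expect_equal(as.vector(table(cls)), c(3, 3, 3))
  expect_error(tercile_cutpoints(rep(5, 30)), "distinct")
  expect_error(tercile_cutpoints(c(1, 2)), "distinct")
})

test_that("tercile cut-points reproduce printed-style integer cuts on matched data", {
  # a women's PCS-like sample whose empirical terciles sit at 12 and 24
  set.seed(4)
  x <- c(sample(0:11, 40, TRUE), 12, sample(13:23, 40, TRUE), 24,
         sample(25:52, 40, TRUE))
  cuts <- tercile_cutpoints(x)
  expect_true(cuts[1] <= 12 + 1 && cuts[1] >= 11)
  expect_true(all(cuts %in% x))  # inclusive quantile: cuts are data values
})

test_that("density-valley cut-points find the valley and detect unimodality", {
  # balanced point masses at 10 and 30: symmetry forces the midway point
  x <- rep(c(10, 30), each = 50)
  expect_equal(multimodal_cutpoints(x, bandwidth = 1), 20, tolerance = 0.2)
  # Gaussian mixture: analytic valley at 20
  set.seed(8)
  y <- c(rnorm(1000, 10, 1), rnorm(1000, 30, 1))
  cut <- multimodal_cutpoints(y, bandwidth = 1)
  expect_length(cut, 1)
  expect_lt(abs(cut - 20), 1)
  # unimodal sample: empty list (caller falls back to terciles)
  set.seed(9)
  expect_length(multimodal_cutpoints(rnorm(500)), 0)
  expect_error(multimodal_cutpoints(1:5), "at least 10")
})

test_that("rule application honours both printed bracket dialects", {
  hads <- categorization_rule("hads_anxiety", "REF", c(8, 11),
                              c("low", "intermediate", "high"),
                              boundary_policy = c("upper", "lower"))
  expect_identical(apply_rule(c(7, 8, 11, 12), hads),
                   c("low", "intermediate", "intermediate", "high"))
  tsk <- categorization_rule("tsk", "REF", 40, c("negative", "positive"),
                             boundary_policy = "upper")
  expect_identical(apply_rule(c(39, 40), tsk), c("negative", "positive"))
  # stress at work (women): < 51 / [51-70[ / >= 70 - half-open middle
  sw <- categorization_rule("stress_work", "TER", c(51, 70),
                            c("low", "intermediate", "high"),
                            boundary_policy = c("upper", "upper"))
  expect_identical(apply_rule(c(50, 51, 69, 70), sw),
                   c("low", "intermediate", "intermediate", "high"))
  expect_error(apply_rule(200, sw, lo = 0, hi = 100), "bounds")
})

test_that("schemes share REF rules across sexes and compute terciles from the subsample", {
  cfg <- preset_config("full_cohort", seed = 14)
  co <- derive_variables(generate_cohort(cfg))
  sw <- build_scheme(co[co$sex == "woman", ], "woman")
  sm <- build_scheme(co[co$sex == "man", ], "man")
  for (v in c("bmi", "hads_anxiety", "hads_depression", "tsk")) {
    expect_identical(sw$rules[[v]]$cutpoints, sm$rules[[v]]$cutpoints)
    expect_identical(sw$rules[[v]]$labels, sm$rules[[v]]$labels)
  }
  # TER rules differ by sex here (distinct subsamples)
  expect_false(identical(sw$rules$faw$cutpoints, sm$rules$faw$cutpoints))
  expect_error(build_scheme(co[co$sex == "woman", ], "man"), "sex")
})

test_that("applying a scheme to the data that built it balances tercile classes", {
  cfg <- preset_config("women_like", seed = 23)
  co <- derive_variables(generate_cohort(cfg))
  sw <- build_scheme(co, "woman")
  coded <- apply_scheme(co, sw)
  expect_false(anyNA(coded))
  n <- nrow(coded)
  for (v in c("pcs", "fapa", "stress_home")) {
    counts <- table(coded[[v]])
    cuts <- sw$rules[[v]]$cutpoints
    ties <- sum(co[[v]] %in% cuts)
    # brute-force balance check: each class within n/3 +- ties at the cuts
    expect_true(all(abs(counts - n / 3) <= ties + 1),
                label = paste("tercile balance of", v))
  }
})

test_that("grade ordering follows the score for ordered rules", {
  cfg <- preset_config("women_like", seed = 31)
  co <- derive_variables(generate_cohort(cfg))
  sw <- build_scheme(co, "woman")
  glev <- c(low = 1, intermediate = 2, high = 3)
  for (v in c("pcs", "pain_interference", "hads_anxiety", "tsk")) {
    r <- sw$rules[[v]]
    vals <- sort(co[[v]])
    g <- glev[r$disorder_grade[apply_rule(vals, r)]]
    expect_true(all(diff(g) >= 0), label = paste("grade monotone for", v))
  }
  # inverted direction: quality of life grades decrease with the score
  r <- sw$rules$sf12_physical
  vals <- sort(co$sf12_physical)
  g <- glev[r$disorder_grade[apply_rule(vals, r)]]
  expect_true(all(diff(g) <= 0))
})

test_that("every rule is total on its instrument bounds", {
  cfg <- preset_config("men_like", seed = 3)
  co <- derive_variables(generate_cohort(cfg))
  sm <- build_scheme(co, "man")
  reg <- instrument_table()
  for (i in seq_len(nrow(reg))) {
    v <- reg$variable[i]
    grid <- seq(reg$lo[i], reg$hi[i], length.out = 101)
    lab <- apply_rule(grid, sm$rules[[v]], lo = reg$lo[i], hi = reg$hi[i])
    expect_true(all(lab %in% sm$rules[[v]]$labels),
                label = paste("totality of", v))
  }
})

test_that("scheme serialization round-trips", {
  cfg <- preset_config("women_like", seed = 12)
  co <- derive_variables(generate_cohort(cfg))
  sw <- build_scheme(co, "woman")
  path <- tempfile(fileext = ".scheme")
  write_scheme(sw, path)
  back <- read_scheme(path)
  expect_identical(back$sex, sw$sex)
  expect_identical(names(back$rules), names(sw$rules))
  for (v in names(sw$rules)) {
    expect_equal(back$rules[[v]]$cutpoints, sw$rules[[v]]$cutpoints,
                 tolerance = 1e-12)
    expect_identical(back$rules[[v]]$labels, sw$rules[[v]]$labels)
    expect_identical(back$rules[[v]]$boundary_policy,
                     sw$rules[[v]]$boundary_policy)
    expect_identical(unname(back$rules[[v]]$disorder_grade),
                     unname(sw$rules[[v]]$disorder_grade))
  }
  # re-application of the parsed scheme gives the same coded table
  expect_identical(as.data.frame(apply_scheme(co, back)),
                   as.data.frame(apply_scheme(co, sw)))
})
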