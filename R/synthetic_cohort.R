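#' Configuration for the synthetic cLBP cohort generator
#'
#' The generator draws, per subject, a scalar latent disorder factor
#' `z ~ N(0, 1)`. Every numeric analysis variable is a bounded affine
#' transform of `loading * z + noise_sd * eps` (standardized so the
#' marginal location/scale matches the registry), rounded to the
#' instrument's granularity and clipped to its bounds. Loadings therefore
#' encode, per sex, which variables travel together with the overall
#' disorder state; the correlation induced between variables with loadings
#' `a`, `b` is `a * b / sqrt((a^2 + s^2) * (b^2 + s^2))` with `s = noise_sd`
#' before discretization.
#'
#' @param n_women,n_men Number of subjects per sex (non-negative).
#' @param loadings_women,loadings_men Named numeric vectors in `[-1, 1]`
#'   covering exactly the registry variables ([analysis_variables()]).
#' @param noise_sd Standard deviation of the per-variable independent
#'   noise, positive.
#' @param gesture_prevalence Data frame with columns `gesture`, `p_women`,
#'   `p_men`; probabilities in `[0, 1]` for each declared repetitive
#'   gesture. Defaults to the shipped service-company prevalences.
#' @param neuropathic_rate Marginal probability of neuropathic features
#'   (neuropathic or mixed pain type); default 0.289.
#' @param neuropathic_slope Slope of the logistic link between the latent
#'   factor and neuropathic features; the intercept is solved so the
#'   marginal rate equals `neuropathic_rate`.
#' @param dn4_positive_frac Fraction of neuropathic-features cases that are
#'   DN4-positive (mainly neuropathic) rather than mixed.
#' @param undefined_rate,nociplastic_rate Marginal rates of undefined
#'   (incomplete DN4) and nociplastic (widespread pain) types.
#' @param eligible_fraction Fraction of subjects satisfying the analysis
#'   eligibility (average severity > 30/100 for >= 3 months) by
#'   construction.
#' @param rest_days_prevalence,sick_leave_prevalence Length-2 vectors
#'   (women, men) of prevalences for consecutive rest days and sick-leave
#'   history.
#' @param gesture_shift Optional named list `gesture -> c(women, men)`
#'   additive shift applied to pain interference of exposed subjects
#'   (0-10 scale), used to emulate gesture/pain associations.
#' @param missing_rate Probability that a numeric analysis field is set
#'   missing (applied through [inject_missing()]); in `[0, 1)`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated list of class `clbp_config`.
#' @seealso [preset_config()] for the shipped sex-specific presets.
#' @export
generator_config <- function(n_women, n_men,
                             loadings_women, loadings_men,
                             noise_sd = 0.5,
                             gesture_prevalence = default_gesture_prevalence(),
                             neuropathic_rate = 0.289,
                             neuropathic_slope = 2,
                             dn4_positive_frac = 10 / 74,
                             undefined_rate = 19 / 256,
                             nociplastic_rate = 13 / 256,
                             eligible_fraction = 1,
                             rest_days_prevalence = c(0.445, 0.435),
                             sick_leave_prevalence = c(0.598, 0.609),
                             gesture_shift = NULL,
                             missing_rate = 0,
                             seed = 1L) {
  cfg <- list(
    n_women = n_women, n_men = n_men,
    loadings_women = loadings_women, loadings_men = loadings_men,
    noise_sd = noise_sd, gesture_prevalence = gesture_prevalence,
    neuropathic_rate = neuropathic_rate,
    neuropathic_slope = neuropathic_slope,
    dn4_positive_frac = dn4_positive_frac,
    undefined_rate = undefined_rate, nociplastic_rate = nociplastic_rate,
    eligible_fraction = eligible_fraction,
    rest_days_prevalence = rest_days_prevalence,
    sick_leave_prevalence = sick_leave_prevalence,
    gesture_shift = gesture_shift,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "clbp_config"
  cfg
}

validate_config <- function(cfg) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x != round(x)) {
      stop("generator_config(): invalid field '", nm,
           "': must be a non-negative integer count")
    }
  }
  chk_count(cfg$n_women, "n_women")
  chk_count(cfg$n_men, "n_men")
  vars <- analysis_variables()
  for (nm in c("loadings_women", "loadings_men")) {
    l <- cfg[[nm]]
    if (!setequal(names(l), vars)) {
      stop("generator_config(): invalid field '", nm,
           "': must cover exactly the analysis variables; missing: ",
           paste(setdiff(vars, names(l)), collapse = ", "),
           "; extra: ", paste(setdiff(names(l), vars), collapse = ", "))
    }
    if (any(!is.finite(l)) || any(abs(l) > 1)) {
      stop("generator_config(): invalid field '", nm,
           "': loadings must lie in [-1, 1]")
    }
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop("generator_config(): invalid field 'noise_sd': must be > 0")
  }
  gp <- cfg$gesture_prevalence
  if (!is.data.frame(gp) ||
      !all(c("gesture", "p_women", "p_men") %in% names(gp)) ||
      any(gp$p_women < 0 | gp$p_women > 1 | gp$p_men < 0 | gp$p_men > 1)) {
    stop("generator_config(): invalid field 'gesture_prevalence': ",
         "needs columns gesture/p_women/p_men with probabilities in [0, 1]")
  }
  for (nm in c("neuropathic_rate", "dn4_positive_frac", "undefined_rate",
               "nociplastic_rate", "eligible_fraction")) {
    x <- cfg[[nm]]
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
      stop("generator_config(): invalid field '", nm, "': must lie in [0, 1]")
    }
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("generator_config(): invalid field 'missing_rate': must lie in [0, 1)")
  }
  for (nm in c("rest_days_prevalence", "sick_leave_prevalence")) {
    x <- cfg[[nm]]
    if (length(x) != 2 || any(x < 0 | x > 1)) {
      stop("generator_config(): invalid field '", nm,
           "': needs 2 probabilities (women, men) in [0, 1]")
    }
  }
  invisible(cfg)
}

#' Default prevalences of declared repetitive gestures
#'
#' Sex-specific prevalences of the twelve declared repetitive gestures in
#' a service-company cLBP workforce.
#'
#' @return Data frame with columns `gesture`, `p_women`, `p_men`.
#' @export
default_gesture_prevalence <- function() {
  data.frame(
    gesture = .clbp_gestures,
    p_women = c(0.579, 0.476, 0.457, 0.488, 0.409, 0.628, 0.616, 0.122,
                0.622, 0.494, 0.226, 0.500),
    p_men = c(0.761, 0.609, 0.652, 0.576, 0.565, 0.772, 0.783, 0.402,
              0.728, 0.446, 0.348, 0.478),
    stringsAsFactors = FALSE
  )
}

# Loadings encoding the sex-specific disorder proximities: high loadings
# (0.85; 0.90 for the anchor variable, pain interference) on exactly the
# variables whose worst modality belongs to each sex's final cluster, and
# zero elsewhere. Quality-of-life loadings are negative (a low score is
# the worse state).
.preset_loadings <- function(sex) {
  vars <- analysis_variables()
  l <- setNames(rep(0, length(vars)), vars)
  common <- c(pcs = 0.85, faw = 0.85, pain_severity = 0.85,
              pain_interference = 0.90)
  l[names(common)] <- common
  if (sex == "woman") {
    l["stress_work"] <- 0.85
    l["fapa"] <- 0.85
    l["tsk"] <- 0.85
    l["sf12_physical"] <- -0.85
  } else {
    l["hads_anxiety"] <- 0.85
    l["hads_depression"] <- 0.85
    l["sf12_mental"] <- -0.85
  }
  l
}

#' Shipped generator presets
#'
#' `women_like` (n = 164 women) and `men_like` (n = 92 men) encode the
#' sex-specific disorder proximities of the phenotyping analysis as high
#' positive loadings on exactly the variables whose worst modality belongs
#' to each sex's final cluster; `full_cohort` combines both strata
#' (164 women + 92 men) for whole-sample descriptive analyses.
#'
#' @param preset One of `"women_like"`, `"men_like"`, `"full_cohort"`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [generator_config()].
#' @return A `clbp_config`.
#' @export
preset_config <- function(preset = c("women_like", "men_like", "full_cohort"),
                          seed = 1L, ...) {
  preset <- match.arg(preset)
  n <- switch(preset,
              women_like = c(164L, 0L),
              men_like = c(0L, 92L),
              full_cohort = c(164L, 92L))
  args <- list(
    n_women = n[1], n_men = n[2],
    loadings_women = .preset_loadings("woman"),
    loadings_men = .preset_loadings("man"),
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

# Intercept of the logistic link so that E[plogis(a + slope * z)] = rate
# for z ~ N(0, 1).
.logit_intercept <- function(rate, slope) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  f <- function(a) {
    stats::integrate(function(z) stats::dnorm(z) * stats::plogis(a + slope * z),
                     -Inf, Inf)$value - rate
  }
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

.round_to <- function(x, g) round(x / g) * g

# Simulate the numeric analysis variables of one sex stratum.
.simulate_stratum <- function(n, sex, loadings, noise_sd, reg) {
  z <- stats::rnorm(n)
  out <- list(z = z)
  musd <- if (sex == "woman") c("mu_women", "sd_women") else c("mu_men", "sd_men")
  for (i in seq_len(nrow(reg))) {
    v <- reg$variable[i]
    a <- loadings[[v]]
    s <- a * z + noise_sd * stats::rnorm(n)
    s <- s / sqrt(a^2 + noise_sd^2)  # preserve the marginal scale
    raw <- reg[[musd[1]]][i] + reg[[musd[2]]][i] * s
    out[[v]] <- pmin(reg$hi[i], pmax(reg$lo[i], .round_to(raw, reg$granularity[i])))
  }
  out
}

#' Generate a seeded synthetic cLBP cohort
#'
#' Draws one latent disorder factor per subject and builds every numeric
#' analysis variable as a bounded affine transform of the latent factor
#' plus independent noise (see [generator_config()]). Binary work/gesture
#' fields are Bernoulli draws with the configured prevalences; pain type
#' is assembled so that DN4-based adjudication
#' ([adjudicate_pain_type()]) reproduces the configured marginal rates,
#' with the probability of neuropathic features increasing logistically
#' with the latent factor. Height is drawn per sex and weight derived from
#' the simulated BMI, so the BMI recomputed from weight and height agrees
#' with the simulated one up to rounding.
#'
#' @param config A `clbp_config` from [generator_config()] or
#'   [preset_config()].
#' @return Data frame, one row per subject, with demographics, job and
#'   gesture fields, instrument scores, the BPI average-pain 0-100 item
#'   (`pain_avg_0100`), pain duration and the DN4 fields. Deterministic
#'   for a fixed `config$seed`. The latent disorder factor is attached as
#'   attribute `latent_z` (named by subject id) for diagnostics.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "clbp_config")) validate_config(config)
  set.seed(config$seed)
  reg <- instrument_table()
  strata <- list()
  for (sex in c("woman", "man")) {
    n <- if (sex == "woman") config$n_women else config$n_men
    if (n == 0) next
    loadings <- if (sex == "woman") config$loadings_women else config$loadings_men
    sim <- .simulate_stratum(n, sex, loadings, config$noise_sd, reg)
    z <- sim$z

    # anthropometry: height per sex, weight derived from simulated BMI
    h_mu <- if (sex == "woman") 166 else 179
    h_sd <- if (sex == "woman") 7.4 else 8.9
    height <- pmin(210, pmax(140, round(stats::rnorm(n, h_mu, h_sd))))
    weight <- round(sim$bmi * (height / 100)^2, 1)

    # BPI average-pain item (0-100) tracks the 0-10 severity composite;
    # eligibility is imposed by truncation for the configured fraction
    raw_avg <- round(sim$pain_severity * 10 + stats::rnorm(n, 0, 8))
    eligible <- stats::rbinom(n, 1, config$eligible_fraction) == 1
    pain_avg <- ifelse(eligible, pmax(31, raw_avg), pmin(30, raw_avg))
    pain_avg <- pmin(100, pmax(0, pain_avg))
    dur_raw <- 3 + round(stats::rlnorm(n, log(24), 0.9))
    short_dur <- sample(0:2, n, replace = TRUE)
    duration <- ifelse(eligible, dur_raw, short_dur)

    # pain-type assembly: P(neuropathic features) rises logistically in z
    alpha <- .logit_intercept(config$neuropathic_rate, config$neuropathic_slope)
    npf <- stats::rbinom(n, 1, stats::plogis(alpha + config$neuropathic_slope * z)) == 1
    neuro <- npf & stats::rbinom(n, 1, config$dn4_positive_frac) == 1
    p_rest <- max(0, 1 - config$neuropathic_rate)
    u_c <- if (p_rest > 0) min(1, config$undefined_rate / p_rest) else 0
    w_c <- if (p_rest > 0) min(1, config$nociplastic_rate / p_rest) else 0
    undef <- !npf & stats::rbinom(n, 1, u_c) == 1
    nocip <- !npf & !undef & stats::rbinom(n, 1, w_c) == 1
    dn4 <- ifelse(neuro, sample(4:9, n, replace = TRUE,
                                prob = c(0.35, 0.25, 0.18, 0.12, 0.07, 0.03)),
                  sample(0:3, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)))
    dn4[undef] <- NA_integer_

    # gestures and work binaries
    gp <- config$gesture_prevalence
    pcol <- if (sex == "woman") "p_women" else "p_men"
    gest <- sapply(seq_len(nrow(gp)), function(i) {
      stats::rbinom(n, 1, gp[[pcol]][i]) == 1
    })
    gest <- matrix(gest, nrow = n,
                   dimnames = list(NULL, paste0("gesture_", gp$gesture)))
    sexi <- if (sex == "woman") 1L else 2L
    rest <- stats::rbinom(n, 1, config$rest_days_prevalence[sexi]) == 1
    sick <- stats::rbinom(n, 1, config$sick_leave_prevalence[sexi]) == 1

    df <- data.frame(
      subject_id = paste0(substr(sex, 1, 1), sprintf("%04d", seq_len(n))),
      sex = sex, age = sim$age, weight = weight, height = height,
      physical_activity = sim$physical_activity,
      seniority_job = sim$seniority_job, hours_week = sim$hours_week,
      gest,
      rest_days_consecutive = rest, sick_leave_history = sick,
      pain_severity = sim$pain_severity,
      pain_interference = sim$pain_interference,
      pain_avg_0100 = pain_avg, pain_duration_months = duration,
      dn4_score = dn4, dn4_complete = !undef,
      neuropathic_symptoms = npf & !neuro,
      widespread_pain = nocip,
      hads_anxiety = sim$hads_anxiety, hads_depression = sim$hads_depression,
      pcs = sim$pcs, tsk = sim$tsk, fapa = sim$fapa, faw = sim$faw,
      sf12_physical = sim$sf12_physical, sf12_mental = sim$sf12_mental,
      stress_home = sim$stress_home, stress_work = sim$stress_work,
      stringsAsFactors = FALSE
    )

    # optional gesture -> interference coupling
    if (!is.null(config$gesture_shift)) {
      for (g in names(config$gesture_shift)) {
        shift <- config$gesture_shift[[g]][sexi]
        col <- paste0("gesture_", g)
        if (shift != 0 && col %in% names(df)) {
          df$pain_interference <- pmin(10, pmax(0, round(
            df$pain_interference + shift * df[[col]], 1)))
        }
      }
    }
    attr(df, "latent_z") <- setNames(z, df$subject_id)
    strata[[sex]] <- df
  }
  zs <- do.call(c, unname(lapply(strata, attr, "latent_z")))
  out <- do.call(rbind, strata)
  rownames(out) <- NULL
  attr(out, "latent_z") <- zs
  if (config$missing_rate > 0) {
    out <- inject_missing(out, config$missing_rate,
                          seed = config$seed + 1L)
  }
  out
}

#' Inject missing values into the numeric analysis fields
#'
#' Each numeric analysis field (registry variables, with BMI represented
#' by its source fields weight and height) is independently set missing
#' with the given probability; seeded and reproducible.
#'
#' @param records Cohort data frame from [generate_cohort()].
#' @param rate Missingness probability, in `[0, 1)`.
#' @param seed Integer seed for the missingness mask.
#' @return The cohort with `NA`s injected.
#' @export
inject_missing <- function(records, rate, seed = 1L) {
  if (length(rate) != 1 || !is.finite(rate) || rate < 0 || rate >= 1) {
    stop("inject_missing(): rate must lie in [0, 1)")
  }
  if (rate == 0) return(records)
  fields <- intersect(c(setdiff(analysis_variables(), "bmi"),
                        "weight", "height"), names(records))
  set.seed(seed)
  for (f in fields) {
    mask <- stats::runif(nrow(records)) < rate
    records[[f]][mask] <- NA
  }
  records
}
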