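#' Tercile cut-points
#'
#' Empirical 1/3 and 2/3 quantiles using the inclusive empirical quantile
#' (type 1, cut-points are attained data values), so classes built as
#' `< c1 / [c1, c2] / > c2` are balanced up to ties at the cuts.
#'
#' @param values Numeric vector with at least 3 distinct values.
#' @return Numeric length-2 vector `(c1, c2)`.
#' @export
tercile_cutpoints <- function(values) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 3) {
    stop("tercile_cutpoints(): need at least 3 distinct values")
  }
  unname(stats::quantile(values, c(1 / 3, 2 / 3), type = 1))
}

#' Density-valley cut-points for multimodal distributions
#'
#' Gaussian kernel density estimate on a fixed grid; cut-points are placed
#' at the local density minima between detected peaks (at the midpoint of
#' the argmin set when the valley is a flat plateau, i.e. midway between
#' the flanking peaks for symmetric mixtures). A unimodal density yields
#' an empty cut-point list, signalling the caller to fall back to
#' terciles.
#'
#' @param values Numeric vector, at least 10 values.
#' @param bandwidth Kernel bandwidth; Silverman's rule by default.
#' @param grid_n Number of grid points for the density estimate.
#' @param min_peak_frac Peaks lower than this fraction of the tallest peak
#'   are ignored (guards against noise wiggles in the KDE tail).
#' @param min_valley_drop Minimum relative dip of a valley below its lower
#'   flanking peak for the two peaks to count as separate modes; adjacent
#'   peaks separated by a shallower valley are merged (guards against
#'   sampling wiggles on a unimodal density).
#' @return Numeric vector of cut-points (possibly empty).
#' @export
multimodal_cutpoints <- function(values, bandwidth = NULL, grid_n = 512,
                                 min_peak_frac = 0.1,
                                 min_valley_drop = 0.2) {
  values <- values[!is.na(values)]
  if (length(values) < 10) {
    stop("multimodal_cutpoints(): need at least 10 values")
  }
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(values)
  if (bandwidth <= 0) stop("multimodal_cutpoints(): bandwidth must be > 0")
  d <- stats::density(values, bw = bandwidth, n = grid_n)
  y <- d$y
  x <- d$x
  # interior local maxima (plateau-aware: compare to nearest differing values)
  n <- length(y)
  is_peak <- logical(n)
  for (i in 2:(n - 1)) {
    if (y[i] >= y[i - 1] && y[i] >= y[i + 1] &&
        (y[i] > y[i - 1] || y[i] > y[i + 1])) {
      is_peak[i] <- TRUE
    }
  }
  peaks <- which(is_peak)
  peaks <- peaks[y[peaks] >= min_peak_frac * max(y)]
  # collapse adjacent grid points of one plateau-peak
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) > 1)
    peaks <- peaks[keep]
  }
  # merge adjacent peaks whose separating valley is too shallow
  while (length(peaks) >= 2) {
    drops <- vapply(seq_len(length(peaks) - 1), function(i) {
      v <- min(y[peaks[i]:peaks[i + 1]])
      1 - v / min(y[peaks[i]], y[peaks[i + 1]])
    }, numeric(1))
    j <- which.min(drops)
    if (drops[j] >= min_valley_drop) break
    drop_peak <- if (y[peaks[j]] <= y[peaks[j + 1]]) j else j + 1
    peaks <- peaks[-drop_peak]
  }
  if (length(peaks) < 2) return(numeric(0))
  cuts <- numeric(0)
  for (i in seq_len(length(peaks) - 1)) {
    seg <- seq(peaks[i], peaks[i + 1])
    ymin <- min(y[seg])
    argmin <- seg[y[seg] <= ymin + 1e-12]
    cuts <- c(cuts, mean(range(x[argmin])))
  }
  cuts
}

#' Build a categorization rule
#'
#' @param variable Variable name.
#' @param kind `"REF"` (referenced cut-offs), `"TER"` (terciles) or
#'   `"MM"` (multimodal-distribution cut-offs).
#' @param cutpoints Strictly increasing numeric cut-points.
#' @param labels Ordered modality labels, one more than cut-points.
#' @param boundary_policy Per-cut-point tie policy: `"upper"` sends a value
#'   equal to the cut to the class above it, `"lower"` to the class below.
#'   Printed brackets dictate it: `< c1 / [c1-c2] / > c2` is
#'   `c("upper", "lower")`; `[25-30[` is `c("upper", "upper")`.
#' @param disorder_grade Named map label -> one of `"low"`,
#'   `"intermediate"`, `"high"`, `"none"`.
#' @param sex `"woman"`, `"man"` or `"both"` (REF rules are sex-invariant).
#' @return A list of class `clbp_rule`.
#' @export
categorization_rule <- function(variable, kind, cutpoints, labels,
                                boundary_policy = rep("upper", length(cutpoints)),
                                disorder_grade = NULL, sex = "both") {
  kind <- match.arg(kind, c("REF", "TER", "MM"))
  if (length(cutpoints) >= 2 && any(diff(cutpoints) <= 0)) {
    stop("categorization_rule(): cutpoints must be strictly increasing")
  }
  if (length(labels) != length(cutpoints) + 1) {
    stop("categorization_rule(): need |labels| = |cutpoints| + 1")
  }
  if (length(boundary_policy) != length(cutpoints) ||
      !all(boundary_policy %in% c("upper", "lower"))) {
    stop("categorization_rule(): boundary_policy must be 'upper'/'lower' per cutpoint")
  }
  if (is.null(disorder_grade)) {
    disorder_grade <- setNames(rep("none", length(labels)), labels)
  }
  if (!setequal(names(disorder_grade), labels) ||
      !all(disorder_grade %in% c("low", "intermediate", "high", "none"))) {
    stop("categorization_rule(): disorder_grade must map every label to ",
         "low/intermediate/high/none")
  }
  structure(list(variable = variable, kind = kind,
                 cutpoints = as.numeric(cutpoints), labels = labels,
                 boundary_policy = boundary_policy,
                 disorder_grade = disorder_grade[labels], sex = sex),
            class = "clbp_rule")
}

#' Apply a categorization rule to values
#'
#' Interval membership honouring each cut-point's tie policy, so both the
#' closed (`[a-b]`) and half-open (`[a-b[`) printed bracket dialects are
#' supported.
#'
#' @param value Numeric vector.
#' @param rule A `clbp_rule`.
#' @param lo,hi Optional instrument bounds; values outside are rejected.
#' @return Character vector of modality labels.
#' @export
apply_rule <- function(value, rule, lo = -Inf, hi = Inf) {
  stopifnot(inherits(rule, "clbp_rule"))
  if (any(!is.na(value) & (value < lo | value > hi))) {
    stop("apply_rule(): value outside instrument bounds for '",
         rule$variable, "'")
  }
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  idx <- rep(1L, sum(ok))
  v <- value[ok]
  for (i in seq_along(rule$cutpoints)) {
    cut <- rule$cutpoints[i]
    above <- if (rule$boundary_policy[i] == "upper") v >= cut else v > cut
    idx[above] <- i + 1L
  }
  out[ok] <- rule$labels[idx]
  out
}

# Fixed (referenced or printed single-column) rules shared by both sexes.
.ref_rules <- function() {
  grade3 <- function(labels, direction) {
    g <- if (direction >= 0) c("low", "intermediate", "high")
    else c("high", "intermediate", "low")
    setNames(g, labels)
  }
  list(
    bmi = categorization_rule(
      "bmi", "REF", c(25, 30), c("normal", "overweight", "obesity"),
      boundary_policy = c("upper", "upper"),
      disorder_grade = c(normal = "low", overweight = "intermediate",
                         obesity = "high")),
    hads_anxiety = categorization_rule(
      "hads_anxiety", "REF", c(8, 11), c("low", "intermediate", "high"),
      boundary_policy = c("upper", "lower"),
      disorder_grade = grade3(c("low", "intermediate", "high"), 1)),
    hads_depression = categorization_rule(
      "hads_depression", "REF", c(8, 11), c("low", "intermediate", "high"),
      boundary_policy = c("upper", "lower"),
      disorder_grade = grade3(c("low", "intermediate", "high"), 1)),
    tsk = categorization_rule(
      "tsk", "REF", 40, c("negative", "positive"),
      boundary_policy = "upper",
      disorder_grade = c(negative = "low", positive = "high")),
    physical_activity = categorization_rule(
      "physical_activity", "MM", c(2, 4), c("low", "moderate", "high"),
      boundary_policy = c("upper", "upper"),
      disorder_grade = c(low = "high", moderate = "intermediate",
                         high = "low")),
    hours_week = categorization_rule(
      "hours_week", "MM", 30, c("partial", "full"),
      boundary_policy = "upper",
      disorder_grade = c(partial = "none", full = "none"))
  )
}

#' Build a sex-specific categorization scheme
#'
#' Referenced rules are fixed (WHO BMI classes at 25/30; HADS subscales at
#' 8/11 with a closed middle class; TSK kinesiophobia positive at >= 40;
#' the printed physical-activity and weekly-hours splits). Tercile and
#' multimodal rules are computed from the given sex subsample: `TER`
#' variables get classes `T1 / T2 / T3` at the empirical tercile
#' cut-points (closed middle class); `MM` variables get density-valley
#' cut-points, falling back to terciles when the estimated density is
#' unimodal.
#'
#' @param records Complete-case cohort rows of one sex (data frame with a
#'   `bmi` column, e.g. from [derive_variables()]).
#' @param sex `"woman"` or `"man"`.
#' @param min_n Minimum subsample size for computing TER/MM cut-points.
#' @param variables Analysis variables to build rules for (defaults to the
#'   full registry; the pipeline passes the subset that survived the
#'   completeness filter).
#' @return A list of class `clbp_scheme`: `sex`, `rules` (named list of
#'   `clbp_rule`).
#' @export
build_scheme <- function(records, sex = c("woman", "man"), min_n = 10,
                         variables = analysis_variables()) {
  sex <- match.arg(sex)
  if (!all(records$sex == sex)) {
    stop("build_scheme(): records must all be of sex '", sex, "'")
  }
  reg <- instrument_table()
  reg <- reg[reg$variable %in% variables, , drop = FALSE]
  rules <- .ref_rules()
  grade_t <- function(direction) {
    if (direction > 0) c(T1 = "low", T2 = "intermediate", T3 = "high")
    else c(T1 = "high", T2 = "intermediate", T3 = "low")
  }
  for (i in seq_len(nrow(reg))) {
    v <- reg$variable[i]
    if (v %in% names(rules)) {
      rules[[v]]$sex <- "both"
      next
    }
    vals <- records[[v]]
    vals <- vals[!is.na(vals)]
    if (length(vals) < min_n) {
      stop("build_scheme(): subsample too small for variable '", v, "'")
    }
    cuts <- numeric(0)
    kind <- reg$kind[i]
    if (kind == "MM") {
      cuts <- multimodal_cutpoints(vals)
      if (length(cuts) == 0) kind <- "TER"  # unimodal fallback
    }
    if (kind == "TER" || length(cuts) == 0) {
      cuts <- tercile_cutpoints(vals)
      kind <- if (reg$kind[i] == "MM") "MM" else "TER"
    }
    k <- length(cuts) + 1
    labels <- paste0("T", seq_len(k))
    dg <- if (reg$disorder_direction[i] == 0) {
      setNames(rep("none", k), labels)
    } else if (k == 3) {
      grade_t(reg$disorder_direction[i])
    } else {
      # non-tercile class count: grade extremes, middle classes intermediate
      g <- rep("intermediate", k)
      if (reg$disorder_direction[i] > 0) { g[1] <- "low"; g[k] <- "high" }
      else { g[1] <- "high"; g[k] <- "low" }
      setNames(g, labels)
    }
    # closed middle class dialect: < c1 / [c1, c2] / > c2
    pol <- c("upper", rep("lower", length(cuts) - 1))
    rules[[v]] <- categorization_rule(v, kind, cuts, labels,
                                      boundary_policy = pol,
                                      disorder_grade = dg, sex = sex)
  }
  structure(list(sex = sex, rules = rules[reg$variable]),
            class = "clbp_scheme")
}

#' Code a cohort into the modality table
#'
#' Applies a categorization scheme to the numeric analysis variables and
#' (by default) appends the binary neuropathic-features variable, giving
#' the subjects-by-variables table of modality labels consumed by the MCA.
#' Incomplete subjects must have been discarded upstream; any remaining
#' absent cell is an error.
#'
#' @param records Complete-case cohort rows (with derived columns from
#'   [derive_variables()]).
#' @param scheme A `clbp_scheme` from [build_scheme()].
#' @param include_npf Append the `npf` (neuropathic features)
#'   absent/present variable.
#' @return A data frame of class `clbp_coded` with `subject_id` rownames;
#'   attribute `scheme` carries the scheme used.
#' @export
apply_scheme <- function(records, scheme, include_npf = TRUE) {
  stopifnot(inherits(scheme, "clbp_scheme"))
  reg <- instrument_table()
  out <- list()
  for (v in names(scheme$rules)) {
    i <- match(v, reg$variable)
    out[[v]] <- apply_rule(records[[v]], scheme$rules[[v]],
                           lo = reg$lo[i], hi = reg$hi[i])
  }
  if (include_npf) {
    if (is.null(records$neuropathic_features)) {
      stop("apply_scheme(): records lack the neuropathic_features column; ",
           "run derive_variables() first")
    }
    out$npf <- ifelse(records$neuropathic_features, "present", "absent")
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  rownames(df) <- records$subject_id
  if (anyNA(df)) {
    bad <- rownames(df)[apply(is.na(df), 1, any)]
    stop("apply_scheme(): absent cells for subjects: ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; discard incomplete subjects upstream")
  }
  structure(df, class = c("clbp_coded", "data.frame"), scheme = scheme)
}

#' Disorder grade of every modality in a coded table
#'
#' @param coded A `clbp_coded` table.
#' @return Named character vector mapping `variable=label` modality names
#'   to `low`/`intermediate`/`high`/`none`.
#' @export
modality_grades <- function(coded) {
  scheme <- attr(coded, "scheme")
  out <- c()
  for (v in names(coded)) {
    if (v == "npf") {
      g <- c("npf=absent" = "low", "npf=present" = "high")
    } else {
      r <- scheme$rules[[v]]
      g <- setNames(unname(r$disorder_grade), paste0(v, "=", r$labels))
    }
    out <- c(out, g)
  }
  out
}

#' Serialize a categorization scheme to flat text
#'
#' One rule per line: `variable;sex;kind;cutpoints;labels;policy;grades`
#' with comma-separated inner lists.
#'
#' @param scheme A `clbp_scheme`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  lines <- vapply(scheme$rules, function(r) {
    paste(r$variable, r$sex, r$kind,
          paste(sprintf("%.17g", r$cutpoints), collapse = ","),
          paste(r$labels, collapse = ","),
          paste(r$boundary_policy, collapse = ","),
          paste(r$disorder_grade, collapse = ","),
          sep = ";")
  }, character(1))
  writeLines(c(paste0("# clbpmca scheme; sex=", scheme$sex), lines), path)
  invisible(path)
}

#' Read a categorization scheme from flat text
#'
#' @param path File written by [write_scheme()].
#' @return A `clbp_scheme`.
#' @export
read_scheme <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")][1]
  sex <- sub(".*sex=", "", hdr)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rules <- list()
  for (ln in lines) {
    f <- strsplit(ln, ";", fixed = TRUE)[[1]]
    labels <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    rules[[f[1]]] <- categorization_rule(
      f[1], f[3], as.numeric(strsplit(f[4], ",", fixed = TRUE)[[1]]),
      labels, strsplit(f[6], ",", fixed = TRUE)[[1]],
      setNames(strsplit(f[7], ",", fixed = TRUE)[[1]], labels), sex = f[2])
  }
  structure(list(sex = sex, rules = rules), class = "clbp_scheme")
}
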