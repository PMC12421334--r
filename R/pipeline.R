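#' Add the derived analysis columns to a cohort
#'
#' Computes BMI and its WHO class from weight and height, adjudicates the
#' pain type from the DN4 fields, derives the neuropathic-features
#' composite and the analysis-eligibility flag.
#'
#' @param records Cohort data frame.
#' @param dn4_threshold DN4 positivity cut-off (default 4).
#' @return The cohort with columns `bmi`, `bmi_class`, `pain_type`,
#'   `neuropathic_features`, `eligible` appended.
#' @export
derive_variables <- function(records, dn4_threshold = 4L) {
  records$bmi <- round(bmi(records$weight, records$height), 1)
  records$bmi_class <- who_bmi_class(records$bmi)
  records$pain_type <- adjudicate_pain_type(
    records$dn4_score, records$dn4_complete,
    records$neuropathic_symptoms, records$widespread_pain,
    threshold = dn4_threshold)
  records$neuropathic_features <- neuropathic_features(records$pain_type)
  records$eligible <- eligible_case(records$pain_avg_0100,
                                    records$pain_duration_months)
  records
}

#' Write a cohort CSV
#'
#' One row per subject with the documented header; absent values are
#' empty cells; the seed (when known) is recorded in a leading comment
#' line.
#'
#' @param records Cohort data frame.
#' @param path Output path.
#' @param seed Optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# clbpmca cohort",
                    if (!is.null(seed)) paste0("; seed=", seed)), con)
  utils::write.csv(records, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort CSV with bounds validation
#'
#' Reads a file written by [write_cohort_csv()] (comment lines allowed),
#' types the logical columns, and validates every instrument score
#' against its bounds; offending subject ids are reported. Unknown
#' columns are preserved.
#'
#' @param path CSV path.
#' @return Cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("read_cohort_csv(): empty cohort file")
    return(df)
  }
  logical_cols <- c(paste0("gesture_", .clbp_gestures),
                    "rest_days_consecutive", "sick_leave_history",
                    "dn4_complete", "neuropathic_symptoms",
                    "widespread_pain", "neuropathic_features", "eligible")
  for (cl in intersect(logical_cols, names(df))) {
    df[[cl]] <- as.logical(df[[cl]])
  }
  reg <- instrument_table()
  for (i in seq_len(nrow(reg))) {
    v <- reg$variable[i]
    if (!v %in% names(df)) next
    bad <- !is.na(df[[v]]) & (df[[v]] < reg$lo[i] | df[[v]] > reg$hi[i])
    if (any(bad)) {
      stop("read_cohort_csv(): '", v, "' outside [", reg$lo[i], ", ",
           reg$hi[i], "] for subjects: ",
           paste(utils::head(df$subject_id[bad], 5), collapse = ", "))
    }
  }
  if ("dn4_score" %in% names(df)) {
    bad <- !is.na(df$dn4_score) & (df$dn4_score < 0 | df$dn4_score > 10)
    if (any(bad)) {
      stop("read_cohort_csv(): dn4_score outside [0, 10] for subjects: ",
           paste(utils::head(df$subject_id[bad], 5), collapse = ", "))
    }
  }
  df
}

#' Pipeline configuration
#'
#' @param input A `clbp_config` (synthetic preset) or a cohort CSV path.
#' @param sex_strata Strata to analyse: subset of `c("women", "men")`.
#' @param apply_eligibility Apply the moderate-to-severe cLBP filter.
#' @param axis_threshold_pct Minimum adjusted inertia share for axis
#'   retention.
#' @param k Number of clusters for the three methods.
#' @param kmeans_seed,kmeans_n_init k-means determinism parameters.
#' @param dn4_threshold DN4 positivity cut-off.
#' @param anchor_variable Variable whose highest-disorder modality anchors
#'   the consensus (pain interference).
#' @return List of class `clbp_pipeline_config`.
#' @export
pipeline_config <- function(input, sex_strata = c("women", "men"),
                            apply_eligibility = TRUE,
                            axis_threshold_pct = 5, k = 3,
                            kmeans_seed = 20250904, kmeans_n_init = 50,
                            dn4_threshold = 4L,
                            anchor_variable = "pain_interference") {
  if (is.character(input) && !file.exists(input)) {
    stop("pipeline_config(): input path does not exist: ", input)
  }
  if (axis_threshold_pct <= 0 || k < 2) {
    stop("pipeline_config(): thresholds must be positive and k >= 2")
  }
  sex_strata <- match.arg(sex_strata, several.ok = TRUE)
  structure(list(input = input, sex_strata = sex_strata,
                 apply_eligibility = apply_eligibility,
                 axis_threshold_pct = axis_threshold_pct, k = k,
                 kmeans_seed = kmeans_seed, kmeans_n_init = kmeans_n_init,
                 dn4_threshold = dn4_threshold,
                 anchor_variable = anchor_variable),
            class = "clbp_pipeline_config")
}

# anchor modality name for a stratum: the highest-disorder modality of the
# anchor variable (3rd tercile of pain interference under tercile coding)
.anchor_modality <- function(scheme, anchor_variable) {
  r <- scheme$rules[[anchor_variable]]
  hi <- names(r$disorder_grade)[r$disorder_grade == "high"]
  if (length(hi) == 0) hi <- r$labels[length(r$labels)]
  paste0(anchor_variable, "=", hi[length(hi)])
}

#' Run the full sex-stratified phenotyping pipeline
#'
#' Per stratum: eligibility filter, variable/subject completeness filter,
#' sex-specific categorization scheme, modality coding, MCA with
#' Benzecri-adjusted axis selection, the three parallel clusterings, and
#' the anchored consensus cluster. A manifest records parameters, seeds
#' and row counts at every filter stage.
#'
#' @param config A `clbp_pipeline_config`.
#' @return List of class `clbp_run`: per-stratum results (`cohort` counts,
#'   `scheme`, `coded`, `mca`, `K`, `consensus`) plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "clbp_pipeline_config"))
  records <- if (is.character(config$input)) {
    read_cohort_csv(config$input)
  } else {
    generate_cohort(config$input)
  }
  records <- derive_variables(records, config$dn4_threshold)
  manifest <- list()
  note <- function(stage, stratum, n_in, n_out, detail = "") {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, stratum = stratum, n_in = n_in, n_out = n_out,
      detail = detail, stringsAsFactors = FALSE)
  }
  note("load", "all", nrow(records), nrow(records),
       if (is.character(config$input)) config$input else
         paste0("synthetic; seed=", config$input$seed))
  out <- list()
  for (stratum in config$sex_strata) {
    sex <- if (stratum == "women") "woman" else "man"
    sub <- records[records$sex == sex, , drop = FALSE]
    n0 <- nrow(sub)
    if (n0 == 0) {
      note("skip_empty_stratum", stratum, 0, 0)
      next
    }
    if (config$apply_eligibility) {
      sub <- sub[sub$eligible, , drop = FALSE]
    }
    note("eligibility", stratum, n0, nrow(sub))
    # drop all-absent variables, then incomplete subjects
    vars <- analysis_variables()
    all_absent <- vars[vapply(vars, function(v) all(is.na(sub[[v]])),
                              logical(1))]
    vars_used <- setdiff(vars, all_absent)
    if (length(all_absent) > 0) {
      warning("run_pipeline(): variable(s) with no data dropped in ",
              stratum, ": ", paste(all_absent, collapse = ", "))
    }
    n1 <- nrow(sub)
    complete <- stats::complete.cases(sub[, vars_used, drop = FALSE])
    sub <- sub[complete, , drop = FALSE]
    note("complete_cases", stratum, n1, nrow(sub),
         paste0("variables=", length(vars_used)))
    if (nrow(sub) < 10) {
      stop("run_pipeline(): stage complete_cases left fewer than 10 ",
           "subjects in stratum ", stratum)
    }
    scheme <- build_scheme(sub, sex, variables = vars_used)
    coded <- apply_scheme(sub, scheme)
    ind <- build_indicator(coded)
    anchor <- .anchor_modality(scheme, config$anchor_variable)
    mca <- run_mca(ind, orient_modality = anchor)
    K <- select_axes(mca, config$axis_threshold_pct)
    consensus <- cluster_modalities(
      mca, anchor, k = config$k, axes = seq_len(K),
      seed = config$kmeans_seed, n_init = config$kmeans_n_init)
    note("mca", stratum, nrow(sub), mca$J,
         paste0("Q=", mca$Q, "; K=", K, "; F1adj=",
                round(mca$adjusted_inertia_pct[1], 1), "%"))
    note("consensus", stratum, mca$J, length(consensus$final_cluster),
         paste0("k=", config$k, "; kmeans_seed=", config$kmeans_seed,
                "; anchor=", anchor))
    out[[stratum]] <- list(n = nrow(sub), scheme = scheme, coded = coded,
                           mca = mca, K = K, anchor = anchor,
                           consensus = consensus)
  }
  out$manifest <- do.call(rbind, manifest)
  class(out) <- "clbp_run"
  out
}

#' Write the tables of a pipeline run
#'
#' Eigenvalue table, modality coordinates/contributions, subject
#' coordinates, per-method assignments and the consensus table, as plain
#' CSV per stratum, plus the manifest.
#'
#' @param run A `clbp_run`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  for (stratum in setdiff(names(run), "manifest")) {
    s <- run[[stratum]]
    mca <- s$mca
    wr(data.frame(axis = seq_along(mca$eigenvalues),
                  eigenvalue = mca$eigenvalues,
                  raw_pct = mca$raw_inertia_pct,
                  adjusted_pct = mca$adjusted_inertia_pct),
       paste0(stratum, "_eigenvalues.csv"))
    wr(data.frame(modality = rownames(mca$modality_coords),
                  mca$modality_coords,
                  contrib = mca$modality_contrib_pct),
       paste0(stratum, "_modalities.csv"))
    wr(data.frame(subject_id = rownames(mca$subject_coords),
                  mca$subject_coords),
       paste0(stratum, "_subjects.csv"))
    asg <- attr(s$consensus, "assignments")
    lab <- sapply(asg, function(a) a$labels[rownames(mca$modality_coords)])
    colnames(lab) <- sapply(asg, `[[`, "method")
    cons <- data.frame(
      modality = rownames(mca$modality_coords), lab,
      in_final_cluster = rownames(mca$modality_coords) %in%
        s$consensus$final_cluster)
    wr(cons, paste0(stratum, "_consensus.csv"))
  }
  wr(run$manifest, "manifest.csv")
  invisible(paths)
}

#' Plot the modality map of a stratum
#'
#' F1 x F2 modality map with the conventional symbol semantics: plotting
#' symbol by variable family (square = pain, triangle = affective,
#' diamond = cognitive, circle = other health, cross = work description)
#' and shade by disorder grade (black = high, grey = intermediate,
#' white = low); final-cluster modalities are circled.
#'
#' @param run A `clbp_run`.
#' @param stratum `"women"` or `"men"`.
#' @param label Draw modality names.
#' @return Invisibly, the coordinates plotted.
#' @export
plot_modality_map <- function(run, stratum, label = TRUE) {
  s <- run[[stratum]]
  co <- s$mca$modality_coords[, 1:2]
  grades <- modality_grades(s$coded)[rownames(co)]
  fam <- instrument_table()$family
  names(fam) <- instrument_table()$variable
  vfam <- fam[sub("=.*", "", rownames(co))]
  vfam[is.na(vfam)] <- "pain"  # npf
  pch <- c(pain = 22, affective = 24, cognitive = 23, health = 21,
           work = 4)[vfam]
  bg <- c(high = "black", intermediate = "grey60", low = "white",
          none = "grey90")[grades]
  plot(co, pch = pch, bg = bg, cex = 1.3, xlab = "F1", ylab = "F2",
       main = paste("Modality map -", stratum))
  abline(h = 0, v = 0, col = "grey80", lty = 3)
  infc <- rownames(co) %in% s$consensus$final_cluster
  points(co[infc, , drop = FALSE], cex = 2.2, col = "grey40")
  if (label) {
    text(co, labels = rownames(co), pos = 3, cex = 0.55)
  }
  invisible(co)
}

#' @export
print.clbp_run <- function(x, ...) {
  cat("clbpmca pipeline run\n")
  for (stratum in setdiff(names(x), "manifest")) {
    s <- x[[stratum]]
    cat("\n[", stratum, "] n =", s$n, "; Q =", s$mca$Q, "; J =", s$mca$J,
        "\n  adjusted inertia F1/F2: ",
        sprintf("%.1f%% / %.1f%%", s$mca$adjusted_inertia_pct[1],
                s$mca$adjusted_inertia_pct[2]),
        "(K =", s$K, "axes retained)\n")
    cat("  final cluster (by proximity to ", s$anchor, "):\n    ",
        paste(s$consensus$final_cluster, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
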