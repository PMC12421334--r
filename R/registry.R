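#' Instrument registry for the cLBP analysis variables
#'
#' Metadata for the numeric analysis variables: instrument bounds,
#' reporting granularity, the categorization kind used for each variable
#' (referenced cut-offs, terciles, or density-valley cut-offs), the
#' direction in which the score indicates disorder, the variable family
#' used in the modality map, and sex-specific location/scale parameters
#' used by the synthetic-cohort generator (medians and quartile spreads of
#' a service-company cLBP workforce).
#'
#' `disorder_direction` is +1 when a high score marks the worse state
#' (pain, stress, catastrophizing, fear-avoidance, kinesiophobia, BMI,
#' age), -1 when a low score does (quality of life, physical activity) and
#' 0 for work-description variables that carry no disorder ordering
#' (seniority, weekly hours).
#'
#' @return A data frame with one row per numeric analysis variable and
#'   columns `variable`, `lo`, `hi`, `granularity`, `kind`,
#'   `disorder_direction`, `family`, `mu_women`, `sd_women`, `mu_men`,
#'   `sd_men`.
#' @export
instrument_table <- function() {
  df <- read.csv(text = "
variable,lo,hi,granularity,kind,disorder_direction,family,mu_women,sd_women,mu_men,sd_men
age,20,60,1,TER,1,health,41,11.9,40,10.4
bmi,14,50,0.1,REF,1,health,23.4,4.4,25.5,3.8
physical_activity,0,30,1,MM,-1,health,1.3,2.4,1.8,2.8
seniority_job,0,480,1,MM,0,work,84,75.6,86,86.0
hours_week,0,60,1,MM,0,work,34,3.5,34.5,2.5
hads_anxiety,0,21,1,REF,1,affective,8,3.7,7,4.4
hads_depression,0,21,1,REF,1,affective,5,4.4,6,3.7
pcs,0,52,1,TER,1,cognitive,18,14.1,20,14.1
stress_home,0,100,1,TER,1,affective,30,25.9,30,21.5
stress_work,0,100,1,TER,1,affective,60,19.3,70,22.2
pain_severity,0,10,0.1,TER,1,pain,4.7,1.9,5.0,1.5
pain_interference,0,10,0.1,TER,1,pain,4.0,2.8,4.0,3.0
sf12_physical,0,100,0.1,TER,-1,health,46,11.1,44,8.2
sf12_mental,0,100,0.1,TER,-1,health,43,11.1,42,11.1
tsk,17,68,1,REF,1,cognitive,38,10.4,44,7.4
fapa,0,24,1,TER,1,cognitive,12,7.4,13,5.9
faw,0,42,1,TER,1,cognitive,16,14.1,23,10.4
", stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

#' Names of the numeric analysis variables
#'
#' @return Character vector of the registry's variable names, in the
#'   canonical ordering used throughout the pipeline.
#' @export
analysis_variables <- function() instrument_table()$variable

# Gestures considered likely to favour cLBP, plus the remaining declared
# repetitive gestures collected by the survey.
.clbp_gestures <- c(
  "arms_raised", "wrist_torsion", "wrist_flexion", "neck_torsion",
  "neck_flexion", "back_torsion", "back_flexion", "vibrations",
  "heavy_loads", "static_standing", "static_sitting", "screen_work"
)

# Subset tested against pain interference in the work-factor analysis.
.clbp_back_gestures <- c(
  "back_torsion", "back_flexion", "vibrations", "heavy_loads",
  "static_standing", "static_sitting", "screen_work"
)

#' Declared repetitive gestures recognised by the pipeline
#'
#' @param back_relevant If `TRUE`, only the gestures considered likely to
#'   favour low back pain (the set tested against pain interference).
#' @return Character vector of gesture names.
#' @export
gesture_names <- function(back_relevant = FALSE) {
  if (back_relevant) .clbp_back_gestures else .clbp_gestures
}
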