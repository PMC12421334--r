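#' Body mass index
#'
#' @param weight_kg Body weight in kilograms, positive.
#' @param height_cm Height in centimetres, positive.
#' @return BMI in kg/m^2 (vectorised).
#' @examples
#' bmi(72, 170)  # 24.91
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("bmi(): weight_kg and height_cm must be finite and positive")
  }
  weight_kg / (height_cm / 100)^2
}

#' WHO body-mass-index class
#'
#' Partition of BMI into the WHO classes: normal (< 25),
#' overweight (25 to < 30, half-open) and obesity (>= 30).
#'
#' @param bmi_value BMI in kg/m^2, positive.
#' @return Character vector with levels `normal`, `overweight`, `obesity`.
#' @export
who_bmi_class <- function(bmi_value) {
  if (any(!is.finite(bmi_value)) || any(bmi_value <= 0)) {
    stop("who_bmi_class(): bmi_value must be finite and positive")
  }
  ifelse(bmi_value < 25, "normal",
         ifelse(bmi_value < 30, "overweight", "obesity"))
}

#' Pain-type adjudication from DN4 screening
#'
#' Applies the adjudication rules in order of precedence:
#' an incomplete DN4 gives `undefined`; a positive DN4 (score at or above
#' the positivity threshold) gives `neuropathic`; typical neuropathic
#' symptoms despite a negative DN4 give `mixed`; widespread pain gives
#' `nociplastic`; anything else is `nociceptive`. A mixed case that also
#' reports widespread pain is classified `mixed` (nociplastic is the
#' fallback for widespread pain only).
#'
#' @param dn4_score DN4 total, 0-10, or `NA` when the questionnaire was
#'   not completed.
#' @param dn4_complete Logical; was the DN4 fully answered?
#' @param neuropathic_symptoms Logical; typical neuropathic symptoms noted
#'   on review despite a negative DN4.
#' @param widespread_pain Logical; pain reported as widespread.
#' @param threshold DN4 positivity cut-off; the standard published
#'   cut-off of 4/10 by default.
#' @return One of `"nociceptive"`, `"neuropathic"`, `"mixed"`,
#'   `"nociplastic"`, `"undefined"` (vectorised).
#' @export
adjudicate_pain_type <- function(dn4_score, dn4_complete,
                                 neuropathic_symptoms, widespread_pain,
                                 threshold = 4L) {
  n <- length(dn4_complete)
  dn4_score <- rep_len(dn4_score, n)
  neuropathic_symptoms <- rep_len(neuropathic_symptoms, n)
  widespread_pain <- rep_len(widespread_pain, n)
  if (any(dn4_complete & is.na(dn4_score))) {
    stop("adjudicate_pain_type(): dn4_complete = TRUE with absent dn4_score is inconsistent")
  }
  if (any(!is.na(dn4_score) & (dn4_score < 0 | dn4_score > 10))) {
    stop("adjudicate_pain_type(): dn4_score must lie in [0, 10]")
  }
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <-
      if (!dn4_complete[i]) "undefined"
      else if (dn4_score[i] >= threshold) "neuropathic"
      else if (neuropathic_symptoms[i]) "mixed"
      else if (widespread_pain[i]) "nociplastic"
      else "nociceptive"
  }
  out
}

#' Neuropathic-features composite
#'
#' Binary composite: `TRUE` iff the adjudicated pain type is neuropathic
#' or mixed.
#'
#' @param pain_type Character vector of adjudicated pain types.
#' @return Logical vector.
#' @export
neuropathic_features <- function(pain_type) {
  ok <- c("nociceptive", "neuropathic", "mixed", "nociplastic", "undefined")
  if (!all(pain_type %in% ok)) {
    stop("neuropathic_features(): unknown pain type: ",
         paste(setdiff(unique(pain_type), ok), collapse = ", "))
  }
  pain_type %in% c("neuropathic", "mixed")
}

#' Analysis-eligibility filter for cLBP cases
#'
#' A case enters the analysis when the average pain-severity item (BPI
#' "pain on average", 0-100 scale) exceeds 30 strictly, and the pain has
#' lasted at least 3 months (inclusive) - i.e. moderate-to-severe chronic
#' low back pain.
#'
#' @param pain_severity_avg Average pain item on the 0-100 scale.
#' @param duration_months Pain duration in months.
#' @return Logical vector.
#' @export
eligible_case <- function(pain_severity_avg, duration_months) {
  if (any(pain_severity_avg < 0, na.rm = TRUE) ||
      any(duration_months < 0, na.rm = TRUE)) {
    stop("eligible_case(): negative inputs are invalid")
  }
  pain_severity_avg > 30 & duration_months >= 3
}
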