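#!/usr/bin/env Rscript
# Descriptive/comparative layer: per-variable sex-group summaries with the
# explicit test-selection rule (Shapiro-Wilk proxy for the visual
# normality check -> Student's t or Mann-Whitney), plus the nominal
# splits of BMI class and pain type by sex.

library(clbpmca)

cohort <- read_cohort_csv("results/cohort.csv")

tab <- compare_sex_groups(cohort)
write.csv(tab, "results/sex_comparisons.csv", row.names = FALSE)
cat("sex-group comparisons (numeric variables):\n")
print(tab[, c("variable", "women_median", "men_median", "test", "p_value")],
      digits = 3)

for (v in c("bmi_class", "pain_type")) {
  counts <- table(cohort[[v]], cohort$sex)
  cmp <- compare_nominal(unclass(counts))
  cat(sprintf("\n%s by sex: %s p = %.3g\n", v, cmp$test_used, cmp$p_value))
  print(counts)
}

sig <- tab$variable[tab$p_value < 0.05]
cat("\nvariables differing between sexes at p < 0.05:",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
cat("written: results/sex_comparisons.csv\n")
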