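#!/usr/bin/env Rscript
# Builds the working dataset for the downstream analyses: a seeded
# synthetic cohort of workers with chronic low back pain (164 women,
# 92 men) under the shipped sex-specific presets, with the derived
# variables (BMI class, DN4-adjudicated pain type, neuropathic features,
# eligibility) appended.

library(clbpmca)

dir.create("results", showWarnings = FALSE)
seed <- 20250904

cohort <- derive_variables(generate_cohort(preset_config("full_cohort",
                                                         seed = seed)))
write_cohort_csv(cohort, "results/cohort.csv", seed = seed)

cat("cohort:", nrow(cohort), "subjects (",
    sum(cohort$sex == "woman"), "women /", sum(cohort$sex == "man"),
    "men )\n")
cat("eligible (severity > 30/100, >= 3 months):", sum(cohort$eligible), "\n")
cat("pain types:\n")
print(table(cohort$pain_type))
cat(sprintf("neuropathic features: %.1f%%\n",
            100 * mean(cohort$neuropathic_features)))
cat("written: results/cohort.csv\n")
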