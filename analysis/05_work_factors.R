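#!/usr/bin/env Rscript
# Work-factor layer: Mann-Whitney associations of pain interference with
# the back-relevant repetitive gestures, the absence of consecutive rest
# days and sick-leave history, in the whole sample and per sex.

library(clbpmca)

cohort <- read_cohort_csv("results/cohort.csv")

out <- NULL
for (group in c("all", "women", "men")) {
  wf <- work_factor_associations(cohort, group)
  wf$group <- group
  out <- rbind(out, wf)
  sig <- wf$factor[wf$tested & wf$p_value < 0.05]
  cat(sprintf("%-6s: %d factors tested, significant at p < 0.05: %s\n",
              group, sum(wf$tested),
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
}
write.csv(out, "results/work_factor_associations.csv", row.names = FALSE)
cat("written: results/work_factor_associations.csv\n")
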