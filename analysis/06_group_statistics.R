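#!/usr/bin/env Rscript
# Group comparisons over the measurements produced by the earlier steps:
# unpaired, unequal-variance (Welch) t-tests with Holm-Bonferroni
# correction within each metric family, plus mean +/- 95% CI summaries.
# Run after 01, 02 and 04.

suppressMessages(library(cardiomapr))

need <- c("results/voltage_summary.csv", "results/calcium_summary.csv",
          "results/zline_lengths.csv")
missing <- need[!file.exists(need)]
if (length(missing))
  stop("missing inputs (run analysis/01,02,04 first): ",
       paste(missing, collapse = ", "))

vm <- read.csv("results/voltage_summary.csv")
ca <- read.csv("results/calcium_summary.csv")
zl <- read.csv("results/zline_lengths.csv")

long <- rbind(
  data.frame(group = vm$line, metric = "apd30_ms", value = vm$apd30_ms),
  data.frame(group = vm$line, metric = "apd80_ms", value = vm$apd80_ms),
  data.frame(group = vm$line, metric = "upstroke_rsd", value = vm$upstroke_rsd),
  data.frame(group = vm$line, metric = "cv_cm_s", value = vm$cv_cm_s),
  data.frame(group = ca$line, metric = "ttp_ms", value = ca$ttp_ms),
  data.frame(group = ca$line, metric = "decay_rate_s", value = ca$decay_rate_s),
  data.frame(group = zl$line, metric = "zline_um", value = zl$length_um))

rep <- compare_groups(long)
print(rep)
write.csv(rep$summaries, "results/group_summaries.csv", row.names = FALSE)
write.csv(rep$comparisons, "results/comparisons.csv", row.names = FALSE)
for (fam in unique(rep$comparisons$metric))
  cat(sprintf("family %-13s m = %d tests\n", fam,
              unique(rep$comparisons$m[rep$comparisons$metric == fam])))
cat("wrote results/group_summaries.csv and results/comparisons.csv\n")
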