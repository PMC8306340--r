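#!/usr/bin/env Rscript
# Efficiency-corrected relative quantification of DSG2 expression.
#
# Two designed truths: the mutant line's DSG2 reduction relative to the two
# control lines (fold changes 0.648 and 0.504 vs Ctrl1-calibrated scale),
# and the siRNA knockdown (fold change 0.19 vs untreated). GAPDH and an 18S
# rRNA stand-in serve in combination as internal controls; quantities are
# normalized to their geometric mean and calibrated to the control group.

suppressMessages(library(cardiomapr))
dir.create("results", showWarnings = FALSE)

genes <- data.frame(gene = c("DSG2", "GAPDH", "RNA18S"),
                    role = c("target", "reference", "reference"))

des <- qpcr_design(
  genes, groups = c("Ctrl1", "Ctrl2", "DSG2Mut"),
  fold_changes = data.frame(gene = c("DSG2", "DSG2"),
                            group = c("Ctrl2", "DSG2Mut"),
                            fold_change = c(0.648 / 0.504, 0.648)),
  n_samples = 4, cq_noise_sd = 0.08, loading_sd = 0.15, seed = 31)
tab <- simulate_cq_table(des)
res <- nrq(tab, "Ctrl1")
print(res$per_group, digits = 3)
mutv <- res$per_group$nrq[res$per_group$gene == "DSG2" &
                            res$per_group$group == "DSG2Mut"]
c1 <- res$per_group$nrq[res$per_group$gene == "DSG2" &
                          res$per_group$group == "Ctrl1"]
c2 <- res$per_group$nrq[res$per_group$gene == "DSG2" &
                          res$per_group$group == "Ctrl2"]
cat(sprintf("DSG2 reduction vs Ctrl1: %.1f%%  vs Ctrl2: %.1f%%\n",
            percent_change(mutv, c1), percent_change(mutv, c2)))

des_kd <- qpcr_design(
  genes, groups = c("NegControl", "DSG2KD"),
  fold_changes = data.frame(gene = "DSG2", group = "DSG2KD",
                            fold_change = 0.19),
  n_samples = 4, cq_noise_sd = 0.08, loading_sd = 0.15, seed = 32)
res_kd <- nrq(simulate_cq_table(des_kd), "NegControl")
kd <- res_kd$per_group$nrq[res_kd$per_group$gene == "DSG2" &
                             res_kd$per_group$group == "DSG2KD"]
cat(sprintf("DSG2 knockdown vs untreated: %.1f%% decrease\n",
            percent_change(kd, 1)))

write.csv(rbind(cbind(experiment = "lines", res$per_group),
                cbind(experiment = "siRNA", res_kd$per_group)),
          "results/qpcr_nrq.csv", row.names = FALSE)
cat("wrote results/qpcr_nrq.csv\n")
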