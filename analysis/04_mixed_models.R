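#!/usr/bin/env Rscript
# Step 4 - mixed-effects models.
#
# Behavioral: response time ~ task + (1 | subject), Stroop vs pooled word
# reading (840 trials, DF 838) and incongruent vs congruent reading (560
# trials, DF 558). Amplitude: for every region and 200-ms window (sliding
# 50 ms over -600..200 ms response-locked), high-gamma percent change ~
# task + trial number + age + sex + lesion + medication count +
# (1 | subject), Wald t with DF = n - n_fixed, Benjamini-Hochberg over all
# region x window cells.

library(hgconn)

seed <- 42
dir.create("results", showWarnings = FALSE)
hg_file <- file.path("scratch", sprintf("hg_%d.rds", seed))
if (!file.exists(hg_file)) source("analysis/02_highgamma.R") else
  hg <- readRDS(hg_file)
coh <- readRDS(file.path("scratch", sprintf("cohort_%d.rds", seed)))

rt1 <- fit_rt_model(coh$events, "stroop_vs_reading",
                    subjects = coh$participants$subject)
rt2 <- fit_rt_model(coh$events, "incongruent_vs_congruent",
                    subjects = coh$participants$subject)
rt_tab <- rbind(cbind(contrast = "stroop_vs_reading", rt1),
                cbind(contrast = "incongruent_vs_congruent", rt2))
write.table(rt_tab, "results/04_rt_models.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf(paste0(
  "Stroop responses are %.0f ms slower than word reading ",
  "(t = %.1f, DF = %d, 95%% CI %.0f..%.0f ms).\n"),
  rt1$coefficient, rt1$t, rt1$df, rt1$ci_lo, rt1$ci_hi))
cat(sprintf("Incongruent reading is %.0f ms slower than congruent (DF = %d).\n",
            rt2$coefficient, rt2$df))

wc <- run_window_contrasts(hg, coh$participants)
write.table(wc$effects, "results/04_window_effects.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(wc$effects, file.path("scratch", sprintf("effects_%d.rds", seed)))

sig <- wc$effects[wc$effects$q_significant, ]
cat(sprintf("\n%d of %d region x window cells significant after FDR.\n",
            nrow(sig), nrow(wc$effects)))
best <- sig[which.max(abs(sig$coefficient)), ]
cat(sprintf("Largest effect: %s, window %d..%d ms, %.1f%% (%s-preferential).\n",
            best$roi, best$window_start, best$window_start + 200,
            abs(best$coefficient), best$preference))
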