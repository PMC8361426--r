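#!/usr/bin/env Rscript
# End-to-end demonstration: synthesize a small cohort in which a latent
# severity drives both cord compression depth and contralateral M1
# activation, run every stage (morphometry, reliability, GLM, ROI
# extraction, association), and show the recovered compression-activation
# correlation.

library(cordmotor)
dir.create("results", showWarnings = FALSE)

cfg <- pipeline_config("results/pipeline", seed = 23, n_subjects = 23,
                       n_perm = 200, severity_activation_r = 0.56)
man <- run_pipeline(cfg)

cat("stage outputs:\n")
for (s in names(man$stages)) cat(sprintf("  %-12s %s\n", s, man$stages[[s]]))

rel <- read.csv(file.path("results/pipeline", "reliability", "icc.csv"))
cat("\nreliability of the simulated volume measurement:\n")
print(rel)

bat <- read.csv(man$stages$association)
m1 <- bat[bat$y == "pb_M1_right", ]
cat(sprintf("\nrecovered compression x M1 %%BOLD correlation: r = %.2f (p = %.3g, n = %d)\n",
            m1$r, m1$p, m1$n))
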