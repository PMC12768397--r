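#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study data.
#
# Draws a main sample from the packaged hierarchical factor model (43 Likert
# items, 10 first-order factors, 2 correlated second-order domains), six
# external criterion scales with known regression structure, a second
# three-weeks-later wave with latent stability 0.9, and two invariance
# groups from the stress model. Everything downstream reads these files.

suppressMessages(library(wonemetrics))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

seed <- 20260920L
spec <- wone_phase2_spec()
cfg <- sim_config(n = 1000, seed = seed, mode = "continuous")

sample <- simulate_responses(spec, cfg)
write_responses(sample$responses, "results/analysis/responses.csv")
write.csv(sample$factor_scores, "results/analysis/factor_scores_true.csv",
          row.names = FALSE)

betas <- wonemetrics:::.default_criterion_betas(spec)
crit <- simulate_criteria(sample$factor_scores, betas, noise_sd = 0.8,
                          seed = seed + 1L)
write.csv(as.data.frame(crit$scores), "results/analysis/criteria.csv",
          row.names = FALSE)

retest <- simulate_retest(sample, stability = 0.9, seed = seed + 2L)
write_responses(rbind(retest$wave1, retest$wave2),
                "results/analysis/retest.csv", wave = retest$wave)

groups <- simulate_groups(wone_phase2_spec("stress"),
                          sim_config(n = 500, seed = seed + 3L),
                          groups = c("g1", "g2"))
write_responses(groups$responses, "results/analysis/groups.csv",
                group = groups$group)

imp <- implied_moments(spec)
cat(sprintf("simulated n = %d respondents x %d items (seed %d)\n",
            nrow(sample$responses), ncol(sample$responses), seed))
cat(sprintf("max |sample cov - implied cov| = %.3f\n",
            max(abs(cov(sample$responses) - imp$sigma))))
cat("wrote responses.csv, criteria.csv, retest.csv, groups.csv\n")
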