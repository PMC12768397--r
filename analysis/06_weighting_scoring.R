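#!/usr/bin/env Rscript
# Stage 6 — hybrid weighting and index scoring.
#
# Derives empirical construct weights from priority-weighted standardized
# regressions of the six criterion scales on the ten factor scores, blends
# them 50/50 with the published theoretical weights, applies the 5% floor
# with proportional renormalization, scores the weighted index, and
# compares it against unweighted and item-level composites. Also reproduces
# the published final-weight column from the published hybrid column.

suppressMessages(library(wonemetrics))
spec <- wone_phase2_spec()
resp <- read_responses("results/analysis/responses.csv")$responses
crit_scores <- as.matrix(read.csv("results/analysis/criteria.csv",
                                  check.names = FALSE))
pw <- wone_published_weights()

eq <- setNames(rep(10, 10), spec$factors$id)
fs <- score_index(resp, spec, eq)$factor_scores_reversed
crit <- list(scores = crit_scores,
             orientation = setNames(colnames(crit_scores) %in%
                                      pw$reverse_criteria,
                                    colnames(crit_scores)))
emp <- empirical_weights(fs, crit, pw$priorities)
theo <- setNames(pw$constructs$theoretical, pw$constructs$construct)
wt <- weight_table(emp, theo, floor = pw$floor)
write.csv(wt, "results/analysis/weight_table.csv", row.names = FALSE)
cat("hybrid weight table (synthetic empirical column):\n")
print(cbind(wt[, "construct", drop = FALSE],
            round(wt[, c("empirical", "theoretical", "hybrid", "final")], 1),
            display = wt$display), row.names = FALSE)

# the published hybrid column pushed through the floor reproduces the
# published integer final column exactly
fl <- apply_floor(setNames(pw$constructs$hybrid_printed,
                           pw$constructs$construct), pw$floor)
stopifnot(all(fl$display[pw$constructs$construct] ==
                pw$constructs$final_printed))
cat("\npublished hybrid column + 5% floor reproduces the published final column\n")
cat("floored constructs:", paste(fl$floored, collapse = ", "), "\n")

w <- setNames(wt$final, wt$construct)
cmp <- compare_scorers(resp, spec, w, crit)
write.csv(cmp, "results/analysis/scorer_comparison.csv", row.names = FALSE)
cat("\ncomposite-vs-criterion correlations (weighted / unweighted / item-level):\n")
print(cbind(cmp[, "criterion", drop = FALSE],
            round(cmp[, c("weighted", "unweighted", "item_level")], 3),
            best = cmp$best), row.names = FALSE)
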