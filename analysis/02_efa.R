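#!/usr/bin/env Rscript
# Stage 2 — exploratory factor analysis per domain.
#
# Mirrors the staged EFA: principal axis factoring with Promax rotation on
# the resilience items (7 factors) and the stress items (3 factors), with
# KMO / Bartlett suitability diagnostics and rule-based item retention.

suppressMessages(library(wonemetrics))
spec <- wone_phase2_spec()
resp <- read_responses("results/analysis/responses.csv")$responses

for (dom in c("resilience", "stress")) {
  items <- spec$items$id[spec$items$domain == dom]
  k <- if (dom == "resilience") 7 else 3
  ef <- run_efa(resp[, items], k = k, rules = retention_rules("phase2"))
  cat(sprintf("%s items (p = %d, k = %d): KMO = %.3f, Bartlett chisq(%d) = %.1f, %.1f%% variance\n",
              dom, length(items), k, ef$kmo$overall, ef$bartlett$df,
              ef$bartlett$chisq, 100 * ef$paf$var_explained))
  dropped <- ef$retention$item[!ef$retention$kept]
  cat(sprintf("  retained %d/%d items%s\n", sum(ef$retention$kept),
              length(items),
              if (length(dropped)) paste0(" (dropped: ",
                                          paste(dropped, collapse = ", "), ")")
              else ""))
  write.csv(cbind(item = rownames(ef$rotation$pattern),
                  as.data.frame(round(ef$rotation$pattern, 4))),
            sprintf("results/analysis/efa_%s_pattern.csv", dom),
            row.names = FALSE)
  write.csv(as.data.frame(round(ef$rotation$phi, 4)),
            sprintf("results/analysis/efa_%s_phi.csv", dom),
            row.names = FALSE)
  write.csv(ef$retention,
            sprintf("results/analysis/efa_%s_retention.csv", dom),
            row.names = FALSE)
  # scree data for human inspection (no automated retention from it)
  write.csv(data.frame(component = seq_along(ef$paf$initial_eigen),
                       eigenvalue = ef$paf$initial_eigen),
            sprintf("results/analysis/efa_%s_scree.csv", dom),
            row.names = FALSE)
}
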