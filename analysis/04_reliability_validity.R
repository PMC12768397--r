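#!/usr/bin/env Rscript
# Stage 4 — reliability and validity panel.
#
# Composite reliability and AVE from the packaged model's standardized
# loadings and printed communalities, sample Cronbach alpha and McDonald
# omega per factor, test-retest ICCs on the composite scales, HTMT
# discriminant-validity ratios, the criterion correlation panel, and
# hierarchical incremental validity of the weighted index beyond
# established-measure analogues.

suppressMessages(library(wonemetrics))
spec <- wone_phase2_spec()
resp <- read_responses("results/analysis/responses.csv")$responses
crit <- as.matrix(read.csv("results/analysis/criteria.csv",
                           check.names = FALSE))
rt <- read_responses("results/analysis/retest.csv")
w1 <- rt$responses[rt$wave == 1, ]
w2 <- rt$responses[rt$wave == 2, ]

rel <- reliability_report(spec, resp)
write.csv(rel, "results/analysis/reliability.csv", row.names = FALSE)
cat("per-factor reliability (CR from published loadings; alpha/omega from sample):\n")
print(cbind(rel[, c("factor", "k")], round(rel[, c("cr", "ave", "alpha", "omega")], 2)),
      row.names = FALSE)

w <- setNames(wone_published_weights()$constructs$final_printed,
              wone_published_weights()$constructs$construct)
s1 <- score_index(w1, spec, w); s2 <- score_index(w2, spec, w)
iccs <- do.call(rbind, lapply(
  list(index = list(s1$index, s2$index),
       stress = list(s1$stress_subscale, s2$stress_subscale),
       resilience = list(s1$resilience_subscale, s2$resilience_subscale)),
  function(p) {
    x <- icc(p[[1]], p[[2]], "ICC(2,1)")
    data.frame(icc = x$icc, lo = x$ci[1], hi = x$ci[2], band = x$band)
  }))
iccs <- cbind(scale = c("index", "stress", "resilience"), iccs)
write.csv(iccs, "results/analysis/retest_icc.csv", row.names = FALSE)
cat(sprintf("\n3-week retest ICC(2,1): index %.2f [%.2f, %.2f] (%s)\n",
            iccs$icc[1], iccs$lo[1], iccs$hi[1], iccs$band[1]))

ht <- htmt(resp, spec$items$factor)
write.csv(round(ht$ratios, 3), "results/analysis/htmt.csv")
cat(sprintf("HTMT: max ratio %.2f (conservative threshold 0.85 %s)\n",
            max(ht$ratios, na.rm = TRUE),
            if (max(ht$ratios, na.rm = TRUE) < 0.85) "met" else "exceeded"))

sc <- score_index(resp, spec, w)
panel <- correlation_panel(cbind(index = sc$index, stress = sc$stress_subscale,
                                 resilience = sc$resilience_subscale, crit))
write.csv(round(panel$r, 3), "results/analysis/correlation_panel.csv")

incr <- do.call(rbind, lapply(c("PHQ-8", "GAD-7", "WHO-5"), function(oc) {
  iv <- incremental_validity(crit[, oc], crit[, c("PSS-4", "CD-RISC", "BRS")],
                             matrix(sc$index, ncol = 1))
  data.frame(outcome = oc, delta_r2 = iv$delta_r2, f = iv$f, p = iv$p.value)
}))
write.csv(incr, "results/analysis/incremental_validity.csv", row.names = FALSE)
cat("\nincremental validity of the index beyond the criterion trio:\n")
print(cbind(incr[, "outcome", drop = FALSE], round(incr[, -1], 4)),
      row.names = FALSE)
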