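test_that("fitting the generating model to its population covariance is exact", {
  for (dom in c("stress", "resilience")) {
    spec <- wone_phase2_spec(dom)
    imp <- implied_moments(spec)
    fit <- fit_cfa(cfa_model(spec, second_order = TRUE),
                   sample_cov = imp$sigma, n = 306, se = FALSE)
    expect_lt(fit$fmin, 1e-9)
    expect_lt(fit$T, 1e-5)
    sl <- standardized_loadings(fit)
    item_sl <- sl[sl$to %in% spec$items$id, ]
    expect_equal(item_sl$std[match(spec$items$id, item_sl$to)],
                 spec$items$loading, tolerance = 1e-4)
    gam_sl <- sl[sl$to %in% spec$factors$id, ]
    expect_equal(gam_sl$std[match(spec$factors$id, gam_sl$to)],
                 spec$factors$gamma, tolerance = 1e-4)
    # R-squared equals lambda^2 for items without residual covariances
    r2 <- fit$standardized[[1]]$r2
    expect_equal(unname(r2[spec$items$id]), spec$items$loading^2,
                 tolerance = 1e-4)
  }
})

test_that("a just-identified three-indicator factor is saturated", {
  spec <- one_factor_spec(c(0.8, 0.7, 0.6), ids = c("a", "b", "c"))
  s <- simulate_responses(spec, sim_config(150, seed = 19))
  fit <- fit_cfa(cfa_model(spec, second_order = FALSE), data = s$responses,
                 se = FALSE)
  expect_equal(fit$df, 0)
  expect_lt(fit$T, 1e-6)
  expect_lt(fit$fit$srmr, 1e-4)
  expect_equal(fit$fit$rmsea, 0)
  expect_true(is.na(fit$fit$tli))
})

test_that("sample estimates match an independent ML factor analysis", {
  # single congeneric factor: stats::factanal fits the identical model
  spec <- one_factor_spec()
  s <- simulate_responses(spec, sim_config(500, seed = 23))
  fit <- fit_cfa(cfa_model(spec, second_order = FALSE), data = s$responses)
  ours <- standardized_loadings(fit)$std
  ref <- stats::factanal(covmat = cov(s$responses), factors = 1, n.obs = 500,
                         rotation = "none")
  expect_equal(abs(ours), abs(as.numeric(ref$loadings)), tolerance = 1e-3)
  # two-factor model: loadings recovered within sampling tolerance
  spec2 <- two_factor_spec(l1 = rep(0.7, 3), l2 = rep(0.7, 3), fcorr = 0.36)
  s2 <- simulate_responses(spec2, sim_config(500, seed = 29))
  fit2 <- fit_cfa(cfa_model(spec2, second_order = FALSE), data = s2$responses)
  sl2 <- standardized_loadings(fit2)
  expect_equal(sl2$std[sl2$to %in% spec2$items$id],
               spec2$items$loading, tolerance = 0.08)
})

test_that("standardized solution is invariant to the marker indicator", {
  spec <- two_factor_spec()
  s <- simulate_responses(spec, sim_config(400, seed = 31))
  f1 <- fit_cfa(cfa_model(spec, second_order = FALSE), data = s$responses,
                se = FALSE)
  f2 <- fit_cfa(cfa_model(spec, second_order = FALSE,
                          markers = c(A = "x3", B = "x6")),
                data = s$responses, se = FALSE)
  s1 <- standardized_loadings(f1); s2 <- standardized_loadings(f2)
  expect_equal(s1$std[order(s1$to)], s2$std[order(s2$to)], tolerance = 1e-5)
  expect_equal(f1$T, f2$T, tolerance = 1e-6)
})

test_that("a Heywood uniqueness is bounded at the variance floor and flagged", {
  lam <- c(0.9, 0.7, 0.6)
  sigma <- tcrossprod(lam) + diag(c(-0.02, 1, 1) - c(0, lam[2]^2, lam[3]^2))
  dimnames(sigma) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_gt(min(eigen(sigma, only.values = TRUE)$values), 0)
  spec <- one_factor_spec(lam, ids = c("a", "b", "c"))
  fit <- fit_cfa(cfa_model(spec, second_order = FALSE), sample_cov = sigma,
                 n = 300, se = FALSE)
  expect_true(fit$heywood)
  est <- fit$estimates
  expect_equal(est$est[est$label == "v_a"], 1e-3, tolerance = 1e-6)
})

test_that("SE magnitudes are plausible at the published sample size", {
  spec <- wone_phase2_spec("stress")
  s <- simulate_responses(spec, sim_config(306, seed = 37))
  fit <- fit_cfa(cfa_model(spec, second_order = TRUE), data = s$responses)
  est <- fit$estimates
  se_load <- est$se[est$matrix == "A" & est$free & est$row %in% spec$items$id]
  expect_true(all(is.finite(se_load)))
  expect_true(all(se_load > 0.01 & se_load < 0.3))
})

test_that("fit indices follow their closed forms", {
  # better-than-expected fit
  f <- compute_fit_indices(80, 100, 900, 120, 300)
  expect_equal(f$cfi, 1)
  expect_equal(f$rmsea, 0)
  # perfect reproduction gives SRMR 0
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  f2 <- compute_fit_indices(0, 1, 50, 1, 100, S = S, sigma = S)
  expect_equal(f2$srmr, 0)
  # hand arithmetic
  f3 <- compute_fit_indices(200, 100, 1100, 120, 300)
  expect_equal(f3$cfi, 1 - 100 / 980, tolerance = 1e-12)
  rb <- 1100 / 120
  expect_equal(f3$tli, (rb - 2) / (rb - 1), tolerance = 1e-12)
  expect_equal(f3$rmsea, sqrt(100 / (100 * 299)), tolerance = 1e-12)
  # RMSEA CI endpoints invert the noncentral chi-square cdf
  expect_equal(pchisq(200, 100, ncp = f3$rmsea_ci[1]^2 * 100 * 299), 0.95,
               tolerance = 1e-6)
  expect_equal(pchisq(200, 100, ncp = f3$rmsea_ci[2]^2 * 100 * 299), 0.05,
               tolerance = 1e-6)
  # degenerate df
  f4 <- compute_fit_indices(0, 0, 50, 3, 100)
  expect_equal(f4$rmsea, 0)
  expect_true(is.na(f4$tli))
})

test_that("modification indices locate an omitted residual covariance", {
  sm <- wone_phase2_spec("stress")
  sm2 <- measurement_model(sm$items, sm$factors,
                           residual_covariances = data.frame(
                             item1 = "anxious_personal", item2 = "anxious_work",
                             theta = 0.15),
                           cross_domain_corr = sm$cross_domain_corr)
  s <- simulate_responses(sm2, sim_config(1000, seed = 7))
  fit <- fit_cfa(cfa_model(sm, second_order = TRUE), data = s$responses)
  # the score of every free parameter is zero at the optimum, so already-free
  # parameters carry no modification index
  expect_lt(fit$gradient_norm, 1e-6)
  mi <- modification_indices(fit)
  expect_equal(mi$type[1], "resid_cov")
  expect_setequal(c(mi$a[1], mi$b[1]), c("anxious_personal", "anxious_work"))
  # MI approximates the chi-square drop from actually freeing the parameter
  m1 <- free_parameter(fit$model, "resid_cov", mi$a[1], mi$b[1])
  fit1 <- fit_cfa(m1, data = s$responses, se = FALSE)
  drop <- fit$T - fit1$T
  expect_lt(abs(mi$mi[1] - drop) / drop, 0.15)
  # expected parameter change approximates the freed estimate
  freed <- fit1$estimates
  est <- freed$est[grepl("^rc_", freed$label)]
  expect_equal(mi$epc[1], est, tolerance = 0.05)
})

test_that("refinement is gated by the allowlist and ordered by MI", {
  sm <- wone_phase2_spec("stress")
  sm2 <- measurement_model(sm$items, sm$factors,
                           residual_covariances = data.frame(
                             item1 = c("anxious_personal", "disengagement"),
                             item2 = c("anxious_work", "lack_productivity"),
                             theta = c(0.15, 0.12)),
                           cross_domain_corr = sm$cross_domain_corr)
  s <- simulate_responses(sm2, sim_config(1000, seed = 41))
  model <- cfa_model(sm, second_order = TRUE)
  # empty allowlist: model unchanged even with MIs above threshold
  r0 <- refine_model(model, data = s$responses, mi_threshold = 10,
                     allowlist = NULL)
  expect_equal(nrow(r0$audit), 0)
  expect_equal(length(r0$model$theta_labels), length(model$theta_labels))
  # one allowed pair: exactly one parameter freed, CFI increases
  allow1 <- data.frame(type = "resid_cov", a = "anxious_personal",
                       b = "anxious_work")
  r1 <- refine_model(model, data = s$responses, mi_threshold = 10,
                     allowlist = allow1)
  expect_equal(nrow(r1$audit), 1)
  expect_gte(r1$fit$fit$cfi, r0$fit$fit$cfi)
  # both pairs allowed: freed in descending MI order, discrepancy monotone
  allow2 <- data.frame(type = "resid_cov",
                       a = c("anxious_personal", "disengagement"),
                       b = c("anxious_work", "lack_productivity"))
  r2 <- refine_model(model, data = s$responses, mi_threshold = 10,
                     allowlist = allow2)
  expect_equal(nrow(r2$audit), 2)
  expect_gte(r2$audit$mi[1], r2$audit$mi[2])
  expect_lte(r2$audit$chisq[2], r2$audit$chisq[1])
})

test_that("multigroup discrepancy pools group contributions", {
  spec <- two_factor_spec()
  g <- simulate_groups(spec, sim_config(300, seed = 43),
                       groups = c("g1", "g2"))
  model <- cfa_model(spec, second_order = FALSE, ngroups = 2)
  fit <- fit_cfa(model, data = g$responses, group = g$group, se = FALSE)
  # configural multigroup df is twice the single-group df
  single <- cfa_model(spec, second_order = FALSE)
  f1 <- fit_cfa(single, data = g$responses[g$group == "g1", ], se = FALSE)
  expect_equal(fit$df, 2 * f1$df)
  expect_true(fit$converged)
})
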