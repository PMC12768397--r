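test_that("zero loadings produce independent items", {
  spec <- measurement_model(
    items = data.frame(id = paste0("n", 1:6), factor = rep(c("A", "B"), 3),
                       loading = 0),
    factors = data.frame(id = c("A", "B"), parent = "ResilienceResources",
                         gamma = c(0.7, 0.7)))
  s <- simulate_responses(spec, sim_config(10000, seed = 101))
  R <- cor(s$responses)
  expect_lt(max(abs(R[lower.tri(R)])), 0.03)
})

test_that("simulation is seed-deterministic", {
  spec <- two_factor_spec()
  cfg <- sim_config(200, seed = 7, mode = "ordinal")
  a <- simulate_responses(spec, cfg)
  b <- simulate_responses(spec, cfg)
  expect_identical(a$responses, b$responses)
  expect_identical(a$factor_scores, b$factor_scores)
  c <- simulate_responses(spec, sim_config(200, seed = 8, mode = "ordinal"))
  expect_false(identical(a$responses, c$responses))
})

test_that("sample covariance converges to the model-implied covariance", {
  spec <- wone_phase2_spec()
  imp <- implied_moments(spec)
  s <- simulate_responses(spec, sim_config(50000, seed = 42))
  expect_lt(max(abs(cov(s$responses) - imp$sigma)), 0.02)
})

test_that("ordinal mode produces complete 1-5 integers with attenuated correlations", {
  spec <- two_factor_spec()
  s_ord <- simulate_responses(spec, sim_config(8000, seed = 5, mode = "ordinal"))
  expect_true(all(s_ord$responses %in% 1:5))
  expect_false(anyNA(s_ord$responses))
  s_cont <- simulate_responses(spec, sim_config(8000, seed = 5))
  r_ord <- cor(s_ord$responses)
  r_cont <- cor(s_cont$responses)
  idx <- lower.tri(r_ord)
  expect_true(all(abs(r_ord[idx]) <= abs(r_cont[idx]) + 0.03))
})

test_that("criterion generation follows its closed-form structure", {
  set.seed(1)
  lat <- matrix(rnorm(20000), ncol = 1, dimnames = list(NULL, "F"))
  # null structure
  cr0 <- simulate_criteria(lat, data.frame(criterion = "C", factor = "F",
                                           beta = 0), seed = 2,
                           orientation = c(C = FALSE))
  expect_lt(abs(cor(lat[, 1], cr0$scores[, 1])), 0.03)
  # beta 0.6, noise 0.8: population correlation 0.6/sqrt(0.36+0.64) = 0.6
  cr <- simulate_criteria(lat, data.frame(criterion = "C", factor = "F",
                                          beta = 0.6), noise_sd = 0.8,
                          seed = 3, orientation = c(C = FALSE))
  expect_equal(cor(lat[, 1], cr$scores[, 1]), 0.6, tolerance = 0.02 / 0.6)
  # higher-is-worse orientation flips the sign
  crr <- simulate_criteria(lat, data.frame(criterion = "PSS-4", factor = "F",
                                           beta = 0.6), noise_sd = 0.8, seed = 3)
  expect_lt(cor(lat[, 1], crr$scores[, 1]), 0)
  expect_error(simulate_criteria(lat, data.frame(criterion = "C",
                                                 factor = "nope", beta = 1)),
               "unknown factor")
})

test_that("retest stability controls the intraclass correlation", {
  spec <- wone_phase2_spec()
  w <- setNames(rep(10, 10), spec$factors$id)
  # perfect stability + zero uniqueness noise: waves identical
  s0 <- simulate_responses(spec, sim_config(300, seed = 6))
  rt0 <- simulate_retest(s0, 1, seed = 7, error_scale = 0)
  sc1 <- score_index(rt0$wave1, spec, w)
  sc2 <- score_index(rt0$wave2, spec, w)
  # wave-2 latents equal wave-1 latents, so error-free scale scores agree up
  # to the wave-1 uniqueness noise; compare latent-driven parts directly
  expect_equal(rt0$factor_scores_wave2, s0$factor_scores, tolerance = 1e-12)
  expect_gt(icc(sc1$index, sc2$index, "ICC(3,1)")$icc, 0.85)
  # zero stability: ICC confidence interval covers 0
  s <- simulate_responses(spec, sim_config(5000, seed = 8))
  rt <- simulate_retest(s, 0, seed = 9)
  z1 <- score_index(rt$wave1, spec, w)
  z2 <- score_index(rt$wave2, spec, w)
  ic0 <- icc(z1$index, z2$index, "ICC(3,1)")
  expect_lt(abs(ic0$icc), 0.05)
  expect_lt(ic0$ci[1], ic0$icc)
  expect_gt(ic0$ci[2], ic0$icc)
  # s = 0.9: ICC(3,1) matches the construction-implied value within its CI
  rt9 <- simulate_retest(s, 0.9, seed = 10)
  a <- score_index(rt9$wave1, spec, w)
  b <- score_index(rt9$wave2, spec, w)
  obs <- icc(a$index, b$index, "ICC(3,1)")
  imp <- implied_moments(spec)
  it <- spec$items
  wv <- vapply(seq_len(nrow(it)), function(i) {
    k <- sum(it$factor == it$factor[i])
    0.1 / k * if (it$domain[i] == "stress") -1 else 1
  }, 0)
  implied_icc <- as.numeric(0.9 * t(wv) %*% (imp$sigma - imp$theta) %*% wv /
                              (t(wv) %*% imp$sigma %*% wv))
  expect_gt(implied_icc, obs$ci[1])
  expect_lt(implied_icc, obs$ci[2])
  expect_error(simulate_retest(s, 1.2), "\\[0, 1\\]")
})

test_that("group generation injects the configured non-invariance", {
  spec <- wone_phase2_spec("stress")
  cfg <- sim_config(4000, seed = 11)
  # identical populations: pooled and per-group covariances agree
  g0 <- simulate_groups(spec, cfg, groups = c("g1", "g2"))
  S1 <- cov(g0$responses[g0$group == "g1", ])
  S2 <- cov(g0$responses[g0$group == "g2", ])
  expect_lt(max(abs(S1 - S2)), 0.08)
  # intercept shift: group mean difference tracks the injected delta
  pert <- data.frame(group = "g2", item = c("cynicism", "anxious_work"),
                     intercept_delta = 0.8)
  g1 <- simulate_groups(spec, cfg, groups = c("g1", "g2"),
                        perturbations = pert)
  d <- colMeans(g1$responses[g1$group == "g2", c("cynicism", "anxious_work")]) -
    colMeans(g1$responses[g1$group == "g1", c("cynicism", "anxious_work")])
  expect_equal(unname(d), c(0.8, 0.8), tolerance = 0.1)
  # loading drop: item-factor correlation falls to its construction value
  pert2 <- data.frame(group = "g2", item = "cynicism", loading_delta = -0.3)
  g2 <- simulate_groups(spec, cfg, groups = c("g1", "g2"),
                        perturbations = pert2)
  lam <- spec$items$loading[spec$items$id == "cynicism"]
  lam2 <- lam - 0.3
  implied_r <- lam2 / sqrt(lam2^2 + 1 - lam^2)
  obs_r <- cor(g2$responses[g2$group == "g2", "cynicism"],
               g2$factor_scores[g2$group == "g2", "Burnout"])
  expect_equal(obs_r, implied_r, tolerance = 0.05)
  expect_error(simulate_groups(spec, cfg, groups = "only_one"), "2 groups")
  expect_warning(simulate_groups(spec, sim_config(8, seed = 1),
                                 groups = c("a", "b")),
                 "under-identified")
})

test_that("response CSV io preserves the matrix with wave and group labels", {
  spec <- two_factor_spec()
  s <- simulate_responses(spec, sim_config(50, seed = 3, mode = "ordinal"))
  path <- tempfile(fileext = ".csv")
  write_responses(s$responses, path, wave = rep(1L, 50),
                  group = rep(c("a", "b"), 25))
  back <- read_responses(path)
  expect_equal(unname(back$responses), unname(s$responses))
  expect_equal(colnames(back$responses), colnames(s$responses))
  expect_equal(back$group, rep(c("a", "b"), 25))
})
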