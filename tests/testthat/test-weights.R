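test_that("empirical weights recover known regression structure", {
  set.seed(71)
  n <- 2000
  # two exactly orthogonal factor-score columns
  Z <- matrix(rnorm(n * 2), ncol = 2)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z)))
  colnames(Z) <- c("f1", "f2")
  # a single factor perfectly predicting one criterion
  crit1 <- list(scores = cbind(C = Z[, 1]), orientation = c(C = FALSE))
  w1 <- empirical_weights(Z, crit1, priorities = c(C = 100))
  expect_equal(as.numeric(w1), c(100, 0), tolerance = 1e-8)
  # betas 0.6 / 0.3 on orthogonal predictors: weights 66.7% / 33.3%
  crit2 <- list(scores = matrix(Z %*% c(0.6, 0.3), ncol = 1,
                                dimnames = list(NULL, "C")),
                orientation = c(C = FALSE))
  w2 <- empirical_weights(Z, crit2, priorities = c(C = 100))
  expect_equal(as.numeric(w2), c(200 / 3, 100 / 3), tolerance = 1e-6)
  # reverse-oriented criterion contributes positively after sign flip
  crit3 <- list(scores = matrix(-(Z %*% c(0.5, 0)), ncol = 1,
                                dimnames = list(NULL, "PSS-4")),
                orientation = c(`PSS-4` = TRUE))
  w3 <- empirical_weights(Z, crit3, priorities = c(`PSS-4` = 100))
  expect_equal(as.numeric(w3), c(100, 0), tolerance = 1e-8)
  # collinear factor scores are named in the error
  Zc <- cbind(Z, f3 = Z[, 1])
  expect_error(empirical_weights(Zc, crit1, priorities = c(C = 100)),
               "collinear.*f1.*f3|collinear.*f3.*f1")
})

test_that("empirical weights recover the priority-blended betas at scale", {
  spec <- wone_phase2_spec()
  s <- simulate_responses(spec, sim_config(20000, seed = 73))
  w <- setNames(rep(10, 10), spec$factors$id)
  sc <- score_index(s$responses, spec, w)
  betas <- rbind(
    data.frame(criterion = "CD-RISC", factor = "EmotionRegulation", beta = 0.6),
    data.frame(criterion = "WHO-5", factor = "SocialConnection", beta = 0.5))
  cr <- simulate_criteria(s$factor_scores, betas, noise_sd = 0.6, seed = 74)
  emp <- empirical_weights(sc$factor_scores, cr,
                           priorities = c(`CD-RISC` = 70, `WHO-5` = 30))
  # the two generating constructs dominate, in priority-weighted order
  top2 <- names(sort(emp, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("EmotionRegulation", "SocialConnection"))
  expect_gt(emp[["EmotionRegulation"]], emp[["SocialConnection"]])
  expect_equal(sum(emp), 100, tolerance = 1e-9)
})

test_that("hybrid blend reproduces the published rows", {
  expect_equal(hybrid_weights(c(x = 44.6), c(x = 20.0)), c(x = 32.3))
  expect_equal(hybrid_weights(c(x = 7.8), c(x = 18.0)), c(x = 12.9))
  v <- c(a = 30, b = 70)
  expect_equal(hybrid_weights(v, v), v)
  expect_error(hybrid_weights(c(a = 50, b = 50), c(a = 50, c = 50)),
               "same constructs")
  # linear and order preserving
  e1 <- c(a = 10, b = 40, c = 50); t1 <- c(a = 20, b = 30, c = 50)
  h <- hybrid_weights(e1, t1)
  expect_equal(unname(h), unname(0.5 * e1 + 0.5 * t1))
})

test_that("the weight floor elevates and renormalizes exactly", {
  pw <- wone_published_weights()
  ct <- pw$constructs
  hy <- setNames(ct$hybrid_printed, ct$construct)
  fl <- apply_floor(hy, 5)
  # the published below-floor constructs land exactly on the floor
  expect_equal(unname(fl$final["PhysicalActivity"]), 5)
  expect_equal(unname(fl$final["WorkStress"]), 5)
  expect_setequal(fl$floored, c("PhysicalActivity", "WorkStress",
                                "PurposeProsociality"))
  # the full display column reproduces the published final weights
  expect_equal(unname(fl$display[ct$construct]), ct$final_printed)
  expect_equal(sum(fl$final), 100, tolerance = 1e-9)
  expect_equal(sum(fl$display), 100L)
  # ranking of above-floor constructs is preserved
  above <- setdiff(ct$construct, fl$floored)
  expect_equal(order(hy[above]), order(fl$final[above]))
  # no-op when everything clears the floor
  ok <- c(a = 40, b = 35, c = 25)
  expect_equal(apply_floor(ok, 5)$final, ok)
  # proportional-removal arithmetic
  fl3 <- apply_floor(c(60, 37, 3), 5)
  expect_equal(unname(fl3$final), c(60 * 95 / 97, 37 * 95 / 97, 5),
               tolerance = 1e-10)
  expect_error(apply_floor(rep(4, 30), 5), "infeasible")
  expect_error(apply_floor(c(50, -1, 51), 5), ">= 0")
})

test_that("largest-remainder display integers always sum to the total", {
  set.seed(75)
  for (i in 1:20) {
    w <- runif(10); w <- 100 * w / sum(w)
    d <- largest_remainder(w)
    expect_equal(sum(d), 100L)
    expect_true(all(abs(d - w) < 1))
  }
})

test_that("weight_table chains blend, floor and display", {
  pw <- wone_published_weights()
  ct <- pw$constructs
  wt <- weight_table(setNames(ct$empirical, ct$construct),
                     setNames(ct$theoretical, ct$construct), floor = 5)
  # hybrid column matches the printed one where rounding is unambiguous
  hy <- setNames(wt$hybrid, wt$construct)
  expect_equal(unname(hy["EmotionRegulation"]), 32.3)
  expect_equal(unname(hy["SocialConnection"]), 12.9)
  expect_equal(unname(hy["WorkStress"]), 4.0)
  expect_equal(unname(hy["DietaryIntake"]), 5.6)
  expect_equal(sum(wt$final), 100, tolerance = 1e-9)
  expect_equal(sum(wt$display), 100L)
})
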