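test_that("KMO matches its anti-image definition", {
  # any 2-variable matrix: partial correlation equals the zero-order one
  expect_equal(kmo(matrix(c(1, 0.4, 0.4, 1), 2))$overall, 0.5)
  expect_equal(kmo(matrix(c(1, -0.8, -0.8, 1), 2))$overall, 0.5)
  # brute-force anti-image oracle on a random PSD matrix
  set.seed(14)
  L <- matrix(rnorm(25), 5)
  S <- tcrossprod(L) + diag(5)
  R <- cov2cor(S)
  inv <- solve(R)
  q <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    if (i != j) q[i, j] <- -inv[i, j] / sqrt(inv[i, i] * inv[j, j])
  r_off <- R; diag(r_off) <- 0
  oracle <- sum(r_off^2) / (sum(r_off^2) + sum(q^2))
  got <- kmo(R)
  expect_equal(got$overall, oracle, tolerance = 1e-12)
  for (i in 1:5)
    expect_equal(unname(got$msa[i]),
                 sum(r_off[i, ]^2) / (sum(r_off[i, ]^2) + sum(q[i, ]^2)),
                 tolerance = 1e-12)
  # near-singular matrix is rejected with ridge advice
  Rbad <- matrix(1 - 1e-13, 3, 3); diag(Rbad) <- 1   # condition > 1e12
  expect_error(kmo(Rbad), "ridge")
})

test_that("Bartlett sphericity follows the chi-square closed form", {
  expect_equal(bartlett_sphericity(diag(4), 100)$chisq, 0)
  expect_equal(bartlett_sphericity(diag(4), 100)$p.value, 1)
  # 11 stress items give the printed df = 55 subscript
  R11 <- diag(11) * 0.5 + 0.5
  expect_equal(bartlett_sphericity(R11, 306)$df, 55)
  b <- bartlett_sphericity(matrix(c(1, 0.5, 0.5, 1), 2), 100)
  expect_equal(b$chisq, -(100 - 1 - 9 / 6) * log(0.75), tolerance = 1e-12)
  expect_error(bartlett_sphericity(diag(4), 3), "exceed")
})

test_that("principal axis factoring recovers population structure", {
  R <- tcrossprod(rep(0.8, 5)); diag(R) <- 1
  pf <- paf(R, 1)
  expect_equal(unname(pf$loadings[, 1]), rep(0.8, 5), tolerance = 1e-4)
  expect_equal(unname(pf$communalities), rep(0.64, 5), tolerance = 1e-3)
  expect_error(paf(R, 0), "1 <= k < p")
  expect_error(paf(R, 5), "1 <= k < p")
})

test_that("PAF agrees with an independent iteration on sample data", {
  spec <- two_factor_spec()
  s <- simulate_responses(spec, sim_config(600, seed = 15))
  R <- cor(s$responses)
  pf <- paf(R, 2, tol = 1e-8, max_iter = 2000)
  # independently re-written iterated-communality loop
  h2 <- 1 - 1 / diag(solve(R))
  for (i in 1:2000) {
    Rr <- R; diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    L <- e$vectors[, 1:2] %*% diag(sqrt(pmax(e$values[1:2], 0)))
    h2_new <- pmin(rowSums(L^2), 1)
    if (max(abs(h2_new - h2)) < 1e-8) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  expect_equal(unname(pf$communalities), unname(h2), tolerance = 1e-6)
  expect_equal(abs(unname(pf$loadings)), abs(L), tolerance = 1e-5)
})

test_that("promax handles degenerate and simple-structure inputs", {
  L1 <- matrix(c(0.8, 0.7, 0.6), dimnames = list(NULL, "F1"))
  pr1 <- promax_rotation(L1)
  expect_equal(pr1$pattern, L1)
  expect_equal(pr1$phi, matrix(1, 1, 1))
  # orthogonal perfect simple structure: pattern preserved, phi near identity
  L0 <- matrix(0, 6, 2)
  L0[1:3, 1] <- c(0.8, 0.7, 0.75); L0[4:6, 2] <- c(0.72, 0.68, 0.77)
  pr0 <- promax_rotation(L0, 4)
  # align columns by where each item's primary loading lands
  perm <- apply(abs(pr0$pattern), 1, which.max)
  expect_equal(unname(perm[1:3]), rep(perm[[1]], 3))
  expect_equal(unname(perm[4:6]), rep(perm[[4]], 3))
  expect_true(perm[[1]] != perm[[4]])
  aligned <- abs(pr0$pattern[, c(perm[[1]], perm[[4]])])
  expect_equal(unname(aligned), unname(L0), tolerance = 0.02)
  expect_lt(abs(pr0$phi[1, 2]), 0.05)
  expect_error(promax_rotation(L0, 0.5), "kappa")
})

test_that("promax recovers an oblique population factor correlation", {
  spec <- two_factor_spec(fcorr = 0.5)
  Rpop <- implied_moments(spec)$sigma
  pr <- promax_rotation(paf(Rpop, 2)$loadings, 4)
  expect_equal(pr$phi[1, 2], 0.5, tolerance = 0.05 / 0.5)
  expect_equal(pr$structure, pr$pattern %*% pr$phi)
  # dual route: sample-data rotation matches stats::promax
  s <- simulate_responses(spec, sim_config(3000, seed = 9))
  L <- paf(cor(s$responses), 2)$loadings
  ours <- promax_rotation(L, 4)
  ref <- stats::promax(L, m = 4)
  expect_equal(max(abs(abs(ours$pattern) - abs(unclass(ref$loadings)))), 0,
               tolerance = 1e-8)
  ui <- solve(ref$rotmat)
  expect_equal(abs(ours$phi[1, 2]), abs((ui %*% t(ui))[1, 2]), tolerance = 1e-8)
})

test_that("promax approaches varimax as kappa decreases to 1", {
  spec <- two_factor_spec(fcorr = 0.4)
  s <- simulate_responses(spec, sim_config(2000, seed = 17))
  L <- paf(cor(s$responses), 2)$loadings
  d <- vapply(c(4, 3, 2, 1), function(kap) {
    pr <- promax_rotation(L, kap)
    sqrt(mean((pr$pattern - pr$varimax)^2))
  }, 0)
  expect_true(all(diff(d) <= 1e-10))
  expect_equal(d[4], 0, tolerance = 1e-10)
})

test_that("retention rules fire in a fixed order with one reason per item", {
  pattern <- rbind(
    weak =    c(0.38, 0.05),   # fails phase-1 primary rule
    crosser = c(0.55, 0.45),   # fails phase-1 cross-loading rule
    lowcom =  c(0.45, 0.00),   # communality forced below 0.30
    keeper =  c(0.90, 0.00))
  phi <- diag(2)
  h2 <- c(0.40, 0.60, 0.20, 0.81)
  rep1 <- retain_items(pattern, phi, retention_rules("phase1"),
                       communalities = h2)
  expect_equal(rep1$kept, c(FALSE, FALSE, FALSE, TRUE))
  expect_match(rep1$rule[1], "primary >= 0.40")
  expect_match(rep1$rule[2], "cross-loading < 0.30")
  expect_match(rep1$rule[3], "communality >= 0.30")   # communality checked first
  # phase-2 rules keep a 0.35 primary loading
  rep2 <- retain_items(rbind(mid = c(0.35, 0.05)), phi,
                       retention_rules("phase2"),
                       communalities = 0.35)
  expect_true(rep2$kept)
  # clear keeper survives both rule sets
  rep3 <- retain_items(rbind(keeper = c(0.90, 0)), phi,
                       retention_rules("phase2"), communalities = 0.81)
  expect_true(rep3$kept)
  # every input item appears exactly once
  expect_equal(nrow(rep1), 4)
})

test_that("full EFA recovers the packaged resilience factor-item assignment", {
  rspec <- wone_phase2_spec("resilience")
  s <- simulate_responses(rspec, sim_config(4000, seed = 13))
  ef <- run_efa(s$responses, k = 7, rules = retention_rules("phase2"))
  ret <- ef$retention
  truth <- rspec$items$factor[match(ret$item, rspec$items$id)]
  tab <- table(ret$factor, truth)
  # each true factor maps to exactly one recovered factor (structure, not
  # loading values)
  expect_true(all(colSums(tab > 0) == 1))
  expect_gt(ef$kmo$overall, 0.8)
  expect_equal(ef$bartlett$df, 32 * 31 / 2)
  expect_gt(ef$paf$var_explained, 0.4)
  # explained-variance fraction consistent with retained eigenvalues
  expect_equal(ef$paf$var_explained,
               sum(pmax(ef$paf$eigenvalues[1:7], 0)) / 32)
})
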