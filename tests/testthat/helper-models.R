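# toy model builders shared across test files

one_factor_spec <- function(loadings = c(0.8, 0.7, 0.6, 0.75, 0.65),
                            ids = paste0("y", seq_along(loadings))) {
  measurement_model(
    items = data.frame(id = ids, factor = "F1", loading = loadings),
    factors = data.frame(id = "F1", parent = "ResilienceResources",
                         gamma = 0.7))
}

# two first-order factors under one parent; factor correlation = gamma^2
two_factor_spec <- function(l1 = c(0.7, 0.65, 0.75, 0.6),
                            l2 = c(0.7, 0.68, 0.72, 0.66),
                            fcorr = 0.5) {
  g <- sqrt(fcorr)
  measurement_model(
    items = data.frame(id = paste0("x", seq_len(length(l1) + length(l2))),
                       factor = rep(c("A", "B"), c(length(l1), length(l2))),
                       loading = c(l1, l2)),
    factors = data.frame(id = c("A", "B"), parent = "ResilienceResources",
                         gamma = c(g, g)))
}

# cross-domain two-factor model (one stress, one resilience factor)
cross_domain_spec <- function(l1 = c(0.7, 0.6, 0.8), l2 = c(0.5, 0.7, 0.6, 0.75),
                              g = c(0.8, 0.6), rho = -0.5) {
  measurement_model(
    items = data.frame(id = paste0("z", seq_len(length(l1) + length(l2))),
                       factor = rep(c("S", "R"), c(length(l1), length(l2))),
                       loading = c(l1, l2)),
    factors = data.frame(id = c("S", "R"),
                         parent = c("StressLoad", "ResilienceResources"),
                         gamma = g),
    cross_domain_corr = rho)
}

# data matrix whose sample covariance equals `S` exactly (whitening trick)
exact_cov_sample <- function(n, S, seed = 1) {
  set.seed(seed)
  p <- ncol(S)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(stats::cov(Z)))
  X <- Z %*% chol(S)
  colnames(X) <- colnames(S)
  X
}

table1_loadings <- list(
  SocialConnection = c(0.89, 0.87, 0.87, 0.85, 0.83),
  PerseverativeThinking = c(0.91, 0.88),
  PhysicalActivity = c(0.99, 0.63),
  EmotionRegulation = c(0.74, 0.61, 0.70, 0.50, 0.76, 0.73, 0.83, 0.68, 0.66),
  WorkStress = c(0.90, 0.76, 0.83, 0.79))

table1_r2 <- list(
  PerseverativeThinking = c(0.82, 0.78),
  PhysicalActivity = c(1.00, 0.40),
  SocialConnection = c(0.79, 0.76, 0.76, 0.72, 0.69))
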