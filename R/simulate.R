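#' Simulation configuration
#'
#' @param n respondent count (>= 1).
#' @param seed integer RNG seed.
#' @param mode `"continuous"` (latent-response scale, unit item variances) or
#'   `"ordinal"` (responses thresholded into integer categories 1-5).
#' @param thresholds strictly increasing cut points mapping latent responses
#'   to categories; defaults to standard-normal quantiles -1.5, -0.5, 0.5,
#'   1.5, a symmetric five-category split.
#' @param retest_stability latent autocorrelation in \[0, 1\] used by
#'   [simulate_retest()].
#' @return a `wone_sim_config` list.
#' @export
sim_config <- function(n, seed = 1L, mode = c("continuous", "ordinal"),
                       thresholds = c(-1.5, -0.5, 0.5, 1.5),
                       retest_stability = 0.9) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be >= 1")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (retest_stability < 0 || retest_stability > 1)
    stop("retest_stability must lie in [0, 1]")
  structure(list(n = as.integer(n), seed = as.integer(seed), mode = mode,
                 thresholds = thresholds, retest_stability = retest_stability),
            class = "wone_sim_config")
}

# lower-triangular factor of a PSD matrix, tolerant of zero eigenvalues
.psd_chol <- function(m, label = "covariance") {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("matrix is not positive semidefinite (", label, ")")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m))
}

.threshold_items <- function(x, thresholds) {
  k <- length(thresholds) + 1L
  out <- matrix(findInterval(x, thresholds) + 1L, nrow(x), ncol(x),
                dimnames = dimnames(x))
  storage.mode(out) <- "integer"
  out
}

# draw latents and continuous item responses for given innovations-free state;
# returns list(responses, factor_scores, domain_scores, errors)
.draw_latents <- function(spec, n) {
  fa <- spec$factors; it <- spec$items
  phi <- matrix(c(1, spec$cross_domain_corr, spec$cross_domain_corr, 1), 2, 2)
  eta2 <- matrix(stats::rnorm(n * 2), n, 2) %*% t(.psd_chol(phi, "cross-domain"))
  colnames(eta2) <- c("StressLoad", "ResilienceResources")
  dist <- matrix(stats::rnorm(n * nrow(fa)), n, nrow(fa))
  f <- eta2[, match(fa$parent, colnames(eta2)), drop = FALSE] %*%
    diag(fa$gamma, nrow(fa)) +
    dist %*% diag(sqrt(1 - fa$gamma^2), nrow(fa))
  colnames(f) <- fa$id
  list(second_order = eta2, factors = f)
}

.draw_errors <- function(spec, n) {
  it <- spec$items
  p <- nrow(it)
  theta <- diag(1 - it$loading^2, p)
  rc <- spec$residual_covariances
  if (nrow(rc) > 0) {
    i <- match(rc$item1, it$id); j <- match(rc$item2, it$id)
    theta[cbind(i, j)] <- theta[cbind(i, j)] + rc$theta
    theta[cbind(j, i)] <- theta[cbind(i, j)]
  }
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("model-implied covariance is not positive semidefinite ",
         "(residual/uniqueness block); offending residual covariances: ",
         paste(rc$item1, rc$item2, sep = "~", collapse = ", "))
  e <- matrix(stats::rnorm(n * p), n, p) %*% t(.psd_chol(theta, "residual block"))
  colnames(e) <- it$id
  e
}

.items_from_latents <- function(spec, f, e) {
  it <- spec$items
  y <- f[, match(it$factor, colnames(f)), drop = FALSE] %*%
    diag(it$loading, nrow(it)) + e
  colnames(y) <- it$id
  y
}

#' Generate an item-response sample from a measurement model
#'
#' Second-order factors are drawn standard normal with the configured
#' cross-domain correlation; first-order factors are
#' \eqn{\gamma \cdot} parent plus a disturbance scaled to unit variance;
#' each continuous item is \eqn{\lambda \cdot} factor plus uniqueness noise
#' scaled so the item variance is 1 (plus any specified residual
#' covariances). In ordinal mode the continuous responses are thresholded
#' into integer categories. Latent scores are returned alongside for
#' parameter-recovery testing.
#'
#' @param spec a [measurement_model()] specification.
#' @param cfg a [sim_config()].
#' @return list of class `wone_sample`: `responses` (n x p matrix, item ids as
#'   columns), `factor_scores` (n x q true first-order factor scores),
#'   `second_order` (n x 2), `mode`, `spec`.
#' @export
simulate_responses <- function(spec, cfg) {
  stopifnot(inherits(spec, "wone_model_spec"), inherits(cfg, "wone_sim_config"))
  set.seed(cfg$seed)
  lat <- .draw_latents(spec, cfg$n)
  e <- .draw_errors(spec, cfg$n)
  y <- .items_from_latents(spec, lat$factors, e)
  if (cfg$mode == "ordinal") y <- .threshold_items(y, cfg$thresholds)
  structure(list(responses = y, factor_scores = lat$factors,
                 second_order = lat$second_order, mode = cfg$mode,
                 thresholds = cfg$thresholds, spec = spec),
            class = "wone_sample")
}

#' Generate external criterion scales from latent factor scores
#'
#' Each criterion is a linear combination of true factor scores plus Gaussian
#' noise; criteria flagged higher-is-worse are sign-flipped so that, e.g.,
#' a perceived-stress analogue correlates negatively with resources.
#'
#' @param latents n x q matrix of factor scores (columns named by factor id).
#' @param betas data.frame with columns `criterion`, `factor`, `beta`.
#' @param noise_sd residual standard deviation (>= 0), recycled per criterion.
#' @param seed integer seed.
#' @param orientation named logical vector, `TRUE` = higher-is-worse; defaults
#'   to the published convention (PSS-4, PHQ-8, GAD-7 reversed).
#' @return list of class `wone_criteria`: `scores` (n x criteria matrix),
#'   `orientation`, `betas` (the true generating coefficients).
#' @export
simulate_criteria <- function(latents, betas, noise_sd = 1, seed = 1L,
                              orientation = NULL) {
  betas <- as.data.frame(betas, stringsAsFactors = FALSE)
  if (!all(c("criterion", "factor", "beta") %in% names(betas)))
    stop("`betas` must have columns criterion, factor, beta")
  unknown <- setdiff(betas$factor, colnames(latents))
  if (length(unknown) > 0)
    stop("unknown factor id in betas: ", paste(unknown, collapse = ", "))
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  crits <- unique(betas$criterion)
  if (is.null(orientation)) {
    orientation <- stats::setNames(crits %in% c("PSS-4", "PHQ-8", "GAD-7"), crits)
  }
  noise_sd <- rep_len(noise_sd, length(crits))
  set.seed(seed)
  n <- nrow(latents)
  out <- matrix(0, n, length(crits), dimnames = list(NULL, crits))
  for (k in seq_along(crits)) {
    b <- betas[betas$criterion == crits[k], , drop = FALSE]
    y <- latents[, b$factor, drop = FALSE] %*% b$beta +
      stats::rnorm(n, sd = noise_sd[k])
    if (isTRUE(orientation[[crits[k]]])) y <- -y
    out[, k] <- y
  }
  structure(list(scores = out, orientation = orientation, betas = betas),
            class = "wone_criteria")
}

#' Generate a two-wave retest sample
#'
#' Wave-2 first-order factor scores are `s` times the wave-1 scores plus
#' \eqn{\sqrt{1-s^2}} times an independent innovation with the same factor
#' covariance structure, so the latent autocorrelation is exactly `s`. Items
#' are regenerated from the wave-2 latents with fresh uniqueness noise.
#'
#' @param wave1 a `wone_sample` from [simulate_responses()].
#' @param stability latent autocorrelation `s` in \[0, 1\].
#' @param seed seed for the wave-2 innovations.
#' @param error_scale multiplier on the uniqueness noise (0 gives error-free
#'   items, useful for degenerate-case checks).
#' @return list of class `wone_retest` with `wave1`, `wave2` response
#'   matrices, `wave` labels and the wave-2 factor scores.
#' @export
simulate_retest <- function(wave1, stability, seed = 2L, error_scale = 1) {
  stopifnot(inherits(wave1, "wone_sample"))
  if (stability < 0 || stability > 1) stop("stability must lie in [0, 1]")
  spec <- wave1$spec
  n <- nrow(wave1$responses)
  set.seed(seed)
  innov <- .draw_latents(spec, n)$factors
  f2 <- stability * wave1$factor_scores + sqrt(1 - stability^2) * innov
  e2 <- .draw_errors(spec, n) * error_scale
  y2 <- .items_from_latents(spec, f2, e2)
  if (wave1$mode == "ordinal") y2 <- .threshold_items(y2, wave1$thresholds)
  structure(list(wave1 = wave1$responses, wave2 = y2,
                 wave = rep(c(1L, 2L), each = n),
                 factor_scores_wave2 = f2, spec = spec, mode = wave1$mode),
            class = "wone_retest")
}

#' Generate multi-group samples with injectable non-invariance
#'
#' Each group is generated from the base specification with optional
#' per-group loading deltas (added to the standardized loading before
#' rescaling of uniqueness noise is NOT applied, so a lowered loading lowers
#' the item-factor correlation) and intercept deltas (added to the item mean
#' on the latent-response scale).
#'
#' @param spec a `wone_model_spec`.
#' @param cfg a [sim_config()]; `cfg$n` is the per-group size (scalar or one
#'   per group).
#' @param groups character vector of group labels (>= 2).
#' @param perturbations optional data.frame with columns `group`, `item`,
#'   `loading_delta`, `intercept_delta` (either delta column may be omitted).
#' @return list of class `wone_groups`: `responses` (stacked matrix), `group`
#'   (label per row), `factor_scores`.
#' @export
simulate_groups <- function(spec, cfg, groups = c("g1", "g2"),
                            perturbations = NULL) {
  stopifnot(inherits(spec, "wone_model_spec"), inherits(cfg, "wone_sim_config"))
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (!is.null(perturbations)) {
    perturbations <- as.data.frame(perturbations, stringsAsFactors = FALSE)
    if (!all(perturbations$item %in% spec$items$id))
      stop("perturbations reference unknown items")
    if (!all(perturbations$group %in% groups))
      stop("perturbations reference unknown groups")
    if (is.null(perturbations$loading_delta)) perturbations$loading_delta <- 0
    if (is.null(perturbations$intercept_delta)) perturbations$intercept_delta <- 0
  }
  ns <- rep_len(cfg$n, length(groups))
  if (any(ns < nrow(spec$items)))
    warning("group n below the number of items; downstream models may be under-identified")
  set.seed(cfg$seed)
  res <- vector("list", length(groups))
  fs <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    lat <- .draw_latents(spec, ns[g])
    e <- .draw_errors(spec, ns[g])
    it <- spec$items
    load <- it$loading
    shift <- rep(0, nrow(it))
    if (!is.null(perturbations)) {
      pg <- perturbations[perturbations$group == groups[g], , drop = FALSE]
      idx <- match(pg$item, it$id)
      load[idx] <- load[idx] + pg$loading_delta
      shift[idx] <- shift[idx] + pg$intercept_delta
    }
    y <- lat$factors[, match(it$factor, colnames(lat$factors)), drop = FALSE] %*%
      diag(load, nrow(it)) + e
    y <- sweep(y, 2, shift, "+")
    colnames(y) <- it$id
    if (cfg$mode == "ordinal") y <- .threshold_items(y, cfg$thresholds)
    res[[g]] <- y
    fs[[g]] <- lat$factors
  }
  structure(list(responses = do.call(rbind, res),
                 group = rep(groups, times = ns),
                 factor_scores = do.call(rbind, fs), spec = spec,
                 mode = cfg$mode),
            class = "wone_groups")
}

#' Read / write wide item-response CSV
#'
#' Wide CSV with a header row of item ids and optional `wave` and `group`
#' columns (RFC 4180, UTF-8).
#'
#' @param path file path.
#' @return [read_responses()] returns a list with `responses` matrix and
#'   optional `wave` / `group` vectors.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wave <- df$wave; group <- df$group
  df$wave <- NULL; df$group <- NULL
  list(responses = as.matrix(df), wave = wave, group = group)
}

#' @rdname read_responses
#' @param responses numeric matrix with item-id column names.
#' @param wave,group optional per-row labels.
#' @export
write_responses <- function(responses, path, wave = NULL, group = NULL) {
  df <- as.data.frame(responses, check.names = FALSE)
  if (!is.null(wave)) df$wave <- wave
  if (!is.null(group)) df$group <- group
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
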