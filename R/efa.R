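#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Standard KMO from squared zero-order correlations versus squared
#' anti-image partial correlations: overall
#' \eqn{\sum r^2 / (\sum r^2 + \sum q^2)} over off-diagonal elements, where
#' \eqn{q_{ij} = -s_{ij}/\sqrt{s_{ii}s_{jj}}} and \eqn{S = R^{-1}}, plus the
#' analogous per-item measures.
#'
#' @param corr correlation matrix (symmetric, unit diagonal, invertible).
#' @return list with `overall` and per-item `msa` (named numeric).
#' @export
kmo <- function(corr) {
  .check_corr(corr)
  if (rcond(corr) < 1e-12)
    stop("correlation matrix is computationally singular; ",
         "apply a small ridge (e.g. corr + 1e-8 * diag) or drop redundant items")
  inv <- solve(corr)
  q <- -inv / sqrt(outer(diag(inv), diag(inv)))
  diag(q) <- 0
  r <- corr; diag(r) <- 0
  overall <- sum(r^2) / (sum(r^2) + sum(q^2))
  msa <- colSums(r^2) / (colSums(r^2) + colSums(q^2))
  names(msa) <- colnames(corr)
  list(overall = overall, msa = msa)
}

#' Bartlett test of sphericity
#'
#' \eqn{\chi^2 = -(n-1-(2p+5)/6)\,\ln|R|} on \eqn{p(p-1)/2} degrees of
#' freedom.
#'
#' @param corr correlation matrix.
#' @param n sample size (> number of variables).
#' @return list with `chisq`, `df`, `p.value`.
#' @export
bartlett_sphericity <- function(corr, n) {
  .check_corr(corr)
  p <- ncol(corr)
  if (n <= p) stop("n must exceed the number of variables")
  detR <- det(corr)
  if (detR <= 0) stop("correlation matrix has non-positive determinant")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df,
       p.value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

.check_corr <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("`corr` must be a square matrix")
  if (max(abs(corr - t(corr))) > 1e-8) stop("`corr` must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("`corr` must have unit diagonal")
  invisible(TRUE)
}

#' Principal axis factoring
#'
#' Iterated-communality PAF: communalities are seeded with squared multiple
#' correlations, the reduced correlation matrix (communalities on the
#' diagonal) is eigendecomposed, loadings are taken from the k leading
#' components, and communalities are updated until the largest change drops
#' below `tol`. Heywood communalities are capped at 1 and flagged.
#'
#' @param corr correlation matrix.
#' @param k number of factors, `1 <= k < p`.
#' @param max_iter,tol iteration controls.
#' @return list with `loadings` (p x k unrotated), `communalities`,
#'   `eigenvalues` (of the reduced matrix at convergence), `initial_eigen`
#'   (of the unreduced matrix, for the Kaiser criterion), `iterations`,
#'   `heywood` (logical per item), `var_explained` (fraction of total item
#'   variance).
#' @export
paf <- function(corr, k, max_iter = 500, tol = 1e-3) {
  .check_corr(corr)
  p <- ncol(corr)
  if (k < 1 || k >= p) stop("k must satisfy 1 <= k < p")
  inv <- solve(corr)
  h2 <- 1 - 1 / diag(inv)   # squared multiple correlations
  heywood <- rep(FALSE, p)
  L <- NULL; ev <- NULL; delta <- Inf
  for (iter in seq_len(max_iter)) {
    red <- corr
    diag(red) <- h2
    e <- eigen(red, symmetric = TRUE)
    ev <- e$values
    d <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(d), k)
    new_h2 <- rowSums(L^2)
    hit <- new_h2 > 1
    heywood <- heywood | hit
    new_h2[hit] <- 1
    delta <- max(abs(new_h2 - h2))
    h2 <- new_h2
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("principal axis factoring did not converge in ", max_iter,
         " iterations; last max communality change ", format(delta))
  # sign convention: largest-magnitude loading in each column positive
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(corr)
  colnames(L) <- paste0("F", seq_len(k))
  list(loadings = L, communalities = stats::setNames(h2, colnames(corr)),
       eigenvalues = ev, initial_eigen = eigen(corr, symmetric = TRUE,
                                               only.values = TRUE)$values,
       iterations = iter, heywood = stats::setNames(heywood, colnames(corr)),
       var_explained = sum(pmax(ev[seq_len(k)], 0)) / p)
}

#' Promax oblique rotation
#'
#' Varimax pre-rotation (Kaiser-normalized) followed by an element-wise
#' power-kappa target and an oblique Procrustes (least squares) solution.
#' Returns the pattern matrix, the factor correlation matrix Phi, and the
#' structure matrix (pattern times Phi). With a single factor the input is
#' passed through unchanged.
#'
#' @param loadings unrotated loading matrix (p x k).
#' @param kappa Promax power, >= 1 (conventional default 4).
#' @return list with `pattern`, `structure`, `phi`, `varimax` (the
#'   pre-rotated loadings).
#' @export
promax_rotation <- function(loadings, kappa = 4) {
  if (kappa < 1) stop("kappa must be >= 1")
  k <- ncol(loadings)
  if (k == 1) {
    return(list(pattern = loadings, structure = loadings,
                phi = matrix(1, 1, 1), varimax = loadings))
  }
  A <- .varimax_multistart(loadings)
  # sign convention: column sums positive, so factor correlations keep the
  # orientation of the (predominantly positive) loadings
  sgn <- ifelse(colSums(A) < 0, -1, 1)
  A <- A %*% diag(sgn, k)
  dimnames(A) <- dimnames(loadings)
  # element-wise power target, signs preserved
  Q <- abs(A)^kappa * sign(A)
  if (qr(A)$rank < k) stop("rank-deficient target; fewer effective factors than k")
  U <- solve(crossprod(A), crossprod(A, Q))     # oblique Procrustes transform
  d <- diag(solve(crossprod(U)))
  U <- U %*% diag(sqrt(d), k)                   # unit-variance factor scaling
  pattern <- A %*% U
  phi <- solve(crossprod(U))
  phi <- (phi + t(phi)) / 2
  dimnames(pattern) <- dimnames(loadings)
  dimnames(phi) <- list(colnames(loadings), colnames(loadings))
  list(pattern = pattern, structure = pattern %*% phi, phi = phi, varimax = A)
}

# Varimax from several deterministic starting rotations, keeping the best
# criterion value. A single start from the identity can stall on a symmetric
# saddle point (exactly balanced bipolar columns, as arise from population
# correlation matrices); perturbed starts break the symmetry.
.varimax_multistart <- function(loadings) {
  k <- ncol(loadings)
  crit <- function(A) {
    # Kaiser-normalized varimax criterion
    h <- sqrt(rowSums(A^2)); h[h == 0] <- 1
    Z <- (A / h)^2
    sum(apply(Z, 2, stats::var))
  }
  starts <- list(diag(k))
  set.seed_state <- .Random.seed_exists <- exists(".Random.seed", envir = globalenv())
  if (.Random.seed_exists) old_seed <- get(".Random.seed", envir = globalenv())
  set.seed(20240101)
  for (s in 1:3) starts[[s + 1]] <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  if (.Random.seed_exists) assign(".Random.seed", old_seed, envir = globalenv())
  best <- NULL; best_val <- -Inf
  for (R0 in starts) {
    A0 <- loadings %*% R0
    vm <- tryCatch(stats::varimax(A0, normalize = TRUE),
                   error = function(e) NULL)
    if (is.null(vm)) next
    A <- A0 %*% vm$rotmat
    v <- crit(A)
    if (v > best_val) { best_val <- v; best <- A }
  }
  if (is.null(best)) stop("varimax pre-rotation failed")
  dimnames(best) <- dimnames(loadings)
  best
}

#' Phase-specific item-retention rule sets
#'
#' The development-phase rules require a primary loading of at least 0.40,
#' cross-loadings below 0.30, a primary-secondary gap of at least 0.15 and a
#' communality of at least 0.30; the confirmation-phase rules relax the
#' primary-loading requirement to 0.30 and drop the gap and cross-loading
#' requirements.
#'
#' @param phase `"phase1"` or `"phase2"`.
#' @return a `wone_retention_rules` list with `min_primary`, `max_cross`,
#'   `min_gap`, `min_communality`, `phase`.
#' @export
retention_rules <- function(phase = c("phase1", "phase2")) {
  phase <- match.arg(phase)
  if (phase == "phase1") {
    r <- list(min_primary = 0.40, max_cross = 0.30, min_gap = 0.15,
              min_communality = 0.30, phase = phase)
  } else {
    r <- list(min_primary = 0.30, max_cross = NA_real_, min_gap = NA_real_,
              min_communality = 0.30, phase = phase)
  }
  structure(r, class = "wone_retention_rules")
}

#' Apply item-retention rules to a rotated pattern matrix
#'
#' Items are checked against each rule in a fixed order (communality, primary
#' loading, cross-loading, primary-secondary gap) and the first violated rule
#' is recorded, so a dropped item always reports one deterministic reason.
#' Assignment is to the factor with the largest absolute pattern loading
#' (ties broken toward the lower-index factor).
#'
#' @param pattern p x k pattern matrix.
#' @param phi k x k factor correlation matrix (used for communalities when
#'   `communalities` is not supplied).
#' @param rules a [retention_rules()] set.
#' @param communalities optional per-item communalities; defaults to the
#'   diagonal of `pattern %*% phi %*% t(pattern)`.
#' @return data.frame with one row per item: `item`, `kept`, `factor`,
#'   `primary`, `secondary`, `communality`, `rule` (the violated rule, or NA).
#' @export
retain_items <- function(pattern, phi, rules, communalities = NULL) {
  stopifnot(ncol(pattern) >= 1)
  if (is.null(communalities))
    communalities <- diag(pattern %*% phi %*% t(pattern))
  p <- nrow(pattern)
  res <- data.frame(item = rownames(pattern) %||% paste0("item", seq_len(p)),
                    kept = TRUE, factor = NA_character_,
                    primary = NA_real_, secondary = NA_real_,
                    communality = as.numeric(communalities),
                    rule = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(p)) {
    a <- abs(pattern[i, ])
    ord <- order(-a, seq_along(a))   # deterministic tie-break: lower index wins
    res$factor[i] <- colnames(pattern)[ord[1]] %||% paste0("F", ord[1])
    res$primary[i] <- a[ord[1]]
    res$secondary[i] <- if (length(a) > 1) a[ord[2]] else 0
    rule <- NA_character_
    if (res$communality[i] < rules$min_communality) {
      rule <- sprintf("communality >= %.2f", rules$min_communality)
    } else if (res$primary[i] < rules$min_primary) {
      rule <- sprintf("primary >= %.2f", rules$min_primary)
    } else if (!is.na(rules$max_cross) && res$secondary[i] >= rules$max_cross) {
      rule <- sprintf("cross-loading < %.2f", rules$max_cross)
    } else if (!is.na(rules$min_gap) &&
               res$primary[i] - res$secondary[i] < rules$min_gap) {
      rule <- sprintf("primary-secondary gap >= %.2f", rules$min_gap)
    }
    if (!is.na(rule)) {
      res$kept[i] <- FALSE
      res$rule[i] <- rule
    }
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full exploratory factor analysis
#'
#' Convenience wrapper: suitability diagnostics (KMO, Bartlett), principal
#' axis factoring, Promax rotation, and rule-based item retention.
#'
#' @param data n x p response matrix (or a correlation matrix with `n`
#'   supplied and `is_corr = TRUE`).
#' @param k number of factors.
#' @param kappa Promax power.
#' @param rules a [retention_rules()] set.
#' @param n sample size (required when `is_corr = TRUE`).
#' @param is_corr whether `data` is already a correlation matrix.
#' @return list of class `wone_efa`: `kmo`, `bartlett`, `paf`, `rotation`,
#'   `retention`, `k`, `n`.
#' @export
run_efa <- function(data, k, kappa = 4, rules = retention_rules("phase1"),
                    n = NULL, is_corr = FALSE) {
  if (is_corr) {
    corr <- data
    if (is.null(n)) stop("supply n when passing a correlation matrix")
  } else {
    corr <- stats::cor(data)
    n <- nrow(data)
  }
  km <- kmo(corr)
  bt <- bartlett_sphericity(corr, n)
  pf <- paf(corr, k)
  rot <- promax_rotation(pf$loadings, kappa)
  ret <- retain_items(rot$pattern, rot$phi, rules,
                      communalities = pf$communalities)
  structure(list(kmo = km, bartlett = bt, paf = pf, rotation = rot,
                 retention = ret, k = k, n = n),
            class = "wone_efa")
}
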