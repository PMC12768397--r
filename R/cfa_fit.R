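# ---- internal: sample moments ------------------------------------------------

# normalize data/cov input into per-group sample statistics
.sample_stats <- function(model, data = NULL, group = NULL,
                          sample_cov = NULL, sample_mean = NULL, n = NULL) {
  p <- model$p
  item_ids <- model$vars[seq_len(p)]
  if (!is.null(data)) {
    data <- as.matrix(data)
    if (!all(item_ids %in% colnames(data)))
      stop("data is missing items: ",
           paste(setdiff(item_ids, colnames(data)), collapse = ", "))
    data <- data[, item_ids, drop = FALSE]
    if (model$ngroups > 1) {
      if (is.null(group)) stop("multigroup model needs a `group` vector")
      glev <- sort(unique(group))
      if (length(glev) != model$ngroups)
        stop("expected ", model$ngroups, " groups, found ", length(glev))
      S <- lapply(glev, function(g) stats::cov(data[group == g, , drop = FALSE]))
      xb <- lapply(glev, function(g) colMeans(data[group == g, , drop = FALSE]))
      ns <- as.numeric(table(factor(group, levels = glev)))
    } else {
      S <- list(stats::cov(data)); xb <- list(colMeans(data)); ns <- nrow(data)
      glev <- "all"
    }
  } else {
    if (is.null(sample_cov) || is.null(n))
      stop("supply either `data` or `sample_cov` + `n`")
    S <- if (is.list(sample_cov)) sample_cov else list(sample_cov)
    S <- lapply(S, function(s) s[item_ids, item_ids, drop = FALSE])
    ns <- n
    xb <- if (is.null(sample_mean)) lapply(S, function(s) rep(0, p))
          else if (is.list(sample_mean)) sample_mean else list(sample_mean)
    glev <- if (length(S) > 1) paste0("g", seq_along(S)) else "all"
  }
  if (length(S) != model$ngroups) stop("group count mismatch")
  logdetS <- vapply(S, function(s) determinant(s)$modulus[1], 0)
  N <- sum(ns); G <- length(S)
  list(S = S, xbar = xb, n = ns, N = N, G = G, w = (ns - 1) / (N - G),
       logdetS = logdetS, levels = glev)
}

# ---- internal: objective and gradient ---------------------------------------

.fml <- function(model, theta, st) {
  p <- model$p
  total <- 0
  for (g in seq_len(model$ngroups)) {
    mats <- .group_matrices(model, theta, g)
    imp <- .implied_group(model, mats)
    ch <- tryCatch(chol(imp$sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    W <- chol2inv(ch)
    ld <- 2 * sum(log(diag(ch)))
    Fg <- ld + sum(W * st$S[[g]]) - st$logdetS[g] - p
    if (model$meanstructure) {
      r <- st$xbar[[g]] - imp$mu
      Fg <- Fg + as.numeric(t(r) %*% W %*% r)
    }
    if (!is.finite(Fg)) return(1e10)
    total <- total + st$w[g] * Fg
  }
  total
}

.fml_grad <- function(model, theta, st) {
  grad <- numeric(length(model$theta_labels))
  p <- model$p
  for (g in seq_len(model$ngroups)) {
    mats <- .group_matrices(model, theta, g)
    imp <- .implied_group(model, mats)
    ch <- tryCatch(chol(imp$sigma), error = function(e) NULL)
    if (is.null(ch)) return(grad)   # objective is at penalty plateau
    W <- chol2inv(ch)
    meanstr <- model$meanstructure
    r <- if (meanstr) st$xbar[[g]] - imp$mu else NULL
    E <- imp$sigma - st$S[[g]]
    if (meanstr) E <- E - tcrossprod(r)
    D <- W %*% E %*% W
    FB <- imp$FB
    Gm <- crossprod(FB, D %*% FB)          # m x m, for S-parameters
    V <- imp$V
    QA <- V[, seq_len(p), drop = FALSE] %*% D %*% FB   # (V F' D F B), for A-parameters
    if (meanstr) {
      u <- as.numeric(crossprod(FB, W %*% r))
      bm <- as.numeric(solve(diag(length(model$vars)) - mats$A, mats$M))
    }
    pr <- model$params[model$params$group == g & model$params$free, ]
    for (i in seq_len(nrow(pr))) {
      k <- pr$ri[i]; l <- pr$ci[i]
      gval <- switch(pr$matrix[i],
        S = if (k == l) Gm[k, k] else 2 * Gm[k, l],
        A = {
          v <- 2 * QA[l, k]
          if (meanstr) v <- v - 2 * bm[l] * u[k]
          v
        },
        M = -2 * u[k])
      if (pr$vartype[i] == "logvar")
        gval <- gval * exp(theta[pr$theta[i]])   # chain rule d/d(log v)
      grad[pr$theta[i]] <- grad[pr$theta[i]] + st$w[g] * gval
    }
  }
  grad
}

# ---- internal: expected information / derivative matrices --------------------

# per-group derivative of sigma (p x p) and mu (p) for a parameter row
.param_derivs <- function(model, mats, imp, pr_row, theta) {
  p <- model$p
  FB <- imp$FB; V <- imp$V
  k <- pr_row$ri; l <- pr_row$ci
  scale <- if (pr_row$vartype == "logvar") exp(theta[pr_row$theta]) else 1
  if (pr_row$matrix == "S") {
    dS <- if (k == l) tcrossprod(FB[, k]) else
      tcrossprod(FB[, k], FB[, l]) + tcrossprod(FB[, l], FB[, k])
    list(dsigma = scale * dS, dmu = rep(0, p))
  } else if (pr_row$matrix == "A") {
    w_l <- V[l, seq_len(p)]
    dS <- tcrossprod(FB[, k], w_l) + tcrossprod(w_l, FB[, k])
    bm <- as.numeric(solve(diag(length(model$vars)) - mats$A, mats$M))
    list(dsigma = dS, dmu = FB[, k] * bm[l])
  } else {
    list(dsigma = matrix(0, p, p), dmu = FB[, k])
  }
}

# expected information (per unit of N - G, on the F_ML scale) and score for
# the free parameters, optionally augmented with candidate rows
.info_score <- function(model, theta, st, candidates = NULL) {
  nfree <- length(model$theta_labels)
  ncand <- if (is.null(candidates)) 0L else nrow(candidates)
  ntot <- nfree + ncand
  A_info <- matrix(0, ntot, ntot)
  score <- numeric(ntot)
  p <- model$p
  for (g in seq_len(model$ngroups)) {
    mats <- .group_matrices(model, theta, g)
    imp <- .implied_group(model, mats)
    W <- chol2inv(chol(imp$sigma))
    meanstr <- model$meanstructure
    r <- if (meanstr) st$xbar[[g]] - imp$mu else NULL
    E <- imp$sigma - st$S[[g]]
    if (meanstr) E <- E - tcrossprod(r)
    D <- W %*% E %*% W
    pr <- model$params[model$params$group == g & model$params$free, ]
    idx <- pr$theta
    if (ncand > 0) {
      cg <- candidates[candidates$group == g, , drop = FALSE]
      if (nrow(cg) > 0) {
        cg$theta <- nfree + match(
          paste(cg$matrix, cg$ri, cg$ci),
          paste(candidates$matrix, candidates$ri, candidates$ci))
        pr <- rbind(pr[, c("matrix", "ri", "ci", "vartype", "theta")],
                    cg[, c("matrix", "ri", "ci", "vartype", "theta")])
        idx <- pr$theta
      } else {
        pr <- pr[, c("matrix", "ri", "ci", "vartype", "theta")]
      }
    }
    nloc <- nrow(pr)
    X <- matrix(0, p * p, nloc)       # vec(dSigma_i)
    Y <- matrix(0, p * p, nloc)       # vec(W dSigma_i W)
    MU <- matrix(0, p, nloc)
    for (i in seq_len(nloc)) {
      d <- .param_derivs(model, mats, imp,
                         pr[i, c("matrix", "ri", "ci", "vartype", "theta")], theta)
      X[, i] <- as.numeric(d$dsigma)
      Y[, i] <- as.numeric(W %*% d$dsigma %*% W)
      MU[, i] <- d$dmu
    }
    sc_g <- as.numeric(crossprod(X, as.numeric(D)))
    if (meanstr) sc_g <- sc_g - 2 * as.numeric(crossprod(MU, W %*% r))
    # A_ij = tr(W dSi W dSj) + 2 dmu_i' W dmu_j
    blk <- crossprod(Y, X)
    if (meanstr) blk <- blk + 2 * crossprod(MU, W %*% MU)
    blk <- (blk + t(blk)) / 2
    if (anyDuplicated(idx))
      stop("internal error: duplicate parameter index within a group")
    score[idx] <- score[idx] + st$w[g] * sc_g
    A_info[idx, idx] <- A_info[idx, idx] + st$w[g] * blk
  }
  list(info = A_info, score = score, nfree = nfree)
}

# ---- public fitting ----------------------------------------------------------

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' \eqn{F_{ML} = \ln|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p}
#' (plus a mean term for mean-structured models; group-weighted for
#' multigroup models) by quasi-Newton iteration with analytic gradients.
#' Variances are optimized on the log scale; a fitted uniqueness collapsing
#' toward zero is reported as a Heywood flag rather than crossing zero.
#'
#' @param model a [cfa_model()].
#' @param data n x p response matrix with item ids as column names, or NULL
#'   if `sample_cov` is given.
#' @param group group label per row (multigroup models fitted from data).
#' @param sample_cov covariance matrix, or list of per-group matrices.
#' @param sample_mean optional mean vector(s) for mean-structured models.
#' @param n sample size(s) when fitting from `sample_cov`.
#' @param se compute standard errors from the expected information matrix.
#' @param max_iter iteration budget for the optimizer.
#' @return an object of class `wone_cfa_fit` with elements `estimates`
#'   (parameter table with est, se), `standardized` (completely standardized
#'   loadings and R-squared), `fit` (see [compute_fit_indices()]), `fmin`,
#'   `T`, `df`, `converged`, `model`, `stats`.
#' @export
fit_cfa <- function(model, data = NULL, group = NULL, sample_cov = NULL,
                    sample_mean = NULL, n = NULL, se = TRUE, max_iter = 500) {
  stopifnot(inherits(model, "wone_cfa_model"))
  st <- .sample_stats(model, data, group, sample_cov, sample_mean, n)
  nfree <- length(model$theta_labels)
  moments <- model$ngroups * model$p * (model$p + 1) / 2 +
    (if (model$meanstructure) model$ngroups * model$p else 0)
  df <- moments - nfree
  if (df < 0) stop("model has negative degrees of freedom (", df, ")")
  if (min(st$n) <= nfree / model$ngroups && min(st$n) < model$p + 1)
    warning("sample size is small relative to the free parameter count")

  start <- .start_theta(model)
  obj <- function(th) .fml(model, th, st)
  gr <- function(th) .fml_grad(model, th, st)
  # variances are bounded below at 1e-3 (on the log scale): a Heywood case
  # lands on this bound and is flagged instead of crossing zero
  pr1 <- model$params[model$params$free, ]
  pr1 <- pr1[!duplicated(pr1$theta), ]
  pr1 <- pr1[order(pr1$theta), ]
  lower <- ifelse(pr1$vartype == "logvar", log(1e-3), -Inf)
  opt <- stats::nlminb(start, obj, gr, lower = lower,
                       control = list(iter.max = max_iter, eval.max = 4 * max_iter,
                                      rel.tol = 1e-12, x.tol = 1e-10))
  theta <- opt$par
  fmin <- opt$objective
  # Fisher-scoring polish: quadratic convergence near the optimum drives the
  # gradient below the 1e-6 infinity-norm target
  at_bound <- function(th) is.finite(lower) & th <= lower + 1e-8
  for (it in seq_len(25)) {
    gcur <- gr(theta)
    act <- at_bound(theta) & gcur > 0     # pushing into the bound: inactive
    if (max(abs(gcur[!act]), 0) < 1e-8) break
    isc <- tryCatch(.info_score(model, theta, st), error = function(e) NULL)
    if (is.null(isc)) break
    keep <- !act
    step <- rep(0, length(theta))
    s0 <- tryCatch(solve(isc$info[keep, keep, drop = FALSE], gcur[keep]),
                   error = function(e) NULL)
    if (is.null(s0)) break
    step[keep] <- s0
    h <- 1
    repeat {
      cand <- pmax(theta - h * step, lower)
      fc <- obj(cand)
      if (fc <= fmin + 1e-12 || h < 1e-6) break
      h <- h / 2
    }
    if (fc > fmin + 1e-12) break
    theta <- cand; fmin <- fc
  }
  gcur <- gr(theta)
  act <- at_bound(theta) & gcur > 0
  gnorm <- max(abs(gcur[!act]), 0)
  converged <- is.finite(fmin) && fmin < 1e9 &&
    (gnorm < 1e-6 || fmin < 1e-10 || abs(fmin - opt$objective) < 1e-12 && gnorm < 1e-4)
  if (!converged)
    stop("CFA did not converge: F=", format(fmin),
         ", gradient max |g|=", format(gnorm))

  Tstat <- (st$N - st$G) * max(fmin, 0)

  # parameter table
  params <- model$params
  params$est <- ifelse(params$free,
                       ifelse(params$vartype == "logvar",
                              exp(theta[pmax(params$theta, 1)]),
                              theta[pmax(params$theta, 1)]),
                       params$value)
  bnd <- at_bound(theta)
  heywood <- params$free & params$vartype == "logvar" &
    bnd[pmax(params$theta, 1)]
  params$heywood <- heywood

  if (se) {
    isc <- .info_score(model, theta, st)
    keep <- !at_bound(theta)     # boundary (Heywood) parameters get NA SEs
    se_theta <- rep(NA_real_, nfree)
    acov <- tryCatch(
      2 / (st$N - st$G) * solve(isc$info[keep, keep, drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(acov)) {
      se_theta[keep] <- sqrt(pmax(diag(acov), 0))
      params$se <- ifelse(params$free,
                          ifelse(params$vartype == "logvar",
                                 params$est * se_theta[pmax(params$theta, 1)],
                                 se_theta[pmax(params$theta, 1)]),
                          NA_real_)
    } else {
      params$se <- NA_real_
      warning("information matrix is singular; standard errors unavailable")
    }
  } else params$se <- NA_real_

  # implied moments and standardized solution per group
  implied <- vector("list", model$ngroups)
  stdsol <- vector("list", model$ngroups)
  for (g in seq_len(model$ngroups)) {
    mats <- .group_matrices(model, theta, g)
    imp <- .implied_group(model, mats)
    implied[[g]] <- imp
    V <- imp$V
    pg <- params[params$group == g & params$matrix == "A", ]
    sl <- pg$est * sqrt(diag(V)[pg$ci] / diag(V)[pg$ri])
    r2 <- 1 - diag(mats$S)[seq_len(model$p)] / diag(V)[seq_len(model$p)]
    stdsol[[g]] <- list(
      loadings = data.frame(from = model$vars[pg$ci], to = model$vars[pg$ri],
                            std = sl, stringsAsFactors = FALSE),
      r2 = stats::setNames(r2, model$vars[seq_len(model$p)]))
  }

  # baseline (independence) model for incremental indices
  Fb <- sum(st$w * vapply(seq_len(st$G), function(g)
    sum(log(diag(st$S[[g]]))) - st$logdetS[g], 0))
  Tb <- (st$N - st$G) * Fb
  dfb <- st$G * model$p * (model$p - 1) / 2

  fit <- compute_fit_indices(Tstat, df, Tb, dfb, n = st$N,
                             S = st$S,
                             sigma = lapply(implied, `[[`, "sigma"),
                             ngroups = st$G)

  structure(list(estimates = params, standardized = stdsol, fit = fit,
                 fmin = fmin, T = Tstat, df = df, baseline = list(T = Tb, df = dfb),
                 theta = theta, gradient_norm = gnorm, converged = converged,
                 boundary = at_bound(theta),
                 heywood = any(heywood), model = model, stats = st),
            class = "wone_cfa_fit")
}

#' @export
print.wone_cfa_fit <- function(x, ...) {
  cat("ML CFA fit:", length(x$model$theta_labels), "free parameters\n")
  cat(sprintf("  chisq(%d) = %.3f, F = %.6f\n", x$df, x$T, x$fmin))
  f <- x$fit
  cat(sprintf("  CFI = %.3f  TLI = %s  RMSEA = %.3f [%.3f, %.3f]  SRMR = %.3f\n",
              f$cfi, ifelse(is.na(f$tli), "NA", sprintf("%.3f", f$tli)),
              f$rmsea, f$rmsea_ci[1], f$rmsea_ci[2], f$srmr))
  if (x$heywood) cat("  note: Heywood case bounded at the variance floor\n")
  invisible(x)
}

#' Extract standardized loadings from a fit
#'
#' @param fit a `wone_cfa_fit`.
#' @param g group index.
#' @return data.frame with columns `from` (factor), `to` (indicator), `std`.
#' @export
standardized_loadings <- function(fit, g = 1) fit$standardized[[g]]$loadings
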