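#' Incremental and absolute fit indices for a covariance-structure model
#'
#' CFI \eqn{= 1 - \max(T-df,0)/\max(T_b-df_b, T-df, 0)}; TLI
#' \eqn{= ((T_b/df_b)-(T/df))/((T_b/df_b)-1)} (absent when `df = 0`);
#' RMSEA \eqn{= \sqrt{\max(T-df,0)/(df\,(n-1))}} (times \eqn{\sqrt{G}} for G
#' groups) with a 90\% CI by inversion of the noncentral chi-square
#' distribution; SRMR is the root mean squared standardized residual over the
#' unique elements of each group's covariance matrix, averaged over groups.
#'
#' @param T model chi-square statistic.
#' @param df model degrees of freedom.
#' @param T_baseline,df_baseline chi-square and df of the independence
#'   baseline (free variances, zero covariances).
#' @param n total sample size.
#' @param S,sigma sample and model-implied covariance matrices (or lists of
#'   them, one per group); needed for SRMR only.
#' @param ngroups number of groups.
#' @param ci_level confidence level for the RMSEA interval.
#' @return list with `chisq`, `df`, `pvalue`, `cfi`, `tli`, `rmsea`,
#'   `rmsea_ci`, `srmr`.
#' @export
compute_fit_indices <- function(T, df, T_baseline, df_baseline, n,
                                S = NULL, sigma = NULL, ngroups = 1,
                                ci_level = 0.90) {
  if (df < 0) stop("df must be >= 0")
  num <- max(T - df, 0)
  den <- max(T_baseline - df_baseline, T - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  tli <- if (df == 0 || df_baseline == 0) NA_real_ else {
    rb <- T_baseline / df_baseline
    ((rb - T / df) / (rb - 1))
  }
  if (df == 0) {
    rmsea <- 0
    rmsea_ci <- c(0, 0)
  } else {
    scale <- sqrt(ngroups) / sqrt(df * (n - 1))
    rmsea <- sqrt(num) * scale
    alpha <- (1 - ci_level) / 2
    lo <- .ncp_solve(T, df, 1 - alpha)
    hi <- .ncp_solve(T, df, alpha)
    rmsea_ci <- sqrt(c(lo, hi)) * scale
  }
  srmr <- if (is.null(S) || is.null(sigma)) NA_real_ else {
    Sl <- if (is.list(S)) S else list(S)
    Gl <- if (is.list(sigma)) sigma else list(sigma)
    mean(mapply(function(s, sg) {
      ds <- sqrt(diag(s))
      sc <- s / tcrossprod(ds)
      gc <- sg / tcrossprod(ds)
      idx <- lower.tri(s, diag = TRUE)
      sqrt(mean((sc[idx] - gc[idx])^2))
    }, Sl, Gl))
  }
  list(chisq = T, df = df,
       pvalue = if (df > 0) stats::pchisq(T, df, lower.tail = FALSE) else NA_real_,
       cfi = cfi, tli = tli, rmsea = rmsea, rmsea_ci = rmsea_ci, srmr = srmr)
}

# find ncp lambda with pchisq(T, df, ncp = lambda) == prob (0 if impossible)
.ncp_solve <- function(T, df, prob) {
  if (stats::pchisq(T, df) < prob) return(0)
  f <- function(l) stats::pchisq(T, df, ncp = l) - prob
  hi <- max(T, 1)
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-8)$root
}
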