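#' Heterotrait-monotrait ratio of correlations
#'
#' For each construct pair, the mean absolute heterotrait-heteromethod
#' correlation divided by the geometric mean of the two constructs' mean
#' absolute monotrait-heteromethod correlations. Ratios are flagged against
#' the conservative (0.85) and liberal (0.90) discriminant-validity
#' thresholds.
#'
#' @param scores n x p item-score matrix.
#' @param constructs character vector assigning each column to a construct
#'   (each construct needs >= 2 items).
#' @return list of class `wone_htmt`: `ratios` (construct x construct matrix,
#'   NA diagonal), `flags_085`, `flags_090` (logical matrices), `undefined`
#'   (pairs with non-positive monotrait means, if any).
#' @export
htmt <- function(scores, constructs) {
  scores <- as.matrix(scores)
  if (length(constructs) != ncol(scores))
    stop("one construct label per column is required")
  cs <- unique(constructs)
  if (length(cs) < 2) stop("need at least 2 constructs")
  sizes <- table(constructs)
  if (any(sizes < 2)) stop("every construct needs at least 2 items")
  R <- abs(stats::cor(scores))
  mono <- vapply(cs, function(cc) {
    idx <- which(constructs == cc)
    sub <- R[idx, idx, drop = FALSE]
    mean(sub[lower.tri(sub)])
  }, 0)
  k <- length(cs)
  ratios <- matrix(NA_real_, k, k, dimnames = list(cs, cs))
  undefined <- character()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    hetero <- mean(R[constructs == cs[i], constructs == cs[j]])
    if (mono[i] <= 0 || mono[j] <= 0) {
      undefined <- c(undefined, paste(cs[i], cs[j], sep = ":"))
      next
    }
    ratios[i, j] <- ratios[j, i] <- hetero / sqrt(mono[i] * mono[j])
  }
  structure(list(ratios = ratios, flags_085 = ratios > 0.85,
                 flags_090 = ratios > 0.90, undefined = undefined,
                 monotrait = mono),
            class = "wone_htmt")
}

#' Correlation panel with p values
#'
#' Pearson correlations between all column pairs with two-sided p values,
#' in the layout used for convergent/concurrent validity reporting.
#'
#' @param scores n x k score matrix (k >= 2) with column names.
#' @return list with `r` (correlation matrix), `p` (two-sided p values, NA
#'   diagonal), `n`, and `flagged` (zero-variance columns, whose entries are
#'   NA).
#' @export
correlation_panel <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 2) stop("need at least 2 columns")
  sds <- apply(scores, 2, stats::sd)
  flagged <- colnames(scores)[sds == 0]
  n <- nrow(scores)
  r <- suppressWarnings(stats::cor(scores))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  diag(p) <- NA
  list(r = r, p = p, n = n, flagged = flagged)
}

#' Hierarchical incremental validity (Delta R-squared)
#'
#' OLS fit of the nested base and full models;
#' \eqn{F = (\Delta R^2/q) / ((1-R^2_{full})/(n-p_{full}-1))} for the added
#' block of q predictors. A rank-deficient added block is reduced to its
#' effective rank with a warning.
#'
#' @param outcome numeric outcome vector.
#' @param base n x b matrix of base predictors.
#' @param added n x q matrix of added predictors.
#' @return list with `r2_base`, `r2_full`, `delta_r2`, `f`, `df1`, `df2`,
#'   `p.value`, `n`.
#' @export
incremental_validity <- function(outcome, base, added) {
  base <- as.matrix(base); added <- as.matrix(added)
  n <- length(outcome)
  if (n <= ncol(base) + ncol(added) + 1)
    stop("n must exceed the total predictor count + 1")
  fit0 <- stats::lm(outcome ~ base)
  fitX <- cbind(base, added)
  q_eff <- qr(cbind(1, fitX))$rank - qr(cbind(1, base))$rank
  if (q_eff < ncol(added))
    warning("added block is collinear with the base block; effective rank ",
            q_eff, " of ", ncol(added))
  fit1 <- stats::lm(outcome ~ fitX)
  r2_0 <- summary(fit0)$r.squared
  r2_1 <- summary(fit1)$r.squared
  d <- max(r2_1 - r2_0, 0)
  p_full <- qr(cbind(1, fitX))$rank - 1
  df2 <- n - p_full - 1
  f <- if (q_eff == 0) 0 else (d / q_eff) / ((1 - r2_1) / df2)
  pv <- if (q_eff == 0) 1 else stats::pf(f, q_eff, df2, lower.tail = FALSE)
  list(r2_base = r2_0, r2_full = r2_1, delta_r2 = d, f = f,
       df1 = q_eff, df2 = df2, p.value = pv, n = n)
}
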