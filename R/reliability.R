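#' Composite reliability from standardized loadings
#'
#' \eqn{CR = (\Sigma\lambda_i)^2 / [(\Sigma\lambda_i)^2 + \Sigma(1-\lambda_i^2)]}.
#'
#' @param loadings standardized loadings of one factor's items (>= 2 unless
#'   `allow_single = TRUE`).
#' @param allow_single permit a single loading (degenerate testing aid).
#' @return CR value.
#' @export
composite_reliability <- function(loadings, allow_single = FALSE) {
  if (length(loadings) == 0) stop("no loadings supplied")
  if (length(loadings) < 2 && !allow_single)
    stop("composite reliability needs at least 2 loadings")
  s <- sum(loadings)^2
  s / (s + sum(1 - loadings^2))
}

#' Average variance extracted
#'
#' Arithmetic mean of the item communalities (R-squared) of one factor.
#'
#' @param communalities values in \[0, 1\].
#' @return AVE value.
#' @export
ave <- function(communalities) {
  if (length(communalities) == 0) stop("no communalities supplied")
  if (any(communalities < 0 | communalities > 1))
    stop("communalities must lie in [0, 1]")
  mean(communalities)
}

#' Cronbach's alpha with Feldt confidence interval
#'
#' \eqn{\alpha = k/(k-1)\,(1 - \Sigma\sigma^2_i/\sigma^2_{total})}; the CI
#' uses the Feldt F method: \eqn{(1-\alpha)/(1-\hat\alpha) \sim F_{n-1,
#' (n-1)(k-1)}}.
#'
#' @param scores n x k item-score matrix for one scale (k >= 2).
#' @param level confidence level.
#' @return list with `alpha`, `ci` (length-2), `k`, `n`.
#' @export
cronbach_alpha <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  k <- ncol(scores); n <- nrow(scores)
  if (k < 2) stop("alpha needs at least 2 items")
  tot <- stats::var(rowSums(scores))
  if (tot <= 0) stop("zero total-score variance")
  a <- k / (k - 1) * (1 - sum(apply(scores, 2, stats::var)) / tot)
  alpha2 <- (1 - level) / 2
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  ci <- c(1 - (1 - a) * stats::qf(1 - alpha2, df1, df2),
          1 - (1 - a) * stats::qf(alpha2, df1, df2))
  list(alpha = a, ci = ci, k = k, n = n)
}

#' McDonald's omega from a unidimensional congeneric model
#'
#' Fits a single-factor congeneric model by maximum likelihood (via the
#' package's CFA engine) and returns
#' \eqn{\omega = (\Sigma\lambda)^2 / ((\Sigma\lambda)^2 + \Sigma\theta)} on
#' the standardized solution.
#'
#' @param scores n x k item-score matrix (k >= 3 for identification).
#' @return list with `omega`, `loadings` (standardized), `fit` (the CFA fit).
#' @export
mcdonald_omega <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 3) stop("omega needs at least 3 items (single-factor identification)")
  ids <- colnames(scores) %||% paste0("x", seq_len(k))
  colnames(scores) <- ids
  spec <- measurement_model(
    items = data.frame(id = ids, factor = "F1", loading = 0.7),
    factors = data.frame(id = "F1", parent = "ResilienceResources", gamma = 0.7))
  model <- cfa_model(spec, second_order = FALSE)
  fit <- fit_cfa(model, data = scores, se = FALSE)
  lam <- standardized_loadings(fit)$std
  th <- 1 - lam^2
  list(omega = sum(lam)^2 / (sum(lam)^2 + sum(th)), loadings = lam, fit = fit)
}

#' Intraclass correlation for two-wave test-retest data
#'
#' Two-way ANOVA decomposition over subjects and waves.
#' ICC(2,1) (two-way random, absolute agreement):
#' \eqn{(MS_R-MS_E)/(MS_R+(k-1)MS_E + k(MS_C-MS_E)/n)};
#' ICC(3,1) (two-way mixed, consistency): \eqn{(MS_R-MS_E)/(MS_R+(k-1)MS_E)}.
#' Confidence intervals use the standard F-based forms; the interpretation
#' band follows the published cut points (<0.50 poor, 0.50-0.75 moderate,
#' 0.75-0.90 good, >0.90 excellent).
#'
#' @param wave1,wave2 paired score vectors (>= 3 subjects).
#' @param form `"ICC(2,1)"` or `"ICC(3,1)"`.
#' @param level confidence level.
#' @return list with `icc`, `form`, `ci`, `band`, `ms` (mean squares).
#' @export
icc <- function(wave1, wave2, form = c("ICC(2,1)", "ICC(3,1)"), level = 0.95) {
  form <- match.arg(form)
  if (length(wave1) != length(wave2)) stop("waves must be paired")
  n <- length(wave1)
  if (n < 3) stop("need at least 3 subjects")
  x <- cbind(wave1, wave2)
  k <- 2
  row_m <- rowMeans(x); col_m <- colMeans(x); gm <- mean(x)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_tot <- sum((x - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  alpha <- 1 - level
  if (form == "ICC(3,1)") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    Fobs <- msr / mse
    fl <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # McGraw & Wong F-based interval with Satterthwaite df
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    Fstar <- msc / mse
    v <- (a * Fstar + b)^2 /
      (a^2 * Fstar^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lo, hi)
  }
  band <- if (est < 0.5) "poor" else if (est <= 0.75) "moderate"
          else if (est <= 0.90) "good" else "excellent"
  list(icc = est, form = form, ci = ci, band = band,
       ms = c(msr = msr, msc = msc, mse = mse))
}

#' Per-factor reliability report from a measurement model and data
#'
#' Computes CR and AVE from the model's standardized loadings and printed
#' communalities, plus sample Cronbach alpha and McDonald omega per factor.
#'
#' @param spec a `wone_model_spec`.
#' @param responses optional n x p response matrix for the sample statistics
#'   (alpha, omega); CR / AVE come from the model specification itself.
#' @return data.frame with one row per factor: factor, k, cr, ave, alpha,
#'   alpha_lo, alpha_hi, omega.
#' @export
reliability_report <- function(spec, responses = NULL) {
  out <- lapply(spec$factors$id, function(f) {
    sel <- spec$items$factor == f
    lam <- spec$items$loading[sel]
    h2 <- spec$items$communality[sel]
    row <- data.frame(factor = f, k = sum(sel),
                      cr = composite_reliability(lam, allow_single = TRUE),
                      ave = ave(pmin(h2, 1)),
                      alpha = NA_real_, alpha_lo = NA_real_,
                      alpha_hi = NA_real_, omega = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(responses) && sum(sel) >= 2) {
      a <- cronbach_alpha(responses[, spec$items$id[sel], drop = FALSE])
      row$alpha <- a$alpha; row$alpha_lo <- a$ci[1]; row$alpha_hi <- a$ci[2]
      if (sum(sel) >= 3)
        row$omega <- mcdonald_omega(responses[, spec$items$id[sel],
                                              drop = FALSE])$omega
    }
    row
  })
  do.call(rbind, out)
}
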