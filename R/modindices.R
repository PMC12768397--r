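#' Modification indices for fixed parameters
#'
#' Univariate score (Lagrange multiplier) tests for the parameters held at
#' zero in a fitted model: item residual covariances and cross-loadings.
#' Each MI approximates the chi-square drop expected from freeing that
#' single parameter; the expected parameter change (EPC) is reported
#' alongside. Computed from the analytic score and expected information at
#' the restricted solution.
#'
#' @param fit a `wone_cfa_fit`.
#' @param types which fixed-parameter classes to test: `"resid_cov"`,
#'   `"cross_loading"` or both.
#' @param sort_desc sort by MI, largest first.
#' @return data.frame with columns `type`, `a`, `b`, `mi`, `epc`; rows with a
#'   numerically singular information block are omitted with a warning.
#' @export
modification_indices <- function(fit,
                                 types = c("resid_cov", "cross_loading"),
                                 sort_desc = TRUE) {
  stopifnot(inherits(fit, "wone_cfa_fit"))
  model <- fit$model
  types <- match.arg(types, several.ok = TRUE)
  p <- model$p; vars <- model$vars
  it <- model$spec$items
  existing <- paste(model$params$matrix, model$params$ri, model$params$ci)

  cand <- list()
  if ("resid_cov" %in% types) {
    for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
      if (!(paste("S", i, j) %in% existing) && !(paste("S", j, i) %in% existing))
        cand[[length(cand) + 1L]] <- data.frame(
          matrix = "S", ri = i, ci = j, vartype = "plain",
          type = "resid_cov", a = vars[i], b = vars[j],
          stringsAsFactors = FALSE)
    }
  }
  if ("cross_loading" %in% types) {
    fidx <- p + seq_len(model$q)
    for (i in seq_len(p)) for (f in fidx) {
      if (!(paste("A", i, f) %in% existing))
        cand[[length(cand) + 1L]] <- data.frame(
          matrix = "A", ri = i, ci = f, vartype = "plain",
          type = "cross_loading", a = vars[i], b = vars[f],
          stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0)
    return(data.frame(type = character(), a = character(), b = character(),
                      mi = numeric(), epc = numeric()))
  cand <- do.call(rbind, cand)
  # candidates are evaluated in every group (freed simultaneously)
  cand_all <- do.call(rbind, lapply(seq_len(model$ngroups), function(g) {
    cg <- cand; cg$group <- g; cg
  }))
  # theta column required by .info_score bookkeeping
  cand_all$theta <- 0L

  isc <- .info_score(model, fit$theta, fit$stats, candidates = cand_all)
  nfree <- isc$nfree
  Afull <- isc$info
  sc <- isc$score
  # parameters at the variance bound are treated as fixed in the score test
  keep <- which(!fit$boundary)
  Aff <- Afull[keep, keep, drop = FALSE]
  Aff_inv <- tryCatch(solve(Aff), error = function(e) NULL)
  if (is.null(Aff_inv)) {
    warning("information matrix singular; modification indices unavailable")
    return(data.frame(type = character(), a = character(), b = character(),
                      mi = numeric(), epc = numeric()))
  }
  scale <- fit$stats$N - fit$stats$G
  out <- cand
  out$mi <- NA_real_; out$epc <- NA_real_
  dropped <- 0L
  for (c0 in seq_len(nrow(cand))) {
    ci <- nfree + c0
    a_cc <- Afull[ci, ci]
    a_cf <- Afull[ci, keep]
    eff <- a_cc - as.numeric(a_cf %*% Aff_inv %*% a_cf)
    if (!is.finite(eff) || eff < 1e-10) { dropped <- dropped + 1L; next }
    out$mi[c0] <- scale * sc[ci]^2 / (2 * eff)
    out$epc[c0] <- -sc[ci] / eff
  }
  if (dropped > 0)
    warning(dropped, " candidate(s) omitted: singular information block")
  out <- out[!is.na(out$mi), c("type", "a", "b", "mi", "epc")]
  if (sort_desc) out <- out[order(-out$mi), ]
  rownames(out) <- NULL
  out
}

#' Free one parameter in a CFA model
#'
#' @param model a `wone_cfa_model`.
#' @param type `"resid_cov"` or `"cross_loading"`.
#' @param a,b item id / item id (residual covariance) or item id / factor id
#'   (cross-loading).
#' @return the revised model.
#' @export
free_parameter <- function(model, type = c("resid_cov", "cross_loading"),
                           a, b) {
  type <- match.arg(type)
  vars <- model$vars
  stopifnot(a %in% vars, b %in% vars)
  newrows <- do.call(rbind, lapply(seq_len(model$ngroups), function(g) {
    data.frame(matrix = if (type == "resid_cov") "S" else "A",
               row = a, col = b, free = TRUE, value = 0,
               label = paste0(if (type == "resid_cov") "rc_" else "xl_",
                              a, "~", b,
                              if (model$ngroups > 1) paste0(".g", g) else ""),
               vartype = "plain", group = g,
               stringsAsFactors = FALSE)
  }))
  newrows$theta <- 0L
  newrows$ri <- match(newrows$row, vars)
  newrows$ci <- match(newrows$col, vars)
  dup <- paste(model$params$matrix, model$params$ri, model$params$ci,
               model$params$group)
  if (any(paste(newrows$matrix, newrows$ri, newrows$ci, newrows$group) %in% dup))
    stop("parameter ", a, if (type == "resid_cov") "~~" else "=~", b,
         " already exists in the model")
  params <- rbind(model$params, newrows)
  labs <- unique(params$label[params$free])
  params$theta <- 0L
  params$theta[params$free] <- match(params$label[params$free], labs)
  model$params <- params
  model$theta_labels <- labs
  model
}

#' Modification-index guided model refinement
#'
#' Frees one parameter per iteration: the highest-MI candidate that
#' intersects the user-supplied allowlist (residual covariances are
#' preferred over cross-loadings), refits, and repeats until no allowed
#' candidate reaches the MI threshold. The allowlist is an explicit input:
#' the theoretical-justifiability gate is never automatic. An empty
#' allowlist returns the model unchanged (with the surviving MI report).
#'
#' @param model a `wone_cfa_model`.
#' @param data,group,sample_cov,sample_mean,n data interface as in
#'   [fit_cfa()].
#' @param mi_threshold free parameters only while an allowed MI is at or
#'   above this value (published practice: 10).
#' @param allowlist data.frame with columns `type` (`"resid_cov"` /
#'   `"cross_loading"`), `a`, `b`; order of `a`, `b` is ignored for residual
#'   covariances.
#' @param max_steps safety bound on the number of freed parameters.
#' @return list with `model` (revised), `fit` (final fit), `audit`
#'   (data.frame of freed parameters: step, type, a, b, mi, plus the fit
#'   trajectory columns chisq, df, cfi, rmsea, srmr).
#' @export
refine_model <- function(model, data = NULL, group = NULL, sample_cov = NULL,
                         sample_mean = NULL, n = NULL, mi_threshold = 10,
                         allowlist = NULL, max_steps = 20) {
  if (is.null(allowlist) || nrow(allowlist) == 0) {
    fit <- fit_cfa(model, data, group, sample_cov, sample_mean, n)
    return(list(model = model, fit = fit,
                audit = data.frame(step = integer(), type = character(),
                                   a = character(), b = character(),
                                   mi = numeric(), chisq = numeric(),
                                   df = numeric(), cfi = numeric(),
                                   rmsea = numeric(), srmr = numeric())))
  }
  allow_key <- c(
    paste("resid_cov", pmin(allowlist$a[allowlist$type == "resid_cov"],
                            allowlist$b[allowlist$type == "resid_cov"]),
          pmax(allowlist$a[allowlist$type == "resid_cov"],
               allowlist$b[allowlist$type == "resid_cov"])),
    paste("cross_loading", allowlist$a[allowlist$type == "cross_loading"],
          allowlist$b[allowlist$type == "cross_loading"]))
  audit <- list()
  fit <- fit_cfa(model, data, group, sample_cov, sample_mean, n)
  prev_fml <- fit$fmin
  for (step in seq_len(max_steps)) {
    mi <- modification_indices(fit)
    if (nrow(mi) == 0) break
    key <- ifelse(mi$type == "resid_cov",
                  paste("resid_cov", pmin(mi$a, mi$b), pmax(mi$a, mi$b)),
                  paste("cross_loading", mi$a, mi$b))
    mi <- mi[key %in% allow_key & mi$mi >= mi_threshold, , drop = FALSE]
    if (nrow(mi) == 0) break
    # residual covariances preferred over cross-loadings, then by MI
    mi <- mi[order(mi$type != "resid_cov", -mi$mi), , drop = FALSE]
    pick <- mi[1, ]
    model <- free_parameter(model, pick$type, pick$a, pick$b)
    fit <- fit_cfa(model, data, group, sample_cov, sample_mean, n)
    if (fit$fmin > prev_fml + 1e-8)
      stop("discrepancy increased after freeing a parameter; refinement aborted")
    prev_fml <- fit$fmin
    audit[[step]] <- data.frame(step = step, type = pick$type, a = pick$a,
                                b = pick$b, mi = pick$mi, chisq = fit$T,
                                df = fit$df, cfi = fit$fit$cfi,
                                rmsea = fit$fit$rmsea, srmr = fit$fit$srmr,
                                stringsAsFactors = FALSE)
  }
  list(model = model, fit = fit,
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(step = integer(), type = character(), a = character(),
                    b = character(), mi = numeric(), chisq = numeric(),
                    df = numeric(), cfi = numeric(), rmsea = numeric(),
                    srmr = numeric()))
}
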