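#' Construct a hierarchical measurement-model specification
#'
#' A `wone_model_spec` is the single source of truth shared by the simulator,
#' the CFA engine, and the index scorer. It describes a set of Likert items
#' loading on first-order factors, which in turn load on one of two
#' second-order factors (a stress-load domain and a resilience-resources
#' domain), plus optional item residual covariances and the correlation
#' between the two second-order factors.
#'
#' @param items data.frame with columns `id` (character, unique), `factor`
#'   (character, first-order factor id), `loading` (standardized loading in
#'   \[-1, 1\]), `reverse` (logical, reverse-scored when combined across
#'   domains), `domain` (`"stress"` or `"resilience"`), and optionally
#'   `communality` (printed R-squared; defaults to `loading^2`).
#' @param factors data.frame with columns `id`, `parent` (second-order factor
#'   id, one of `"StressLoad"`, `"ResilienceResources"`), `gamma`
#'   (standardized second-order loading in \[-1, 1\]).
#' @param residual_covariances optional data.frame with columns `item1`,
#'   `item2`, `theta` giving residual covariances between distinct items.
#' @param cross_domain_corr correlation between the two second-order factors,
#'   in \[-1, 1\].
#'
#' @return An object of class `wone_model_spec`.
#' @export
measurement_model <- function(items, factors, residual_covariances = NULL,
                              cross_domain_corr = 0) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  need <- c("id", "factor", "loading")
  if (!all(need %in% names(items)))
    stop("`items` must have columns id, factor, loading")
  if (!all(c("id", "parent", "gamma") %in% names(factors)))
    stop("`factors` must have columns id, parent, gamma")
  if (is.null(items$reverse)) items$reverse <- FALSE
  if (is.null(items$domain)) {
    dom <- ifelse(factors$parent[match(items$factor, factors$id)] == "StressLoad",
                  "stress", "resilience")
    items$domain <- dom
  }
  if (is.null(items$communality)) items$communality <- items$loading^2
  if (anyDuplicated(items$id)) stop("item ids must be unique")
  if (anyDuplicated(factors$id)) stop("factor ids must be unique")
  if (!all(items$factor %in% factors$id))
    stop("every item must map to an existing factor; unknown: ",
         paste(setdiff(items$factor, factors$id), collapse = ", "))
  if (!all(factors$parent %in% c("StressLoad", "ResilienceResources")))
    stop("factor parents must be 'StressLoad' or 'ResilienceResources'")
  if (any(abs(items$loading) > 1)) stop("standardized loadings must lie in [-1, 1]")
  if (any(abs(factors$gamma) > 1)) stop("second-order loadings must lie in [-1, 1]")
  if (abs(cross_domain_corr) > 1) stop("cross_domain_corr must lie in [-1, 1]")
  if (length(residual_covariances) == 0) residual_covariances <- NULL
  if (is.null(residual_covariances)) {
    residual_covariances <- data.frame(item1 = character(), item2 = character(),
                                       theta = numeric(), stringsAsFactors = FALSE)
  } else {
    residual_covariances <- as.data.frame(residual_covariances,
                                          stringsAsFactors = FALSE)
    if (!all(c("item1", "item2", "theta") %in% names(residual_covariances)))
      stop("`residual_covariances` must have columns item1, item2, theta")
    ok <- residual_covariances$item1 %in% items$id &
      residual_covariances$item2 %in% items$id &
      residual_covariances$item1 != residual_covariances$item2
    if (!all(ok)) stop("residual covariances must reference distinct existing items")
  }
  spec <- structure(
    list(items = items, factors = factors,
         residual_covariances = residual_covariances,
         cross_domain_corr = cross_domain_corr),
    class = "wone_model_spec")
  # fail fast on a non-PSD implied covariance, naming the offending block;
  # the residual block must itself be PSD for response generation
  imp <- implied_moments(spec)
  ev_sigma <- min(eigen(imp$sigma, symmetric = TRUE, only.values = TRUE)$values)
  ev_theta <- min(eigen(imp$theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_sigma < -1e-8 || ev_theta < -1e-8) {
    bad <- if (any(1 - items$loading^2 < -1e-12))
      "item uniquenesses (|loading| > 1 effect)"
    else if (ev_theta < -1e-8) paste0(
      "residual-covariance block: ",
      paste(residual_covariances$item1, residual_covariances$item2,
            sep = "~", collapse = ", "))
    else "latent covariance block"
    stop("model-implied covariance is not positive semidefinite (", bad,
         "); smallest eigenvalue ", format(min(ev_sigma, ev_theta)))
  }
  spec
}

#' @export
print.wone_model_spec <- function(x, ...) {
  cat("Hierarchical measurement model:", nrow(x$items), "items,",
      nrow(x$factors), "first-order factors, 2 second-order domains\n")
  cat("cross-domain correlation:", x$cross_domain_corr, "\n")
  tab <- table(x$items$factor)
  for (f in x$factors$id)
    cat(sprintf("  %-22s parent=%-20s gamma=%5.2f  items=%d\n", f,
                x$factors$parent[x$factors$id == f],
                x$factors$gamma[x$factors$id == f], tab[[f]]))
  invisible(x)
}

#' Model-implied moments of a measurement model
#'
#' Computes the population item covariance matrix
#' \eqn{\Sigma = \Lambda(\Gamma\Phi\Gamma' + \Psi)\Lambda' + \Theta}
#' where \eqn{\Phi} is the 2x2 second-order factor correlation,
#' \eqn{\Psi = I - \mathrm{diag}(\gamma^2)} holds first-order disturbances,
#' and \eqn{\Theta} holds uniquenesses \eqn{1-\lambda^2} plus any specified
#' residual covariances. All latent variables and items have unit variance,
#' so the matrix is also the implied correlation matrix when residual
#' covariances are absent.
#'
#' @param spec a [measurement_model()] specification.
#' @return list with `sigma` (item covariance), `mu` (item means, all zero on
#'   the latent-response scale), `factor_cov` (first-order factor covariance),
#'   `lambda`, `theta`.
#' @export
implied_moments <- function(spec) {
  it <- spec$items; fa <- spec$factors
  p <- nrow(it); q <- nrow(fa)
  lambda <- matrix(0, p, q, dimnames = list(it$id, fa$id))
  lambda[cbind(seq_len(p), match(it$factor, fa$id))] <- it$loading
  phi <- matrix(c(1, spec$cross_domain_corr, spec$cross_domain_corr, 1), 2, 2,
                dimnames = list(c("StressLoad", "ResilienceResources"),
                                c("StressLoad", "ResilienceResources")))
  gam <- matrix(0, q, 2, dimnames = list(fa$id, colnames(phi)))
  gam[cbind(seq_len(q), match(fa$parent, colnames(phi)))] <- fa$gamma
  psi <- diag(1 - fa$gamma^2, q)
  fcov <- gam %*% phi %*% t(gam) + psi
  dimnames(fcov) <- list(fa$id, fa$id)
  theta <- diag(1 - it$loading^2, p)
  dimnames(theta) <- list(it$id, it$id)
  rc <- spec$residual_covariances
  if (nrow(rc) > 0) {
    i <- match(rc$item1, it$id); j <- match(rc$item2, it$id)
    theta[cbind(i, j)] <- theta[cbind(i, j)] + rc$theta
    theta[cbind(j, i)] <- theta[cbind(i, j)]
  }
  sigma <- lambda %*% fcov %*% t(lambda) + theta
  list(sigma = sigma, mu = stats::setNames(rep(0, p), it$id),
       factor_cov = fcov, lambda = lambda, theta = theta)
}

#' Read / write a measurement-model specification as JSON
#'
#' The JSON document mirrors the model-specification fields: an `items` array (id, factor,
#' loading, reverse, domain, communality), a `factors` array (id, parent,
#' gamma), a `residual_covariances` array and a `cross_domain_corr` scalar.
#'
#' @param path file path.
#' @return [read_model_spec()] returns a `wone_model_spec`.
#' @export
read_model_spec <- function(path) {
  doc <- jsonlite::fromJSON(path)
  measurement_model(items = doc$items, factors = doc$factors,
                    residual_covariances = doc$residual_covariances,
                    cross_domain_corr = doc$cross_domain_corr)
}

#' @rdname read_model_spec
#' @param spec a `wone_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  doc <- list(items = spec$items, factors = spec$factors,
              residual_covariances = spec$residual_covariances,
              cross_domain_corr = spec$cross_domain_corr)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Canonical published measurement model of the WONE Index
#'
#' Returns the packaged Phase 2 measurement model: 43 Likert items on 10
#' first-order factors (3 stress-load, 7 resilience-resources) under 2
#' second-order factors, with the published standardized loadings and
#' communalities, the published second-order loadings, and a cross-domain
#' correlation of -0.71. The Dietary Intake second-order loading (0.51) is
#' back-solved from the published mean of the seven resilience second-order
#' loadings (0.59) and the six printed values; it is an inference and can be
#' overridden by editing the JSON fixture.
#'
#' @param domain `"full"`, `"stress"` (11 items, 3 factors) or `"resilience"`
#'   (32 items, 7 factors) to subset to one published CFA model.
#' @return a `wone_model_spec`.
#' @export
wone_phase2_spec <- function(domain = c("full", "stress", "resilience")) {
  domain <- match.arg(domain)
  path <- system.file("extdata", "wone_phase2_model.json",
                      package = "wonemetrics", mustWork = TRUE)
  spec <- read_model_spec(path)
  if (domain == "full") return(spec)
  keep_dom <- if (domain == "stress") "stress" else "resilience"
  subset_model(spec, spec$factors$id[
    (spec$factors$parent == "StressLoad") == (keep_dom == "stress")])
}

#' Subset a measurement model to a set of first-order factors
#'
#' @param spec a `wone_model_spec`.
#' @param factor_ids factor ids to keep.
#' @return a `wone_model_spec` containing only those factors and their items.
#' @export
subset_model <- function(spec, factor_ids) {
  stopifnot(all(factor_ids %in% spec$factors$id))
  it <- spec$items[spec$items$factor %in% factor_ids, , drop = FALSE]
  fa <- spec$factors[spec$factors$id %in% factor_ids, , drop = FALSE]
  rc <- spec$residual_covariances
  rc <- rc[rc$item1 %in% it$id & rc$item2 %in% it$id, , drop = FALSE]
  measurement_model(it, fa, rc, spec$cross_domain_corr)
}

#' Published weighting table of the WONE Index
#'
#' Returns the packaged published weighting inputs: per-construct empirical
#' and theoretical weight columns (percentages), the printed hybrid and final
#' columns for comparison, the criterion priority weights
#' (CD-RISC 25, BRS 22, PSS-4 18, PHQ-8 15, GAD-7 12, WHO-5 8) and the set of
#' reverse-oriented criteria (PSS-4, PHQ-8, GAD-7).
#'
#' @return list with `constructs` data.frame (construct, empirical,
#'   theoretical, hybrid_printed, final_printed), `priorities` named numeric,
#'   `reverse_criteria` character, `floor` numeric.
#' @export
wone_published_weights <- function() {
  path <- system.file("extdata", "wone_published_weights.json",
                      package = "wonemetrics", mustWork = TRUE)
  doc <- jsonlite::fromJSON(path)
  doc$priorities <- unlist(doc$priorities)
  doc
}
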