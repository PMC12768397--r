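#' Build a confirmatory factor model from a measurement-model specification
#'
#' Translates a [measurement_model()] specification into an estimable CFA
#' model in RAM form (directed paths A, symmetric parameters S, optional
#' means M). Each factor is identified by fixing its marker indicator's
#' unstandardized loading to 1; with `second_order = TRUE` each second-order
#' factor is likewise identified through its first first-order factor.
#' Variances are optimized on the log scale so they stay positive.
#'
#' @param spec a `wone_model_spec`.
#' @param second_order include the second-order layer; otherwise first-order
#'   factors covary freely.
#' @param meanstructure include item intercepts (and, in constrained
#'   multigroup models, latent means).
#' @param ngroups number of groups (parameters are duplicated per group).
#' @param group_equal any of `"loadings"`, `"intercepts"`, `"residuals"`:
#'   parameter classes constrained equal across groups. Constraining
#'   intercepts frees first-order latent means in all but the first group.
#' @param markers `"first"` or a named character vector (factor id -> item
#'   id) choosing the fixed-loading marker indicator per factor.
#' @return an object of class `wone_cfa_model`.
#' @export
cfa_model <- function(spec, second_order = TRUE, meanstructure = FALSE,
                      ngroups = 1, group_equal = character(),
                      markers = "first") {
  stopifnot(inherits(spec, "wone_model_spec"))
  bad <- setdiff(group_equal, c("loadings", "intercepts", "residuals"))
  if (length(bad) > 0) stop("unknown group_equal class: ", paste(bad, collapse = ", "))
  it <- spec$items; fa <- spec$factors
  p <- nrow(it); q <- nrow(fa)
  so_ids <- unique(fa$parent)
  use_so <- second_order && q > 1
  vars <- c(it$id, fa$id, if (use_so) so_ids)
  m <- length(vars)

  marker_of <- function(f) {
    ids <- it$id[it$factor == f]
    if (identical(markers, "first")) return(ids[1])
    mk <- markers[[f]]
    if (is.null(mk) || !(mk %in% ids)) ids[1] else mk
  }

  rows <- list()
  cur_group <- 1L
  add <- function(mat, r, c, free, value, label, vartype = "plain") {
    rows[[length(rows) + 1L]] <<- data.frame(
      matrix = mat, row = r, col = c, free = free, value = value,
      label = label, vartype = vartype, group = cur_group,
      stringsAsFactors = FALSE)
  }

  eq_load <- "loadings" %in% group_equal
  eq_int <- "intercepts" %in% group_equal
  eq_res <- "residuals" %in% group_equal
  for (g in seq_len(ngroups)) {
    cur_group <- g
    gs <- function(base, shared) if (shared || ngroups == 1) base else paste0(base, ".g", g)
    # first-order loadings
    for (f in fa$id) {
      mk <- marker_of(f)
      for (id in it$id[it$factor == f]) {
        if (id == mk) add("A", id, f, FALSE, 1, gs(paste0("l_", id), eq_load))
        else add("A", id, f, TRUE, 0.7, gs(paste0("l_", id), eq_load))
      }
    }
    # uniquenesses (log-parameterized variances)
    for (id in it$id)
      add("S", id, id, TRUE, 0.5, gs(paste0("v_", id), eq_res), "logvar")
    # residual covariances carried by the model specification
    rc <- spec$residual_covariances
    if (nrow(rc) > 0) {
      for (i in seq_len(nrow(rc)))
        add("S", rc$item1[i], rc$item2[i], TRUE, rc$theta[i],
            gs(paste0("rc_", rc$item1[i], "~", rc$item2[i]), FALSE))
    }
    if (use_so) {
      for (soid in so_ids) {
        fs <- fa$id[fa$parent == soid]
        for (k in seq_along(fs)) {
          if (k == 1) add("A", fs[k], soid, FALSE, 1,
                          gs(paste0("g_", fs[k]), eq_load))
          else add("A", fs[k], soid, TRUE, 0.7,
                   gs(paste0("g_", fs[k]), eq_load))
        }
      }
      for (f in fa$id)   # first-order disturbances
        add("S", f, f, TRUE, 0.5, gs(paste0("d_", f), FALSE), "logvar")
      for (soid in so_ids)
        add("S", soid, soid, TRUE, 0.5, gs(paste0("vso_", soid), FALSE), "logvar")
      if (length(so_ids) == 2)
        add("S", so_ids[1], so_ids[2], TRUE, -0.3,
            gs(paste0("cso_", so_ids[1], "~", so_ids[2]), FALSE))
    } else {
      for (f in fa$id)
        add("S", f, f, TRUE, 0.5, gs(paste0("d_", f), FALSE), "logvar")
      if (q > 1) {
        for (i in seq_len(q - 1)) for (j in seq(i + 1, q))
          add("S", fa$id[i], fa$id[j], TRUE, 0.2,
              gs(paste0("c_", fa$id[i], "~", fa$id[j]), FALSE))
      }
    }
    if (meanstructure) {
      for (id in it$id) add("M", id, NA, TRUE, 0, gs(paste0("t_", id), eq_int))
      if (ngroups > 1 && eq_int && g > 1) {
        for (f in fa$id) add("M", f, NA, TRUE, 0, gs(paste0("a_", f), FALSE))
      }
    }
  }
  params <- do.call(rbind, rows)

  # theta indices by label; fixed params have index 0
  free <- params$free
  labs <- unique(params$label[free])
  params$theta <- 0L
  params$theta[free] <- match(params$label[free], labs)
  # matrix index positions
  params$ri <- match(params$row, vars)
  params$ci <- ifelse(is.na(params$col), NA_integer_, match(params$col, vars))

  structure(list(vars = vars, p = p, q = q, so_ids = if (use_so) so_ids else character(),
                 second_order = use_so, meanstructure = meanstructure,
                 ngroups = ngroups, group_equal = group_equal,
                 params = params, theta_labels = labs, spec = spec),
            class = "wone_cfa_model")
}

#' @export
print.wone_cfa_model <- function(x, ...) {
  cat("CFA model:", x$p, "items,", x$q, "factors",
      if (x$second_order) "(second-order)", "\n")
  cat("groups:", x$ngroups,
      if (length(x$group_equal)) paste0("(equal: ", paste(x$group_equal, collapse = ", "), ")"),
      "\n")
  cat("free parameters:", length(x$theta_labels), "\n")
  invisible(x)
}

# starting values for theta (variances on log scale)
.start_theta <- function(model) {
  pr <- model$params[model$params$free, ]
  pr <- pr[!duplicated(pr$theta), ]
  pr <- pr[order(pr$theta), ]
  ifelse(pr$vartype == "logvar", log(pmax(pr$value, 1e-3)), pr$value)
}

# materialize A, S, M for one group at theta
.group_matrices <- function(model, theta, g) {
  m <- length(model$vars)
  A <- matrix(0, m, m); S <- matrix(0, m, m); M <- rep(0, m)
  pr <- model$params[model$params$group == g, ]
  val <- ifelse(pr$free,
                ifelse(pr$vartype == "logvar", exp(theta[pmax(pr$theta, 1)]),
                       theta[pmax(pr$theta, 1)]),
                pr$value)
  isA <- pr$matrix == "A"; isS <- pr$matrix == "S"; isM <- pr$matrix == "M"
  A[cbind(pr$ri[isA], pr$ci[isA])] <- val[isA]
  S[cbind(pr$ri[isS], pr$ci[isS])] <- val[isS]
  S[cbind(pr$ci[isS], pr$ri[isS])] <- val[isS]
  M[pr$ri[isM]] <- val[isM]
  dimnames(A) <- dimnames(S) <- list(model$vars, model$vars)
  names(M) <- model$vars
  list(A = A, S = S, M = M)
}

# model-implied moments for one group
.implied_group <- function(model, mats) {
  m <- length(model$vars); p <- model$p
  B <- solve(diag(m) - mats$A)
  FB <- B[seq_len(p), , drop = FALSE]
  V <- B %*% mats$S %*% t(B)          # implied covariance of all variables
  sigma <- V[seq_len(p), seq_len(p), drop = FALSE]
  mu <- as.numeric(FB %*% mats$M)
  list(B = B, FB = FB, V = V, sigma = sigma, mu = mu)
}
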