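#' Regression-derived empirical construct weights
#'
#' For each criterion scale, the outcome and the construct (factor) scores
#' are standardized and a least-squares regression of the outcome on all
#' construct scores is fitted; the standardized betas are extracted, signs
#' are flipped for criteria oriented higher-is-worse so every construct
#' contributes positively, the betas are combined across criteria by the
#' priority weights, negatives are clipped to zero, and the result is
#' normalized to percentages summing to 100.
#'
#' @param factor_scores n x q matrix of construct scores (columns named).
#' @param criteria a `wone_criteria` object from [simulate_criteria()], or a
#'   list with `scores` (n x c matrix) and `orientation` (named logical,
#'   TRUE = higher-is-worse).
#' @param priorities named numeric criterion priority percentages; defaults
#'   to the published values (CD-RISC 25, BRS 22, PSS-4 18, PHQ-8 15,
#'   GAD-7 12, WHO-5 8), renormalized over the criteria actually present.
#' @return named numeric vector of empirical weights (percent, sums to 100),
#'   with attribute `betas` (criterion x construct standardized betas after
#'   orientation correction).
#' @export
empirical_weights <- function(factor_scores, criteria, priorities = NULL) {
  fs <- as.matrix(factor_scores)
  q <- ncol(fs)
  sc <- criteria$scores
  orient <- criteria$orientation
  if (is.null(sc)) stop("criteria must carry a `scores` matrix")
  if (nrow(sc) != nrow(fs)) stop("criteria and factor scores must be paired")
  if (nrow(fs) < q + 11) stop("need at least 10+1 respondents per regression")
  if (is.null(priorities)) {
    def <- c(`CD-RISC` = 25, BRS = 22, `PSS-4` = 18, `PHQ-8` = 15,
             `GAD-7` = 12, `WHO-5` = 8)
    priorities <- def[intersect(names(def), colnames(sc))]
    if (length(priorities) == 0)
      stop("no default priorities match these criteria; supply `priorities`")
  }
  priorities <- priorities[names(priorities) %in% colnames(sc)]
  priorities <- priorities / sum(priorities)
  Z <- scale(fs)
  if (any(!is.finite(Z))) stop("zero-variance factor score column")
  qrz <- qr(Z)
  if (qrz$rank < q) {
    cc <- abs(stats::cor(fs)); diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop("collinear factor scores: ", colnames(fs)[worst[1]], " and ",
         colnames(fs)[worst[2]])
  }
  betas <- matrix(0, length(priorities), q,
                  dimnames = list(names(priorities), colnames(fs)))
  for (cr in names(priorities)) {
    y <- as.numeric(scale(sc[, cr]))
    b <- stats::coef(stats::lm(y ~ Z))[-1]
    if (isTRUE(orient[[cr]])) b <- -b   # reverse-scored so stress-type criteria contribute positively
    betas[cr, ] <- b
  }
  avg <- as.numeric(priorities %*% betas)
  avg <- pmax(avg, 0)
  if (sum(avg) == 0) stop("all averaged betas are non-positive")
  w <- 100 * avg / sum(avg)
  names(w) <- colnames(fs)
  attr(w, "betas") <- betas
  w
}

#' Hybrid 50/50 weight blend
#'
#' Element-wise average of the empirical and theoretical percentage vectors.
#'
#' @param empirical,theoretical named percentage vectors over the same
#'   constructs.
#' @return named hybrid percentage vector.
#' @export
hybrid_weights <- function(empirical, theoretical) {
  if (is.null(names(empirical)) || is.null(names(theoretical)) ||
      !setequal(names(empirical), names(theoretical)))
    stop("empirical and theoretical weights must cover the same constructs")
  theoretical <- theoretical[names(empirical)]
  0.5 * empirical + 0.5 * theoretical
}

#' Minimum-weight floor with proportional renormalization
#'
#' Entries below the floor are raised to exactly the floor; the excess is
#' removed from the above-floor entries in proportion to their weight. The
#' adjustment iterates if a reduction pushes a new entry below the floor,
#' then the vector is renormalized to sum to 100. Integer display weights
#' use largest-remainder rounding so they sum to exactly 100.
#'
#' @param hybrid named percentage vector (non-negative).
#' @param floor minimum weight percentage (default 5).
#' @return list of class `wone_weight_table`: `final` (numeric, sums to 100),
#'   `display` (integers summing to 100), `floored` (construct names raised
#'   to the floor), `audit` (per-iteration record).
#' @export
apply_floor <- function(hybrid, floor = 5) {
  if (any(hybrid < 0)) stop("hybrid weights must be >= 0")
  k <- length(hybrid)
  if (floor * k > 100) stop("floor x constructs exceeds 100%: infeasible")
  w <- 100 * hybrid / sum(hybrid)
  floored <- rep(FALSE, k)
  audit <- list()
  repeat {
    below <- !floored & w < floor - 1e-9
    if (!any(below)) break
    floored <- floored | below
    w[floored] <- floor
    free <- !floored
    if (!any(free)) break
    scale <- (100 - floor * sum(floored)) / sum(w[free])
    audit[[length(audit) + 1L]] <- data.frame(
      raised = paste(names(w)[below], collapse = ","),
      scale = scale, stringsAsFactors = FALSE)
    w[free] <- w[free] * scale
  }
  w <- 100 * w / sum(w)
  structure(list(final = w, display = largest_remainder(w),
                 floored = names(w)[floored], floor = floor,
                 audit = if (length(audit)) do.call(rbind, audit) else NULL),
            class = "wone_weight_table")
}

#' Largest-remainder integer rounding to a fixed total
#'
#' @param w numeric vector of percentages.
#' @param total target integer sum (default 100).
#' @return named integer vector summing to `total`.
#' @export
largest_remainder <- function(w, total = 100) {
  fl <- floor(w)
  rem <- w - fl
  short <- total - sum(fl)
  if (short > 0) {
    idx <- order(-rem, seq_along(w))[seq_len(short)]
    fl[idx] <- fl[idx] + 1
  }
  stats::setNames(as.integer(fl), names(w))
}

#' Full weight table from empirical and theoretical columns
#'
#' Convenience wrapper: hybrid blend, floor, and display rounding in one
#' table.
#'
#' @param empirical,theoretical named percentage vectors.
#' @param floor minimum weight percentage.
#' @return data.frame with columns construct, empirical, theoretical,
#'   hybrid, final, display; attribute `floored` lists floored constructs.
#' @export
weight_table <- function(empirical, theoretical, floor = 5) {
  hy <- hybrid_weights(empirical, theoretical)
  fl <- apply_floor(hy, floor)
  out <- data.frame(construct = names(hy),
                    empirical = as.numeric(empirical[names(hy)]),
                    theoretical = as.numeric(theoretical[names(hy)]),
                    hybrid = as.numeric(hy),
                    final = as.numeric(fl$final[names(hy)]),
                    display = as.integer(fl$display[names(hy)]),
                    stringsAsFactors = FALSE)
  attr(out, "floored") <- fl$floored
  out
}
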