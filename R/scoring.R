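#' Score the weighted index and its subscales
#'
#' Factor scores are unit-weighted means of each factor's items. For the
#' full index, stress-load items are reverse-coded (6 - x on the 1-5
#' response scale, or negated on the continuous latent-response scale) so
#' higher overall scores reflect greater resilience. Subscale scores are
#' weight-proportional combinations of the factor scores within each
#' domain; the full index is the final-weight combination of all 10
#' (orientation-corrected) factor scores. Alternative composites
#' (`unweighted`: equal factor weights; `item_level`: grand item mean) are
#' returned for the validation-comparison harness.
#'
#' @param responses n x p response matrix covering all spec items.
#' @param spec a `wone_model_spec`.
#' @param weights named final weight vector (percent, summing to 100); e.g.
#'   the `final` element of [apply_floor()] or the published final column.
#' @param likert whether responses are on the 1-5 category scale (reverse =
#'   6 - x) or continuous latent-response scale (reverse = -x).
#' @return list of class `wone_index_scores`: `factor_scores` (raw, per
#'   domain orientation), `factor_scores_reversed` (stress factors
#'   reverse-coded), `stress_subscale`, `resilience_subscale`, `index`
#'   (weighted), `index_unweighted`, `index_item_level`.
#' @export
score_index <- function(responses, spec, weights, likert = NULL) {
  responses <- as.matrix(responses)
  miss <- setdiff(spec$items$id, colnames(responses))
  if (length(miss) > 0)
    stop("responses missing items: ", paste(miss, collapse = ", "))
  responses <- responses[, spec$items$id, drop = FALSE]
  if (is.null(likert))
    likert <- all(responses >= 1 & responses <= 5 & responses == round(responses))
  if (likert && any(responses < 1 | responses > 5))
    stop("Likert responses must lie in 1..5")
  fids <- spec$factors$id
  if (is.null(names(weights)) || !setequal(names(weights), fids))
    stop("weights must be named with the model's factor ids")
  weights <- weights[fids]
  stress_f <- fids[spec$factors$parent == "StressLoad"]

  fscore <- function(x) rowMeans(x)
  raw <- sapply(fids, function(f) {
    fscore(responses[, spec$items$id[spec$items$factor == f], drop = FALSE])
  })
  rev_items <- function(x) if (likert) 6 - x else -x
  revd <- raw
  for (f in stress_f) {
    cols <- spec$items$id[spec$items$factor == f]
    revd[, f] <- fscore(rev_items(responses[, cols, drop = FALSE]))
  }

  wsub <- function(fsub, mat) {
    w <- weights[fsub] / sum(weights[fsub])
    as.numeric(mat[, fsub, drop = FALSE] %*% w)
  }
  res_f <- setdiff(fids, stress_f)
  stress_sub <- wsub(stress_f, raw)          # raw orientation: higher = more stress
  resil_sub <- wsub(res_f, raw)
  index <- as.numeric(revd %*% (weights / 100))
  index_unw <- rowMeans(revd)
  item_rev <- responses
  sitems <- spec$items$id[spec$items$factor %in% stress_f]
  item_rev[, sitems] <- rev_items(item_rev[, sitems])
  index_item <- rowMeans(item_rev)

  structure(list(factor_scores = raw, factor_scores_reversed = revd,
                 stress_subscale = stress_sub, resilience_subscale = resil_sub,
                 index = index, index_unweighted = index_unw,
                 index_item_level = index_item, weights = weights,
                 likert = likert),
            class = "wone_index_scores")
}

#' Compare weighted, unweighted and item-level composites against criteria
#'
#' Correlates each composite with each criterion scale and flags the best
#' performer per criterion (largest absolute correlation).
#'
#' @param responses n x p response matrix.
#' @param spec a `wone_model_spec`.
#' @param weights named final weight vector (percent).
#' @param criteria a `wone_criteria` or list with a `scores` matrix.
#' @return data.frame with one row per criterion: criterion, weighted,
#'   unweighted, item_level, best.
#' @export
compare_scorers <- function(responses, spec, weights, criteria) {
  sc <- score_index(responses, spec, weights)
  cs <- criteria$scores
  if (is.null(cs)) stop("criteria must carry a `scores` matrix")
  if (nrow(cs) != length(sc$index)) stop("criteria rows must pair with responses")
  out <- lapply(colnames(cs), function(cr) {
    r <- c(weighted = stats::cor(sc$index, cs[, cr]),
           unweighted = stats::cor(sc$index_unweighted, cs[, cr]),
           item_level = stats::cor(sc$index_item_level, cs[, cr]))
    data.frame(criterion = cr, weighted = r["weighted"],
               unweighted = r["unweighted"], item_level = r["item_level"],
               best = names(r)[which.max(abs(r))],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
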