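#' Split an association score map into gold-standard positive sets
#'
#' From a database of gene-disease association scores, derives the two
#' gold-standard groups used to benchmark propagation rankings: genes
#' scoring strictly above the third quartile (the 25% most significant
#' associations) and genes attaining the maximum score. The quartile is
#' computed with R's default type-7 (linear interpolation) definition.
#'
#' @param association_scores named numeric vector: gene -> association
#'   score.
#' @param quantile_type passed to [stats::quantile()]; default 7.
#' @return list with elements `above_Q3` and `max_score`, each a
#'   `gold_standard` object (list with `label` and `positives`). When all
#'   scores are equal `above_Q3` is empty, with a warning, and `max_score`
#'   contains every gene.
#' @export
split_gold_standard <- function(association_scores, quantile_type = 7) {
  s <- association_scores
  if (!length(s) || is.null(names(s))) {
    stop("association_scores must be a nonempty named numeric vector")
  }
  q3 <- unname(quantile(s, 0.75, type = quantile_type))
  above <- names(s)[s > q3]
  if (!length(above)) {
    warning("no gene scores strictly above Q3 (all scores equal?); ",
            "'above_Q3' gold standard is empty")
  }
  maxg <- names(s)[s == max(s)]
  list(above_Q3 = structure(list(label = "above_Q3", positives = above),
                            class = "gold_standard"),
       max_score = structure(list(label = "max_score", positives = maxg),
                             class = "gold_standard"))
}

#' ROC curve and AUC of a score ranking against a gold standard
#'
#' Evaluates how well scores rank a positive gene set above the rest of
#' the scored universe. The AUC is computed by the Mann-Whitney
#' pair-counting identity (ties between a positive and a negative count
#' one half), which equals the trapezoidal area under the empirical ROC
#' curve; the curve itself is returned with thresholds at the distinct
#' score values.
#'
#' @param scores `ppr_scores` or named numeric vector over the evaluation
#'   universe. Negatives are all scored genes not in the positive set.
#' @param gold a `gold_standard` object (see [split_gold_standard()]) or a
#'   character vector of positive genes.
#' @return a `roc_result` object: list with `auc`, `curve` (data.frame of
#'   `fpr`, `tpr` from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, gold) {
  s <- score_vector(scores)
  positives <- if (inherits(gold, "gold_standard")) gold$positives else gold
  pos <- intersect(names(s), positives)
  if (!length(pos)) stop("no positive gene overlaps the scored universe")
  is_pos <- names(s) %in% pos
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_neg == 0) stop("no negative genes left in the scored universe")
  # Mann-Whitney: average rank of positives, ties shared
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # stepwise ROC curve over decreasing distinct thresholds
  ord <- order(s, decreasing = TRUE)
  sp <- s[ord]; ip <- is_pos[ord]
  grp <- cumsum(!duplicated(sp))            # group equal scores
  tp <- cumsum(ip); fp <- cumsum(!ip)
  last <- !duplicated(grp, fromLast = TRUE) # curve point after each tie group
  curve <- data.frame(fpr = c(0, fp[last] / n_neg),
                      tpr = c(0, tp[last] / n_pos))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC = ", format(x$auc, digits = 4), " (", x$n_pos,
      " positives vs ", x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}
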