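#' Essential proteins among the top k of a ranking
#'
#' @param ranking Ordered character vector of protein identifiers (best
#'   first), or an `lds_ranking` tibble.
#' @param essentials Character vector of known essential proteins; every
#'   other ranked protein counts as non-essential.
#' @param k Cutoff, `1 <= k <= length(ranking)`.
#' @return Integer count of true essentials in the top k.
#' @export
topk_essential_count <- function(ranking, essentials, k) {
  ranking <- ranking_ids(ranking)
  if (k < 1 || k > length(ranking)) {
    abort(sprintf("k = %d is out of range [1, %d]", k, length(ranking)))
  }
  sum(head(ranking, k) %in% essentials)
}

ranking_ids <- function(ranking) {
  if (is.data.frame(ranking)) ranking$protein else as.character(ranking)
}

#' Confusion matrix at a ranking cutoff
#'
#' The top `cutoff` proteins are predicted essential, the remainder
#' non-essential; true labels come from `essentials`, with every other
#' ranked protein (including unknowns) treated as non-essential.
#'
#' @inheritParams topk_essential_count
#' @param cutoff Number of top proteins predicted essential.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutoff <- function(ranking, essentials, cutoff) {
  ranking <- ranking_ids(ranking)
  if (cutoff < 1 || cutoff > length(ranking)) {
    abort(sprintf("cutoff = %d is out of range [1, %d]", cutoff, length(ranking)))
  }
  pred <- head(ranking, cutoff)
  rest <- ranking[-seq_len(cutoff)]
  tibble(tp = sum(pred %in% essentials),
         fp = sum(!pred %in% essentials),
         tn = sum(!rest %in% essentials),
         fn = sum(rest %in% essentials))
}

#' Confusion-matrix metrics
#'
#' The six standard ratios: sensitivity `SN = TP/(TP+FN)`, specificity
#' `SP = TN/(TN+FP)`, positive predictive value `PPV = TP/(TP+FP)`, negative
#' predictive value `NPV = TN/(TN+FN)`, the F-measure (harmonic mean of SN
#' and PPV), and accuracy `ACC = (TP+TN)/n`. A 0/0 ratio is defined as 0
#' with a warning (it only arises on degenerate inputs).
#'
#' @param cm One-row tibble or list with `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion_at_cutoff()]).
#' @return One-row tibble `sn`, `sp`, `ppv`, `npv`, `f_measure`, `acc`.
#' @examples
#' classification_metrics(tibble::tibble(tp = 30, fn = 70, tn = 80, fp = 20))
#' @export
classification_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  stopifnot(length(tp) == 1, tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  ratio <- function(num, den) {
    if (den == 0) {
      warn("0/0 ratio in classification metrics; defined as 0")
      return(0)
    }
    num / den
  }
  sn <- ratio(tp, tp + fn)
  sp <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  f <- if (sn + ppv == 0) 0 else 2 * sn * ppv / (sn + ppv)
  acc <- ratio(tp + tn, tp + fp + tn + fn)
  tibble(sn = sn, sp = sp, ppv = ppv, npv = npv, f_measure = f, acc = acc)
}

#' Full evaluation of one ranking
#'
#' Top-k essential counts over a grid of cutoffs plus the six
#' confusion-matrix metrics at a single classification cutoff — the
#' machine-readable analog of a methods-comparison table.
#'
#' @inheritParams confusion_at_cutoff
#' @param ks Top-k grid for enrichment counts (values beyond the ranking
#'   length are dropped).
#' @param cutoff Classification cutoff for the metrics (default 1500,
#'   capped at the ranking length).
#' @return List with `topk` (tibble `k`, `essential_count`) and `metrics`
#'   (one-row tibble: `cutoff`, confusion counts, the six ratios).
#' @export
evaluate_ranking <- function(ranking, essentials, ks = seq(1000, 1500, 100),
                             cutoff = 1500) {
  ids <- ranking_ids(ranking)
  ks <- ks[ks >= 1 & ks <= length(ids)]
  cutoff <- min(cutoff, length(ids))
  topk <- tibble(k = as.integer(ks),
                 essential_count = vapply(ks, function(k) {
                   topk_essential_count(ids, essentials, k)
                 }, integer(1)))
  cm <- confusion_at_cutoff(ids, essentials, cutoff)
  list(topk = topk,
       metrics = dplyr::bind_cols(tibble(cutoff = cutoff), cm,
                                  classification_metrics(cm)))
}
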