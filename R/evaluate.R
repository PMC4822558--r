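#' Confusion counts of document-level predictions
#'
#' Set comparison on `(doc_id, chemical_id, disease_id)` triples:
#' `tp = |pred & gold|`, `fp = |pred \ gold|`, `fn = |gold \ pred|`.
#'
#' @param pred Data frame of predicted triples (`doc_id`, `chemical_id`,
#'   `disease_id`).
#' @param gold Data frame of gold triples (same columns).
#' @return List with integer fields `tp`, `fp`, `fn`.
#' @export
relation_confusion <- function(pred, gold) {
  pk <- unique(paste(pred$doc_id, pred$chemical_id, pred$disease_id))
  gk <- unique(paste(gold$doc_id, gold$chemical_id, gold$disease_id))
  list(tp = length(intersect(pk, gk)),
       fp = length(setdiff(pk, gk)),
       fn = length(setdiff(gk, pk)))
}

#' Precision, recall and F-score
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F = 2PR/(P+R)`, on the percentage
#' scale.  `0/0` is taken as 0.  `F` is computed from the unrounded `P` and
#' `R`; round for reporting.
#'
#' @param counts A list with `tp`, `fp`, `fn` (e.g. from
#'   [relation_confusion()]), or the `tp` count if `fp`/`fn` are given.
#' @param fp,fn Optional counts when `counts` is a scalar `tp`.
#' @return Named numeric vector `c(precision, recall, f)` in percent,
#'   unrounded.
#' @export
precision_recall_f <- function(counts, fp = NULL, fn = NULL) {
  if (is.list(counts)) {
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  } else {
    tp <- counts
  }
  div0 <- function(a, b) if (b == 0) 0 else a / b
  p <- div0(tp, tp + fp)
  r <- div0(tp, tp + fn)
  f <- div0(2 * p * r, p + r)
  c(precision = 100 * p, recall = 100 * r, f = 100 * f)
}

#' Mention-level scores against distant labels
#'
#' Since no manual mention-level annotation exists, instance-level
#' performance is scored approximately against the distant-supervision
#' labels, separately per level.
#'
#' @param instances Labeled instance data frame.
#' @param predictions Data frame from [cid_predict_model()], row-parallel to
#'   `instances` (column `positive`).
#' @return Data frame with one row per level: `level`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f`.
#' @export
mention_level_scores <- function(instances, predictions) {
  stopifnot(nrow(instances) == nrow(predictions))
  rows <- lapply(unique(instances$level), function(lv) {
    sel <- instances$level == lv
    lab <- instances$label[sel]
    pos <- predictions$positive[sel]
    counts <- list(tp = sum(pos & lab), fp = sum(pos & !lab),
                   fn = sum(!pos & lab))
    prf <- precision_recall_f(counts)
    data.frame(level = lv, tp = counts$tp, fp = counts$fp, fn = counts$fn,
               precision = prf[["precision"]], recall = prf[["recall"]],
               f = prf[["f"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluation report
#'
#' @param pred Predicted document-level triples.
#' @param gold Gold triples.
#' @return Data frame with `tp`, `fp`, `fn`, `precision`, `recall`, `f`
#'   (percentages rounded to one decimal for reporting).
#' @export
evaluation_report <- function(pred, gold) {
  counts <- relation_confusion(pred, gold)
  prf <- precision_recall_f(counts)
  data.frame(tp = counts$tp, fp = counts$fp, fn = counts$fn,
             precision = round(prf[["precision"]], 1),
             recall = round(prf[["recall"]], 1),
             f = round(prf[["f"]], 1))
}
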