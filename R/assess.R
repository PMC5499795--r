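# Classifier assessment: confusion counts, the five standard metrics,
# ROC/AUC, threshold-sweep cut-off optimization, and residue-interval
# overlap sensitivity.

#' Construct confusion counts
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return a \code{\link{ConfusionCounts-class}}.
#' @export
ConfusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      tn = as.numeric(tn), fn = as.numeric(fn))
}

.safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from confusion counts
#'
#' Computes the five standard binary-classification metrics:
#' \deqn{SN = TP/(TP+FN), \quad SP = TN/(TN+FP),}
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN),}
#' \deqn{MCC = (TP \cdot TN - FN \cdot FP)/\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)},}
#' \deqn{F = 2 \cdot SN \cdot SP / (SN + SP).}
#' Note the F-measure combines sensitivity and specificity (not
#' precision/recall). Any metric with a zero denominator is defined as 0.
#' Values are kept at full precision; report tables round half-up to 2
#' decimals (\code{\link{metricsVector}}).
#'
#' @param counts a \code{\link{ConfusionCounts-class}}, or tp when the four
#'   counts are given positionally.
#' @param fp,tn,fn optional counts when \code{counts} is tp.
#' @return a \code{\link{Metrics-class}}.
#' @examples
#' metricsVector(classMetrics(ConfusionCounts(tp = 106, fp = 0, tn = 0,
#'                                            fn = 4)), digits = 2)["sn"]
#' @export
classMetrics <- function(counts, fp = NULL, tn = NULL, fn = NULL) {
  if (!is(counts, "ConfusionCounts")) {
    counts <- ConfusionCounts(counts, fp, tn, fn)
  }
  v <- confusionVector(counts)
  tp <- v[["tp"]]; fp <- v[["fp"]]; tn <- v[["tn"]]; fn <- v[["fn"]]
  sn <- .safe_div(tp, tp + fn)
  sp <- .safe_div(tn, tn + fp)
  acc <- .safe_div(tp + tn, tp + tn + fp + fn)
  mcc_den <- sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fn * fp) / mcc_den
  f <- .safe_div(2 * sn * sp, sn + sp)
  new("Metrics", sn = sn, sp = sp, acc = acc, mcc = mcc, fmeasure = f)
}

.check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) .stop_input("labels must be logical (or coercible)")
  if (all(labels) || !any(labels)) {
    .stop_input("degenerate labels: both classes must be present")
  }
  labels
}

#' Receiver operating characteristic curve
#'
#' Sweeps the distinct score values from high to low as thresholds (tied
#' items cross together), recording the false positive rate (1 - SP) and
#' true positive rate (SN) at each; the area under the curve is the
#' trapezoidal area, which for this construction equals the rank-sum
#' (Mann-Whitney) probability that a random positive outscores a random
#' negative (ties counted half).
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels logical (or coercible) true class labels; both classes must
#'   be present.
#' @return a \code{\link{ROCCurve-class}}.
#' @export
rocCurve <- function(scores, labels) {
  labels <- .check_labels(labels)
  if (length(scores) != length(labels)) {
    .stop_input("scores and labels must have equal length")
  }
  nP <- sum(labels)
  nN <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / nP, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / nN, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  new("ROCCurve", points = pts, auc = auc)
}

#' Optimize a parameter cut-off by threshold sweep
#'
#' Sweeps every distinct value of the parameter as a candidate cut-off
#' (\code{direction = "min-threshold"}: items at or above the cut-off are
#' called positive, as for coverage or similarity;
#' \code{"max-threshold"}: items at or below, as for E-values) and picks the
#' cut-off maximizing accuracy. Ties are broken by higher Youden's J
#' (TPR - FPR), then by the less stringent threshold (lower for
#' min-thresholds, higher for max-thresholds). The full sweep table is
#' returned for plotting.
#'
#' @param values per-item parameter values.
#' @param labels true class labels (both classes required).
#' @param direction \code{"min-threshold"} or \code{"max-threshold"}.
#' @return list with \code{threshold}, \code{metrics}
#'   (\code{\link{Metrics-class}} at the chosen cut-off), \code{counts}
#'   (\code{\link{ConfusionCounts-class}}), and \code{sweep} (data.frame of
#'   threshold, tp, fp, tn, fn, sn, sp, acc, youden).
#' @export
optimizeCutoff <- function(values, labels,
                           direction = c("min-threshold", "max-threshold")) {
  direction <- match.arg(direction)
  labels <- .check_labels(labels)
  if (length(values) != length(labels)) {
    .stop_input("values and labels must have equal length")
  }
  thr <- sort(unique(values))
  rows <- lapply(thr, function(t) {
    pred <- if (direction == "min-threshold") values >= t else values <= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
    m <- classMetrics(ConfusionCounts(tp, fp, tn, fn))
    mv <- metricsVector(m)
    data.frame(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
               sn = mv[["sn"]], sp = mv[["sp"]], acc = mv[["acc"]],
               youden = mv[["sn"]] - (1 - mv[["sp"]]))
  })
  sweep <- do.call(rbind, rows)
  best <- sweep$acc == max(sweep$acc)
  best <- best & sweep$youden == max(sweep$youden[best])
  cand <- sweep$threshold[best]
  chosen <- if (direction == "min-threshold") min(cand) else max(cand)
  row <- sweep[sweep$threshold == chosen, ]
  counts <- ConfusionCounts(row$tp, row$fp, row$tn, row$fn)
  list(threshold = chosen, metrics = classMetrics(counts), counts = counts,
       sweep = sweep)
}

#' Overlap of predicted domain sites with annotated binding residues
#'
#' For each protein, the fraction of its annotated binding residues that fall
#' inside the union of its predicted site intervals. A protein is
#' \emph{recovered} when the fraction is positive; the cohort sensitivity is
#' the recovered share of proteins with at least one annotated residue.
#' Proteins without annotated residues are excluded with a warning.
#'
#' @param predicted named list of interval tables (data.frame or matrix with
#'   columns start, end; 1-based inclusive), one entry per protein; proteins
#'   missing from the list count as having no predicted site.
#' @param binding named list of 1-based residue position vectors.
#' @param highOverlap fraction above which a protein counts as
#'   high-overlap (default 0.70).
#' @return list with \code{perProtein} (data.frame: protein_id, n_residues,
#'   n_overlap, fraction, recovered), \code{sensitivity},
#'   \code{nRecovered}, \code{nHighOverlap}, \code{nProteins}.
#' @examples
#' ro <- residueOverlap(list(P1 = data.frame(start = 1, end = 10)),
#'                      list(P1 = c(5L, 10L, 20L)))
#' ro$perProtein$fraction   # 2/3
#' @export
residueOverlap <- function(predicted, binding, highOverlap = 0.70) {
  ids <- names(binding)
  empty <- vapply(binding, function(p) length(p) == 0L, logical(1))
  if (any(empty)) {
    warning(sum(empty), " protein(s) without annotated residues excluded",
            call. = FALSE)
    ids <- ids[!empty]
  }
  rows <- lapply(ids, function(id) {
    pos <- as.integer(binding[[id]])
    iv <- predicted[[id]]
    inside <- rep(FALSE, length(pos))
    if (!is.null(iv) && nrow(iv) > 0L) {
      iv <- as.data.frame(iv)
      names(iv)[1:2] <- c("start", "end")
      for (k in seq_len(nrow(iv))) {
        inside <- inside | (pos >= iv$start[k] & pos <= iv$end[k])
      }
    }
    data.frame(protein_id = id, n_residues = length(pos),
               n_overlap = sum(inside), fraction = mean(inside),
               recovered = any(inside), stringsAsFactors = FALSE)
  })
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), n_residues = integer(0),
               n_overlap = integer(0), fraction = numeric(0),
               recovered = logical(0))
  list(perProtein = per,
       sensitivity = if (nrow(per)) mean(per$recovered) else NA_real_,
       nRecovered = sum(per$recovered),
       nHighOverlap = sum(per$fraction > highOverlap),
       nProteins = nrow(per))
}
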