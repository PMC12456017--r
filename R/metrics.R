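# metrics_eval: confusion matrices, the four evaluation metrics, and the
# tetranucleotide-threshold sweep producing ROC/PR points.

#' Construct a confusion matrix
#'
#' @param tp,fp,fn,tn Non-negative counts; the positive class is CHROMID.
#' @return A [ConfusionMatrix-class].
#' @examples
#' cm <- confusionMatrix(33, 0, 12, 111)
#' accuracy(cm)   # 92.31
#' @export
confusionMatrix <- function(tp, fp, fn, tn) {
  new("ConfusionMatrix", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: TP=%d FP=%d FN=%d TN=%d\n",
              object@tp, object@fp, object@fn, object@tn))
})

#' Tally a confusion matrix from calls and truth
#'
#' The positive class is CHROMID: a prediction is positive iff the call is
#' CHROMID (OTHER, CHROMOSOME and UNASSIGNED all count as negative
#' predictions), and a replicon is a true positive iff the truth labels it
#' CHROMID. Every truth id must be present among the calls and vice versa.
#'
#' @param result A [ChromidClassification-class] or calls data.frame.
#' @param truth data.frame with columns `replicon_id` and `role`
#'   (CHROMOSOME / CHROMID / PLASMID), e.g. from [generateBenchmark()].
#' @return A [ConfusionMatrix-class].
#' @export
chromidConfusion <- function(result, truth) {
  calls <- .callsOf(result)
  orphanTruth <- setdiff(truth$replicon_id, calls$replicon_id)
  orphanCalls <- setdiff(calls$replicon_id, truth$replicon_id)
  if (length(orphanTruth) || length(orphanCalls))
    stop("id mismatch between calls and truth; orphans: ",
         paste(c(orphanTruth, orphanCalls), collapse = ", "))
  pred <- calls$role[match(truth$replicon_id, calls$replicon_id)] == "CHROMID"
  pos <- truth$role == "CHROMID"
  confusionMatrix(tp = sum(pred & pos), fp = sum(pred & !pos),
                  fn = sum(!pred & pos), tn = sum(!pred & !pos))
}

# round half-up to `digits` decimals (72.335 -> 72.34, not banker's)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

.metricPct <- function(num, denom, what) {
  if (denom == 0) {
    warning(what, " undefined: zero denominator")
    return(NaN)
  }
  roundHalfUp(100 * num / denom, 2)
}

#' Evaluation metrics on a confusion matrix
#'
#' The four classifier metrics, each as a percentage rounded half-up to two
#' decimals: accuracy = (TP + TN) / (TP + FP + FN + TN); precision =
#' TP / (TP + FP); TPR (sensitivity/recall) = TP / (TP + FN); FPR =
#' FP / (FP + TN). A zero denominator yields `NaN` with a warning rather
#' than an error.
#'
#' @param x A [ConfusionMatrix-class].
#' @param ... Unused.
#' @return Percentage (0–100), rounded half-up to 2 decimals.
#' @name metrics
#' @aliases accuracy precision tpr fpr
NULL

#' @rdname metrics
#' @export
setMethod("accuracy", "ConfusionMatrix", function(x, ...)
  .metricPct(x@tp + x@tn, x@tp + x@fp + x@fn + x@tn, "accuracy"))

#' @rdname metrics
#' @export
setMethod("precision", "ConfusionMatrix", function(x, ...)
  .metricPct(x@tp, x@tp + x@fp, "precision"))

#' @rdname metrics
#' @export
setMethod("tpr", "ConfusionMatrix", function(x, ...)
  .metricPct(x@tp, x@tp + x@fn, "TPR"))

#' @rdname metrics
#' @export
setMethod("fpr", "ConfusionMatrix", function(x, ...)
  .metricPct(x@fp, x@fp + x@tn, "FPR"))

#' Sweep the tetranucleotide distance threshold
#'
#' Runs steps 1–3 of the pooled pipeline (gene prediction, marker scan,
#' DnaA-centered clustering) once, then re-applies only the step-4 distance
#' filter for each threshold of the grid — the threshold only comes into
#' play at step 4, so the sweep is cheap. Returns one ROC/PR point per
#' threshold. `Inf` is a valid sentinel at which every cluster member
#' passes.
#'
#' @param pool A [RepliconSet-class] of pooled replicons.
#' @param truth Truth table as for [chromidConfusion()].
#' @param db A [MarkerDatabase-class].
#' @param thresholds Base [ChromidThresholds-class]; `tetraDistMax` is
#'   replaced by each grid value in turn.
#' @param grid Numeric vector of thresholds, sorted ascending.
#' @param backend,eThreshold Passed to the pipeline stages.
#' @return data.frame with columns `threshold`, `tp`, `fp`, `fn`, `tn`,
#'   `tpr`, `fpr`, `precision`, `recall` (percentages; `recall` duplicates
#'   `tpr` by definition).
#' @seealso [aucTrapezoid()]
#' @export
thresholdSweep <- function(pool, truth, db,
                           thresholds = chromidThresholds(), grid,
                           backend = c("naive", "prodigal"),
                           eThreshold = 1e-5) {
  backend <- match.arg(backend)
  if (length(grid) == 0L) stop("threshold grid is empty")
  if (is.unsorted(grid)) stop("threshold grid must be sorted ascending")
  state <- .chromidFinderState(pool, db, thresholds, backend = backend,
                               eThreshold = eThreshold)
  rows <- lapply(grid, function(g) {
    th <- thresholds
    th@tetraDistMax <- g
    cm <- chromidConfusion(.finishChromidFinder(state, th), truth)
    data.frame(threshold = g, tp = cm@tp, fp = cm@fp, fn = cm@fn,
               tn = cm@tn, tpr = tpr(cm), fpr = fpr(cm),
               precision = suppressWarnings(precision(cm)),
               recall = tpr(cm))
  })
  do.call(rbind, rows)
}

#' Trapezoidal area under a curve
#'
#' Intended for ROC (x = FPR, y = TPR) or PR points from
#' [thresholdSweep()]; points are sorted by x and the curve is anchored
#' at (0, 0) and (max x, last y) implicitly only through the supplied
#' points — supply boundary points yourself if you want them included.
#'
#' @param x,y Coordinates in percent or fractions (same unit).
#' @return The trapezoidal integral of y over x.
#' @export
aucTrapezoid <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
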