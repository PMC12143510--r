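# Confusion-matrix benchmarking of a predicted gene set against a curated
# driver list (e.g., the Cancer Gene Census) over an explicit gene universe.

#' Confusion-matrix metrics for a predicted gene set
#'
#' Computes TP, FP, FN, TN and accuracy = (TP+TN)/(TP+TN+FP+FN),
#' precision = TP/(TP+FP), recall = TP/(TP+FN) for a predicted gene set
#' against a benchmark driver list. Because TN (and therefore accuracy)
#' depends on the assumed gene universe, the universe is a required,
#' explicit argument. Predicted or benchmark genes outside the universe
#' are dropped (predicted genes with a warning). When a metric's
#' denominator is zero it is reported as 0 and flagged.
#'
#' @param predicted Character vector of predicted genes.
#' @param benchmark Character vector of known driver genes (truth).
#' @param universe Character vector of all genes under consideration.
#' @return An object of class `confusion_metrics`: list with `TP`, `FP`,
#'   `FN`, `TN`, `universe_size`, `accuracy`, `precision`, `recall`,
#'   `precision_defined`, `recall_defined`.
#' @examples
#' confusion_metrics(c("A", "B"), c("B", "C"), c("A", "B", "C", "D", "E"))
#' @export
confusion_metrics <- function(predicted, benchmark, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  predicted <- unique(predicted)
  benchmark <- unique(benchmark)
  outside <- setdiff(predicted, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " predicted gene(s) outside the universe dropped",
            call. = FALSE)
    predicted <- intersect(predicted, universe)
  }
  benchmark <- intersect(benchmark, universe)
  TP <- length(intersect(predicted, benchmark))
  FP <- length(setdiff(predicted, benchmark))
  FN <- length(setdiff(benchmark, predicted))
  TN <- length(universe) - TP - FP - FN
  precision_defined <- (TP + FP) > 0L
  recall_defined <- (TP + FN) > 0L
  structure(list(
    TP = TP, FP = FP, FN = FN, TN = TN,
    universe_size = length(universe),
    accuracy = (TP + TN) / length(universe),
    precision = if (precision_defined) TP / (TP + FP) else 0,
    recall = if (recall_defined) TP / (TP + FN) else 0,
    precision_defined = precision_defined,
    recall_defined = recall_defined),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d TN=%d (universe %d)\n",
              x$TP, x$FP, x$FN, x$TN, x$universe_size))
  cat(sprintf("accuracy=%.4f precision=%.4f%s recall=%.4f%s\n",
              x$accuracy,
              x$precision, if (x$precision_defined) "" else " (undefined)",
              x$recall, if (x$recall_defined) "" else " (undefined)"))
  invisible(x)
}
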