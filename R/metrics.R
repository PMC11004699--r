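#' Binary confusion counts
#'
#' Tallies true/false positives and negatives of a binary prediction
#' against the truth, given which label is the positive class.
#'
#' @param truth,predicted equal-length label vectors drawing on at most
#'   two distinct labels overall.
#' @param positive the label counted as positive (default 1).
#' @return A \linkS4class{ConfusionCounts}.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))  # tp=1 fn=1 tn=1 fp=1
#' @export
confusionCounts <- function(truth, predicted, positive = 1) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  if (length(truth) < 1L) stop("at least one observation is required")
  labs <- unique(c(as.character(truth), as.character(predicted)))
  if (length(labs) > 2L)
    stop("labels must be binary; found: ", paste(labs, collapse = ", "))
  pos <- as.character(positive)
  if (!(pos %in% labs) && length(labs) == 2L)
    stop("positive label '", pos, "' does not occur in the data")
  tpos <- as.character(truth) == pos
  ppos <- as.character(predicted) == pos
  new("ConfusionCounts",
      tp = as.integer(sum(tpos & ppos)),
      tn = as.integer(sum(!tpos & !ppos)),
      fp = as.integer(sum(!tpos & ppos)),
      fn = as.integer(sum(tpos & !ppos)))
}

.safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Full confusion-matrix metric report
#'
#' Computes the eight classification metrics from binary confusion
#' counts: accuracy \eqn{(TP+TN)/n}, sensitivity \eqn{TP/(TP+FN)},
#' specificity \eqn{TN/(TN+FP)}, precision \eqn{= PPV = TP/(TP+FP)},
#' NPV \eqn{TN/(TN+FN)}, F1
#' \eqn{2 \cdot \mathrm{prec} \cdot \mathrm{sens} /
#' (\mathrm{prec} + \mathrm{sens})}, and the Matthews correlation
#' coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}} \in [-1, 1].}
#' A metric whose denominator is zero is reported as \code{NA}
#' (undefined) without failing the rest of the report.
#'
#' @param counts a \linkS4class{ConfusionCounts}, or truth labels (then
#'   \code{predicted}/\code{positive} are forwarded to
#'   \code{\link{confusionCounts}}).
#' @param predicted,positive see \code{\link{confusionCounts}}.
#' @param percent logical; report on the 0-100 scale instead of 0-1.
#' @return Named list with elements \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{precision}, \code{f1}, \code{mcc},
#'   \code{ppv}, \code{npv}.
#' @examples
#' metricReport(confusionCounts(rep(1:0, c(50, 50)), rep(1:0, c(45, 55))))
#' @export
metricReport <- function(counts, predicted = NULL, positive = 1,
                         percent = FALSE) {
  if (!is(counts, "ConfusionCounts"))
    counts <- confusionCounts(counts, predicted, positive)
  tp <- as.numeric(counts@tp); tn <- as.numeric(counts@tn)
  fp <- as.numeric(counts@fp); fn <- as.numeric(counts@fn)
  total <- tp + tn + fp + fn
  sens <- .safeRatio(tp, tp + fn)
  spec <- .safeRatio(tn, tn + fp)
  prec <- .safeRatio(tp, tp + fp)
  npv  <- .safeRatio(tn, tn + fn)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  mccDen <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mccDen == 0) NA_real_ else (tp * tn - fp * fn) / mccDen
  report <- list(accuracy = .safeRatio(tp + tn, total),
                 sensitivity = sens, specificity = spec, precision = prec,
                 f1 = f1, mcc = mcc, ppv = prec, npv = npv)
  if (percent) report <- lapply(report, function(v) v * 100)
  report
}

#' Write a metric report to disk
#'
#' @param report a list from \code{\link{metricReport}}.
#' @param path output path; format follows the extension (\code{.json} or
#'   \code{.csv}).
#' @return The path, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE,
                         na = "null")
  } else {
    utils::write.csv(
      data.frame(metric = names(report), value = unlist(report),
                 row.names = NULL),
      path, row.names = FALSE)
  }
  invisible(path)
}
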