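#' Confusion counts for binary PPI predictions
#'
#' @param truth,estimate Binary vectors (0/1) of equal length; 1 =
#'   interacting.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate have different lengths", class = "mldppi_error_config")
  }
  truth <- as.integer(truth)
  estimate <- as.integer(estimate)
  if (!all(truth %in% c(0L, 1L)) || !all(estimate %in% c(0L, 1L))) {
    abort("truth and estimate must be binary 0/1", class = "mldppi_error_validation")
  }
  tibble(
    tp = sum(truth == 1L & estimate == 1L),
    fp = sum(truth == 0L & estimate == 1L),
    tn = sum(truth == 0L & estimate == 0L),
    fn = sum(truth == 1L & estimate == 0L)
  )
}

#' The seven standard confusion-matrix metrics
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value, F-score and Matthews correlation coefficient from raw
#' confusion counts:
#' \deqn{ACC = (TP+TN)/(TP+FP+TN+FN)}
#' \deqn{SN = TP/(TP+FN), \quad Spec = TN/(TN+FP)}
#' \deqn{PPV = TP/(TP+FP), \quad NPV = TN/(TN+FN)}
#' \deqn{F = 2 \cdot SN \cdot PPV / (SN + PPV)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}
#' A metric whose denominator is zero is reported as 0 with `undefined =
#' TRUE`, never as a silent `NaN`.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts, or pass a one-row
#'   tibble from [confusion_counts()] as `tp` and leave the rest missing.
#' @return A tibble with columns `metric` (acc, sn, spec, ppv, npv, f_score,
#'   mcc), `value` (fraction; MCC in \[-1, 1\]), `percent` (value x 100) and
#'   `undefined`.
#' @examples
#' classification_metrics(tp = 8, fp = 3, tn = 7, fn = 2)
#' @export
classification_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    cc <- tp
    tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) {
    abort("cannot compute metrics from an empty confusion matrix",
          class = "mldppi_error_validation")
  }
  safe_div <- function(num, den) {
    if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  }
  acc <- c((tp + tn) / total, FALSE)
  sn <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  f <- if (sn[2] || ppv[2] || (sn[1] + ppv[1]) == 0) {
    c(0, TRUE)
  } else {
    c(2 * sn[1] * ppv[1] / (sn[1] + ppv[1]), FALSE)
  }
  mcc_den <- sqrt(prod(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  mcc <- if (mcc_den == 0) c(0, TRUE) else c((tp * tn - fp * fn) / mcc_den, FALSE)
  vals <- rbind(acc = acc, sn = sn, spec = spec, ppv = ppv, npv = npv,
                f_score = f, mcc = mcc)
  tibble(
    metric = rownames(vals),
    value = unname(vals[, 1]),
    percent = unname(vals[, 1]) * 100,
    undefined = unname(as.logical(vals[, 2]))
  )
}

# Wide one-row form used when aggregating folds.
metrics_wide <- function(metrics_tbl) {
  out <- as.list(setNames(metrics_tbl$value, metrics_tbl$metric))
  as_tibble(out)
}
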