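#' Confusion counts at a score threshold
#'
#' A residue is called positive when its score is greater than or equal to
#' the threshold (the boundary counts positive).
#'
#' @param scores Numeric scores in `[0,1]`.
#' @param labels Binary labels (logical or 0/1).
#' @param threshold Positive-call cutoff (default 0.5).
#' @return Tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) stop("confusion: empty input")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  labels <- as.logical(labels)
  call <- scores >= threshold
  tibble::tibble(tp = sum(call & labels), fp = sum(call & !labels),
                 tn = sum(!call & !labels), fn = sum(!call & labels))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`.
#' When any denominator factor is zero the value is undefined and `NA` is
#' returned (never silently zeroed).
#'
#' @param c Confusion tibble from [confusion()].
#' @return MCC, or `NA` when undefined.
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  tn <- as.numeric(c$tn); fn <- as.numeric(c$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  ifelse(den == 0, NA_real_, (tp * tn - fp * fn) / sqrt(den))
}

#' Threshold metrics in percent
#'
#' `q_total` is the percentage of correctly classified residues;
#' `ppv` (precision) is `100*TP/(TP+FP)`; `sensitivity` (recall) is
#' `100*TP/(TP+FN)`; `specificity` is `100*TN/(TN+FP)`. Zero denominators
#' yield `NA`.
#'
#' @param c Confusion tibble from [confusion()].
#' @return Percentage value(s).
#' @export
q_total <- function(c) {
  n <- c$tp + c$fp + c$tn + c$fn
  ifelse(n == 0, NA_real_, 100 * (c$tp + c$tn) / n)
}

#' @rdname q_total
#' @export
ppv <- function(c) {
  d <- c$tp + c$fp
  ifelse(d == 0, NA_real_, 100 * c$tp / d)
}

#' @rdname q_total
#' @export
sensitivity <- function(c) {
  d <- c$tp + c$fn
  ifelse(d == 0, NA_real_, 100 * c$tp / d)
}

#' @rdname q_total
#' @export
specificity <- function(c) {
  d <- c$tn + c$fp
  ifelse(d == 0, NA_real_, 100 * c$tn / d)
}

#' ROC curve and area under it
#'
#' The ROC traces sensitivity against the false-positive rate over all
#' score thresholds, grouping tied scores; the AUC is the trapezoidal
#' integral, equivalent to the normalized Mann-Whitney U statistic with
#' half credit for ties.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; both classes must be present.
#' @return A `bturn_roc`: list with `points` (tibble `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0 || N == 0) stop("roc_auc requires both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  grp <- cumsum(!duplicated(s))                      # tie groups
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last <- which(!duplicated(grp, fromLast = TRUE))   # end of each tie group
  pts <- tibble::tibble(threshold = s[last],
                        fpr = fp[last] / N, tpr = tp[last] / P)
  pts <- dplyr::bind_rows(tibble::tibble(threshold = Inf, fpr = 0, tpr = 0),
                          pts)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "bturn_roc")
}

#' @export
print.bturn_roc <- function(x, ...) {
  cat(sprintf("<bturn_roc: AUC = %.4f, %d points>\n", x$auc,
              nrow(x$points)))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#' @param object A `bturn_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bturn_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "False positive rate", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::coord_equal()
}

#' Full residue-level metric set
#'
#' @param scores,labels As in [confusion()].
#' @param threshold Positive-call cutoff.
#' @return One-row tibble: the four confusion counts, `mcc`, `q_total`,
#'   `ppv`, `sensitivity`, `specificity` (percent), `auc`, `threshold`.
#' @export
metric_set <- function(scores, labels, threshold = 0.5) {
  cc <- confusion(scores, labels, threshold)
  dplyr::mutate(cc,
                mcc = mcc(cc), q_total = q_total(cc), ppv = ppv(cc),
                sensitivity = sensitivity(cc), specificity = specificity(cc),
                auc = roc_auc(scores, labels)$auc,
                threshold = threshold)
}

#' Sweep the positive-call threshold
#'
#' Evaluates MCC and Q_total over a threshold grid and reports both curves
#' together with the argmax threshold of each (the Q_total optimum
#' typically sits above the MCC optimum when positives are the minority
#' class).
#'
#' @param scores,labels As in [confusion()].
#' @param step Grid step on `[0, 1]` (default 0.01).
#' @return A `bturn_sweep`: list with `curve` (tibble `threshold`, `mcc`,
#'   `q_total`), `best_mcc_threshold`, `best_q_total_threshold`.
#' @export
threshold_sweep <- function(scores, labels, step = 0.01) {
  grid <- seq(0, 1, by = step)
  rows <- purrr::map(grid, function(th) {
    cc <- confusion(scores, labels, th)
    tibble::tibble(threshold = th, mcc = mcc(cc), q_total = q_total(cc))
  })
  curve <- dplyr::bind_rows(rows)
  structure(list(
    curve = curve,
    best_mcc_threshold = curve$threshold[which.max(curve$mcc)],
    best_q_total_threshold = curve$threshold[which.max(curve$q_total)]
  ), class = "bturn_sweep")
}

#' @export
print.bturn_sweep <- function(x, ...) {
  cat(sprintf(paste0("<bturn_sweep: best MCC at %.2f, ",
                     "best Q_total at %.2f>\n"),
              x$best_mcc_threshold, x$best_q_total_threshold))
  invisible(x)
}

#' Plot MCC and Q_total against the call threshold
#' @param object A `bturn_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bturn_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("mcc", "q_total"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Positive-call threshold", y = NULL)
}

# Hanley-McNeil standard error of an AUC estimate
.auc_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Unpaired test for a difference between two AUCs
#'
#' Two-sided z-test on the AUC difference of two score vectors over the
#' same labels, with Hanley-McNeil standard errors combined as for two
#' independent samples.
#'
#' @param scores_a,scores_b Two score vectors.
#' @param labels Binary labels shared by both.
#' @return Tibble with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
auc_difference_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  a <- roc_auc(scores_a, labels)$auc
  b <- roc_auc(scores_b, labels)$auc
  P <- sum(labels)
  N <- sum(!labels)
  se <- sqrt(.auc_se(a, P, N)^2 + .auc_se(b, P, N)^2)
  z <- if (a == b) 0 else (a - b) / se
  tibble::tibble(auc_a = a, auc_b = b, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}
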