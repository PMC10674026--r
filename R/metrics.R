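#' Pixel confusion matrix between predicted and ground-truth masks
#'
#' Counts are restricted to FOV pixels when a FOV mask is given.
#'
#' @param pred_mask,gt_mask Binary matrices of equal shape.
#' @param fov_mask Optional binary matrix; only pixels inside it are counted.
#' @return A `confusion_matrix`: list with integer `TN`, `FP`, `FN`, `TP`.
#' @export
confusion <- function(pred_mask, gt_mask, fov_mask = NULL) {
  if (!all(dim(pred_mask) == dim(gt_mask)))
    stop("shape mismatch between predicted and ground-truth masks",
         call. = FALSE)
  chk <- function(m, what) {
    if (!all(m %in% c(0, 1)))
      stop(sprintf("validation error: %s is not binary", what), call. = FALSE)
  }
  chk(pred_mask, "pred_mask"); chk(gt_mask, "gt_mask")
  sel <- if (is.null(fov_mask)) rep(TRUE, length(gt_mask)) else fov_mask > 0
  p <- pred_mask[sel] > 0
  g <- gt_mask[sel] > 0
  structure(list(TN = sum(!p & !g), FP = sum(p & !g),
                 FN = sum(!p & g), TP = sum(p & g)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  # Table-style layout: [(TN) (FP) (FN) (TP)]
  cat(sprintf("[[%d %d][%d %d]]\n", x$TN, x$FP, x$FN, x$TP))
  invisible(x)
}

cm_total <- function(cm) cm$TN + cm$FP + cm$FN + cm$TP

undefined_ratio <- function(num, den) {
  if (den <= 0) {
    warning("undefined metric: zero denominator", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Confusion-matrix metrics
#'
#' Exact ratios as conventionally defined for binary vessel maps:
#' accuracy (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), sensitivity (recall)
#' TP/(TP+FN), F1 the harmonic mean of precision and sensitivity
#' (equivalently 2TP/(2TP+FP+FN)), Jaccard TP/(TP+FP+FN).  Undefined ratios
#' (zero denominator) return `NA` with a warning rather than a silent 0.
#'
#' @param cm A [confusion()] result.
#' @return A fraction in \[0, 1\], or `NA` when undefined.
#' @export
accuracy <- function(cm) {
  if (cm_total(cm) == 0)
    stop("degenerate input: empty confusion matrix", call. = FALSE)
  (cm$TP + cm$TN) / cm_total(cm)
}

#' @rdname accuracy
#' @export
precision <- function(cm) undefined_ratio(cm$TP, cm$TP + cm$FP)

#' @rdname accuracy
#' @export
sensitivity <- function(cm) undefined_ratio(cm$TP, cm$TP + cm$FN)

#' @rdname accuracy
#' @export
f1_score <- function(cm) undefined_ratio(2 * cm$TP, 2 * cm$TP + cm$FP + cm$FN)

#' @rdname accuracy
#' @export
jaccard <- function(cm) undefined_ratio(cm$TP, cm$TP + cm$FP + cm$FN)

#' Area under the ROC curve of a probability map
#'
#' Trapezoidal area under the TPR/FPR curve swept over all distinct predicted
#' values (equal to the Mann--Whitney pairwise-ordering probability with ties
#' counted half).
#'
#' @param prob_map Matrix/array of probabilities.
#' @param gt_mask Binary ground truth of the same shape.
#' @param fov_mask Optional binary matrix restricting evaluation.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(prob_map, gt_mask, fov_mask = NULL) {
  sel <- if (is.null(fov_mask)) rep(TRUE, length(gt_mask)) else fov_mask > 0
  p <- as.vector(prob_map)[sel]
  g <- as.vector(gt_mask)[sel] > 0
  npos <- sum(g); nneg <- sum(!g)
  if (npos == 0 || nneg == 0)
    stop("degenerate input: ground truth contains a single class",
         call. = FALSE)
  o <- order(p, decreasing = TRUE)
  po <- p[o]; go <- g[o]
  grp <- cumsum(c(TRUE, diff(po) != 0))       # threshold groups
  tp <- cumsum(go); fp <- cumsum(!go)
  last <- c(which(diff(grp) != 0), length(po))
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Wilcoxon rank-sum test (two-sample, two-sided)
#'
#' Midrank statistic (sum of pooled ranks of the first sample).  The p-value
#' is exact by enumeration of all rank assignments when both groups have at
#' most 10 observations (ties handled naturally by enumerating the observed
#' midranks), and a tie-corrected normal approximation otherwise.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `statistic` (rank sum of `sample_a`) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("invalid parameter: empty sample", call. = FALSE)
  n1 <- length(sample_a); n2 <- length(sample_b)
  N <- n1 + n2
  r <- rank(c(sample_a, sample_b))            # midranks
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (n1 <= 10 && n2 <= 10) {
    sums <- utils::combn(N, n1, function(ix) sum(r[ix]))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- table(r)
    tiecorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tiecorr)
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
  }
  list(statistic = W, p.value = p)
}

#' All confusion-based metrics plus AUC for one prediction
#'
#' @param prob_map Probability matrix.
#' @param gt_mask Binary ground truth.
#' @param fov_mask Optional FOV mask.
#' @param threshold Probability cut for the binary metrics (default 0.5).
#' @return One-row [tibble::tibble()] with accuracy, precision, sensitivity,
#'   f1, jaccard and auc.
#' @export
metrics_report <- function(prob_map, gt_mask, fov_mask = NULL,
                           threshold = 0.5) {
  cm <- confusion((prob_map >= threshold) * 1, gt_mask, fov_mask)
  tibble::tibble(accuracy = accuracy(cm),
                 precision = precision(cm),
                 sensitivity = sensitivity(cm),
                 f1 = f1_score(cm),
                 jaccard = jaccard(cm),
                 auc = roc_auc(prob_map, gt_mask, fov_mask))
}
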