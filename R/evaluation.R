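# Evaluation statistics for paired EF predictions and HFrEF classification:
# Pearson correlation, paired t-test, ROC/AUC, percentile-bootstrap
# confidence intervals and the confusion matrix. Classical exact-distribution
# tests (t, F) are used throughout; AUC counts ties as 1/2 (the Mann-Whitney
# convention).

#' Pearson correlation with its two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r` and `p` (t-transform with n - 2 df).
#' @export
pearson_r <- function(x, y) {
  stop_if(length(x) != length(y), "x and y must have equal length")
  stop_if(length(x) < 3, "need at least 3 pairs")
  stop_if(sd(x) == 0 || sd(y) == 0, "undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired Student's t-test
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the differences `d = x - y`; two-sided
#' p with n - 1 df.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with `t` and `p`.
#' @export
paired_t <- function(x, y) {
  stop_if(length(x) != length(y), "x and y must have equal length")
  stop_if(length(x) < 2, "need at least 2 pairs")
  d <- x - y
  stop_if(sd(d) == 0, "degenerate test: differences have zero variance")
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' ROC curve and AUC for a binary outcome
#'
#' AUC is the probability that a random positive outranks a random negative,
#' ties counting 1/2; the curve is evaluated at every distinct threshold.
#' Optionally a percentile-bootstrap CI on the AUC (resampling subjects).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1 or logical); both classes required.
#' @param n_boot bootstrap replicates for the CI, or `NULL` to skip.
#' @param level CI level in percent.
#' @param seed bootstrap seed.
#' @return A `ROCResult`: list with `auc`, `thresholds`, `tpr`, `fpr`, `ci`.
#' @export
roc_auc <- function(scores, labels, n_boot = NULL, level = 95, seed = 1L) {
  labels <- as.integer(labels)
  stop_if(length(unique(labels)) < 2, "labels must contain both classes")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ci <- NULL
  if (!is.null(n_boot)) {
    dat <- data.frame(scores = scores, labels = labels)
    ci <- bootstrap_ci(function(d) {
      if (length(unique(d$labels)) < 2) stop("single-class resample")
      as.numeric(pROC::auc(pROC::roc(response = d$labels, predictor = d$scores,
                                     levels = c(0, 1), direction = "<",
                                     quiet = TRUE)))
    }, dat, n_boot = n_boot, level = level, seed = seed)
  }
  structure(list(auc = as.numeric(pROC::auc(r)),
                 thresholds = r$thresholds,
                 tpr = r$sensitivities,
                 fpr = 1 - r$specificities,
                 ci = ci),
            class = "ROCResult")
}

#' Percentile-bootstrap confidence interval of a statistic
#'
#' Resamples the data with replacement `n_boot` times (rows for a data.frame,
#' elements otherwise) and returns the percentile interval of the statistic.
#' A resample on which the statistic fails is redrawn, at most 10 times, then
#' an error is raised.
#'
#' @param stat function of a sample returning one number.
#' @param data vector or data.frame.
#' @param n_boot replicates (default 100).
#' @param level interval level in percent (default 95).
#' @param seed RNG seed; the same seed reproduces the interval exactly.
#' @return named numeric `c(lo =, hi =)`.
#' @export
bootstrap_ci <- function(stat, data, n_boot = 100L, level = 95, seed = 1L) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  stop_if(n == 0, "data must be non-empty")
  take <- function(idx) if (is.data.frame(data)) data[idx, , drop = FALSE]
                        else data[idx]
  vals <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    for (try in 1:11) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(stat(take(idx)), error = function(e) NULL)
      if (!is.null(v)) return(v)
      if (try == 11) stop("statistic failed on 10 consecutive resamples")
    }
  }, numeric(1)))
  alpha <- (100 - level) / 200
  q <- quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Confusion matrix of binary HFrEF flags
#'
#' @param pred,ref binary vectors (logical or 0/1) of equal length;
#'   `1`/`TRUE` = HFrEF.
#' @return A `ConfusionMatrix`: list with counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, ref) {
  stop_if(length(pred) != length(ref), "pred and ref must have equal length")
  pred <- as.logical(pred); ref <- as.logical(ref)
  structure(list(tp = sum(pred & ref), fp = sum(pred & !ref),
                 tn = sum(!pred & !ref), fn = sum(!pred & ref)),
            class = "ConfusionMatrix")
}
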