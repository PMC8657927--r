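# Model validation: confusion-matrix metrics, Roy's rm2 external
# predictivity metric, and the standardization-approach applicability
# domain.

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, tn = 0, fp = 0, fn = 0) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("at least one count must be positive")
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' `TPR = TP / (TP + FN)` (sensitivity), `TNR = TN / (FP + TN)`
#' (specificity). A metric whose denominator vanishes is reported as
#' `NA` ("undefined"), never silently 0.
#'
#' @param counts a `confusion_counts` object.
#' @return list with `mcc`, `tpr`, `tnr` (numeric or NA).
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  list(mcc = mcc, tpr = tpr, tnr = tnr)
}

#' Roy's rm2 external-predictivity metric
#'
#' `r2` is the squared Pearson correlation of observed vs predicted;
#' `r0_2` the coefficient of determination of the through-origin
#' regression of observed on predicted (slope `k = sum(o*p) / sum(p^2)`,
#' `r0_2 = 1 - sum((o - k p)^2) / sum((o - mean(o))^2)`); and
#' `rm2 = r2 * (1 - sqrt(max(r2 - r0_2, 0)))`. Values above 0.5 are
#' conventionally read as good external predictability.
#'
#' @param observed,predicted numeric vectors, `n >= 3`.
#' @return list with `r2`, `r0_2`, `rm2` and logical `good_external`
#'   (`rm2 > 0.5`). Constant predictions give `NA` metrics.
#' @export
rm_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L)
    stop("need >= 3 paired values")
  if (sd(observed) == 0) stop("observed values have zero variance")
  if (sd(predicted) == 0)
    return(list(r2 = NA_real_, r0_2 = NA_real_, rm2 = NA_real_,
                good_external = NA))
  r2 <- cor(observed, predicted)^2
  k <- sum(observed * predicted) / sum(predicted^2)
  r0_2 <- 1 - sum((observed - k * predicted)^2) /
    sum((observed - mean(observed))^2)
  rm2 <- r2 * (1 - sqrt(max(r2 - r0_2, 0)))
  list(r2 = r2, r0_2 = r0_2, rm2 = rm2, good_external = rm2 > 0.5)
}

#' Applicability domain by the standardization approach
#'
#' Each query descriptor is standardized against the training mean and SD:
#' `s_ki = |x_ki - mu_i| / sigma_i`. A compound is inside the domain when
#' its maximum score is <= 3; outside when even its minimum score exceeds
#' 3; otherwise the decision falls to `S_k = mean_i(s_ki) +
#' 1.28 * sd_i(s_ki)` (90th-percentile normal quantile), inside iff
#' `S_k <= 3`. Constant training columns are dropped with a warning.
#'
#' @param X_train training descriptor matrix.
#' @param X_query query descriptor matrix (same columns).
#' @param cutoff domain cutoff in SD units (default 3).
#' @return data.frame per query compound: `mean_score`, `max_score`,
#'   `min_score`, `snew` (the composite score, NA when not needed) and
#'   logical `in_domain`.
#' @export
applicability_domain <- function(X_train, X_query, cutoff = 3) {
  X_train <- as.matrix(X_train); X_query <- as.matrix(X_query)
  if (ncol(X_train) != ncol(X_query)) stop("descriptor dimension mismatch")
  mu <- colMeans(X_train)
  sigma <- apply(X_train, 2L, sd)
  keep <- sigma > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant training column(s) dropped")
    if (!any(keep)) stop("no non-constant training columns")
  }
  mu <- mu[keep]; sigma <- sigma[keep]
  Xq <- X_query[, keep, drop = FALSE]
  s <- abs(sweep(sweep(Xq, 2L, mu), 2L, sigma, "/"))
  res <- t(apply(s, 1L, function(sk) {
    mx <- max(sk); mn <- min(sk); m <- mean(sk)
    if (mx <= cutoff) {
      c(m, mx, mn, NA_real_, 1)
    } else if (mn > cutoff) {
      c(m, mx, mn, NA_real_, 0)
    } else {
      snew <- m + 1.28 * sd(sk)
      c(m, mx, mn, snew, as.numeric(snew <= cutoff))
    }
  }))
  out <- data.frame(mean_score = res[, 1], max_score = res[, 2],
                    min_score = res[, 3], snew = res[, 4],
                    in_domain = res[, 5] == 1)
  rownames(out) <- rownames(X_query)
  out
}
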