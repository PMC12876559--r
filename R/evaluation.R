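# Agreement and classification metrics: identity-line R^2, RMSE with
# predictive-sigma calibration, Bland-Altman limits of agreement, FFR
# tolerance/threshold agreement, and ROC AUC with the DeLong test for
# correlated AUCs.

#' Coefficient of determination about the identity line
#'
#' \eqn{R^2_{y=x} = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y)^2}: residuals
#' are taken about the line \eqn{y = x} rather than a fitted regression line,
#' so perfect agreement (not merely perfect correlation) scores 1. The
#' fitted-line variant is available with \code{fitted_line = TRUE}.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @param fitted_line use the classical regression-line R^2 instead.
#' @return dimensionless score (<= 1; can be negative).
#' @export
r2_identity <- function(y_true, y_pred, fitted_line = FALSE) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  if (stats::var(y_true) == 0) stop("y_true has zero variance")
  if (fitted_line) {
    return(summary(stats::lm(y_pred ~ y_true))$r.squared)
  }
  1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
}

#' RMSE and predictive-uncertainty calibration report
#'
#' Root-mean-squared error of the predictions, mean predictive standard
#' deviation, and their ratio (a well-calibrated probabilistic model has a
#' ratio near one; ratios well above one flag overconfidence).
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @param sigmas predictive standard deviations (same length).
#' @return list: \code{rmse}, \code{mean_predictive_sigma},
#'   \code{rmse_sigma_ratio}, \code{n}.
#' @export
rmse_and_calibration <- function(y_true, y_pred, sigmas = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  rmse <- sqrt(mse(y_true, y_pred))
  ms <- if (is.null(sigmas)) NA_real_ else mean(sigmas)
  ratio <- if (!is.na(ms) && ms > 0) rmse / ms else NA_real_
  list(rmse = rmse, mean_predictive_sigma = ms, rmse_sigma_ratio = ratio,
       n = length(y_true))
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are \code{pred - ref}; limits are bias +/- 1.96 sample
#' standard deviations.
#'
#' @param ref,pred numeric vectors of equal length >= 2.
#' @return list: \code{bias}, \code{loa_low}, \code{loa_high}, \code{sd}.
#' @export
bland_altman <- function(ref, pred) {
  stopifnot(length(ref) == length(pred), length(ref) >= 2)
  d <- pred - ref
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s)
}

#' FFR numerical and classification agreement
#'
#' Fraction of cases with \code{|pred - ref| <= tol} (clinical agreement
#' tolerance 0.02 by default) and the 2x2 classification table at the
#' ischemia threshold (FFR <= threshold is positive), with accuracy,
#' sensitivity and specificity.
#'
#' @param ref_ffr,pred_ffr numeric vectors of equal length.
#' @param tol numerical agreement tolerance.
#' @param threshold classification threshold (ischemic if <=).
#' @return list: \code{within_tol_fraction}, \code{table} (TP/FP/TN/FN),
#'   \code{accuracy}, \code{sensitivity}, \code{specificity}, \code{n}.
#' @export
ffr_agreement <- function(ref_ffr, pred_ffr, tol = 0.02, threshold = 0.80) {
  stopifnot(length(ref_ffr) == length(pred_ffr))
  within <- mean(abs(pred_ffr - ref_ffr) <= tol)
  ref_pos <- ref_ffr <= threshold
  pred_pos <- pred_ffr <= threshold
  tp <- sum(ref_pos & pred_pos); fn <- sum(ref_pos & !pred_pos)
  fp <- sum(!ref_pos & pred_pos); tn <- sum(!ref_pos & !pred_pos)
  list(within_tol_fraction = within,
       table = c(TP = tp, FP = fp, TN = tn, FN = fn),
       accuracy = (tp + tn) / length(ref_ffr),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       n = length(ref_ffr))
}

# Mann-Whitney AUC with 0.5 tie credit, plus the DeLong structural
# components V10 (per positive) and V01 (per negative).
auc_components <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' ROC AUC for two correlated classifiers with the DeLong test
#'
#' AUCs are computed with the Mann-Whitney statistic (ties credited 0.5);
#' the paired AUC difference is tested with the DeLong covariance of the two
#' correlated AUCs (two-sided). Identical score vectors return a difference
#' of zero with p = 1.
#'
#' @param labels binary labels (0/1 or logical), both classes present.
#' @param scores_a,scores_b scores of the two classifiers (higher = more
#'   positive).
#' @return list: \code{auc_a}, \code{auc_b}, \code{delta}, \code{p_value},
#'   \code{se}.
#' @export
roc_auc_delong <- function(labels, scores_a, scores_b = NULL) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(labels) == length(scores_a))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  ca <- auc_components(labels, scores_a)
  if (is.null(scores_b)) {
    return(list(auc_a = ca$auc, auc_b = NA_real_, delta = NA_real_,
                p_value = NA_real_, se = NA_real_))
  }
  stopifnot(length(labels) == length(scores_b))
  cb <- auc_components(labels, scores_b)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- ca$auc - cb$auc
  if (var_delta <= 0) {
    p <- if (abs(delta) < .Machine$double.eps^0.5) 1 else 0
    return(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, p_value = p,
                se = 0))
  }
  z <- delta / sqrt(var_delta)
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
       p_value = 2 * stats::pnorm(-abs(z)), se = sqrt(var_delta))
}
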