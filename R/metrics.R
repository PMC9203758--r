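#' Variance explained and original-scale RMSE of a continuous predictor
#'
#' \eqn{R^2} is the squared Pearson correlation of predictions with
#' observations (both on the z-score scale). The RMSE is computed after
#' transforming residuals back to the original measurement scale by the
#' per-stratum standard deviation (for a sex-stratified standardization,
#' pass `strata` and one SD per stratum).
#'
#' @param predicted,observed Numeric vectors of equal length (>= 3),
#'   z-scores.
#' @param scale_sd Original-scale SD: a single number, or a named vector
#'   with one entry per stratum level.
#' @param strata Optional stratum label per individual (e.g. sex).
#' @return A list with `r2` and `rmse`.
#' @examples
#' r2_and_rmse(c(0, 1, 2), c(0.1, 0.9, 2.2), scale_sd = 6.5)
#' @export
r2_and_rmse <- function(predicted, observed, scale_sd = 1, strata = NULL) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 3)
  if (stats::sd(observed) == 0)
    stop("observed values have zero variance; R^2 is undefined")
  # a constant predictor explains nothing rather than being undefined
  r2 <- if (stats::sd(predicted) == 0) 0
        else stats::cor(predicted, observed)^2
  resid <- observed - predicted
  if (is.null(strata)) {
    rmse <- sqrt(mean((resid * scale_sd[[1]])^2))
  } else {
    stopifnot(length(strata) == length(observed),
              all(unique(strata) %in% names(scale_sd)))
    rmse <- sqrt(mean((resid * scale_sd[as.character(strata)])^2))
  }
  list(r2 = unname(r2), rmse = unname(rmse))
}

#' Area under the ROC and precision-recall curves
#'
#' AUROC by the Mann-Whitney statistic with midrank tie handling; AUPRC as
#' average precision (the step-wise sum of precision at each case, no linear
#' interpolation), with ties in scores broken by original order after a
#' stable decreasing sort.
#'
#' @param scores Numeric risk scores, higher = more at risk.
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return A list with `auroc` and `auprc`.
#' @examples
#' auroc_auprc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auroc_auprc <- function(scores, labels) {
  check_binary_labels(labels, scores)
  list(auroc = auroc(scores, labels), auprc = auprc(scores, labels))
}

check_binary_labels <- function(labels, scores) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in `labels`")
  invisible(TRUE)
}

auroc <- function(scores, labels) {
  n1 <- as.numeric(sum(labels == 1))
  n0 <- as.numeric(sum(labels == 0))
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

auprc <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec * lab) / sum(lab)
}

#' DeLong's paired test for two correlated AUROCs
#'
#' Compares the AUROCs of two risk scores evaluated on the same individuals
#' using the structural-components (placement-value) covariance estimate and
#' a two-sided normal test. Midranks handle ties.
#'
#' @param scores_a,scores_b Paired risk scores on identical individuals.
#' @param labels 0/1 outcomes; both classes present.
#' @return A list with `auroc_a`, `auroc_b`, `p_value`, and `degenerate`
#'   (`TRUE` with `p_value = 1` when the variance of the AUROC difference is
#'   numerically zero, e.g. identical scores).
#' @examples
#' set.seed(1)
#' y <- rbinom(200, 1, 0.3)
#' delong_test(rnorm(200) + y, rnorm(200), y)$p_value
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  check_binary_labels(labels, scores_a)
  is_case <- labels == 1
  m <- as.numeric(sum(is_case)); n <- as.numeric(sum(!is_case))

  placements <- function(s) {
    # V10_i = P(score_case_i > score_control) with midranks;
    # V01_j symmetric (fast DeLong via rank decomposition)
    r_all <- rank(s, ties.method = "average")
    r_cases <- rank(s[is_case], ties.method = "average")
    r_controls <- rank(s[!is_case], ties.method = "average")
    v10 <- (r_all[is_case] - r_cases) / n
    v01 <- 1 - (r_all[!is_case] - r_controls) / m
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(v) || v <= .Machine$double.eps) {
    return(list(auroc_a = pa$auc, auroc_b = pb$auc, p_value = 1,
                degenerate = TRUE))
  }
  z <- (pa$auc - pb$auc) / sqrt(v)
  list(auroc_a = pa$auc, auroc_b = pb$auc,
       p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Net reclassification improvement at score-percentile cut-offs
#'
#' At each cut-off, individuals strictly above the within-sample percentile
#' of each score's own distribution are "high risk"; replacing the old score
#' with the new one reclassifies some individuals. The NRI is
#' \deqn{[P(\mathrm{up}\mid\mathrm{case}) - P(\mathrm{down}\mid\mathrm{case})]
#'  + [P(\mathrm{down}\mid\mathrm{noncase}) -
#'     P(\mathrm{up}\mid\mathrm{noncase})],}
#' reported in percent. A cut-off that leaves an empty risk class for either
#' score is undefined and returned as `NA` (flagged in the
#' `undefined` attribute).
#'
#' @param scores_new,scores_old Paired risk scores.
#' @param labels 0/1 outcomes.
#' @param percentiles Percentile cut-offs in (0, 100), default
#'   `c(50, 80, 95, 99)`.
#' @return A named numeric vector of NRI percentages, one per cut-off, with
#'   attribute `undefined` marking flagged cut-offs.
#' @examples
#' set.seed(1)
#' y <- rbinom(400, 1, 0.3)
#' nri_at_percentiles(rnorm(400) + y, rnorm(400), y, percentiles = 50)
#' @export
nri_at_percentiles <- function(scores_new, scores_old, labels,
                               percentiles = c(50, 80, 95, 99)) {
  stopifnot(length(scores_new) == length(scores_old),
            all(percentiles > 0), all(percentiles < 100))
  check_binary_labels(labels, scores_new)
  is_case <- labels == 1
  out <- stats::setNames(rep(NA_real_, length(percentiles)),
                         paste0("p", percentiles))
  undef <- stats::setNames(rep(FALSE, length(percentiles)),
                           names(out))
  for (k in seq_along(percentiles)) {
    p <- percentiles[k] / 100
    hi_new <- scores_new > stats::quantile(scores_new, p)
    hi_old <- scores_old > stats::quantile(scores_old, p)
    if (!any(hi_new) || all(hi_new) || !any(hi_old) || all(hi_old)) {
      undef[k] <- TRUE
      next
    }
    up <- hi_new & !hi_old
    down <- !hi_new & hi_old
    nri_case <- mean(up[is_case]) - mean(down[is_case])
    nri_ctrl <- mean(down[!is_case]) - mean(up[!is_case])
    out[k] <- 100 * (nri_case + nri_ctrl)
  }
  attr(out, "undefined") <- undef
  out
}

#' Integrated discrimination improvement
#'
#' Both scores are mapped to predicted probabilities by a one-dimensional
#' logistic recalibration against the labels (the scores here are
#' liabilities, not probabilities); the IDI is the gain in discrimination
#' slope,
#' \deqn{[\bar p_{new,case} - \bar p_{old,case}] -
#'       [\bar p_{new,noncase} - \bar p_{old,noncase}],}
#' in percent. The recalibration makes the IDI invariant under affine
#' transforms of either score.
#'
#' @param scores_new,scores_old Paired risk scores.
#' @param labels 0/1 outcomes.
#' @return The IDI in percent (a single number).
#' @examples
#' set.seed(1)
#' y <- rbinom(400, 1, 0.3)
#' idi(rnorm(400) + y, rnorm(400), y)
#' @export
idi <- function(scores_new, scores_old, labels) {
  stopifnot(length(scores_new) == length(scores_old))
  check_binary_labels(labels, scores_new)
  calib <- function(s) {
    m <- stats::glm(labels ~ s, family = stats::binomial())
    if (!m$converged) stop("logistic recalibration did not converge")
    stats::fitted(m)
  }
  p_new <- calib(scores_new)
  p_old <- calib(scores_old)
  is_case <- labels == 1
  100 * ((mean(p_new[is_case]) - mean(p_old[is_case])) -
           (mean(p_new[!is_case]) - mean(p_old[!is_case])))
}

#' Evaluation report for a pair of risk scores
#'
#' Convenience wrapper assembling the discrimination and reclassification
#' metrics that apply to the supplied columns: AUROC/AUPRC of the new score,
#' and, when a comparator is given, DeLong's paired p-value, NRI at the
#' requested percentiles, and the IDI.
#'
#' @param scores_new Risk scores under evaluation.
#' @param labels 0/1 outcomes.
#' @param scores_old Optional comparator scores.
#' @param percentiles NRI percentile cut-offs.
#' @return A list of metric values (an evaluation report).
#' @export
evaluate_binary_scores <- function(scores_new, labels, scores_old = NULL,
                                   percentiles = c(50, 80, 95, 99)) {
  rep <- auroc_auprc(scores_new, labels)
  if (!is.null(scores_old)) {
    rep$auroc_comparator <- auroc(scores_old, labels)
    rep$auprc_comparator <- auprc(scores_old, labels)
    rep$delong_p <- delong_test(scores_new, scores_old, labels)$p_value
    rep$nri <- nri_at_percentiles(scores_new, scores_old, labels,
                                  percentiles)
    rep$idi <- idi(scores_new, scores_old, labels)
  }
  rep
}
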