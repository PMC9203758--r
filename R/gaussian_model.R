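#' Covariance of the child/parent trait and polygenic-score vector
#'
#' Builds the joint covariance of the observables used for continuous-trait
#' prediction. With both parents the vector is \eqn{(Y_C, Y_M, Y_F, P_C)}; with
#' a single parent \eqn{(Y_C, Y_{M/F}, P_C)}. All traits and the polygenic
#' score are z-scores, so the diagonal is 1; parent-child trait covariance is
#' \eqn{(\alpha^2+\beta^2)/2} (each child inherits half of each genetic
#' component from each parent), spouses are uncorrelated (no assortative
#' mating), \eqn{\mathrm{Cov}(Y_C, P_C) = \alpha} and
#' \eqn{\mathrm{Cov}(Y_{M/F}, P_C) = \alpha/2}.
#'
#' @param params A [continuous_params()] object.
#' @param mode `"both-parents"` (4x4) or `"single-parent"` (3x3).
#' @return A symmetric positive semi-definite covariance matrix with row and
#'   column names.
#' @examples
#' p <- continuous_params(alpha_sq = 0.367, beta_sq = 0.581)
#' build_trio_covariance(p)
#' @export
build_trio_covariance <- function(params,
                                  mode = c("both-parents", "single-parent")) {
  stopifnot(inherits(params, "continuous_params"))
  mode <- match.arg(mode)
  a <- params$alpha
  h2 <- heritability(params)
  if (mode == "both-parents") {
    m <- matrix(c(
      1,     h2 / 2, h2 / 2, a,
      h2 / 2, 1,     0,      a / 2,
      h2 / 2, 0,     1,      a / 2,
      a,     a / 2,  a / 2,  1), 4, 4, byrow = TRUE)
    dimnames(m) <- rep(list(c("Y_C", "Y_M", "Y_F", "P_C")), 2)
  } else {
    m <- matrix(c(
      1,     h2 / 2, a,
      h2 / 2, 1,     a / 2,
      a,     a / 2,  1), 3, 3, byrow = TRUE)
    dimnames(m) <- rep(list(c("Y_C", "Y_P", "P_C")), 2)
  }
  m
}

#' Under-captured heritability from summary statistics
#'
#' Inverts the closed-form mid-parental variance explained,
#' \eqn{R^2_{mid} = (\alpha^2+\beta^2)^2/2}, to recover the under-captured
#' heritability from two published summary statistics: the variance in the
#' child trait z-score explained by the polygenic score
#' (\eqn{\hat\alpha^2 = r^2_{PRS}}) and the variance explained by the
#' mid-parental z-score. The estimate is
#' \deqn{\hat\beta^2 = \sqrt{2\, r^2_{mid}} - r^2_{PRS}.}
#'
#' Infeasible inputs (implied total heritability outside
#' \eqn{[r^2_{PRS}, 1]}) raise an error rather than being clamped: silently
#' clamping would hide incompatible summary statistics. Violations within
#' `1e-6` of a bound are treated as numerical noise and clamped.
#'
#' @param r2_prs Fraction of trait variance explained by the polygenic score,
#'   in \[0, 1\].
#' @param r2_midparent Fraction of trait variance explained by the
#'   mid-parental trait z-score, in \[0, 1\].
#' @return A list with `alpha_sq` (= `r2_prs`), `beta_sq` (the estimate), and
#'   `params` (the corresponding [continuous_params()]).
#' @examples
#' estimate_beta_sq_from_midparent(r2_prs = 0.367, r2_midparent = 0.449)$beta_sq
#' @export
estimate_beta_sq_from_midparent <- function(r2_prs, r2_midparent) {
  stopifnot(is.numeric(r2_prs), length(r2_prs) == 1L,
            is.numeric(r2_midparent), length(r2_midparent) == 1L)
  if (r2_prs < 0 || r2_prs > 1)
    stop("`r2_prs` must be a fraction in [0, 1]")
  if (r2_midparent < 0 || r2_midparent > 1)
    stop("`r2_midparent` must be a fraction in [0, 1]")
  h2 <- sqrt(2 * r2_midparent)       # implied total heritability
  tol <- 1e-6
  if (h2 < r2_prs - tol || h2 > 1 + tol)
    stop("infeasible summary statistics: the mid-parental R^2 of ",
         signif(r2_midparent, 4), " implies total heritability ",
         signif(h2, 4), ", outside [r2_prs, 1] = [",
         signif(r2_prs, 4), ", 1]")
  beta_sq <- h2 - r2_prs
  beta_sq <- min(max(beta_sq, 0), 1 - r2_prs)  # noise-level clamp only
  list(alpha_sq = r2_prs, beta_sq = beta_sq,
       params = continuous_params(alpha_sq = r2_prs, beta_sq = beta_sq))
}

#' Under-captured heritability from a single-parent summary statistic
#'
#' Single-parent analogue of [estimate_beta_sq_from_midparent()]: under the
#' model the child-on-one-parent regression explains
#' \eqn{(\alpha^2+\beta^2)^2/4} of the child trait variance, so
#' \eqn{\hat\beta^2 = 2\sqrt{r^2_{parent}} - r^2_{PRS}}. This inversion is an
#' extrapolation of the mid-parental derivation and is flagged as such in the
#' result.
#'
#' @param r2_prs Fraction of variance explained by the polygenic score.
#' @param r2_single_parent Fraction of variance explained by one parent's
#'   trait z-score.
#' @return As [estimate_beta_sq_from_midparent()], plus
#'   `extrapolated = TRUE`.
#' @export
estimate_beta_sq_from_single_parent <- function(r2_prs, r2_single_parent) {
  stopifnot(is.numeric(r2_single_parent), length(r2_single_parent) == 1L)
  if (r2_single_parent < 0 || r2_single_parent > 0.25 + 1e-6)
    stop("`r2_single_parent` must lie in [0, 0.25]: a single parent can ",
         "explain at most h^4/4 = 1/4 of the child trait variance")
  out <- estimate_beta_sq_from_midparent(r2_prs, 2 * r2_single_parent)
  out$extrapolated <- TRUE
  out
}

#' Expected variance explained by the mid-parental predictor
#'
#' Closed-form population \eqn{R^2} of the mid-parental trait z-score
#' \eqn{(Y_M + Y_F)/2} as a predictor of the child trait:
#' \eqn{(\alpha^2+\beta^2)^2 / 2}.
#'
#' @param params A [continuous_params()] object.
#' @return A fraction in \[0, 0.5\].
#' @examples
#' expected_r2_midparent(continuous_params(alpha_sq = 0.367, beta_sq = 0.581))
#' @export
expected_r2_midparent <- function(params) {
  stopifnot(inherits(params, "continuous_params"))
  heritability(params)^2 / 2
}

# Conditional-expectation weights for a given availability pattern.
# Solves A w = c where A is the predictor covariance and c the covariance of
# Y_C with the predictors; direct solve, no explicit inverse.
continuous_weights <- function(params,
                               pattern = c("both", "single", "prs_only")) {
  stopifnot(inherits(params, "continuous_params"))
  pattern <- match.arg(pattern)
  a <- params$alpha
  h2 <- heritability(params)
  if (pattern == "both") {
    A <- matrix(c(1, 0, a / 2,
                  0, 1, a / 2,
                  a / 2, a / 2, 1), 3, 3, byrow = TRUE)
    cvec <- c(h2 / 2, h2 / 2, a)
    w <- solve(A, cvec)
    names(w) <- c("y_M", "y_F", "p_C")
  } else if (pattern == "single") {
    A <- matrix(c(1, a / 2,
                  a / 2, 1), 2, 2, byrow = TRUE)
    cvec <- c(h2 / 2, a)
    w <- solve(A, cvec)
    names(w) <- c("y_P", "p_C")
  } else {
    w <- c(p_C = a)
    cvec <- a
  }
  attr(w, "r2") <- sum(w * cvec)   # population R^2 = c' A^-1 c
  w
}

#' Predict a child's trait z-score from the polygenic score and parental traits
#'
#' The predictor is the conditional expectation of the child trait given the
#' available observations under the joint multivariate normal of
#' [build_trio_covariance()]. The conditioning set is chosen by the
#' availability pattern of each row: both parents, one parent, or the
#' polygenic score alone (in which case the predictor is \eqn{\alpha p_C}).
#' A missing parent changes the conditioning set and the weights; it is never
#' imputed as 0.
#'
#' Inputs are vectorized and recycled to a common length. Parental trait
#' values use `NA` for "not measured".
#'
#' @param prs Child polygenic risk score z-scores.
#' @param y_m,y_f Maternal / paternal trait z-scores, `NA` when unavailable.
#' @param params A [continuous_params()] object.
#' @return A data.frame with columns `value` (predicted child trait z-score),
#'   `mc_se` (always `NA`: the continuous predictor is closed form), and
#'   `pattern` (which conditioning set was used per row).
#' @examples
#' p <- continuous_params(alpha_sq = 0.367, beta_sq = 0.581)
#' predict_continuous(prs = c(1, 1), y_m = c(1, NA), y_f = c(1, NA), p)
#' @export
predict_continuous <- function(prs, y_m = NA_real_, y_f = NA_real_, params) {
  stopifnot(inherits(params, "continuous_params"), is.numeric(prs))
  n <- max(length(prs), length(y_m), length(y_f))
  prs <- rep_len(as.numeric(prs), n)
  y_m <- rep_len(as.numeric(y_m), n)
  y_f <- rep_len(as.numeric(y_f), n)
  if (anyNA(prs)) stop("`prs` must be observed for every individual")

  value <- numeric(n)
  pattern <- character(n)
  has_m <- !is.na(y_m)
  has_f <- !is.na(y_f)

  both <- has_m & has_f
  if (any(both)) {
    w <- continuous_weights(params, "both")
    value[both] <- w[1] * y_m[both] + w[2] * y_f[both] + w[3] * prs[both]
    pattern[both] <- "both"
  }
  m_only <- has_m & !has_f
  f_only <- has_f & !has_m
  if (any(m_only | f_only)) {
    w <- continuous_weights(params, "single")
    value[m_only] <- w[1] * y_m[m_only] + w[2] * prs[m_only]
    value[f_only] <- w[1] * y_f[f_only] + w[2] * prs[f_only]
    pattern[m_only] <- "mother_only"
    pattern[f_only] <- "father_only"
  }
  none <- !has_m & !has_f
  if (any(none)) {
    value[none] <- params$alpha * prs[none]
    pattern[none] <- "none"
  }
  data.frame(value = value, mc_se = NA_real_, pattern = pattern,
             stringsAsFactors = FALSE)
}

#' Population variance explained by the joint predictor
#'
#' Closed-form population \eqn{R^2} of the conditional-expectation joint
#' predictor (polygenic score plus parental trait measures):
#' \eqn{c^\top A^{-1} c}, where \eqn{c} is the covariance of the child trait
#' with the predictors and \eqn{A} the predictor covariance. Equals the
#' large-sample empirical \eqn{R^2} of [predict_continuous()].
#'
#' @param params A [continuous_params()] object.
#' @param mode `"both-parents"`, `"single-parent"`, or `"prs-only"`.
#' @return A fraction in \[0, 1\].
#' @export
expected_r2_joint <- function(params,
                              mode = c("both-parents", "single-parent",
                                       "prs-only")) {
  mode <- match.arg(mode)
  pattern <- switch(mode, "both-parents" = "both",
                    "single-parent" = "single", "prs-only" = "prs_only")
  unname(attr(continuous_weights(params, pattern), "r2"))
}
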