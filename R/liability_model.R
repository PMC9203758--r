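#' Disease probability under the logit-link liability model
#'
#' \eqn{P(Z = 1 \mid H = h, Q = q) = \mathrm{expit}(\mu_0 + h + \gamma q)}.
#' Covariates are measured as deviations from the reference values at which
#' `mu0` is defined, so `q = NULL` (or all zeros) gives the baseline
#' individual.
#'
#' @param h Liability value(s).
#' @param q Named covariate vector matching the schema of `params$gamma`, or
#'   `NULL` for the reference individual.
#' @param params A [binary_params()] object.
#' @return Probabilities strictly in (0, 1), vectorized over `h`.
#' @examples
#' disease_probability(0, NULL, binary_params(mu0 = 0, alpha = 0, beta = 0))
#' @export
disease_probability <- function(h, q = NULL, params) {
  stopifnot(inherits(params, "binary_params"), is.numeric(h))
  stats::plogis(params$mu0 + h + covariate_offset(q, params))
}

# gamma . q with schema validation; NULL q means reference (offset 0)
covariate_offset <- function(q, params) {
  if (is.null(q) || length(q) == 0L) return(0)
  g <- params$gamma
  if (length(g) == 0L)
    stop("covariates supplied but the parameter set has an empty covariate schema")
  if (is.null(names(q)) || !setequal(names(q), names(g)))
    stop("covariate vector names {", paste(names(q), collapse = ", "),
         "} do not match the schema {", paste(names(g), collapse = ", "), "}")
  sum(g[names(q)] * q)
}

#' Convert a log-odds genetic effect to the liability scale
#'
#' Under the logit-link model the per-SD genetic effects are log-odds; their
#' contribution to heritability on the classical liability scale is obtained
#' by the probit/logit bridging approximation
#' \deqn{\tau = d / \sqrt{1 + d^2},\qquad
#'       d = \Phi^{-1}[F_L(\mu_0 + e)] - \Phi^{-1}[F_L(\mu_0)],}
#' where \eqn{F_L(x) = 1/(1 + \exp\{-\pi x/\sqrt{3}\})} is the unit-variance
#' logistic CDF and the genetic component has unit variance. The
#' heritability contribution of the component is \eqn{\tau^2}.
#'
#' @param effect Log-odds effect per SD of a genetic component (alpha or
#'   beta).
#' @param mu0 Baseline log-odds.
#' @return The liability-scale effect \eqn{\tau}; same sign as `effect`.
#' @examples
#' liability_scale_effect(0.5, mu0 = -3)
#' @export
liability_scale_effect <- function(effect, mu0) {
  stopifnot(is.numeric(effect), is.numeric(mu0),
            all(is.finite(effect)), all(is.finite(mu0)))
  flog <- function(x) stats::plogis(pi / sqrt(3) * x)
  d <- stats::qnorm(flog(mu0 + effect)) - stats::qnorm(flog(mu0))
  d / sqrt(1 + d^2)   # Var(P) = Var(G) = 1
}

# Gauss-Hermite nodes/weights cache (pracma convention: integral against
# exp(-x^2); for N(0,1) use sqrt(2)*x with weights w/sqrt(pi)).
.gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

#' Theoretical parent-child odds ratio under the liability model
#'
#' Computes the cross odds ratio
#' \deqn{OR = \frac{f(Z_C=1, Z_P=1)/f(Z_C=0, Z_P=1)}
#'                 {f(Z_C=1, Z_P=0)/f(Z_C=0, Z_P=0)}}
#' by integrating the product of Bernoulli kernels over the bivariate normal
#' of the child and parent liabilities (variances \eqn{\alpha^2+\beta^2},
#' covariance \eqn{(\alpha^2+\beta^2)/2}) with a tensor Gauss-Hermite rule.
#' Maternal and paternal ORs differ only through the covariate vectors (e.g.
#' sex): pass the appropriate `q_parent` for each role. Deterministic for
#' fixed `nodes`.
#'
#' @param params A [binary_params()] object with `beta` set.
#' @param q_child,q_parent Named covariate deviation vectors (see
#'   [disease_probability()]), or `NULL` for the reference individual.
#' @param nodes Gauss-Hermite nodes per dimension (default 64).
#' @return The odds ratio (a single number > 0). In the degenerate limit
#'   \eqn{\alpha^2+\beta^2 = 0} the liabilities are constant and the OR is 1.
#' @examples
#' theoretical_parent_child_or(binary_params(mu0 = -2, alpha = 0.3, beta = 0.7))
#' @export
theoretical_parent_child_or <- function(params, q_child = NULL,
                                        q_parent = NULL, nodes = 64L) {
  stopifnot(inherits(params, "binary_params"), nodes >= 2L)
  assert_beta_set(params)
  h2 <- heritability(params)
  if (h2 <= 0) return(1)

  off_c <- covariate_offset(q_child, params)
  off_p <- covariate_offset(q_parent, params)

  gh <- gh_rule(nodes)
  z <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  # liabilities via Cholesky of [[h2, h2/2], [h2/2, h2]]
  l11 <- sqrt(h2)
  l21 <- (h2 / 2) / l11
  l22 <- sqrt(h2 - l21^2)
  hc <- rep(l11 * z, times = nodes)
  hp <- rep(l21 * z, times = nodes) + rep(l22 * z, each = nodes)
  wt <- rep(w, times = nodes) * rep(w, each = nodes)

  pc <- stats::plogis(params$mu0 + hc + off_c)
  pp <- stats::plogis(params$mu0 + hp + off_p)
  f11 <- sum(wt * pc * pp)
  f10 <- sum(wt * pc * (1 - pp))
  f01 <- sum(wt * (1 - pc) * pp)
  f00 <- sum(wt * (1 - pc) * (1 - pp))
  if (!all(is.finite(c(f11, f10, f01, f00))) || min(f11, f10, f01, f00) <= 0)
    stop("non-finite or vanishing joint probabilities in the quadrature; ",
         "cells (f11, f10, f01, f00) = (",
         paste(signif(c(f11, f10, f01, f00), 4), collapse = ", "),
         ") at ", nodes, " nodes per dimension")
  (f11 / f01) / (f10 / f00)
}

#' Estimate the latent-component effect from parental-history odds ratios
#'
#' Given observed maternal and paternal disease-history odds ratios (from a
#' reference study or a training fit) and a parameter set with \eqn{\mu_0},
#' \eqn{\alpha}, \eqn{\gamma} already fixed, finds the \eqn{\beta \ge 0}
#' whose theoretical parent-child odds ratios best match the observed ones
#' by a bracketed one-dimensional minimization of the log-OR discrepancy.
#'
#' The default objective is the sum of absolute log-OR errors
#' \eqn{|\Delta_M| + |\Delta_F|}; `objective = "abs_sum"` uses the absolute
#' value of the signed sum \eqn{|\Delta_M + \Delta_F|} instead (the two
#' coincide when both errors share a sign, but the signed sum allows
#' cancellation).
#'
#' @param or_m_observed,or_f_observed Observed maternal / paternal odds
#'   ratios (> 0).
#' @param params A [binary_params()] with `beta` unset (or ignored).
#' @param q_child,q_mother,q_father Covariate deviation vectors for the
#'   theoretical ORs; typically `q_mother`/`q_father` differ only in the sex
#'   covariate.
#' @param bracket Search interval for beta, default `c(0, 5)`.
#' @param tol Absolute tolerance on beta, default `1e-4`.
#' @param objective `"sum_abs"` (default) or `"abs_sum"`.
#' @param nodes Gauss-Hermite nodes per dimension for the theoretical ORs.
#' @return A list: `beta` (the estimate), `objective` (achieved value),
#'   `or_m_theoretical`, `or_f_theoretical` at the estimate, and `params`
#'   (the input parameters with `beta` filled in).
#' @examples
#' p0 <- binary_params(mu0 = -2, alpha = 0.3)
#' truth <- binary_params(mu0 = -2, alpha = 0.3, beta = 0.8)
#' or_true <- theoretical_parent_child_or(truth)
#' estimate_beta_line_search(or_true, or_true, p0)$beta
#' @export
estimate_beta_line_search <- function(or_m_observed, or_f_observed, params,
                                      q_child = NULL, q_mother = NULL,
                                      q_father = NULL, bracket = c(0, 5),
                                      tol = 1e-4,
                                      objective = c("sum_abs", "abs_sum"),
                                      nodes = 64L) {
  stopifnot(is.numeric(or_m_observed), or_m_observed > 0,
            is.numeric(or_f_observed), or_f_observed > 0,
            inherits(params, "binary_params"),
            length(bracket) == 2L, bracket[1] >= 0, bracket[2] > bracket[1])
  objective <- match.arg(objective)

  theor <- function(beta) {
    p <- binary_params(params$mu0, params$alpha, beta, params$gamma)
    c(m = theoretical_parent_child_or(p, q_child, q_mother, nodes),
      f = theoretical_parent_child_or(p, q_child, q_father, nodes))
  }
  obj <- function(beta) {
    or_t <- theor(beta)
    dm <- log(or_m_observed) - log(or_t[["m"]])
    df <- log(or_f_observed) - log(or_t[["f"]])
    if (objective == "sum_abs") abs(dm) + abs(df) else abs(dm + df)
  }

  opt <- stats::optimize(obj, interval = bracket, tol = tol)
  beta_hat <- opt$minimum
  # boundary diagnostics: the objective still decreasing at the upper end
  # means the bracket is too small
  if (bracket[2] - beta_hat < 10 * tol &&
      obj(bracket[2]) < obj(bracket[2] - 100 * tol))
    stop("line search hit the upper bracket end (beta_max = ", bracket[2],
         ") with the objective still decreasing; enlarge `bracket`")
  # prefer an exact interior 0 when the observed ORs match beta = 0
  if (obj(bracket[1]) <= opt$objective) beta_hat <- bracket[1]
  or_t <- theor(beta_hat)
  list(beta = beta_hat, objective = obj(beta_hat),
       or_m_theoretical = unname(or_t[["m"]]),
       or_f_theoretical = unname(or_t[["f"]]),
       params = binary_params(params$mu0, params$alpha, beta_hat,
                              params$gamma))
}

#' Importance-sample a parent's liability given disease status
#'
#' Draws from the posterior \eqn{f(H \mid Z = z) \propto
#' \mathrm{Bern}(z; \mathrm{expit}(\mu_0 + h + \gamma q))\, N(h; 0,
#' \alpha^2+\beta^2)} by sampling proposals from the prior
#' \eqn{N(0, \alpha^2+\beta^2)} and attaching self-normalized importance
#' weights proportional to the Bernoulli likelihood (the prior density
#' cancels). Weights are computed in log space and shifted by their maximum
#' before exponentiation, so rare diseases (very negative \eqn{\mu_0}) remain
#' stable.
#'
#' @param z Disease indicator, 0 or 1.
#' @param q Named covariate deviation vector for this parent, or `NULL`.
#' @param params A [binary_params()] object with `beta` set.
#' @param n_samples Number of proposal draws (>= 1).
#' @param seed Integer seed; fixed seed gives reproducible draws.
#' @param ess_floor Effective-sample-size floor below which a warning flag is
#'   set on the result (default 100). No exception is thrown.
#' @return A list of class `liability_samples`: `values`, `weights`
#'   (non-negative, summing to 1), `ess`, and `low_ess` (logical flag).
#' @examples
#' s <- sample_parent_liability(1, NULL,
#'   binary_params(mu0 = -2, alpha = 0.3, beta = 0.7), 1000, seed = 1)
#' sum(s$weights * s$values)  # posterior mean liability of an affected parent
#' @export
sample_parent_liability <- function(z, q = NULL, params, n_samples,
                                    seed = NULL, ess_floor = 100) {
  stopifnot(inherits(params, "binary_params"), n_samples >= 1,
            z %in% c(0, 1))
  assert_beta_set(params)
  if (!is.null(seed)) set.seed(seed)
  h2 <- heritability(params)
  if (h2 <= 0) {
    # degenerate prior: liability is identically 0 regardless of z
    out <- list(values = rep(0, n_samples),
                weights = rep(1 / n_samples, n_samples),
                ess = as.numeric(n_samples), low_ess = FALSE)
    class(out) <- "liability_samples"
    return(out)
  }
  h <- stats::rnorm(n_samples, 0, sqrt(h2))
  eta <- params$mu0 + h + covariate_offset(q, params)
  lw <- if (z == 1) stats::plogis(eta, log.p = TRUE)
        else stats::plogis(-eta, log.p = TRUE)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  out <- list(values = h, weights = w, ess = ess, low_ess = ess < ess_floor)
  class(out) <- "liability_samples"
  out
}

# weighted mean and its self-normalized importance-sampling standard error
is_mean_se <- function(s) {
  m <- sum(s$weights * s$values)
  se <- sqrt(sum(s$weights^2 * (s$values - m)^2))
  c(mean = m, se = se)
}

# Conditional-expectation weights for the liability predictor: solve A w = c
# with A the covariance of the conditioning set and c its covariance with H_C.
liability_weights <- function(params, pattern = c("both", "single",
                                                  "prs_only")) {
  pattern <- match.arg(pattern)
  a <- params$alpha
  h2 <- heritability(params)
  if (pattern == "both") {
    A <- matrix(c(h2, 0, a / 2,
                  0, h2, a / 2,
                  a / 2, a / 2, 1), 3, 3, byrow = TRUE)
    cvec <- c(h2 / 2, h2 / 2, a)
    w <- solve(A, cvec)
    names(w) <- c("h_M", "h_F", "p_C")
  } else if (pattern == "single") {
    A <- matrix(c(h2, a / 2,
                  a / 2, 1), 2, 2, byrow = TRUE)
    cvec <- c(h2 / 2, a)
    w <- solve(A, cvec)
    names(w) <- c("h_P", "p_C")
  } else {
    w <- c(p_C = a)
  }
  w
}

#' Predict a child's genetic liability from the polygenic score and parental
#' disease history
#'
#' The predictor is the conditional expectation of the child liability
#' \eqn{H_C} given the child polygenic score and the available parental
#' disease indicators. Parental liabilities are integrated out by importance
#' sampling from their status-conditional posteriors
#' ([sample_parent_liability()]); the inner conditional expectation of
#' \eqn{H_C} given \eqn{(H_M, H_F, P_C)} is linear, so the predictor is the
#' weighted combination of the posterior mean parental liabilities and the
#' polygenic score. With no parental history the predictor is the closed form
#' \eqn{\alpha\, p_C} with no sampling.
#'
#' A single seed deterministically derives the independent maternal and
#' paternal sample streams.
#'
#' @param prs Child polygenic risk score z-score (single value).
#' @param z_m,z_f Maternal / paternal disease indicator in \{0, 1\}, `NA`
#'   when unavailable.
#' @param params A [binary_params()] with `beta` set.
#' @param L Number of importance samples per parent (default 1e6).
#' @param seed Integer seed for the sampling streams.
#' @param q_mother,q_father Parental covariate deviation vectors; default
#'   `NULL` is the reference individual (sex-specific values may be passed
#'   when sex is in the schema).
#' @param ess_floor Passed to [sample_parent_liability()].
#' @return A one-row data.frame: `value` (posterior mean child liability),
#'   `mc_se` (Monte-Carlo standard error; `NA` for the closed-form no-parent
#'   pattern), `pattern`, and `low_ess`.
#' @examples
#' p <- binary_params(mu0 = -2, alpha = 0.3, beta = 0.7)
#' predict_liability(prs = 0, z_m = 1, z_f = 1, p, L = 1e4, seed = 1)
#' @export
predict_liability <- function(prs, z_m = NA, z_f = NA, params, L = 1e6,
                              seed = NULL, q_mother = NULL, q_father = NULL,
                              ess_floor = 100) {
  stopifnot(inherits(params, "binary_params"), length(prs) == 1L, L >= 1)
  assert_beta_set(params)
  h2 <- heritability(params)
  has_m <- !is.na(z_m)
  has_f <- !is.na(z_f)

  if (h2 <= 0) {
    pattern <- if (has_m && has_f) "both"
               else if (has_m) "mother_only"
               else if (has_f) "father_only" else "none"
    return(data.frame(value = 0, mc_se = 0, pattern = pattern,
                      low_ess = FALSE, stringsAsFactors = FALSE))
  }

  if (!has_m && !has_f) {
    return(data.frame(value = params$alpha * prs, mc_se = NA_real_,
                      pattern = "none", low_ess = FALSE,
                      stringsAsFactors = FALSE))
  }

  seed <- if (is.null(seed)) NULL else as.integer(seed)
  if (has_m && has_f) {
    w <- liability_weights(params, "both")
    sm <- sample_parent_liability(z_m, q_mother, params, L,
                                  seed = seed, ess_floor = ess_floor)
    sf <- sample_parent_liability(z_f, q_father, params, L,
                                  seed = if (is.null(seed)) NULL else seed + 1L,
                                  ess_floor = ess_floor)
    mm <- is_mean_se(sm); mf <- is_mean_se(sf)
    value <- w[1] * mm["mean"] + w[2] * mf["mean"] + w[3] * prs
    mc_se <- sqrt(w[1]^2 * mm["se"]^2 + w[2]^2 * mf["se"]^2)
    low <- sm$low_ess || sf$low_ess
    pattern <- "both"
  } else {
    w <- liability_weights(params, "single")
    z <- if (has_m) z_m else z_f
    qp <- if (has_m) q_mother else q_father
    sp <- sample_parent_liability(z, qp, params, L, seed = seed,
                                  ess_floor = ess_floor)
    mp <- is_mean_se(sp)
    value <- w[1] * mp["mean"] + w[2] * prs
    mc_se <- abs(w[1]) * mp["se"]
    low <- sp$low_ess
    pattern <- if (has_m) "mother_only" else "father_only"
  }
  data.frame(value = unname(value), mc_se = unname(mc_se), pattern = pattern,
             low_ess = low, stringsAsFactors = FALSE)
}

#' Vectorized liability prediction for a table of individuals
#'
#' Applies [predict_liability()] to whole columns efficiently. The inner
#' conditional expectation is linear in the sampled parental liabilities and
#' the polygenic score, so individuals sharing the same availability pattern
#' and parental statuses can share one importance-sample set per parent: the
#' grouping is exact, not an approximation. One sample set is drawn for each
#' needed (role, status) condition, with seeds derived deterministically from
#' `seed`.
#'
#' @param prs Numeric vector of child polygenic scores.
#' @param z_m,z_f Parental disease indicators (0/1/NA), recycled to the
#'   length of `prs`.
#' @param params,L,seed,q_mother,q_father,ess_floor As [predict_liability()].
#' @return A data.frame with one row per individual: `value`, `mc_se`,
#'   `pattern`, `low_ess`.
#' @export
predict_liability_table <- function(prs, z_m = NA, z_f = NA, params,
                                    L = 1e6, seed = 1L, q_mother = NULL,
                                    q_father = NULL, ess_floor = 100) {
  stopifnot(inherits(params, "binary_params"), is.numeric(prs))
  assert_beta_set(params)
  n <- length(prs)
  z_m <- rep_len(z_m, n)
  z_f <- rep_len(z_f, n)
  if (anyNA(prs)) stop("`prs` must be observed for every individual")
  bad <- stats::na.omit(c(z_m, z_f))
  if (length(bad) && !all(bad %in% c(0, 1)))
    stop("parental status indicators must be 0, 1 or NA")

  h2 <- heritability(params)
  value <- numeric(n)
  mc_se <- rep(NA_real_, n)
  low_ess <- logical(n)
  has_m <- !is.na(z_m)
  has_f <- !is.na(z_f)
  pattern <- ifelse(has_m & has_f, "both",
                    ifelse(has_m, "mother_only",
                           ifelse(has_f, "father_only", "none")))

  if (h2 <= 0) {
    return(data.frame(value = 0, mc_se = 0, pattern = pattern,
                      low_ess = FALSE, stringsAsFactors = FALSE))
  }

  # one weighted sample set per (role, status) condition actually needed
  seed <- as.integer(seed)
  cond <- expand.grid(role = c("m", "f"), z = c(0, 1),
                      stringsAsFactors = FALSE)
  moments <- list()
  for (i in seq_len(nrow(cond))) {
    role <- cond$role[i]; z <- cond$z[i]
    needed <- if (role == "m") any(has_m & z_m == z)
              else any(has_f & z_f == z)
    if (!needed) next
    qp <- if (role == "m") q_mother else q_father
    s <- sample_parent_liability(z, qp, params, L, seed = seed + i,
                                 ess_floor = ess_floor)
    moments[[paste0(role, z)]] <- c(is_mean_se(s), low = s$low_ess)
  }
  get_mom <- function(role, z) moments[[paste0(role, z)]]

  both <- has_m & has_f
  if (any(both)) {
    w <- liability_weights(params, "both")
    for (zm in 0:1) for (zf in 0:1) {
      idx <- both & z_m == zm & z_f == zf
      if (!any(idx)) next
      mm <- get_mom("m", zm); mf <- get_mom("f", zf)
      value[idx] <- w[1] * mm["mean"] + w[2] * mf["mean"] + w[3] * prs[idx]
      mc_se[idx] <- sqrt(w[1]^2 * mm["se"]^2 + w[2]^2 * mf["se"]^2)
      low_ess[idx] <- mm["low"] > 0 || mf["low"] > 0
    }
  }
  single <- xor(has_m, has_f)
  if (any(single)) {
    w <- liability_weights(params, "single")
    for (role in c("m", "f")) for (z in 0:1) {
      idx <- single & (if (role == "m") has_m & z_m == z
                       else has_f & z_f == z)
      if (!any(idx)) next
      mp <- get_mom(role, z)
      value[idx] <- w[1] * mp["mean"] + w[2] * prs[idx]
      mc_se[idx] <- abs(w[1]) * mp["se"]
      low_ess[idx] <- mp["low"] > 0
    }
  }
  none <- !has_m & !has_f
  if (any(none)) value[none] <- params$alpha * prs[none]

  data.frame(value = value, mc_se = mc_se, pattern = pattern,
             low_ess = low_ess, stringsAsFactors = FALSE)
}

#' Reference covariate deviations for a parent
#'
#' The model never observes parents' covariates directly; by default a parent
#' is represented by the population reference values (deviation 0) with the
#' sex covariate, when present in the schema, set by the parent's role. Sex
#' is assumed coded 0 = female, 1 = male, with `sex_reference` the value at
#' which `mu0` is defined (e.g. the cohort mean).
#'
#' @param params A [binary_params()] object.
#' @param role `"mother"` or `"father"`.
#' @param sex_name Name of the sex covariate in the schema, default `"sex"`.
#' @param sex_reference Reference value of the sex covariate, default 0.5.
#' @return A named covariate deviation vector (or `NULL` when the schema is
#'   empty).
#' @export
parent_reference_q <- function(params, role = c("mother", "father"),
                               sex_name = "sex", sex_reference = 0.5) {
  role <- match.arg(role)
  if (length(params$gamma) == 0L) return(NULL)
  q <- stats::setNames(rep(0, length(params$gamma)), names(params$gamma))
  if (sex_name %in% names(q))
    q[sex_name] <- (if (role == "mother") 0 else 1) - sex_reference
  q
}
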