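#' Parameters of the continuous-trait latent factor model
#'
#' A z-scored polygenic trait is modelled as \eqn{Y = \alpha P + \beta G +
#' \epsilon}, where \eqn{P} is the genetic component captured by a polygenic
#' risk score, \eqn{G} is an orthogonal latent genetic component (under-captured
#' common variants, rare variants, interactions, shared familial environment),
#' and both components are standard normal and transmitted independently from
#' parents to children. The trait heritability is \eqn{h^2 = \alpha^2 + \beta^2}.
#'
#' @param alpha Standardized effect of the captured component \eqn{P}
#'   (unitless, non-negative). Give either `alpha` or `alpha_sq`.
#' @param beta Standardized effect of the latent component \eqn{G}
#'   (unitless, non-negative). Give either `beta` or `beta_sq`.
#' @param alpha_sq,beta_sq Alternatively, the variance fractions
#'   \eqn{\alpha^2} and \eqn{\beta^2}; convenient when working from
#'   variance-explained summary statistics.
#'
#' @return An object of class `continuous_params` with fields `alpha` and
#'   `beta`.
#' @examples
#' p <- continuous_params(alpha_sq = 0.367, beta_sq = 0.581)
#' heritability(p)
#' @export
continuous_params <- function(alpha = NULL, beta = NULL,
                              alpha_sq = NULL, beta_sq = NULL) {
  if (is.null(alpha)) {
    if (is.null(alpha_sq)) stop("give either `alpha` or `alpha_sq`")
    stopifnot(is.numeric(alpha_sq), length(alpha_sq) == 1L)
    if (alpha_sq < 0) stop("`alpha_sq` must be >= 0, got ", alpha_sq)
    alpha <- sqrt(alpha_sq)
  }
  if (is.null(beta)) {
    if (is.null(beta_sq)) stop("give either `beta` or `beta_sq`")
    stopifnot(is.numeric(beta_sq), length(beta_sq) == 1L)
    if (beta_sq < 0) stop("`beta_sq` must be >= 0, got ", beta_sq)
    beta <- sqrt(beta_sq)
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha < 0) stop("`alpha` must be >= 0 (violated bound: alpha >= 0)")
  if (beta < 0) stop("`beta` must be >= 0 (violated bound: beta >= 0)")
  h2 <- alpha^2 + beta^2
  if (h2 > 1 + 1e-8)
    stop("alpha^2 + beta^2 = ", signif(h2, 6),
         " exceeds 1 (violated bound: total heritability of a unit-variance trait)")
  structure(list(alpha = alpha, beta = beta), class = "continuous_params")
}

#' @export
print.continuous_params <- function(x, ...) {
  cat("Continuous-trait latent factor model parameters\n")
  cat(sprintf("  alpha = %.4f  (captured heritability alpha^2 = %.4f)\n",
              x$alpha, x$alpha^2))
  cat(sprintf("  beta  = %.4f  (under-captured heritability beta^2 = %.4f)\n",
              x$beta, x$beta^2))
  cat(sprintf("  total heritability h^2 = %.4f\n", heritability(x)))
  invisible(x)
}

#' Parameters of the binary-disease liability model
#'
#' Disease status follows a Bernoulli distribution with a logit link on the
#' genetic liability: \eqn{Z \mid P, G, Q \sim \mathrm{Bern}(\mathrm{expit}(
#' \mu_0 + \alpha P + \beta G + \gamma Q))}. Writing \eqn{H = \alpha P + \beta
#' G \sim N(0, \alpha^2 + \beta^2)}, parental disease history informs the
#' parental liability and hence the child's. Unlike the continuous model,
#' \eqn{\alpha} and \eqn{\beta} are log-odds effects and are not bounded above.
#'
#' @param mu0 Baseline log-odds of disease in the target population (at the
#'   covariate reference values).
#' @param alpha Log-odds effect per SD of the captured component \eqn{P}
#'   (non-negative).
#' @param beta Log-odds effect per SD of the latent component \eqn{G}
#'   (non-negative). May be `NA` while still to be estimated.
#' @param gamma Named numeric vector of covariate log-odds effects; names
#'   define the covariate schema (may be empty).
#'
#' @return An object of class `binary_params`.
#' @examples
#' binary_params(mu0 = -2, alpha = 0.3, beta = 0.7,
#'               gamma = c(age = 0.02, sex = 0.5))
#' @export
binary_params <- function(mu0, alpha, beta = NA_real_, gamma = numeric(0)) {
  stopifnot(is.numeric(mu0), length(mu0) == 1L, is.finite(mu0),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L,
            is.numeric(gamma))
  if (alpha < 0) stop("`alpha` must be >= 0 (violated bound: alpha >= 0)")
  if (!is.na(beta) && beta < 0)
    stop("`beta` must be >= 0 (violated bound: beta >= 0)")
  if (length(gamma) > 0L && is.null(names(gamma)))
    stop("`gamma` must be a named vector defining the covariate schema")
  structure(list(mu0 = mu0, alpha = alpha, beta = beta, gamma = gamma),
            class = "binary_params")
}

#' @export
print.binary_params <- function(x, ...) {
  cat("Binary-disease liability model parameters (log-odds scale)\n")
  cat(sprintf("  mu0   = %.4f  (baseline log-odds)\n", x$mu0))
  cat(sprintf("  alpha = %.4f  (per-SD effect of captured component P)\n",
              x$alpha))
  cat(sprintf("  beta  = %s  (per-SD effect of latent component G)\n",
              if (is.na(x$beta)) "NA (unset)" else sprintf("%.4f", x$beta)))
  if (length(x$gamma)) {
    cat("  covariate effects gamma:\n")
    for (nm in names(x$gamma))
      cat(sprintf("    %-12s %.4f\n", nm, x$gamma[[nm]]))
  } else cat("  no covariates\n")
  invisible(x)
}

#' Total heritability of a parameter set
#'
#' For continuous parameters, the variance fraction \eqn{\alpha^2+\beta^2} of
#' the unit-variance trait. For binary parameters, the variance
#' \eqn{\alpha^2+\beta^2} of the latent liability \eqn{H} (log-odds scale, not
#' a fraction of one); see [liability_scale_effect()] for conversion to
#' liability-scale heritability contributions.
#'
#' @param params A `continuous_params` or `binary_params` object.
#' @return A single number, \eqn{\alpha^2 + \beta^2}.
#' @export
heritability <- function(params) {
  UseMethod("heritability")
}

#' @export
heritability.continuous_params <- function(params) params$alpha^2 + params$beta^2

#' @export
heritability.binary_params <- function(params) {
  if (is.na(params$beta)) stop("`beta` is unset; estimate it first")
  params$alpha^2 + params$beta^2
}

assert_beta_set <- function(params) {
  if (is.na(params$beta))
    stop("`beta` is unset in these binary parameters; ",
         "estimate it first (see estimate_beta_line_search)")
  invisible(params)
}
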