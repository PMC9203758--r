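#' Summary-statistic inputs for model fitting
#'
#' Containers for the published summary statistics from which the model
#' parameters can be derived without individual-level data: variance
#' explained for a continuous trait, or odds ratios plus baseline log-odds
#' for a binary disease. Exactly one of the two blocks is populated.
#'
#' @param r2_prs Fraction of child trait variance explained by the polygenic
#'   score.
#' @param r2_midparent Fraction explained by the mid-parental z-score.
#' @return An object of class `summary_inputs`.
#' @examples
#' summary_inputs_continuous(0.367, 0.449)
#' @export
summary_inputs_continuous <- function(r2_prs, r2_midparent) {
  stopifnot(r2_prs >= 0, r2_prs <= 1, r2_midparent >= 0, r2_midparent <= 1)
  structure(list(continuous = list(r2_prs = r2_prs,
                                   r2_midparent = r2_midparent),
                 binary = NULL),
            class = "summary_inputs")
}

#' @rdname summary_inputs_continuous
#' @param or_prs_per_sd Odds ratio per SD of the polygenic score.
#' @param or_maternal_history,or_paternal_history Odds ratios for maternal /
#'   paternal disease history (covariate-adjusted, from a logistic model with
#'   both as independent variables).
#' @param baseline_log_odds Baseline log-odds of disease at the covariate
#'   reference values.
#' @param covariate_effects Named numeric vector of covariate log-odds
#'   effects (may be empty).
#' @export
summary_inputs_binary <- function(or_prs_per_sd, or_maternal_history,
                                  or_paternal_history, baseline_log_odds,
                                  covariate_effects = numeric(0)) {
  ors <- c(or_prs_per_sd, or_maternal_history, or_paternal_history)
  if (any(!is.finite(ors)) || any(ors <= 0))
    stop("all odds ratios must be finite and > 0")
  structure(list(continuous = NULL,
                 binary = list(or_prs_per_sd = or_prs_per_sd,
                               or_maternal_history = or_maternal_history,
                               or_paternal_history = or_paternal_history,
                               baseline_log_odds = baseline_log_odds,
                               covariate_effects = covariate_effects)),
            class = "summary_inputs")
}

#' Derive model parameters from summary statistics
#'
#' Continuous traits: \eqn{\hat\alpha^2 = r^2_{PRS}} and \eqn{\hat\beta^2}
#' from the mid-parental inversion ([estimate_beta_sq_from_midparent()]).
#' Binary diseases: \eqn{\hat\alpha = \log(OR_{PRS/SD})}, \eqn{\mu_0} and
#' \eqn{\gamma} passed through, and \eqn{\hat\beta} from the odds-ratio line
#' search ([estimate_beta_line_search()]); when the schema contains a sex
#' covariate the maternal and paternal theoretical ORs use role-specific sex
#' values, which is what makes the two observed ORs jointly informative.
#'
#' @param inputs A `summary_inputs` object.
#' @param sex_name,sex_reference Sex-covariate handling for the binary line
#'   search; see [parent_reference_q()].
#' @param ... Further arguments to [estimate_beta_line_search()] (`bracket`,
#'   `tol`, `objective`, `nodes`).
#' @return A [continuous_params()] or [binary_params()] object; for binary
#'   inputs the line-search report is attached as attribute `line_search`.
#' @examples
#' params_from_summary(summary_inputs_continuous(0.367, 0.449))
#' @export
params_from_summary <- function(inputs, sex_name = "sex",
                                sex_reference = 0.5, ...) {
  stopifnot(inherits(inputs, "summary_inputs"))
  if (!is.null(inputs$continuous)) {
    est <- estimate_beta_sq_from_midparent(inputs$continuous$r2_prs,
                                           inputs$continuous$r2_midparent)
    return(est$params)
  }
  b <- inputs$binary
  base <- binary_params(mu0 = b$baseline_log_odds,
                        alpha = log(b$or_prs_per_sd),
                        gamma = b$covariate_effects)
  fit <- estimate_beta_line_search(
    or_m_observed = b$or_maternal_history,
    or_f_observed = b$or_paternal_history,
    params = base,
    q_mother = parent_reference_q(base, "mother", sex_name, sex_reference),
    q_father = parent_reference_q(base, "father", sex_name, sex_reference),
    ...)
  out <- fit$params
  attr(out, "line_search") <- fit[c("beta", "objective",
                                    "or_m_theoretical", "or_f_theoretical")]
  out
}

#' Marginal training fits for a continuous trait
#'
#' Ordinary least-squares fits replicating the summary statistics the model
#' consumes: the \eqn{R^2} of the child trait z-score on the polygenic score,
#' and on the mid-parental z-score (rows with both parents observed).
#'
#' @param table A trio table (see [read_trio_table()]) with z-scored columns
#'   `pheno`, `prs`, `mother_pheno`, `father_pheno`.
#' @return A `summary_inputs` object (continuous block).
#' @export
fit_marginal_continuous_models <- function(table) {
  need <- c("pheno", "prs", "mother_pheno", "father_pheno")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ok_prs <- stats::complete.cases(table[c("pheno", "prs")])
  if (sum(ok_prs) < 3) stop("fewer than 3 complete rows for the PRS model")
  r2_prs <- summary(stats::lm(pheno ~ prs, data = table[ok_prs, ]))$r.squared
  mid <- (table$mother_pheno + table$father_pheno) / 2
  ok_mid <- !is.na(mid) & !is.na(table$pheno)
  if (sum(ok_mid) < 3)
    stop("fewer than 3 complete rows for the mid-parental model")
  r2_mid <- summary(stats::lm(table$pheno[ok_mid] ~ mid[ok_mid]))$r.squared
  summary_inputs_continuous(r2_prs, r2_mid)
}

#' Marginal training fits for a binary disease
#'
#' Replicates the two-model training recipe: (i) a covariate-adjusted
#' logistic regression of child status on the standardized polygenic score
#' gives \eqn{\hat\alpha} (log-OR per SD), \eqn{\hat\mu_0} and
#' \eqn{\hat\gamma}; (ii) a covariate-adjusted logistic regression of child
#' status on maternal and paternal disease history (as two independent
#' variables) gives the two observed odds ratios. \eqn{\hat\mu_0} is the
#' model (i) intercept evaluated at the covariate reference vector (the
#' training means), so downstream covariates are interpreted as deviations
#' from those means.
#'
#' @param table A trio table with columns `status`, `prs`, `mother_status`,
#'   `father_status` and the covariate columns.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param standardize_prs Standardize the polygenic score to unit SD on this
#'   table before fitting (default `TRUE`), so \eqn{\hat\alpha} is per SD.
#' @return A `summary_inputs` object (binary block), with the covariate
#'   reference vector attached as attribute `covariate_reference` and both
#'   fitted models as attribute `fits`.
#' @export
fit_marginal_binary_models <- function(table, covariates = character(),
                                       standardize_prs = TRUE) {
  need <- c("status", "prs", "mother_status", "father_status")
  miss <- setdiff(c(need, covariates), names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (all(is.na(table$mother_status)) && all(is.na(table$father_status)))
    stop("parental status columns are entirely missing")

  dat <- table
  if (standardize_prs)
    dat$prs <- (dat$prs - mean(dat$prs, na.rm = TRUE)) /
      stats::sd(dat$prs, na.rm = TRUE)

  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 50)
  f1 <- stats::reformulate(c("prs", covariates), response = "status")
  m1 <- stats::glm(f1, family = stats::binomial(), data = dat,
                   control = ctrl)
  f2 <- stats::reformulate(c("mother_status", "father_status", covariates),
                           response = "status")
  m2 <- stats::glm(f2, family = stats::binomial(), data = dat,
                   control = ctrl)
  for (m in list(m1, m2)) {
    if (!m$converged)
      stop("logistic regression did not converge after ", m$iter,
           " IRLS iterations")
    if (any(abs(stats::coef(m)) > 15, na.rm = TRUE))
      stop("likely separation: a fitted log-odds coefficient exceeds 15 ",
           "in absolute value")
  }
  b1 <- stats::coef(m1)
  ref <- if (length(covariates))
    vapply(dat[covariates], function(x) mean(x, na.rm = TRUE), numeric(1))
  else numeric(0)
  gamma_hat <- if (length(covariates)) b1[covariates] else numeric(0)
  mu0_hat <- unname(b1["(Intercept)"] + sum(gamma_hat * ref))
  b2 <- stats::coef(m2)

  out <- summary_inputs_binary(
    or_prs_per_sd = unname(exp(b1["prs"])),
    or_maternal_history = unname(exp(b2["mother_status"])),
    or_paternal_history = unname(exp(b2["father_status"])),
    baseline_log_odds = mu0_hat,
    covariate_effects = stats::setNames(as.numeric(gamma_hat), covariates))
  attr(out, "covariate_reference") <- ref
  attr(out, "fits") <- list(prs_model = m1, history_model = m2)
  out
}

#' Seeded train/test split of a trio table
#'
#' Defaults to a 10% training fraction, the split used to estimate model
#' parameters while holding out the bulk of a cohort for evaluation.
#'
#' @param table A trio table.
#' @param train_frac Fraction of rows assigned to training, default 0.1.
#' @param seed Integer seed.
#' @return A list with data.frames `train` and `test`.
#' @export
train_test_split <- function(table, train_frac = 0.1, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  set.seed(as.integer(seed))
  n <- nrow(table)
  idx <- sample.int(n, size = max(1L, round(train_frac * n)))
  list(train = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE])
}
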