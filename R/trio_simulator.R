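# Mendelian transmission of a standardized polygenic component: each child
# component is the mid-parental average plus N(0, 1/2) segregation noise,
# which reproduces Cov(parent, child) = 1/2 with unit variances everywhere
# without simulating individual loci.
mendelian_child <- function(x_m, x_f) {
  (x_m + x_f) / 2 + stats::rnorm(length(x_m), 0, sqrt(1 / 2))
}

# Latent components for n trios; optional P-G correlation hook (rho_pg) for
# robustness experiments only -- the model itself assumes orthogonality.
simulate_components <- function(n, rho_pg = 0) {
  p_m <- stats::rnorm(n); p_f <- stats::rnorm(n)
  g_m <- stats::rnorm(n); g_f <- stats::rnorm(n)
  if (rho_pg != 0) {
    g_m <- rho_pg * p_m + sqrt(1 - rho_pg^2) * g_m
    g_f <- rho_pg * p_f + sqrt(1 - rho_pg^2) * g_f
  }
  p_c <- mendelian_child(p_m, p_f)
  g_c <- mendelian_child(g_m, g_f)
  list(p_m = p_m, p_f = p_f, p_c = p_c, g_m = g_m, g_f = g_f, g_c = g_c)
}

#' Simulate parent-child trios for a continuous polygenic trait
#'
#' Generates trios under the latent factor model: parental components
#' \eqn{P, G} are iid standard normal; each child component is the
#' mid-parental average plus \eqn{N(0, 1/2)} segregation noise (realizing the
#' parent-child covariance of 1/2 with unit variances); traits are
#' \eqn{Y = \alpha P + \beta G + \epsilon} with residual variance
#' \eqn{1 - \alpha^2 - \beta^2}. Spouses are independent (no assortative
#' mating, no consanguinity).
#'
#' @param params A [continuous_params()] object.
#' @param n Number of trios (>= 1).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param keep_latent Keep the ground-truth latent component columns
#'   (default `TRUE`); disable to produce blind test fixtures.
#' @param rho_pg Optional correlation between \eqn{P} and \eqn{G} within each
#'   parent, default 0 (the model's orthogonality assumption); nonzero values
#'   are an assumption-violation hook for robustness checks only.
#' @return A data.frame with columns `id`, `prs` (= \eqn{P_C}),
#'   `mother_pheno`, `father_pheno`, `pheno` (child trait), and, when
#'   `keep_latent`, the six latent components. Generating parameters and the
#'   seed are attached as attributes `params` and `seed`.
#' @examples
#' tab <- simulate_continuous_trios(
#'   continuous_params(alpha_sq = 0.367, beta_sq = 0.581), 1000, seed = 1)
#' cor(tab$pheno, (tab$mother_pheno + tab$father_pheno) / 2)^2
#' @export
simulate_continuous_trios <- function(params, n, seed = NULL,
                                      keep_latent = TRUE, rho_pg = 0) {
  stopifnot(inherits(params, "continuous_params"), n >= 1)
  h2 <- heritability(params)
  if (h2 > 1 + 1e-8)
    stop("alpha^2 + beta^2 = ", signif(h2, 6), " exceeds 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cmp <- simulate_components(n, rho_pg)
  sd_e <- sqrt(max(0, 1 - h2))
  a <- params$alpha; b <- params$beta
  y_m <- a * cmp$p_m + b * cmp$g_m + stats::rnorm(n, 0, sd_e)
  y_f <- a * cmp$p_f + b * cmp$g_f + stats::rnorm(n, 0, sd_e)
  y_c <- a * cmp$p_c + b * cmp$g_c + stats::rnorm(n, 0, sd_e)
  out <- data.frame(id = paste0("trio", seq_len(n)), prs = cmp$p_c,
                    mother_pheno = y_m, father_pheno = y_f, pheno = y_c,
                    stringsAsFactors = FALSE)
  if (keep_latent)
    out <- cbind(out, data.frame(P_M = cmp$p_m, P_F = cmp$p_f, P_C = cmp$p_c,
                                 G_M = cmp$g_m, G_F = cmp$g_f, G_C = cmp$g_c))
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}

#' Default covariate specification for disease simulations
#'
#' A loose demographic frame for a middle-aged population cohort: age uniform
#' on 40-69 years (reference 54.5) and sex balanced (0 = female, 1 = male,
#' reference 0.5). Each entry has a `sampler(n)` and a `reference` value;
#' simulated linear predictors use deviations from the reference, so `mu0`
#' is the baseline log-odds of the reference individual.
#'
#' @return A named list of covariate specifications.
#' @export
default_covariate_spec <- function() {
  list(
    age = list(sampler = function(n) stats::runif(n, 40, 69),
               reference = 54.5),
    sex = list(sampler = function(n) stats::rbinom(n, 1, 0.5),
               reference = 0.5)
  )
}

#' Simulate parent-child trios for a binary disease
#'
#' Liabilities \eqn{H = \alpha P + \beta G} are built exactly as in
#' [simulate_continuous_trios()] (without a residual term: all remaining
#' variation enters through the Bernoulli draw); disease status is
#' \eqn{Z \sim \mathrm{Bern}(\mathrm{expit}(\mu_0 + H + \gamma (q -
#' q_{ref})))}. Child covariates are drawn from `covariate_spec`; parents
#' draw the same covariates except that a covariate named `sex` is fixed by
#' role (mother 0, father 1).
#'
#' @param params A [binary_params()] with `beta` set; `names(params$gamma)`
#'   must be a subset of `names(covariate_spec)`.
#' @param n Number of trios.
#' @param covariate_spec As [default_covariate_spec()]; use `list()` for no
#'   covariates.
#' @param seed Integer seed.
#' @param keep_latent Keep latent component and liability columns.
#' @param rho_pg See [simulate_continuous_trios()].
#' @return A data.frame with columns `id`, `prs`, `mother_status`,
#'   `father_status`, `status`, and the child covariate columns (raw values,
#'   not deviations). Attributes: `params`, `seed`, `covariate_spec`,
#'   `case_counts` (child/mother/father cases).
#' @examples
#' p <- binary_params(mu0 = -2, alpha = 0.3, beta = 0.7)
#' tab <- simulate_binary_trios(p, 1000, covariate_spec = list(), seed = 1)
#' mean(tab$status)
#' @export
simulate_binary_trios <- function(params, n,
                                  covariate_spec = default_covariate_spec(),
                                  seed = NULL, keep_latent = TRUE,
                                  rho_pg = 0) {
  stopifnot(inherits(params, "binary_params"), n >= 1)
  assert_beta_set(params)
  if (length(params$gamma) &&
      !all(names(params$gamma) %in% names(covariate_spec)))
    stop("covariate schema {", paste(names(params$gamma), collapse = ", "),
         "} not covered by `covariate_spec`")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cmp <- simulate_components(n, rho_pg)
  a <- params$alpha; b <- params$beta
  h_m <- a * cmp$p_m + b * cmp$g_m
  h_f <- a * cmp$p_f + b * cmp$g_f
  h_c <- a * cmp$p_c + b * cmp$g_c

  draw_q <- function(role) {
    q <- lapply(names(covariate_spec), function(nm) {
      if (nm == "sex" && role != "child") {
        rep(if (role == "mother") 0 else 1, n)
      } else covariate_spec[[nm]]$sampler(n)
    })
    names(q) <- names(covariate_spec)
    q
  }
  offset_of <- function(q) {
    if (length(params$gamma) == 0L) return(rep(0, n))
    Reduce(`+`, lapply(names(params$gamma), function(nm) {
      params$gamma[[nm]] * (q[[nm]] - covariate_spec[[nm]]$reference)
    }))
  }
  q_c <- draw_q("child"); q_m <- draw_q("mother"); q_f <- draw_q("father")
  z_m <- stats::rbinom(n, 1, stats::plogis(params$mu0 + h_m + offset_of(q_m)))
  z_f <- stats::rbinom(n, 1, stats::plogis(params$mu0 + h_f + offset_of(q_f)))
  z_c <- stats::rbinom(n, 1, stats::plogis(params$mu0 + h_c + offset_of(q_c)))

  out <- data.frame(id = paste0("trio", seq_len(n)), prs = cmp$p_c,
                    mother_status = z_m, father_status = z_f, status = z_c,
                    stringsAsFactors = FALSE)
  for (nm in names(covariate_spec)) out[[nm]] <- q_c[[nm]]
  if (keep_latent)
    out <- cbind(out, data.frame(P_M = cmp$p_m, P_F = cmp$p_f, P_C = cmp$p_c,
                                 G_M = cmp$g_m, G_F = cmp$g_f, G_C = cmp$g_c,
                                 H_M = h_m, H_F = h_f, H_C = h_c))
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  attr(out, "covariate_spec") <- covariate_spec
  attr(out, "case_counts") <- c(child = sum(z_c), mother = sum(z_m),
                                father = sum(z_f))
  out
}
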