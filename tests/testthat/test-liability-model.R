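test_that("disease probability follows the logit link with covariates", {
  expect_equal(disease_probability(0, NULL, binary_params(0, 0, 0)), 0.5)
  expect_equal(disease_probability(3, NULL, binary_params(-3, 0.2, 0.2)),
               0.5)
  p <- binary_params(-2, 0.3, 0.7, gamma = c(x = 0.1))
  expect_equal(disease_probability(1, c(x = 5), p), plogis(-0.5))
  expect_error(disease_probability(1, c(wrong = 5), p), "schema")
  expect_error(disease_probability(1, c(x = 1),
                                   binary_params(-2, 0.3, 0.7)),
               "empty covariate schema")
})

test_that("liability-scale conversion matches a high-precision evaluation", {
  expect_equal(liability_scale_effect(0, -3), 0)

  # independent evaluation of the probit/logit bridge with the explicit
  # unit-variance logistic CDF
  flog <- function(x) 1 / (1 + exp(-pi * x / sqrt(3)))
  d <- qnorm(flog(-3 + 0.5)) - qnorm(flog(-3))
  expect_equal(liability_scale_effect(0.5, -3), d / sqrt(1 + d^2),
               tolerance = 1e-12)
  expect_equal(liability_scale_effect(0.5, -3), 0.306, tolerance = 5e-3)

  # strictly increasing in the effect at fixed mu0
  taus <- liability_scale_effect(seq(0, 3, by = 0.1), -2)
  expect_true(all(diff(taus) > 0))
  # sign of tau matches the sign of the effect
  expect_lt(liability_scale_effect(-0.5, -3), 0)
})

test_that("theoretical parent-child OR matches Monte-Carlo integration", {
  expect_equal(theoretical_parent_child_or(binary_params(-2, 0, 0)), 1)

  p <- binary_params(-2, 0.3, 0.7)
  or_quad <- theoretical_parent_child_or(p)
  expect_gt(or_quad, 1)
  # doubling the node count leaves the value unchanged (converged)
  expect_equal(or_quad, theoretical_parent_child_or(p, nodes = 128L),
               tolerance = 1e-10)

  # brute-force Monte-Carlo integration of the joint Bernoulli-normal model
  set.seed(202)
  N <- 2e6
  h2 <- 0.3^2 + 0.7^2
  Lc <- chol(matrix(c(h2, h2 / 2, h2 / 2, h2), 2))
  hh <- matrix(rnorm(2 * N), N, 2) %*% Lc
  zc <- rbinom(N, 1, plogis(-2 + hh[, 1]))
  zp <- rbinom(N, 1, plogis(-2 + hh[, 2]))
  tab <- table(zc, zp)
  or_mc <- (tab["1", "1"] / tab["0", "1"]) / (tab["1", "0"] / tab["0", "0"])
  expect_lt(abs(log(or_quad) - log(or_mc)), 3 * log_or_se(tab))
})

test_that("theoretical OR is strictly increasing in beta", {
  ors <- vapply(seq(0, 2, by = 0.25), function(b)
    theoretical_parent_child_or(binary_params(-2, 0.3, b)), numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("line search recovers beta from observed odds ratios", {
  p0 <- binary_params(-2, 0.3)

  # observed ORs at the beta = 0 theoretical value give beta-hat = 0
  or0 <- theoretical_parent_child_or(binary_params(-2, 0.3, 0))
  fit0 <- estimate_beta_line_search(or0, or0, p0)
  expect_equal(fit0$beta, 0, tolerance = 1e-6)

  # self-consistency round trip at beta = 0.8
  truth <- binary_params(-2, 0.3, 0.8)
  or_t <- theoretical_parent_child_or(truth)
  fit <- estimate_beta_line_search(or_t, or_t, p0)
  expect_equal(fit$beta, 0.8, tolerance = 0.01)

  # inflating the observed ORs pushes the estimate up (monotonicity)
  fit_up <- estimate_beta_line_search(1.5 * or_t, 1.5 * or_t, p0)
  expect_gt(fit_up$beta, 0.8)

  # an OR far beyond anything attainable in the bracket is diagnosed
  expect_error(
    estimate_beta_line_search(500, 500, p0, bracket = c(0, 1)),
    "bracket")
})

test_that("line search separates maternal and paternal ORs via sex", {
  p <- binary_params(-2, 0.3, 0.8, gamma = c(sex = 0.5))
  qm <- parent_reference_q(p, "mother")
  qf <- parent_reference_q(p, "father")
  or_m <- theoretical_parent_child_or(p, q_parent = qm)
  or_f <- theoretical_parent_child_or(p, q_parent = qf)
  expect_false(isTRUE(all.equal(or_m, or_f)))
  fit <- estimate_beta_line_search(or_m, or_f,
                                   binary_params(-2, 0.3,
                                                 gamma = c(sex = 0.5)),
                                   q_mother = qm, q_father = qf)
  expect_equal(fit$beta, 0.8, tolerance = 0.01)
})

test_that("importance sampler matches grid quadrature of the posterior", {
  # degenerate prior: liability identically zero
  s0 <- sample_parent_liability(1, NULL, binary_params(-2, 0, 0), 100,
                                seed = 1)
  expect_equal(s0$values, rep(0, 100))
  expect_equal(s0$ess, 100)

  p <- binary_params(-2, 0.3, 0.8)  # h^2 = 0.73
  s <- sample_parent_liability(1, NULL, p, 2e5, seed = 11)
  expect_equal(sum(s$weights), 1)
  expect_true(all(s$weights >= 0))
  m <- sum(s$weights * s$values)
  se <- sqrt(sum(s$weights^2 * (s$values - m)^2))
  expect_gt(m, 0)  # cases have elevated liability
  expect_lt(abs(m - grid_posterior_mean(1, -2, 0.73)), 3 * se)

  s_ctrl <- sample_parent_liability(0, NULL, p, 2e5, seed = 12)
  m0 <- sum(s_ctrl$weights * s_ctrl$values)
  se0 <- sqrt(sum(s_ctrl$weights^2 * (s_ctrl$values - m0)^2))
  expect_lt(abs(m0 - grid_posterior_mean(0, -2, 0.73)), 3 * se0)

  # reproducible under a fixed seed; low-ESS flag is a warning, not an error
  s2 <- sample_parent_liability(1, NULL, p, 2e5, seed = 11)
  expect_identical(s$values, s2$values)
  tiny <- sample_parent_liability(1, NULL, p, 50, seed = 3)
  expect_true(tiny$low_ess)
})

test_that("liability predictor agrees with tensor-grid quadrature", {
  p <- binary_params(-2, 0.3, 0.7)
  pr <- predict_liability(0, 1, 1, p, L = 1e5, seed = 21)
  oracle <- grid_predictor_both(p, 1, 1, 0)
  expect_lt(abs(pr$value - oracle), 3 * pr$mc_se)
  expect_equal(pr$pattern, "both")

  # closed-form patterns
  expect_equal(predict_liability(1.2, NA, NA, p)$value, 0.36)
  expect_equal(predict_liability(0.7, NA, NA,
                                 binary_params(0, 0, 0))$value, 0)
})

test_that("liability predictor is monotone and symmetric", {
  grid <- expand.grid(mu0 = c(-3, -1), a = c(0.2, 0.5), b = c(0.4, 0.9))
  for (i in seq_len(nrow(grid))) {
    p <- binary_params(grid$mu0[i], grid$a[i], grid$b[i])
    v00 <- predict_liability(0.5, 0, 0, p, L = 2e4, seed = 31)$value
    v10 <- predict_liability(0.5, 1, 0, p, L = 2e4, seed = 31)$value
    v11 <- predict_liability(0.5, 1, 1, p, L = 2e4, seed = 31)$value
    expect_gt(v10, v00)   # flipping a parent 0 -> 1 raises the prediction
    expect_gt(v11, v10)
    vp <- predict_liability(1.0, 0, 0, p, L = 2e4, seed = 31)$value
    expect_gt(vp, v00)    # increasing the PRS raises the prediction
  }

  # mother/father exchange symmetry without a sex covariate: swapping the
  # statuses swaps which stream conditions on z = 1, so compare via the
  # table interface where streams are keyed by (role, status)
  p <- binary_params(-2, 0.3, 0.7)
  tab <- predict_liability_table(c(0.5, 0.5), z_m = c(1, 0), z_f = c(0, 1),
                                 p, L = 2e5, seed = 41)
  expect_equal(tab$value[1], tab$value[2], tolerance = 5 * max(tab$mc_se))
})

test_that("parental history carries no information as beta vanishes", {
  p <- binary_params(-2, 0.3, 1e-6)
  pr <- predict_liability(0.8, 1, 1, p, L = 5e4, seed = 51)
  expect_equal(pr$value, 0.3 * 0.8, tolerance = 1e-5)
})

test_that("grouped table prediction is exact, not an approximation", {
  p <- binary_params(-2, 0.3, 0.7)
  prs <- c(-1, 0, 1, -1, 0.3)
  zm <- c(1, 1, 1, 0, NA)
  zf <- c(0, 0, 0, 1, NA)
  tab <- predict_liability_table(prs, zm, zf, p, L = 5e4, seed = 61)

  # individuals sharing (z_m, z_f) share sample sets: their predictions
  # differ exactly by the PRS weight times the PRS difference
  w <- triopred:::liability_weights(p, "both")
  expect_equal(tab$value[3] - tab$value[1], w[["p_C"]] * 2,
               tolerance = 1e-12)
  # no-parent rows are closed form
  expect_equal(tab$value[5], 0.3 * 0.3)
  expect_true(is.na(tab$mc_se[5]))
  expect_equal(tab$pattern, c("both", "both", "both", "both", "none"))

  # each grouped value matches the quadrature oracle
  oracle <- grid_predictor_both(p, 1, 0, 0)
  expect_lt(abs(tab$value[2] - oracle), 4 * tab$mc_se[2])
})
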