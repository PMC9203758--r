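test_that("r2 and original-scale rmse behave at the extremes", {
  obs <- c(-1.2, 0.3, 0.8, 1.5, -0.4)
  perfect <- r2_and_rmse(obs, obs, scale_sd = 6.5)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)

  set.seed(131)
  obs_big <- rnorm(2e4)
  null_fit <- r2_and_rmse(rep(0, 2e4), obs_big, scale_sd = 6.5)
  expect_equal(null_fit$r2, 0)
  expect_equal(null_fit$rmse, 6.5, tolerance = 0.02)

  expect_error(r2_and_rmse(obs, rep(1, 5)), "zero variance")

  # sex-stratified back-transformation uses the per-stratum SD
  strat <- r2_and_rmse(c(0, 0, 0, 0), c(1, -1, 1, -1),
                       scale_sd = c(f = 6, m = 7),
                       strata = c("f", "f", "m", "m"))
  expect_equal(strat$rmse, sqrt((36 + 36 + 49 + 49) / 4))
})

test_that("rmse falls as r2 rises across nested predictors", {
  p <- height_params()
  tab <- simulate_continuous_trios(p, 5e4, seed = 132)
  prs_only <- predict_continuous(tab$prs, NA, NA, p)$value
  single <- predict_continuous(tab$prs, tab$mother_pheno, NA, p)$value
  joint <- predict_continuous(tab$prs, tab$mother_pheno, tab$father_pheno,
                              p)$value
  ms <- lapply(list(prs_only, single, joint),
               function(s) r2_and_rmse(s, tab$pheno, scale_sd = 6.5))
  r2s <- vapply(ms, `[[`, numeric(1), "r2")
  rmses <- vapply(ms, `[[`, numeric(1), "rmse")
  expect_true(all(diff(r2s) > 0))
  expect_true(all(diff(rmses) < 0))
})

test_that("auroc matches brute-force pair counting exactly", {
  expect_equal(auroc_auprc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auroc,
               0.75)
  expect_equal(auroc_auprc(c(1, 2, 3, 10, 11, 12),
                           c(0, 0, 0, 1, 1, 1))$auroc, 1)

  set.seed(141)
  for (rep in 1:5) {
    n <- sample(20:1000, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    # discretized scores force ties
    scores <- round(rnorm(n) + labels, 1)
    expect_equal(auroc_auprc(scores, labels)$auroc,
                 brute_auroc(scores, labels))
  }

  set.seed(142)
  lab <- rbinom(2e4, 1, 0.5)
  expect_equal(auroc_auprc(rnorm(2e4), lab)$auroc, 0.5, tolerance = 0.02)

  expect_error(auroc_auprc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("auprc is step-wise average precision", {
  # hand-enumerated: sorted scores give precisions 1, 1/2, 2/3 at the cases
  expect_equal(auroc_auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auprc,
               mean(c(1, 2 / 3)))
  expect_equal(auroc_auprc(c(1, 2, 3, 4), c(0, 0, 0, 1))$auprc, 1)
})

test_that("DeLong test is symmetric, degenerate-safe, and well powered", {
  set.seed(151)
  y <- rbinom(500, 1, 0.3)
  s <- rnorm(500) + y

  same <- delong_test(s, s, y)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  s2 <- rnorm(500) + 0.5 * y
  ab <- delong_test(s, s2, y)
  ba <- delong_test(s2, s, y)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$auroc_a - ab$auroc_b, -(ba$auroc_a - ba$auroc_b))

  # informative vs pure noise at n = 2000 is decisively separated
  set.seed(152)
  y2 <- rbinom(2000, 1, 0.3)
  informative <- rnorm(2000) + y2
  noise <- rnorm(2000)
  expect_lt(delong_test(informative, noise, y2)$p_value, 0.01)
})

test_that("DeLong agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(153)
  y <- rbinom(400, 1, 0.4)
  latent <- rnorm(400)
  sa <- latent + y + rnorm(400)
  sb <- latent + 0.8 * y + rnorm(400)
  ours <- delong_test(sa, sb, y)
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE),
                        pROC::roc(y, sb, quiet = TRUE), method = "delong")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(ours$auroc_a, as.numeric(ref$estimate[1]), tolerance = 1e-10)
})

test_that("NRI matches the hand-enumerated worked fixture", {
  # 8 individuals, 4 cases; at the 50th percentile (top 4 high risk) one
  # case is reclassified up and one noncase down
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  old <- c(10, 9, 3, 2, 8, 7, 4, 1)
  new <- c(10, 9, 8, 2, 3, 7, 4, 1)
  nri <- nri_at_percentiles(new, old, labels, percentiles = 50)
  expect_equal(unname(nri["p50"]), 50)

  # identical scores give zero NRI at every cut-off
  z <- nri_at_percentiles(old, old, labels, percentiles = c(50, 80))
  expect_equal(as.numeric(z), c(0, 0))

  # a cut-off leaving an empty risk class is flagged undefined: with heavy
  # ties the 99th percentile equals the maximum and nobody exceeds it
  tied <- c(1, 1, 1, 1, 2, 2, 2, 2)
  u <- nri_at_percentiles(tied, tied, labels, percentiles = 99)
  expect_true(is.na(u["p99"]))
  expect_true(attr(u, "undefined")["p99"])

  # antisymmetry under swapping new and old
  set.seed(161)
  y <- rbinom(500, 1, 0.3)
  a <- rnorm(500) + y; b <- rnorm(500) + 0.5 * y
  expect_equal(unname(nri_at_percentiles(a, b, y, 80)),
               -unname(nri_at_percentiles(b, a, y, 80)))
})

test_that("IDI is zero for identical scores and antisymmetric", {
  set.seed(171)
  y <- rbinom(800, 1, 0.3)
  a <- rnorm(800) + y
  b <- rnorm(800) + 0.5 * y
  expect_equal(idi(a, a, y), 0)
  expect_equal(idi(a, b, y), -idi(b, a, y), tolerance = 1e-10)
  # adding pure noise cannot systematically improve discrimination
  expect_lt(idi(a + rnorm(800, sd = 3), a, y), 1)
})

test_that("rank metrics are invariant under increasing transforms", {
  set.seed(181)
  y <- rbinom(300, 1, 0.4)
  s <- rnorm(300) + y
  s_old <- rnorm(300)
  mono <- function(x) exp(2 * x) + 5
  expect_equal(auroc_auprc(mono(s), y), auroc_auprc(s, y))
  expect_equal(unname(nri_at_percentiles(mono(s), mono(s_old), y, 80)),
               unname(nri_at_percentiles(s, s_old, y, 80)))
  expect_equal(delong_test(mono(s), mono(s_old), y)$p_value,
               delong_test(s, s_old, y)$p_value, tolerance = 1e-10)
  # IDI's calibrated probabilities are invariant under affine transforms
  expect_equal(idi(2 * s + 3, s_old, y), idi(s, s_old, y),
               tolerance = 1e-6)
})
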