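# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pair counting, grid quadrature, and
# permutation tests.

# height-like study conditions used repeatedly
height_params <- function() continuous_params(alpha_sq = 0.367,
                                              beta_sq = 0.581)

# brute-force AUROC over all case-control pairs (midrank tie handling)
brute_auroc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (x in cases)
    tot <- tot + sum(x > controls) + 0.5 * sum(x == controls)
  tot / (length(cases) * length(controls))
}

# 1-D trapezoid-grid posterior mean of a parent liability given status
grid_posterior_mean <- function(z, mu0, h2, offset = 0, nodes = 20001,
                                span = 8) {
  s <- sqrt(h2)
  g <- seq(-span * s, span * s, length.out = nodes)
  eta <- mu0 + g + offset
  lik <- if (z == 1) stats::plogis(eta) else stats::plogis(-eta)
  d <- lik * stats::dnorm(g, 0, s)
  sum(g * d) / sum(d)
}

# 2-D tensor-grid quadrature of the both-parent liability predictor: the
# posterior factorizes across parents and the inner conditional expectation
# is linear, evaluated on the full grid for independence from the package
grid_predictor_both <- function(params, z_m, z_f, prs, nodes = 801,
                                span = 8) {
  h2 <- params$alpha^2 + params$beta^2
  s <- sqrt(h2)
  g <- seq(-span * s, span * s, length.out = nodes)
  post <- function(z) {
    eta <- params$mu0 + g
    lik <- if (z == 1) stats::plogis(eta) else stats::plogis(-eta)
    d <- lik * stats::dnorm(g, 0, s)
    d / sum(d)
  }
  a <- params$alpha
  A <- matrix(c(h2, 0, a / 2, 0, h2, a / 2, a / 2, a / 2, 1), 3, 3)
  w <- solve(A, c(h2 / 2, h2 / 2, a))
  W <- outer(post(z_m), post(z_f))
  HM <- matrix(g, nodes, nodes)
  sum(W * (w[1] * HM + w[2] * t(HM))) + w[3] * prs
}

# paired permutation test for the AUROC difference of two correlated scores
permutation_delong_p <- function(scores_a, scores_b, labels, B = 10000,
                                 seed = 1) {
  set.seed(seed)
  n <- length(labels)
  n1 <- sum(labels == 1); n0 <- n - n1
  fast_auc <- function(s) {
    r <- rank(s, ties.method = "average")
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  obs <- abs(fast_auc(scores_a) - fast_auc(scores_b))
  hits <- 0L
  for (b in seq_len(B)) {
    flip <- stats::runif(n) < 0.5
    sa <- ifelse(flip, scores_b, scores_a)
    sb <- ifelse(flip, scores_a, scores_b)
    if (abs(fast_auc(sa) - fast_auc(sb)) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / B
}

# Monte-Carlo standard error of a log odds ratio from a 2x2 count table
log_or_se <- function(tab) sqrt(sum(1 / tab))
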