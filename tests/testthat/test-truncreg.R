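test_that("log-likelihood reduces to known closed forms", {
  # no truncation: ordinary normal log-likelihood
  set.seed(1)
  y <- rnorm(20, 2, 0.5)
  Zd <- cbind(1, rnorm(20))
  beta <- c(1.8, 0.3); sigma <- 0.6
  ll <- truncnorm_loglik(y, Zd, beta, sigma)
  mu <- drop(Zd %*% beta)
  expect_equal(ll, sum(dnorm(y, mu, sigma, log = TRUE)), tolerance = 1e-12)

  # single observation with zero residual
  expect_equal(truncnorm_loglik(1.5, matrix(1), 1.5, 0.7),
               -log(0.7) - 0.5 * log(2 * pi), tolerance = 1e-12)

  # two-sided truncation matches the quadrature oracle
  y3 <- c(0.2, 0.5, 0.9)
  Zd3 <- cbind(1, c(-1, 0, 1))
  expect_equal(truncnorm_loglik(y3, Zd3, c(0.5, 0.2), 0.3, 0, 1),
               oracle_truncnorm_loglik(y3, Zd3, c(0.5, 0.2), 0.3, 0, 1),
               tolerance = 1e-9)
  # one-sided truncation, same oracle
  y1 <- c(1.1, 1.4, 2.2)
  expect_equal(truncnorm_loglik(y1, Zd3, c(1.2, 0.1), 0.4, 1, Inf),
               oracle_truncnorm_loglik(y1, Zd3, c(1.2, 0.1), 0.4, 1, Inf),
               tolerance = 1e-9)

  expect_error(truncnorm_loglik(c(0.5, 1.2), cbind(1, 1), 1, 1, 0, 1),
               "observation\\(s\\) 2")
})

test_that("analytic gradient matches central differences", {
  set.seed(4)
  n <- 40
  Z <- matrix(rnorm(n * 2), n)
  Zd <- cbind(1, Z)
  y <- hospeff:::rtrunc_norm(n, drop(Zd %*% c(1.3, 0.3, -0.2)), 0.2,
                             lower = 1)
  par <- c(1.25, 0.25, -0.15, log(0.25))
  f <- function(p) truncnorm_loglik(y, Zd, p[1:3], exp(p[4]), 1, Inf)
  g <- hospeff:::truncnorm_grad(y, Zd, par[1:3], exp(par[4]), 1, Inf)
  fd <- vapply(1:4, function(k) {
    e <- replace(rep(0, 4), k, 1e-6)
    (f(par + e) - f(par - e)) / 2e-6
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-5)
})

test_that("unbounded fit recovers least squares; intercept-only recovers the location MLE", {
  set.seed(2)
  n <- 150
  Z <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b")))
  y <- drop(1 + Z %*% c(0.5, -0.3) + rnorm(n, 0, 0.4))
  fit <- fit_truncreg(y, Z)
  ls <- lm.fit(cbind(1, Z), y)
  expect_equal(unname(fit$coefficients), unname(ls$coefficients),
               tolerance = 1e-4)
  expect_equal(fit$sigma, sqrt(mean(ls$residuals^2)), tolerance = 1e-4)

  # intercept-only truncated fit equals the 1-d location MLE by direct
  # profile search
  yt <- hospeff:::rtrunc_norm(80, 1.2, 0.3, lower = 1)
  fit0 <- fit_truncreg(yt, lower = 1)
  prof <- function(m) {
    o <- optimize(function(s) -truncnorm_loglik(yt, matrix(1, 80), m, s,
                                                1, Inf),
                  c(0.01, 2))
    -o$objective
  }
  grid <- seq(0.5, 1.6, by = 0.001)
  m_best <- grid[which.max(vapply(grid, prof, numeric(1)))]
  expect_equal(unname(fit0$coefficients[1]), m_best, tolerance = 2e-3)
})

test_that("MLE recovers known truncated-model parameters at large n", {
  set.seed(9)
  n <- 2000
  Z <- matrix(rnorm(n * 2), n)
  beta <- c(1.3, 0.3, -0.2); sigma <- 0.2
  y <- hospeff:::rtrunc_norm(n, drop(cbind(1, Z) %*% beta), sigma,
                             lower = 1)
  fit <- fit_truncreg(y, Z, lower = 1)
  V <- fit$vcov
  se <- sqrt(diag(V))[1:3]
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
  expect_lt(abs(fit$sigma - sigma), 0.02)
  expect_gt(fit$wald, 0)
  expect_true(is.finite(fit$loglik))
})

test_that("optimum is invariant to affine covariate rescaling", {
  set.seed(11)
  n <- 120
  Z <- matrix(rnorm(n * 2), n)
  y <- hospeff:::rtrunc_norm(n, drop(cbind(1, Z) %*% c(1.3, 0.3, -0.2)),
                             0.2, lower = 1)
  f1 <- fit_truncreg(y, Z, lower = 1)
  Z2 <- Z; Z2[, 1] <- Z[, 1] * 10
  f2 <- fit_truncreg(y, Z2, lower = 1)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(unname(f2$coefficients[2] * 10),
               unname(f1$coefficients[2]), tolerance = 1e-4)
})

test_that("algorithm 2 is deterministic and respects its preconditions", {
  pan <- simulate_panel(recovery_config(n = 40, seed = 31))
  s1 <- sw_algorithm2(pan, "crs", L1 = 10, L2 = 20, seed = 6)
  s2 <- sw_algorithm2(pan, "crs", L1 = 10, L2 = 20, seed = 6)
  expect_identical(s1$ci, s2$ci)
  expect_identical(s1$boot, s2$boot)
  expect_error(sw_algorithm2(pan, "crs", L1 = 0, L2 = 5, seed = 1),
               ">= 1")
  expect_error(sw_algorithm2(pan, "crs", L1 = 5, L2 = 5), "seed")
  nocov <- simulate_panel(recovery_config(n = 20, beta_true = c(1.3),
                                          seed = 2))
  expect_error(sw_algorithm2(nocov, "crs", L1 = 5, L2 = 5, seed = 1),
               "covariates")
  expect_true(all(s1$ci[, "lower"] <= s1$ci[, "upper"]))
})

test_that("step-5 bootstrap coefficients centre on the stage-2 estimates", {
  pan <- simulate_panel(recovery_config(n = 80, seed = 41))
  sw <- sw_algorithm2(pan, "crs", L1 = 50, L2 = 400, seed = 13)
  bsd <- apply(sw$boot, 2, sd)
  k <- length(sw$coefficients)
  centre_gap <- abs(colMeans(sw$boot)[1:k] - sw$coefficients)
  expect_true(all(centre_gap <= 3 * bsd[1:k] / sqrt(400)))
})

test_that("shephard convention flips the coefficient signs", {
  pan <- simulate_panel(recovery_config(n = 80, seed = 43))
  sf <- sw_algorithm2(pan, "crs", L1 = 30, L2 = 50, seed = 3)
  ss <- sw_algorithm2(pan, "crs", L1 = 30, L2 = 50, seed = 3,
                      response_convention = "shephard01")
  # covariate 1 raises inefficiency (positive Farrell coefficient) and so
  # lowers the Shephard score
  expect_gt(unname(sf$coefficients[2]), 0)
  expect_lt(unname(ss$coefficients[2]), 0)
})

test_that("double-bootstrap coverage is not inferior to the naive two-stage fit", {
  reps <- 50
  beta_true <- c(1.3, 0.3, -0.2, 0)
  cover_sw <- matrix(FALSE, reps, 3)
  cover_naive <- matrix(FALSE, reps, 3)
  for (rr in seq_len(reps)) {
    pan <- simulate_panel(recovery_config(n = 60,
                                          beta_true = beta_true,
                                          seed = 5000 + rr))
    sw <- sw_algorithm2(pan, "crs", L1 = 50, L2 = 150,
                        seed = 6000 + rr)
    ci <- sw$ci[2:4, , drop = FALSE]
    cover_sw[rr, ] <- ci[, "lower"] <= beta_true[2:4] &
      beta_true[2:4] <= ci[, "upper"]
    nf <- sw$naive_fit
    se <- sqrt(diag(nf$vcov))[2:4]
    lo <- nf$coefficients[2:4] - 1.96 * se
    hi <- nf$coefficients[2:4] + 1.96 * se
    cover_naive[rr, ] <- lo <= beta_true[2:4] & beta_true[2:4] <= hi
  }
  expect_gte(mean(cover_sw), mean(cover_naive) - 0.05)
})
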