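# Independent oracles and fixture builders shared across the test files.

toy_panel <- function(df) {
  dmu_panel(df, id = "id",
            inputs = grep("^x", names(df), value = TRUE),
            outputs = grep("^y", names(df), value = TRUE))
}

# random valid panel with strictly positive inputs/outputs
random_panel <- function(n, p, q, seed) {
  set.seed(seed)
  d <- data.frame(id = sprintf("u%02d", seq_len(n)))
  for (k in seq_len(p)) d[[paste0("x", k)]] <- runif(n, 0.5, 5)
  for (m in seq_len(q)) d[[paste0("y", m)]] <- runif(n, 0.5, 5)
  toy_panel(d)
}

# ratio-form closed form for 1-input/1-output CRS Farrell distance
oracle_crs_ratio <- function(x, y, i) max(y / x) / (y[i] / x[i])

# Staged-grid brute-force search over intensity weights, independent of the
# simplex path.  Enumerates supports up to the Caratheodory bound and
# refines a box grid around the incumbent; accuracy well under 0.01 on the
# unit scales used in the tests.
oracle_dea_grid <- function(panel, i, rts, stages = 4, grid_n = 9) {
  Xr <- panel$X; Yr <- panel$Y
  p <- nrow(Xr); q <- nrow(Yr); n <- ncol(Xr)
  x0 <- Xr[, i]; y0 <- Yr[, i]
  msup <- min(n, p + q + (rts != "crs"))
  pos_out <- y0 > 0

  lam_of <- function(S, W) {
    # W: k x m candidate weights; returns max feasible lambda
    xin <- Xr[, S, drop = FALSE] %*% W
    feas <- colSums(xin > x0 + 1e-9) == 0
    if (rts == "nirs") feas <- feas & (colSums(W) <= 1 + 1e-9)
    if (rts == "vrs") feas <- feas & (abs(colSums(W) - 1) <= 1e-9)
    if (!any(feas)) return(list(lam = -Inf, w = NULL))
    yout <- Yr[, S, drop = FALSE] %*% W[, feas, drop = FALSE]
    lam <- apply(yout[pos_out, , drop = FALSE], 2,
                 function(yy) min(yy / y0[pos_out]))
    j <- which.max(lam)
    list(lam = lam[j], w = W[, feas, drop = FALSE][, j])
  }

  best <- -Inf
  for (k in seq_len(msup)) {
    for (S in utils::combn(n, k, simplify = FALSE)) {
      ub <- vapply(S, function(j) {
        pos <- Xr[, j] > 0
        b <- if (any(pos)) min(x0[pos] / Xr[pos, j]) else Inf
        if (rts == "crs") min(b, 50) else min(b, 1)
      }, numeric(1))
      if (rts == "vrs" && sum(ub) < 1 - 1e-9) next
      lo <- rep(0, k); hi <- ub
      incumbent <- NULL
      for (st in seq_len(stages)) {
        grids <- Map(function(a, b) seq(a, b, length.out = grid_n), lo, hi)
        W <- t(as.matrix(expand.grid(grids)))
        if (rts == "vrs") {
          # project onto the simplex slice: rescale candidates to sum 1
          s <- colSums(W)
          keep <- s > 1e-12
          W <- sweep(W[, keep, drop = FALSE], 2, s[keep], "/")
          W <- W[, colSums(W > ub + 1e-9) == 0, drop = FALSE]
          if (!ncol(W)) break
        }
        r <- lam_of(S, W)
        if (is.null(r$w)) break
        if (r$lam > best) best <- r$lam
        incumbent <- r$w
        step <- (hi - lo) / (grid_n - 1)
        lo <- pmax(0, incumbent - step)
        hi <- pmin(ub, incumbent + step)
      }
    }
  }
  best
}

# quadrature oracle for the truncated-normal log-likelihood
oracle_truncnorm_loglik <- function(y, Zd, beta, sigma, lower, upper) {
  mu <- drop(as.matrix(Zd) %*% beta)
  sum(vapply(seq_along(y), function(i) {
    denom <- stats::integrate(stats::dnorm, lower, upper, mean = mu[i],
                              sd = sigma, rel.tol = 1e-12)$value
    log(stats::dnorm(y[i], mu[i], sigma) / denom)
  }, numeric(1)))
}

# permutation-test oracle for the two-sample mean comparison
oracle_perm_p <- function(a, b, nperm = 1e4, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (k in seq_len(nperm)) {
    idx <- sample.int(length(pooled), na)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12)
      hits <- hits + 1L
  }
  hits / nperm
}

# small known-truth DGP used by the recovery and coverage tests:
# constant-returns Cobb-Douglas frontier (exponents sum to 1) so the true
# CRS Farrell distance of unit i equals its generated delta_i
recovery_config <- function(n = 100, beta_true = c(1.3, 0.3, -0.2, 0),
                            sigma_true = 0.15, seed = 1) {
  r <- length(beta_true) - 1
  synthetic_config(
    c(all = n),
    input_scales = cbind(mean = c(10, 20), sd = c(3, 5)),
    output_multipliers = 5,
    frontier_exponents = c(0.5, 0.5),
    covariate_scales = if (r > 0) cbind(mean = rep(0, r), sd = rep(1, r))
                       else matrix(0, 0, 2),
    beta_true = beta_true, sigma_true = sigma_true, seed = seed)
}
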