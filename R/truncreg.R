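#' Truncated-normal log-likelihood
#'
#' Log-likelihood of a linear model whose response is observed only inside
#' `(lower, upper)`:
#' `sum_i [ log phi((y_i - z_i b)/s) - log s - log(Phi((upper - z_i b)/s)
#'  - Phi((lower - z_i b)/s)) ]`.
#' With both bounds infinite this is the ordinary normal log-likelihood.
#'
#' @param y response vector, strictly inside `(lower, upper)`.
#' @param Zd design matrix (n x k, including any intercept column).
#' @param beta coefficient vector of length k.
#' @param sigma positive scale.
#' @param lower,upper truncation bounds (either may be infinite).
#' @return The scalar log-likelihood.
#' @export
truncnorm_loglik <- function(y, Zd, beta, sigma, lower = -Inf,
                             upper = Inf) {
  Zd <- as.matrix(Zd)
  if (lower >= upper) stop("lower bound must be below upper bound")
  if (sigma <= 0) stop("sigma must be positive")
  bad <- which(y <= lower | y >= upper)
  if (length(bad))
    stop("response on or outside the truncation bounds for observation(s) ",
         paste(bad, collapse = ", "))
  mu <- drop(Zd %*% beta)
  r <- (y - mu) / sigma
  logdenom <- if (is.infinite(lower) && is.infinite(upper)) {
    0
  } else if (is.infinite(upper)) {
    pnorm((lower - mu) / sigma, lower.tail = FALSE, log.p = TRUE)
  } else if (is.infinite(lower)) {
    pnorm((upper - mu) / sigma, log.p = TRUE)
  } else {
    la <- pnorm((lower - mu) / sigma, log.p = TRUE)
    lb <- pnorm((upper - mu) / sigma, log.p = TRUE)
    lb + log1p(-exp(la - lb))
  }
  sum(dnorm(r, log = TRUE) - log(sigma) - logdenom)
}

# gradient of truncnorm_loglik in (beta, log sigma); the phi/D Mills-ratio
# terms are formed on the log scale so deep truncation does not overflow
truncnorm_grad <- function(y, Zd, beta, sigma, lower, upper) {
  mu <- drop(Zd %*% beta)
  r <- (y - mu) / sigma
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  logD <- if (is.infinite(lower) && is.infinite(upper)) {
    rep(0, length(mu))
  } else if (is.infinite(upper)) {
    pnorm(a, lower.tail = FALSE, log.p = TRUE)
  } else if (is.infinite(lower)) {
    pnorm(b, log.p = TRUE)
  } else {
    la <- pnorm(a, log.p = TRUE)
    lb <- pnorm(b, log.p = TRUE)
    lb + log1p(-exp(la - lb))
  }
  ratio_a <- if (is.infinite(lower)) 0 else exp(dnorm(a, log = TRUE) - logD)
  ratio_b <- if (is.infinite(upper)) 0 else exp(dnorm(b, log = TRUE) - logD)
  ara <- if (is.infinite(lower)) 0 else a * ratio_a
  brb <- if (is.infinite(upper)) 0 else b * ratio_b
  gb_obs <- (r - (ratio_a - ratio_b)) / sigma        # d/d beta_j via z_ij
  gbeta <- drop(crossprod(Zd, gb_obs))
  glogsig <- sum(-1 + r^2 + (brb - ara))             # chain rule: log sigma
  c(gbeta, glogsig)
}

#' Fit a truncated-normal regression by maximum likelihood
#'
#' Maximises [truncnorm_loglik()] over `(beta, log sigma)` by BFGS with an
#' analytic gradient, starting from ordinary least squares.  Reports the
#' Wald statistic for joint nullity of all non-intercept coefficients.
#'
#' @param y response, strictly inside the bounds.
#' @param Z covariate matrix (n x r, *without* the intercept, which is
#'   added internally); may have zero columns for an intercept-only fit.
#' @param lower,upper truncation bounds.
#' @param start optional start `c(beta, sigma)`.
#' @return An object of class `truncreg_fit`: `coefficients` (named,
#'   intercept first), `sigma`, `loglik`, `wald`, `vcov` (for
#'   `(beta, log sigma)`), `convergence`, `n`, `bounds`.
#' @export
fit_truncreg <- function(y, Z = NULL, lower = -Inf, upper = Inf,
                         start = NULL) {
  if (is.null(Z)) Z <- matrix(0, length(y), 0)
  Z <- as.matrix(Z)
  n <- length(y)
  r <- ncol(Z)
  if (n <= r + 2)
    stop("need more than r + 2 = ", r + 2, " observations, got ", n)
  cn <- colnames(Z)
  if (is.null(cn) && r > 0) cn <- paste0("z", seq_len(r))

  # standardise the design internally: covariates at very different scales
  # (counts, percentages, logs of near-constant quantities) make the raw
  # likelihood surface ill-conditioned; estimates are mapped back below
  ctr <- if (r > 0) colMeans(Z) else numeric(0)
  scl <- if (r > 0) apply(Z, 2, sd) else numeric(0)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Zs <- if (r > 0) sweep(sweep(Z, 2, ctr), 2, scl, "/") else Z
  Zd <- cbind("(Intercept)" = 1, Zs)
  colnames(Zd) <- c("(Intercept)", cn)

  if (is.null(start)) {
    ls <- lm.fit(Zd, y)
    s0 <- sqrt(max(mean(ls$residuals^2), 1e-6))
    start <- c(ls$coefficients, s0)
  } else {
    b <- start[seq_len(r + 1)]
    bs <- b[-1] * scl
    start <- c(b[1] + sum(b[-1] * ctr), bs, start[r + 2])
  }
  par0 <- c(start[seq_len(r + 1)], log(start[r + 2]))
  negll <- function(par) {
    s <- exp(par[r + 2])
    -truncnorm_loglik(y, Zd, par[seq_len(r + 1)], s, lower, upper)
  }
  neggr <- function(par) {
    s <- exp(par[r + 2])
    -truncnorm_grad(y, Zd, par[seq_len(r + 1)], s, lower, upper)
  }
  opt <- optim(par0, negll, neggr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  sigma <- unname(exp(opt$par[r + 2]))
  if (sigma < 1e-8)
    stop("degenerate fit: sigma collapsed below 1e-8")
  if (opt$convergence != 0) {
    gn <- sqrt(sum(neggr(opt$par)^2))
    if (gn > 1e-4)
      stop("truncated regression did not converge (code ",
           opt$convergence, ", |gradient| = ", format(gn), ")")
  }
  beta_s <- opt$par[seq_len(r + 1)]
  # back-transform to the original covariate scale
  beta <- beta_s
  if (r > 0) {
    beta[-1] <- beta_s[-1] / scl
    beta[1] <- beta_s[1] - sum(beta_s[-1] * ctr / scl)
  }
  beta <- setNames(beta, colnames(Zd))
  H <- optimHess(opt$par, negll, neggr)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V) && r > 0) {
    # Jacobian of (beta_orig, log sigma) wrt (beta_std, log sigma)
    J <- diag(r + 2)
    J[1, 2:(r + 1)] <- -ctr / scl
    for (k in seq_len(r)) J[k + 1, k + 1] <- 1 / scl[k]
    V <- J %*% V %*% t(J)
  }
  wald <- NA_real_
  if (!is.null(V) && r > 0) {
    idx <- 2:(r + 1)
    Vb <- V[idx, idx, drop = FALSE]
    wald <- tryCatch(drop(t(beta[idx]) %*% solve(Vb, beta[idx])),
                     error = function(e) NA_real_)
  }
  structure(list(coefficients = beta, sigma = sigma,
                 loglik = -opt$value, wald = wald, vcov = V,
                 convergence = opt$convergence, n = n,
                 bounds = c(lower, upper)),
            class = "truncreg_fit")
}

#' @export
print.truncreg_fit <- function(x, ...) {
  cat("<truncreg_fit> n=", x$n, ", bounds=(",
      paste(format(x$bounds), collapse = ", "), ")\n", sep = "")
  print(round(x$coefficients, 4))
  cat("sigma=", format(x$sigma, digits = 4),
      "  loglik=", format(x$loglik, digits = 6),
      "  Wald=", format(x$wald, digits = 4), "\n", sep = "")
  invisible(x)
}

# draw a response vector from the fitted truncated model (vectorised)
draw_truncated_response <- function(mu, sigma, lower, upper) {
  rtrunc_norm(length(mu), mu, sigma, lower, upper)
}

# refit with up to `retries` redraws of the replicate on failure
refit_with_retry <- function(draw, Z, lower, upper, retries = 5) {
  for (k in seq_len(retries)) {
    y <- draw()
    fit <- tryCatch(fit_truncreg(y, Z, lower, upper),
                    error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  stop("inner truncated-regression fit failed after ", retries, " redraws")
}

transform_covariates <- function(Z, transforms) {
  # Z is r x n (panel layout); returns n x r design-ready matrix
  if (nrow(Z) == 0) stop("panel has no covariates")
  if (is.null(transforms)) transforms <- rep("identity", nrow(Z))
  t(apply_transforms(Z, transforms))
}

#' Simar-Wilson algorithm 2: double-bootstrap truncated regression
#'
#' The two-stage procedure with internal bias correction:
#' \enumerate{
#'   \item estimate Farrell distances `lambda_hat` by DEA under `rts`;
#'   \item fit a left-truncated (at 1) normal regression of `lambda_hat`
#'     on the covariates, using units with `lambda_hat > 1`;
#'   \item `L1` parametric-bootstrap loops: draw inefficiencies
#'     `delta* = z beta_hat + eps >= 1`, deflate each unit's frontier
#'     projection by `delta*`, re-solve the DEA for every original unit,
#'     and bias-correct `lambda_hat` to `lambda_bc`;
#'   \item refit the truncated regression of `lambda_bc` on the covariates
#'     (units clamped at exactly 1 are excluded, with a logged count);
#'   \item `L2` loops: simulate responses from the refitted model, refit,
#'     and collect the bootstrap distribution of `(beta, sigma)`;
#'   \item report percentile confidence intervals at level `1 - alpha`.
#' }
#'
#' With `response_convention = "farrell_ge1"` (the algorithm's native form)
#' the response is the Farrell distance, truncated below at 1, and a
#' *negative* coefficient means the covariate improves efficiency.  With
#' `"shephard01"` the response is the Shephard score in (0, 1) with
#' two-sided truncation, matching the published sign convention where a
#' positive coefficient improves efficiency.
#'
#' @param panel a [dmu_panel()] with covariates.
#' @param rts technology for the stage-1 scores (default `"crs"`, i.e.
#'   technical efficiency as the dependent variable).
#' @param L1 replications of the inner bias-correction loop.
#' @param L2 replications of the inference loop (default 2000).
#' @param alpha two-sided CI level is `1 - alpha`.
#' @param seed integer seed (required).
#' @param response_convention `"farrell_ge1"` or `"shephard01"`.
#' @param transforms per-covariate `"identity"`/`"log"` applied before the
#'   regression; defaults to the generating config's transforms when the
#'   panel is synthetic, else identity.
#' @return An object of class `sw2_result`: the stage-2 `fit`
#'   (a `truncreg_fit` on the bias-corrected scores), `ci` (percentile
#'   intervals per coefficient and for sigma), `boot` (L2 x (r+2) draws),
#'   `lambda_bc`, `excluded_clamped`, `naive_fit` (stage-2 fit on the raw
#'   scores), and the run parameters.
#' @export
sw_algorithm2 <- function(panel, rts = c("crs", "vrs"), L1 = 100,
                          L2 = 2000, alpha = 0.05, seed,
                          response_convention = c("farrell_ge1",
                                                  "shephard01"),
                          transforms = NULL) {
  stopifnot(inherits(panel, "dmu_panel"))
  rts <- match.arg(rts)
  response_convention <- match.arg(response_convention)
  if (L1 < 1 || L2 < 1) stop("L1 and L2 must be >= 1")
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (nrow(panel$Z) == 0) stop("panel has no covariates")
  if (is.null(transforms)) {
    cfg <- attr(panel, "config")
    transforms <- if (!is.null(cfg)) cfg$covariate_transforms
  }
  Zt <- transform_covariates(panel$Z, transforms)
  n <- nrow(Zt)
  r <- ncol(Zt)
  Zd <- cbind(1, Zt)

  lam <- pmax(solve_dea(panel, rts)$lambda, 1)
  shep <- response_convention == "shephard01"
  bounds <- if (shep) c(0, 1) else c(1, Inf)
  to_resp <- function(l) if (shep) 1 / l else l
  to_farrell <- function(v) if (shep) 1 / v else v

  with_seed(seed, function() {
    # (2) stage-2 fit on raw scores (inefficient units only)
    keep <- lam > 1 + 1e-9
    if (sum(keep) < r + 3)
      stop("fewer than r + 3 = ", r + 3,
           " inefficient units; truncated regression is not identified")
    naive_fit <- fit_truncreg(to_resp(lam[keep]), Zt[keep, , drop = FALSE],
                              bounds[1], bounds[2])
    mu_all <- drop(Zd %*% naive_fit$coefficients)

    # (3) parametric bias-correction loop
    Yf <- sweep(panel$Y, 2, lam, "*")
    ref <- panel
    Lstar <- matrix(NA_real_, n, L1)
    for (b in seq_len(L1)) {
      resp_star <- draw_truncated_response(mu_all, naive_fit$sigma,
                                           bounds[1], bounds[2])
      dstar <- to_farrell(resp_star)
      ref$Y <- sweep(Yf, 2, dstar, "/")
      Lstar[, b] <- .dea_solve_cpp(panel$X, panel$Y, ref$X, ref$Y,
                                   rts_code(rts), FALSE)$lambda
    }
    lam_bc <- 2 * lam - rowMeans(Lstar)
    clamped <- lam_bc <= 1
    lam_bc[clamped] <- 1

    # (4) refit on bias-corrected scores
    keep_bc <- !clamped
    excluded <- sum(clamped)
    if (sum(keep_bc) < r + 3)
      stop("fewer than r + 3 bias-corrected scores remain off the bound")
    fit <- fit_truncreg(to_resp(lam_bc[keep_bc]),
                        Zt[keep_bc, , drop = FALSE], bounds[1], bounds[2])

    # (5) parametric bootstrap of the refitted model
    mu_bc <- drop(Zd %*% fit$coefficients)
    boot <- matrix(NA_real_, L2, r + 2,
                   dimnames = list(NULL, c(names(fit$coefficients),
                                           "sigma")))
    for (b in seq_len(L2)) {
      fb <- refit_with_retry(
        function() draw_truncated_response(mu_bc, fit$sigma, bounds[1],
                                           bounds[2]),
        Zt, bounds[1], bounds[2])
      boot[b, ] <- c(fb$coefficients, fb$sigma)
    }

    ci <- t(apply(boot, 2, quantile,
                  probs = c(alpha / 2, 1 - alpha / 2), names = FALSE,
                  type = 7))
    colnames(ci) <- c("lower", "upper")
    est <- c(fit$coefficients, sigma = fit$sigma)
    structure(list(fit = fit, naive_fit = naive_fit,
                   coefficients = fit$coefficients, sigma = fit$sigma,
                   ci = ci, boot = boot,
                   excludes_zero = ci[, "lower"] > 0 | ci[, "upper"] < 0,
                   estimates = est,
                   lambda_bc = setNames(lam_bc, panel$ids),
                   excluded_clamped = excluded,
                   rts = rts, L1 = L1, L2 = L2, alpha = alpha,
                   seed = seed,
                   response_convention = response_convention,
                   transforms = transforms),
              class = "sw2_result")
  })
}

#' @export
print.sw2_result <- function(x, ...) {
  cat("<sw2_result> rts=", x$rts, ", L1=", x$L1, ", L2=", x$L2,
      ", convention=", x$response_convention, "\n", sep = "")
  tab <- data.frame(beta = round(x$coefficients, 4),
                    ci_low = round(x$ci[seq_along(x$coefficients),
                                        "lower"], 4),
                    ci_high = round(x$ci[seq_along(x$coefficients),
                                         "upper"], 4),
                    excl0 = x$excludes_zero[seq_along(x$coefficients)])
  print(tab)
  cat("sigma=", format(x$sigma, digits = 3), "  loglik=",
      format(x$fit$loglik, digits = 6), "  Wald=",
      format(x$fit$wald, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Simar-Wilson algorithm 1: single-bootstrap truncated regression
#'
#' Fits the truncated regression to the *raw* DEA distances (no internal
#' bias correction) and bootstraps the fitted model `L2` times for
#' percentile confidence intervals.
#'
#' @inheritParams sw_algorithm2
#' @return A list shaped like [sw_algorithm2()] (class `sw1_result`)
#'   without the bias-correction components.
#' @export
sw_algorithm1 <- function(panel, rts = c("crs", "vrs"), L2 = 2000,
                          alpha = 0.05, seed,
                          response_convention = c("farrell_ge1",
                                                  "shephard01"),
                          transforms = NULL) {
  stopifnot(inherits(panel, "dmu_panel"))
  rts <- match.arg(rts)
  response_convention <- match.arg(response_convention)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (is.null(transforms)) {
    cfg <- attr(panel, "config")
    transforms <- if (!is.null(cfg)) cfg$covariate_transforms
  }
  Zt <- transform_covariates(panel$Z, transforms)
  r <- ncol(Zt)
  Zd <- cbind(1, Zt)
  lam <- pmax(solve_dea(panel, rts)$lambda, 1)
  shep <- response_convention == "shephard01"
  bounds <- if (shep) c(0, 1) else c(1, Inf)
  to_resp <- function(l) if (shep) 1 / l else l

  with_seed(seed, function() {
    keep <- lam > 1 + 1e-9
    if (sum(keep) < r + 3)
      stop("fewer than r + 3 inefficient units")
    fit <- fit_truncreg(to_resp(lam[keep]), Zt[keep, , drop = FALSE],
                        bounds[1], bounds[2])
    mu <- drop(Zd %*% fit$coefficients)
    boot <- matrix(NA_real_, L2, r + 2,
                   dimnames = list(NULL, c(names(fit$coefficients),
                                           "sigma")))
    for (b in seq_len(L2)) {
      fb <- refit_with_retry(
        function() draw_truncated_response(mu, fit$sigma, bounds[1],
                                           bounds[2]),
        Zt, bounds[1], bounds[2])
      boot[b, ] <- c(fb$coefficients, fb$sigma)
    }
    ci <- t(apply(boot, 2, quantile,
                  probs = c(alpha / 2, 1 - alpha / 2), names = FALSE,
                  type = 7))
    colnames(ci) <- c("lower", "upper")
    structure(list(fit = fit, coefficients = fit$coefficients,
                   sigma = fit$sigma, ci = ci, boot = boot,
                   excludes_zero = ci[, "lower"] > 0 | ci[, "upper"] < 0,
                   rts = rts, L2 = L2, alpha = alpha, seed = seed,
                   response_convention = response_convention,
                   transforms = transforms),
              class = "sw1_result")
  })
}
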