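#' Reflection bandwidth for the smoothed bootstrap
#'
#' Silverman's rule on the reflected sample: the Farrell distances
#' `lambda >= 1` are reflected about the frontier value 1 to
#' `{lambda} U {2 - lambda}` (removing the boundary discontinuity), and
#' `h = 0.9 * min(sd, IQR/1.349) * (2n)^(-1/5)` is computed on the
#' reflected 2n-point sample.
#'
#' @param lambda_hat numeric vector of Farrell distances `>= 1`, `n >= 2`.
#' @return A list with `h` (the bandwidth), `degenerate` (`TRUE` when all
#'   distances coincide, in which case `h = 0` and the bootstrap falls back
#'   to naive resampling) and `n`.
#' @export
reflect_and_bandwidth <- function(lambda_hat) {
  n <- length(lambda_hat)
  if (n < 2) stop("need at least two scores")
  if (any(lambda_hat < 1 - 1e-9)) stop("Farrell distances must be >= 1")
  if (max(lambda_hat) - min(lambda_hat) < 1e-12)
    return(list(h = 0, degenerate = TRUE, n = n))
  refl <- c(lambda_hat, 2 - lambda_hat)
  spread <- min(sd(refl), IQR(refl) / 1.349)
  list(h = 0.9 * spread * (2 * n)^(-1 / 5), degenerate = FALSE, n = n)
}

#' Smoothed homogeneous bootstrap for DEA scores
#'
#' The Simar-Wilson smoothed bootstrap: each replicate resamples the
#' estimated Farrell distances, perturbs them with reflected kernel noise
#' of bandwidth `h` (variance-corrected so the smoothed draws match the
#' sample variance), deflates every unit's frontier projection by its drawn
#' distance to build a pseudo reference technology, and re-solves the
#' envelopment program for every *original* unit against the pseudo data.
#' Inputs are never perturbed (output orientation).  The replicate
#' distribution yields per-unit bias estimates, bias-corrected scores and
#' percentile confidence intervals.
#'
#' On the Farrell scale the bias estimate `mean_b(lambda*) - lambda_hat` is
#' typically negative (the empirical frontier understates the true
#' distance), so the corrected distance `2*lambda_hat - mean_b(lambda*)`
#' exceeds the raw one and the corrected Shephard efficiency `1/lambda_bc`
#' falls below the raw score.  Corrected distances below 1 are clamped to 1
#' and flagged.
#'
#' @param panel a [dmu_panel()].
#' @param rts `"crs"` (technical efficiency) or `"vrs"` (pure technical
#'   efficiency).
#' @param B number of bootstrap replicates (default 2000).
#' @param alpha two-sided confidence level is `1 - alpha`.
#' @param seed integer seed, required for reproducibility.
#' @param eff optional precomputed [efficiency_table()] for `panel`.
#' @return An object of class `dea_bootstrap`: list with `lambda_hat`,
#'   `replicates` (n x B), `bias` (Farrell scale), `bias_shephard`,
#'   `lambda_bc`, `shephard_bc`, `clamped`, `ci` (n x 2, Farrell scale),
#'   `ci_shephard`, `h`, `degenerate`, `B`, `alpha`, `seed`, `rts`.
#' @export
smoothed_bootstrap <- function(panel, rts = c("crs", "vrs"), B = 2000,
                               alpha = 0.05, seed, eff = NULL) {
  stopifnot(inherits(panel, "dmu_panel"))
  rts <- match.arg(rts)
  if (!is.numeric(B) || B < 1) stop("B must be a positive integer")
  if (missing(seed) || is.null(seed))
    stop("seed is required for a reproducible bootstrap")
  B <- as.integer(B)
  n <- length(panel$ids)

  lam <- if (!is.null(eff)) {
    setNames(eff[[paste0("lambda_", rts)]], eff$id)[panel$ids]
  } else {
    l <- solve_dea(panel, rts)$lambda
    pmax(l, 1)
  }
  bw <- reflect_and_bandwidth(lam)
  h <- bw$h
  vlam <- var(lam)
  corr <- if (h > 0) 1 / sqrt(1 + h^2 / vlam) else 1
  # frontier projections lambda_j * y_j; pseudo outputs divide by delta*
  Yf <- sweep(panel$Y, 2, lam, "*")
  ref <- panel

  Lstar <- with_seed(seed, function() {
    out <- matrix(NA_real_, n, B)
    for (b in seq_len(B)) {
      bstar <- sample(lam, n, replace = TRUE)
      if (h > 0) {
        # draw from the variance-matched reflected kernel estimate: add
        # kernel noise, shrink deviations to undo the kernel's variance
        # inflation, and fold at the frontier last so that the smoothed
        # distribution keeps its mass next to 1 (folding before the
        # moment correction would leave a zero-density gap above the
        # frontier and cripple interval coverage)
        bss <- bstar + h * rnorm(n)
        mbar <- mean(bstar)
        dstar <- mbar + (bss - mbar) * corr
        dstar <- ifelse(dstar < 1, 2 - dstar, dstar)
      } else {
        dstar <- bstar
      }
      ref$Y <- sweep(Yf, 2, dstar, "/")
      out[, b] <- .dea_solve_cpp(panel$X, panel$Y, ref$X, ref$Y,
                                 rts_code(rts), FALSE)$lambda
    }
    out
  })
  rownames(Lstar) <- panel$ids

  bias <- rowMeans(Lstar) - lam
  bias_sh <- rowMeans(1 / Lstar) - 1 / lam
  lam_bc <- lam - bias
  clamped <- lam_bc < 1
  lam_bc[clamped] <- 1
  d <- Lstar - lam                      # bootstrap analogue of lam - truth
  qs <- t(apply(d, 1, quantile, probs = c(1 - alpha / 2, alpha / 2),
                names = FALSE, type = 7))
  ci <- cbind(lower = pmax(lam - qs[, 1], 1), upper = lam - qs[, 2])
  rownames(ci) <- panel$ids

  structure(list(lambda_hat = lam, replicates = Lstar, bias = bias,
                 bias_shephard = bias_sh, lambda_bc = lam_bc,
                 shephard_bc = 1 / lam_bc, clamped = clamped,
                 ci = ci,
                 ci_shephard = cbind(lower = 1 / ci[, "upper"],
                                     upper = 1 / ci[, "lower"]),
                 h = h, degenerate = bw$degenerate, B = B, alpha = alpha,
                 seed = seed, rts = rts),
            class = "dea_bootstrap")
}

#' @export
print.dea_bootstrap <- function(x, ...) {
  cat("<dea_bootstrap> rts=", x$rts, ", B=", x$B, ", h=",
      format(x$h, digits = 4), "\n", sep = "")
  cat("mean raw Shephard score:      ",
      format(mean(1 / x$lambda_hat), digits = 4), "\n", sep = "")
  cat("mean bias-corrected score:    ",
      format(mean(x$shephard_bc), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Combine TE and PTE bootstraps into a per-unit table
#'
#' @param boot_te CRS bootstrap from [smoothed_bootstrap()].
#' @param boot_pte VRS bootstrap for the same panel.
#' @param panel the underlying [dmu_panel()].
#' @return Data frame with raw and bias-corrected TE and PTE, the
#'   bias-corrected scale efficiency `se_bc = te_bc / pte_bc`, CI bounds on
#'   the TE (Shephard) scale, biases and clamp flags.
#' @export
bootstrap_table <- function(boot_te, boot_pte, panel) {
  stopifnot(identical(names(boot_te$lambda_hat),
                      names(boot_pte$lambda_hat)))
  data.frame(
    id = panel$ids, group = panel$groups,
    te_raw = unname(1 / boot_te$lambda_hat),
    te_bc = unname(boot_te$shephard_bc),
    pte_raw = unname(1 / boot_pte$lambda_hat),
    pte_bc = unname(boot_pte$shephard_bc),
    se_bc = unname(pmin(boot_te$shephard_bc / boot_pte$shephard_bc, 1)),
    te_ci_low = unname(boot_te$ci_shephard[, "lower"]),
    te_ci_high = unname(boot_te$ci_shephard[, "upper"]),
    bias_te = unname(boot_te$bias_shephard),
    bias_pte = unname(boot_pte$bias_shephard),
    clamped = unname(boot_te$clamped | boot_pte$clamped),
    stringsAsFactors = FALSE)
}
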