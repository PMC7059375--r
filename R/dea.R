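rts_code <- function(rts) {
  rts <- match.arg(tolower(rts), c("crs", "vrs", "nirs"))
  c(crs = 0L, vrs = 1L, nirs = 2L)[[rts]]
}

#' Output-oriented envelopment program
#'
#' Solves, for each evaluated unit, the Farrell output-distance linear
#' program: maximise `lambda` subject to `X mu <= x0`,
#' `Y mu >= lambda * y0`, `mu >= 0`, with `sum(mu) = 1` under variable
#' returns to scale (VRS, the BCC technology) or `sum(mu) <= 1` under
#' non-increasing returns (NIRS); no convexity constraint under constant
#' returns (CRS, the CCR technology).  `lambda >= 1` is the maximal
#' proportional expansion of all outputs feasible with the unit's inputs;
#' the Shephard efficiency score is `1 / lambda`.
#'
#' @param panel a [dmu_panel()] holding the evaluated units.
#' @param rts `"crs"`, `"vrs"` or `"nirs"`.
#' @param units integer indices of the units to evaluate (default: all).
#' @param ref optional `dmu_panel` supplying the reference technology
#'   (defaults to `panel` itself); used by the bootstrap to evaluate
#'   original units against pseudo-data.
#' @param weights if `TRUE`, also return the optimal intensity weights.
#'
#' @return A list with `lambda` (numeric, one per evaluated unit) and,
#'   when requested, `weights` (reference-units x evaluated-units matrix).
#' @examples
#' d <- data.frame(id = c("A", "B"), x = c(1, 1), y = c(2, 1))
#' p <- dmu_panel(d, id = "id", inputs = "x", outputs = "y")
#' solve_dea(p, "crs")$lambda  # B can double its output: lambda = c(1, 2)
#' @export
solve_dea <- function(panel, rts = c("crs", "vrs", "nirs"), units = NULL,
                      ref = NULL, weights = FALSE) {
  stopifnot(inherits(panel, "dmu_panel"))
  rts <- match.arg(rts)
  if (is.null(ref)) ref <- panel
  if (is.null(units)) units <- seq_along(panel$ids)
  if (any(units < 1 | units > length(panel$ids)))
    stop("evaluated unit index out of range")
  res <- tryCatch(
    .dea_solve_cpp(panel$X[, units, drop = FALSE],
                   panel$Y[, units, drop = FALSE],
                   ref$X, ref$Y, rts_code(rts), isTRUE(weights)),
    error = function(e)
      stop("DEA solve failed (", conditionMessage(e), ") for unit(s) ",
           paste(panel$ids[units], collapse = ", "), call. = FALSE))
  names(res$lambda) <- panel$ids[units]
  if (isTRUE(weights)) dimnames(res$weights) <- list(ref$ids,
                                                     panel$ids[units])
  res
}

#' Returns-to-scale classification
#'
#' Classifies each unit from its Farrell distances under the three nested
#' technologies: `CRS` when the CRS and VRS distances agree within `tol`
#' (the unit is scale efficient), otherwise `IRS` when the NIRS distance
#' equals the CRS distance (the unit sits below its most productive scale),
#' otherwise `DRS`.
#'
#' @param lambda_crs,lambda_vrs,lambda_nirs Farrell distances `>= 1`.
#' @param tol nonnegative comparison tolerance.
#' @return Character vector in `c("CRS", "IRS", "DRS")`.
#' @export
classify_rts <- function(lambda_crs, lambda_vrs, lambda_nirs, tol = 1e-6) {
  if (tol < 0) stop("tol must be nonnegative")
  lam <- cbind(lambda_crs, lambda_vrs, lambda_nirs)
  if (any(lam < 1 - 1e-9)) stop("Farrell distances must be >= 1")
  ifelse(abs(lambda_crs - lambda_vrs) <= tol, "CRS",
         ifelse(abs(lambda_nirs - lambda_crs) <= tol, "IRS", "DRS"))
}

#' Efficiency table: TE, PTE, SE and returns to scale
#'
#' Runs the envelopment program for every unit under CRS, VRS and NIRS and
#' reports technical efficiency `te = 1/lambda_crs`, pure technical
#' efficiency `pte = 1/lambda_vrs`, scale efficiency `se = te/pte`
#' (so `te = pte * se` holds by construction) and the returns-to-scale
#' class.  Distances within `snap_tol` of 1 are snapped to exactly 1 so
#' that frontier units report scores of 1 in band summaries.
#'
#' @param panel a [dmu_panel()].
#' @param snap_tol solver tolerance for snapping scores to the frontier.
#' @param rts_tol tolerance handed to [classify_rts()].
#' @return An object of class `efficiency_result`: a data frame with
#'   columns `id`, `group`, `lambda_crs`, `lambda_vrs`, `lambda_nirs`,
#'   `te`, `pte`, `se`, `rts_class`, with attributes `orientation` and
#'   `tol`.
#' @export
efficiency_table <- function(panel, snap_tol = 1e-8, rts_tol = 1e-6) {
  stopifnot(inherits(panel, "dmu_panel"))
  lam <- lapply(c("crs", "vrs", "nirs"), function(r)
    solve_dea(panel, r)$lambda)
  names(lam) <- c("crs", "vrs", "nirs")
  snap <- function(l) {
    l <- pmax(l, 1)
    l[l - 1 <= snap_tol] <- 1
    l
  }
  lam <- lapply(lam, snap)
  te <- 1 / lam$crs
  pte <- 1 / lam$vrs
  out <- data.frame(id = panel$ids, group = panel$groups,
                    lambda_crs = unname(lam$crs),
                    lambda_vrs = unname(lam$vrs),
                    lambda_nirs = unname(lam$nirs),
                    te = unname(te), pte = unname(pte),
                    se = unname(te / pte),
                    rts_class = unname(classify_rts(lam$crs, lam$vrs,
                                                    lam$nirs, rts_tol)),
                    stringsAsFactors = FALSE)
  structure(out, orientation = "output", tol = snap_tol,
            class = c("efficiency_result", "data.frame"))
}

#' Write per-unit efficiency scores as CSV
#' @param eff an [efficiency_table()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_efficiency_csv <- function(eff, path) {
  write.csv(eff[c("id", "group", "te", "pte", "se", "rts_class")], path,
            row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
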