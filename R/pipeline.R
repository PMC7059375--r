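#' Pipeline run configuration
#'
#' Collects every choice of an end-to-end two-stage run: the panel (or a
#' CSV path plus a column-role map), the bootstrap sizes, the confidence
#' level, the root seed and the output directory.  All randomness in
#' [run_pipeline()] flows from `seed` through a deterministic per-stage
#' seed split.
#'
#' @param input a [dmu_panel()], or a CSV path readable by
#'   [read_panel_csv()].
#' @param inputs,outputs,covariates column roles (ignored when `input` is
#'   already a panel).
#' @param screen run the variable-selection funnel first and restrict the
#'   panel to the surviving variables.
#' @param B stage-1 bootstrap replications (default 2000).
#' @param L1,L2 stage-2 replications (defaults 100 and 2000).
#' @param alpha two-sided CI level is `1 - alpha`.
#' @param seed integer root seed (required).
#' @param response_convention see [sw_algorithm2()].
#' @param transforms per-covariate `"identity"`/`"log"` for stage 2.
#' @param band_edges see [band_distribution()].
#' @param pooled benchmark all groups against one pooled frontier instead
#'   of per-group frontiers.
#' @param out_dir directory for the report bundle, or `NULL` to skip
#'   writing files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, inputs = NULL, outputs = NULL,
                       covariates = NULL, screen = FALSE, B = 2000,
                       L1 = 100, L2 = 2000, alpha = 0.05, seed,
                       response_convention = "farrell_ge1",
                       transforms = NULL,
                       band_edges = c(0, 0.7, 0.8, 0.9, 1),
                       pooled = FALSE, out_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (B < 1 || L1 < 1 || L2 < 1) stop("B, L1 and L2 must be >= 1")
  roles <- list(inputs = inputs, outputs = outputs,
                covariates = covariates)
  if (!inherits(input, "dmu_panel")) {
    ov <- unlist(roles)
    if (anyDuplicated(ov))
      stop("column roles overlap: ",
           paste(unique(ov[duplicated(ov)]), collapse = ", "))
  }
  structure(list(input = input, roles = roles, screen = screen,
                 B = as.integer(B), L1 = as.integer(L1),
                 L2 = as.integer(L2), alpha = alpha,
                 seed = as.integer(seed),
                 response_convention = response_convention,
                 transforms = transforms, band_edges = band_edges,
                 pooled = pooled, out_dir = out_dir),
            class = "run_config")
}

#' Mean output shortfall implied by a mean efficiency score
#'
#' The headline "potential output increase": a mean Shephard score `s` in
#' `(0, 1]` means the units could, on average, have produced
#' `100 * (1 - s)` percent more output from the same inputs.
#'
#' @param mean_score mean efficiency score in `(0, 1]`.
#' @return The percentage shortfall.
#' @examples
#' summarise_shortfall(0.8633)  # 13.67
#' @export
summarise_shortfall <- function(mean_score) {
  if (!is.numeric(mean_score) || any(mean_score <= 0 | mean_score > 1))
    stop("mean efficiency score must lie in (0, 1]")
  100 * (1 - mean_score)
}

#' Run the full two-stage analysis
#'
#' Orchestrates, per group (or pooled): the efficiency table, the smoothed
#' bootstrap for TE (CRS) and PTE (VRS), band distributions of the
#' bias-corrected scores, cross-group pooled-t comparisons of TE, PTE and
#' SE, and the algorithm-2 bootstrap truncated regression when covariates
#' are present.  When `out_dir` is set, writes a bundle of CSV/JSON files
#' plus `manifest.json` (config echo; byte-stable across reruns with the
#' same seed) and `run.log` (wall-clock timings; excluded from the
#' determinism contract).
#'
#' @param config a [run_config()].
#' @return An object of class `pipeline_result` (returned invisibly when a
#'   bundle is written): `efficiency`, `bootstrap` (per-unit table),
#'   `bands`, `comparison`, `regression` (per group), `screening`,
#'   `shortfall`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines,
                    sprintf("[%8.2fs] %s", proc.time()[["elapsed"]] - t0,
                            paste0(...)))
  }

  panel <- if (inherits(config$input, "dmu_panel")) config$input
           else read_panel_csv(config$input,
                               inputs = config$roles$inputs,
                               outputs = config$roles$outputs,
                               covariates = config$roles$covariates)
  note("panel: ", length(panel$ids), " units")

  screening <- NULL
  if (isTRUE(config$screen)) {
    d <- as.data.frame(panel)
    screening <- screen_variables(d, inputs = panel$input_names,
                                  outputs = panel$output_names)
    panel <- dmu_panel(d, id = "id", group = "group",
                       inputs = screening$final_inputs,
                       outputs = screening$final_outputs,
                       covariates = panel$covariate_names)
    note("screening kept ", length(screening$final_inputs), " inputs, ",
         length(screening$final_outputs), " outputs")
  }

  # deterministic seed split: one sub-seed per (stage, group) slot
  seeds <- with_seed(config$seed,
                     function() sample.int(.Machine$integer.max - 1, 64))
  groups <- if (config$pooled) "pooled" else unique(panel$groups)
  get_panel <- function(g) if (config$pooled) panel
                           else panel_subset(panel, g)

  eff_list <- list(); boot_list <- list(); bands <- list()
  reg <- list()
  si <- 0
  for (g in groups) {
    pg <- get_panel(g)
    eff <- efficiency_table(pg)
    note("group ", g, ": efficiency table done")
    bt <- smoothed_bootstrap(pg, "crs", B = config$B,
                             alpha = config$alpha,
                             seed = seeds[si <- si + 1], eff = eff)
    bp <- smoothed_bootstrap(pg, "vrs", B = config$B,
                             alpha = config$alpha,
                             seed = seeds[si <- si + 1], eff = eff)
    note("group ", g, ": smoothed bootstrap (B=", config$B, ") done")
    tab <- bootstrap_table(bt, bp, pg)
    eff_list[[g]] <- eff
    boot_list[[g]] <- tab
    bands[[g]] <- list(
      te = band_distribution(tab$te_bc, config$band_edges),
      pte = band_distribution(tab$pte_bc, config$band_edges),
      se = band_distribution(tab$se_bc, config$band_edges))
    if (nrow(pg$Z) > 0) {
      reg[[g]] <- tryCatch(
        sw_algorithm2(pg, rts = "crs", L1 = config$L1, L2 = config$L2,
                      alpha = config$alpha, seed = seeds[si <- si + 1],
                      response_convention = config$response_convention,
                      transforms = config$transforms),
        error = function(e) {
          note("group ", g, ": stage-2 regression failed: ",
               conditionMessage(e))
          NULL
        })
      if (!is.null(reg[[g]]))
        note("group ", g, ": algorithm-2 regression (L1=", config$L1,
             ", L2=", config$L2, ") done")
    } else si <- si + 1
  }

  comparison <- NULL
  if (length(boot_list) == 2) {
    a <- boot_list[[1]]; b <- boot_list[[2]]
    labs <- names(boot_list)
    rows <- lapply(c(te = "te_bc", pte = "pte_bc", se = "se_bc"),
                   function(col) {
                     cg <- compare_groups(a[[col]], b[[col]], labs)
                     cg$table
                   })
    comparison <- do.call(rbind, Map(function(m, d)
      cbind(measure = m, d), names(rows), rows))
    rownames(comparison) <- NULL
  }

  shortfall <- vapply(boot_list,
                      function(tab) summarise_shortfall(mean(tab$pte_bc)),
                      numeric(1))

  result <- structure(list(efficiency = eff_list, bootstrap = boot_list,
                           bands = bands, comparison = comparison,
                           regression = reg, screening = screening,
                           shortfall = shortfall, config = config,
                           log = log_lines),
                      class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    write_bundle(result, config$out_dir)
    note("bundle written to ", config$out_dir)
    result$log <- log_lines
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
    return(invisible(result))
  }
  result
}

# serialise all result tables; every file except run.log is byte-stable
# for a fixed config + seed
write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  for (g in names(result$efficiency)) {
    write_efficiency_csv(result$efficiency[[g]],
                         file.path(out_dir, paste0("efficiency_", g,
                                                   ".csv")))
    write.csv(result$bootstrap[[g]],
              file.path(out_dir, paste0("bootstrap_", g, ".csv")),
              row.names = FALSE, fileEncoding = "UTF-8")
    bb <- result$bands[[g]]
    bands_tab <- do.call(rbind, Map(function(m, d)
      cbind(measure = m, d), names(bb), bb))
    write.csv(bands_tab, file.path(out_dir, paste0("bands_", g, ".csv")),
              row.names = FALSE, fileEncoding = "UTF-8")
    rg <- result$regression[[g]]
    if (!is.null(rg)) {
      k <- length(rg$coefficients)
      tab4 <- data.frame(variable = names(rg$coefficients),
                         beta = unname(rg$coefficients),
                         ci_low = unname(rg$ci[seq_len(k), "lower"]),
                         ci_high = unname(rg$ci[seq_len(k), "upper"]),
                         excludes_zero = unname(rg$excludes_zero[
                           seq_len(k)]),
                         stringsAsFactors = FALSE)
      write.csv(tab4, file.path(out_dir, paste0("regression_", g,
                                                ".csv")),
                row.names = FALSE, fileEncoding = "UTF-8")
      jsonlite::write_json(
        list(sigma = rg$sigma, loglik = rg$fit$loglik,
             wald = rg$fit$wald, L1 = rg$L1, L2 = rg$L2,
             seed = rg$seed, alpha = rg$alpha,
             convention = rg$response_convention,
             excluded_clamped = rg$excluded_clamped),
        file.path(out_dir, paste0("regression_", g, "_meta.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  if (!is.null(result$comparison))
    write.csv(result$comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(package = "hospeff",
         version = as.character(packageVersion("hospeff")),
         seed = cfg$seed, B = cfg$B, L1 = cfg$L1, L2 = cfg$L2,
         alpha = cfg$alpha, convention = cfg$response_convention,
         pooled = cfg$pooled, band_edges = cfg$band_edges,
         screen = cfg$screen,
         shortfall_pct = as.list(result$shortfall)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> groups: ",
      paste(names(x$efficiency), collapse = ", "), "\n", sep = "")
  for (g in names(x$bootstrap)) {
    tab <- x$bootstrap[[g]]
    cat(sprintf("  %-10s mean te_bc=%.4f  pte_bc=%.4f  se_bc=%.4f\n",
                g, mean(tab$te_bc), mean(tab$pte_bc), mean(tab$se_bc)))
  }
  if (!is.null(x$comparison)) {
    p <- unique(x$comparison[c("measure", "p")])
    cat("  group comparison p-values: ",
        paste(p$measure, signif(p$p, 3), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
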