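#' Decision-making-unit panel
#'
#' Bundles the identifiers, group labels, input matrix, output matrix and
#' covariate matrix of a set of decision-making units (DMUs; here,
#' hospitals).  Matrices are stored column-major by unit: `X` is p x n,
#' `Y` is q x n, `Z` is r x n (possibly zero rows).
#'
#' @param data data frame, one row per unit.
#' @param id name of the unique identifier column.
#' @param group name of the group-label column, or `NULL` for a single group.
#' @param inputs,outputs character vectors of input / output column names.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#'
#' @return An object of class `dmu_panel` with elements `ids`, `groups`,
#'   `X`, `Y`, `Z` and the column-name bookkeeping.
#'
#' @details Validation requires non-negative inputs and outputs, at least one
#'   strictly positive input and one strictly positive output per unit
#'   (a unit with an all-zero output vector has no defined output-oriented
#'   score), and unique identifiers.  Zeros elsewhere are allowed: a
#'   hospital may lack a given service line.
#'
#' @examples
#' d <- data.frame(id = c("a", "b"), g = "all", x = c(1, 1), y = c(2, 1))
#' p <- dmu_panel(d, id = "id", group = "g", inputs = "x", outputs = "y")
#' p$X
#' @export
dmu_panel <- function(data, id, group = NULL, inputs, outputs,
                      covariates = character()) {
  stopifnot(is.data.frame(data), length(inputs) >= 1, length(outputs) >= 1)
  need <- c(id, group, inputs, outputs, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("columns not found in data: ", paste(miss, collapse = ", "))
  ids <- as.character(data[[id]])
  if (anyDuplicated(ids))
    stop("duplicate unit identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  groups <- if (is.null(group)) rep("all", nrow(data))
            else as.character(data[[group]])

  num_mat <- function(cols) {
    m <- t(as.matrix(data[cols]))
    if (!is.numeric(m)) stop("non-numeric values in columns: ",
                             paste(cols, collapse = ", "))
    if (anyNA(m)) stop("missing values in columns: ",
                       paste(cols, collapse = ", "))
    dimnames(m) <- list(cols, ids)
    m
  }
  X <- num_mat(inputs)
  Y <- num_mat(outputs)
  Z <- if (length(covariates)) num_mat(covariates)
       else matrix(0, 0, nrow(data), dimnames = list(NULL, ids))

  if (any(X < 0)) stop("negative input values")
  if (any(Y < 0)) stop("negative output values")
  bad <- which(colSums(X > 0) == 0)
  if (length(bad)) stop("unit(s) with all-zero inputs: ",
                        paste(ids[bad], collapse = ", "))
  bad <- which(colSums(Y > 0) == 0)
  if (length(bad)) stop("unit(s) with all-zero outputs: ",
                        paste(ids[bad], collapse = ", "))

  structure(list(ids = ids, groups = groups, X = X, Y = Y, Z = Z,
                 input_names = inputs, output_names = outputs,
                 covariate_names = covariates),
            class = "dmu_panel")
}

#' @export
print.dmu_panel <- function(x, ...) {
  cat("<dmu_panel> ", length(x$ids), " units, ",
      nrow(x$X), " inputs, ", nrow(x$Y), " outputs, ",
      nrow(x$Z), " covariates\n", sep = "")
  tab <- table(x$groups)
  cat("groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.dmu_panel <- function(x, ...) {
  out <- data.frame(id = x$ids, group = x$groups,
                    t(x$X), t(x$Y), check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(x$Z)) out <- cbind(out, as.data.frame(t(x$Z)))
  td <- attr(x, "true_delta")
  if (!is.null(td)) out$true_delta <- td
  rownames(out) <- NULL
  out
}

#' Subset a panel to one group
#' @param panel a [dmu_panel()].
#' @param group group label to keep.
#' @return A `dmu_panel` restricted to the units of `group`.
#' @export
panel_subset <- function(panel, group) {
  stopifnot(inherits(panel, "dmu_panel"))
  keep <- panel$groups == group
  if (!any(keep)) stop("no units in group '", group, "'")
  out <- panel
  out$ids <- panel$ids[keep]
  out$groups <- panel$groups[keep]
  out$X <- panel$X[, keep, drop = FALSE]
  out$Y <- panel$Y[, keep, drop = FALSE]
  out$Z <- panel$Z[, keep, drop = FALSE]
  for (a in c("true_delta", "true_frontier"))
    if (!is.null(attr(panel, a)))
      attr(out, a) <- if (is.matrix(attr(panel, a)))
        attr(panel, a)[, keep, drop = FALSE] else attr(panel, a)[keep]
  out
}

#' Read / write a DMU panel as CSV
#'
#' The CSV dialect is UTF-8, comma-delimited with a header row and `.` as
#' the decimal mark: columns `id`, `group`, then inputs, outputs and
#' covariates.  `write_panel_csv` optionally emits a sidecar JSON with the
#' generating configuration when the panel came from [simulate_panel()].
#'
#' @param panel a [dmu_panel()].
#' @param path file path.
#' @param sidecar write `<path>.json` with the generating config, if any.
#' @return `read_panel_csv` returns a `dmu_panel`; `write_panel_csv`
#'   returns `path` invisibly.
#' @export
write_panel_csv <- function(panel, path, sidecar = TRUE) {
  stopifnot(inherits(panel, "dmu_panel"))
  write.csv(as.data.frame(panel), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  cfg <- attr(panel, "config")
  if (sidecar && !is.null(cfg)) {
    jsonlite::write_json(
      c(unclass(cfg),
        list(roles = list(inputs = panel$input_names,
                          outputs = panel$output_names,
                          covariates = panel$covariate_names))),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_panel_csv
#' @param inputs,outputs,covariates column names; if `NULL`, taken from the
#'   sidecar JSON next to `path`, else inferred from `x*`/`y*`/`z*` prefixes.
#' @export
read_panel_csv <- function(path, inputs = NULL, outputs = NULL,
                           covariates = NULL) {
  d <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (is.null(inputs)) {
    side <- paste0(path, ".json")
    if (file.exists(side)) {
      roles <- jsonlite::read_json(side, simplifyVector = TRUE)$roles
      inputs <- roles$inputs; outputs <- roles$outputs
      covariates <- roles$covariates
    } else {
      inputs <- grep("^x", names(d), value = TRUE)
      outputs <- grep("^y", names(d), value = TRUE)
      covariates <- grep("^z", names(d), value = TRUE)
    }
  }
  if (is.null(covariates)) covariates <- character()
  dmu_panel(d, id = "id", group = if ("group" %in% names(d)) "group",
            inputs = inputs, outputs = outputs, covariates = covariates)
}
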