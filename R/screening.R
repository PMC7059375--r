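#' Variable-selection funnel: cluster, correlation and R-squared screens
#'
#' Implements a three-step screen of candidate input and output variables:
#' (i) average-linkage hierarchical clustering of all candidates on the
#' `1 - |Pearson r|` distance, to surface groups of variables explaining
#' the same signal; (ii) within any same-role pair with `|r| >
#' r_threshold`, drop the member with the lower variance explained against
#' the other role's variables; (iii) retain only inputs whose regression on
#' the surviving outputs achieves `R^2 > r2_threshold`.
#'
#' @param data data frame holding all candidate columns.
#' @param inputs,outputs character vectors of candidate column names.
#' @param r_threshold absolute-correlation cutoff for the pruning step.
#' @param r2_threshold coefficient-of-determination benchmark for the
#'   regression screen (default 0.5).
#' @param k number of clusters to report (default: cut the dendrogram at
#'   height `1 - r_threshold`).
#' @return An object of class `screening_report`: `candidates`,
#'   `clusters` (named assignments), `dropped` (data frame of drops with
#'   the rule that fired and the |r| or R-squared involved), `r2`
#'   (per-input R-squared against the selected outputs), `final_inputs`,
#'   `final_outputs`, `thresholds`.
#' @export
screen_variables <- function(data, inputs, outputs, r_threshold = 0.9,
                             r2_threshold = 0.5, k = NULL) {
  candidates <- c(inputs, outputs)
  if (length(candidates) < 2) stop("need at least two candidate variables")
  if (nrow(data) < 3) stop("need at least three observations")
  miss <- setdiff(candidates, names(data))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  M <- as.matrix(data[candidates])
  storage.mode(M) <- "double"

  dropped <- data.frame(variable = character(), rule = character(),
                        detail = numeric(), stringsAsFactors = FALSE)
  const <- candidates[apply(M, 2, function(v) sd(v) < 1e-12)]
  if (length(const)) {
    warning("constant column(s) dropped: ", paste(const, collapse = ", "),
            call. = FALSE)
    dropped <- rbind(dropped, data.frame(variable = const,
                                         rule = "constant column",
                                         detail = NA_real_))
    inputs <- setdiff(inputs, const)
    outputs <- setdiff(outputs, const)
    candidates <- c(inputs, outputs)
    M <- M[, candidates, drop = FALSE]
  }
  if (nrow(data) < length(candidates))
    warning("fewer observations than candidates; correlations are ",
            "rank-deficient", call. = FALSE)

  R <- cor(M)
  hc <- hclust(as.dist(1 - abs(R)), method = "average")
  if (is.null(k)) {
    clusters <- cutree(hc, h = 1 - r_threshold)
  } else {
    clusters <- cutree(hc, k = k)
  }

  # variance explained of one variable by a set of others (R^2)
  r2_of <- function(v, against) {
    if (!length(against)) return(0)
    Xd <- cbind(1, M[, against, drop = FALSE])
    f <- lm.fit(Xd, M[, v])
    1 - sum(f$residuals^2) / sum((M[, v] - mean(M[, v]))^2)
  }

  prune <- function(role_set, against_set) {
    # deterministic order: consider pairs by decreasing |r|
    repeat {
      if (length(role_set) < 2) return(role_set)
      Rr <- abs(cor(M[, role_set, drop = FALSE]))
      diag(Rr) <- 0
      if (max(Rr) <= r_threshold) return(role_set)
      ij <- which(Rr == max(Rr), arr.ind = TRUE)[1, ]
      a <- role_set[ij[1]]; b <- role_set[ij[2]]
      va <- r2_of(a, against_set); vb <- r2_of(b, against_set)
      drop_var <- if (va < vb || (va == vb && a > b)) a else b
      dropped <<- rbind(dropped,
                        data.frame(variable = drop_var,
                                   rule = "correlation rule",
                                   detail = max(Rr)))
      role_set <- setdiff(role_set, drop_var)
    }
  }
  inputs <- sort(inputs)    # column-order invariance
  outputs <- sort(outputs)
  outputs <- prune(outputs, inputs)
  inputs <- prune(inputs, outputs)

  r2 <- vapply(inputs, r2_of, numeric(1), against = outputs)
  fail <- inputs[r2 <= r2_threshold]
  if (length(fail))
    dropped <- rbind(dropped,
                     data.frame(variable = fail, rule = "R-squared screen",
                                detail = unname(r2[fail])))
  final_inputs <- setdiff(inputs, fail)

  structure(list(candidates = candidates, clusters = clusters,
                 dropped = dropped, r2 = r2,
                 final_inputs = final_inputs, final_outputs = outputs,
                 thresholds = c(r = r_threshold, r2 = r2_threshold)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report> ", length(x$candidates), " candidates -> ",
      length(x$final_inputs), " inputs + ", length(x$final_outputs),
      " outputs\n", sep = "")
  if (nrow(x$dropped)) {
    cat("dropped:\n")
    print(x$dropped, row.names = FALSE)
  }
  invisible(x)
}

#' Pooled-variance two-sample comparison of efficiency scores
#'
#' Student's t-test (pooled variance, two-sided) between two groups of
#' scores, reported in the shape of a group-comparison table: per-group N,
#' mean, SD and the shared p-value.
#'
#' @param scores_a,scores_b numeric vectors, each of length `>= 2`.
#' @param labels group labels for the output table.
#' @return List with `statistic`, `df`, `p.value` and `table` (two rows:
#'   group, n, mean, sd, p).
#' @export
compare_groups <- function(scores_a, scores_b,
                           labels = c("district", "county")) {
  na <- length(scores_a); nb <- length(scores_b)
  if (na < 2 || nb < 2) stop("each group needs at least two observations")
  pooled <- ((na - 1) * var(scores_a) + (nb - 1) * var(scores_b)) /
    (na + nb - 2)
  if (pooled < 1e-24) {
    if (abs(mean(scores_a) - mean(scores_b)) < 1e-12) {
      tstat <- 0; pval <- 1
    } else {
      stop("zero pooled variance with unequal means")
    }
  } else {
    tstat <- (mean(scores_a) - mean(scores_b)) /
      sqrt(pooled * (1 / na + 1 / nb))
    pval <- 2 * pt(-abs(tstat), df = na + nb - 2)
  }
  tab <- data.frame(group = labels, n = c(na, nb),
                    mean = c(mean(scores_a), mean(scores_b)),
                    sd = c(sd(scores_a), sd(scores_b)),
                    p = pval, stringsAsFactors = FALSE)
  list(statistic = tstat, df = na + nb - 2, p.value = pval, table = tab)
}

#' Score-band distribution
#'
#' Counts efficiency scores into half-open bands `[lo, hi)` defined by
#' `band_edges`, with scores exactly equal to 1 reported in a separate
#' `"=1"` band (frontier units).  Percentages sum to 100.
#'
#' @param scores numeric vector in `(0, 1]`.
#' @param band_edges strictly increasing edges covering `(0, 1]`; the
#'   defaults reproduce the usual reporting bands.
#' @return Data frame with columns `band`, `count`, `percent`.
#' @export
band_distribution <- function(scores, band_edges = c(0, 0.7, 0.8, 0.9, 1)) {
  if (any(scores <= 0 | scores > 1))
    stop("scores must lie in (0, 1]")
  if (any(diff(band_edges) <= 0) || band_edges[1] > min(scores) ||
      band_edges[length(band_edges)] < 1)
    stop("band edges must be strictly increasing and cover (0, 1]")
  ne <- length(band_edges)
  labels <- paste0("[", band_edges[-ne], ", ", band_edges[-1], ")")
  at_one <- scores == 1
  inner <- scores[!at_one]
  counts <- if (length(inner))
    tabulate(findInterval(inner, band_edges,
                          rightmost.closed = FALSE), nbins = ne - 1)
    else integer(ne - 1)
  out <- data.frame(band = c(labels, "=1"),
                    count = c(counts, sum(at_one)),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$count / length(scores)
  out
}

#' Descriptive table by group
#'
#' Mean and standard deviation of each panel variable within each group,
#' in the shape of a descriptive-statistics table.
#'
#' @param panel a [dmu_panel()].
#' @return Data frame with columns `category`, `variable`, `group`,
#'   `mean`, `sd`.
#' @export
describe_panel <- function(panel) {
  stopifnot(inherits(panel, "dmu_panel"))
  blocks <- list(input = panel$X, output = panel$Y, factor = panel$Z)
  out <- list()
  for (cat_ in names(blocks)) {
    M <- blocks[[cat_]]
    if (nrow(M) == 0) next
    for (g in unique(panel$groups)) {
      sel <- panel$groups == g
      out[[length(out) + 1]] <- data.frame(
        category = cat_, variable = rownames(M), group = g,
        mean = rowMeans(M[, sel, drop = FALSE]),
        sd = apply(M[, sel, drop = FALSE], 1, sd),
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}
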