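# Accuracy evaluation (sensitivity, specificity, REQ) and coordinate-wise
# parameter optimisation.

#' Confusion counts between predicted and true accession sets
#'
#' A prediction matching any truth item is a true positive, otherwise a
#' false positive; a truth item never predicted is a false negative.
#' Matching is by accession string equality (apply an alias map beforehand
#' when identifiers come from different databases).
#'
#' @param predicted,truth Character vectors of accessions (duplicates are
#'   ignored; empty sets are legal).
#' @return A list of class `eval_counts` with `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  eval_counts(tp = length(intersect(predicted, truth)),
              fp = length(setdiff(predicted, truth)),
              fn = length(setdiff(truth, predicted)))
}

#' Construct confusion counts directly
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return A list of class `eval_counts`.
#' @export
eval_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("<eval_counts> TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Sensitivity, specificity and REQ from confusion counts
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TP / (TP + FP)` and the
#' Relative Error Quotient `REQ = (FN + FP) / (2 * TP)`, a single error
#' measure combining both (lower is better, 0 for a perfect prediction).
#' With `TP = 0`, REQ is undefined and reported as `NA` (never as
#' infinity).
#'
#' @param counts An [eval_counts()] (or the result of [confusion_counts()]).
#' @return A list of class `accuracy_report` with `counts`, `sensitivity`,
#'   `specificity` and `req`.
#' @export
evaluate <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fn == 0L) stop("tp + fn must be > 0 (empty truth set)",
                          call. = FALSE)
  if (tp + fp == 0L) stop("tp + fp must be > 0 (empty prediction set)",
                          call. = FALSE)
  structure(list(counts = counts,
                 sensitivity = tp / (tp + fn),
                 specificity = tp / (tp + fp),
                 req = if (tp == 0L) NA_real_ else (fn + fp) / (2 * tp)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> Sn=%.1f%% Sp=%.1f%% REQ=%s (TP=%d FP=%d FN=%d)\n",
              100 * x$sensitivity, 100 * x$specificity,
              if (is.na(x$req)) "undefined" else sprintf("%.3f", x$req),
              x$counts$tp, x$counts$fp, x$counts$fn))
  invisible(x)
}

# Pooled (micro-averaged) REQ of a parameter setting over benchmark items.
# Each item is a list(queries, db, truth) with truth a character vector of
# expected homolog accessions; the reference itself is excluded from the
# prediction set.
.pooled_counts <- function(benchmark, params) {
  tp <- fp <- fn <- 0L
  for (item in benchmark) {
    hres <- find_homologs(item$queries, item$db, params)
    pred <- setdiff(hres$members$accession, hres$reference_id)
    cc <- confusion_counts(pred, item$truth)
    tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
  }
  eval_counts(tp, fp, fn)
}

.pooled_req <- function(cc) {
  if (cc$tp == 0L) NA_real_ else (cc$fn + cc$fp) / (2 * cc$tp)
}

#' Coordinate-wise parameter optimisation
#'
#' Reproduces the training procedure: a coordinate-wise grid search over the
#' e-value cutoff, the minimal domain length `m` and the Rost offset `n`, in
#' that order. The e-value is swept first with `m = 0` and `n = 0`; the
#' value with the lowest pooled REQ over the benchmark is fixed; then `m` is
#' swept, then `n`. Counts are pooled (micro-averaged) across benchmark
#' items before computing REQ. Ties are resolved toward the more stringent
#' value: the smaller e-value, the larger `m`, the larger `n`.
#'
#' @param benchmark List of items, each a list with `queries` (a
#'   [protein_db()] or list of records), `db` (a `protein_db`) and `truth`
#'   (character vector of expected homolog accessions, reference excluded).
#' @param evalue_grid,m_grid,n_grid Non-empty numeric grids.
#' @param base [search_params()] supplying everything not being optimised
#'   (scheme, decay constant, iteration cap).
#' @return A list of class `param_optimization` with `params` (the selected
#'   [search_params()]) and `trace` (one row per visited grid point: stage,
#'   value, pooled counts, REQ, selected flag).
#' @export
optimize_parameters <- function(benchmark, evalue_grid, m_grid, n_grid,
                                base = search_params()) {
  stopifnot(length(benchmark) > 0L, length(evalue_grid) > 0L,
            length(m_grid) > 0L, length(n_grid) > 0L)
  trace <- list()
  sweep <- function(stage, grid, make_params, prefer_larger) {
    reqs <- numeric(length(grid))
    for (k in seq_along(grid)) {
      cc <- .pooled_counts(benchmark, make_params(grid[k]))
      reqs[k] <- .pooled_req(cc)
      trace[[length(trace) + 1L]] <<- data.frame(
        stage = stage, value = grid[k], tp = cc$tp, fp = cc$fp, fn = cc$fn,
        req = reqs[k], selected = FALSE, stringsAsFactors = FALSE)
    }
    if (all(is.na(reqs))) {
      stop("all REQ values undefined (tp = 0 everywhere) in the '", stage,
           "' sweep", call. = FALSE)
    }
    best <- which(reqs == min(reqs, na.rm = TRUE))
    # stringent tie-break: smallest e-value, largest m, largest n
    pick <- if (prefer_larger) best[which.max(grid[best])]
            else best[which.min(grid[best])]
    trace[[length(trace) - length(grid) + pick]]$selected <<- TRUE
    grid[pick]
  }

  fp_at <- function(m, n) {
    filter_params(rost_n = n, min_domain_len = m,
                  decay_constant = base$filter$decay_constant)
  }
  sp_at <- function(e, m, n) {
    search_params(evalue_cutoff = e, filter = fp_at(m, n),
                  max_iterations = base$max_iterations, scheme = base$scheme)
  }
  # training order: e-value swept at m = 0, n = 0; then m; then n
  e_best <- sweep("evalue", sort(evalue_grid),
                  function(e) sp_at(e, 0, 0), prefer_larger = FALSE)
  m_best <- sweep("m", sort(m_grid),
                  function(m) sp_at(e_best, m, 0), prefer_larger = TRUE)
  n_best <- sweep("n", sort(n_grid),
                  function(n) sp_at(e_best, m_best, n), prefer_larger = TRUE)

  structure(list(params = sp_at(e_best, m_best, n_best),
                 trace = do.call(rbind, trace)),
            class = "param_optimization")
}

#' @export
print.param_optimization <- function(x, ...) {
  sel <- x$trace[x$trace$selected, ]
  cat("<param_optimization>\n")
  for (i in seq_len(nrow(sel))) {
    cat(sprintf("  %s = %g (pooled REQ %.3f)\n", sel$stage[i], sel$value[i],
                sel$req[i]))
  }
  invisible(x)
}
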