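#' Cross-tabulation of paired binary predictions
#'
#' Holds the 2x2 agreement table of a baseline and an updated binary
#' classifier evaluated on the same samples: counts where both predict
#' positive (`c_pp`), both negative (`c_nn`), baseline negative / updated
#' positive (`d_np`), and baseline positive / updated negative (`d_pn`).
#' The discordant set, of size `D = d_np + d_pn`, is the only part of the
#' data that requires human adjudication under discordant pair analysis.
#'
#' @param c_pp,c_nn,d_np,d_pn Non-negative integer counts.
#' @return An object of class `concordance_table` with elements `c_pp`,
#'   `c_nn`, `d_np`, `d_pn` plus derived totals `n`, `C` (concordant) and
#'   `D` (discordant).
#' @examples
#' concordance_table(c_pp = 2640, c_nn = 1355, d_np = 35, d_pn = 272)
#' @export
concordance_table <- function(c_pp, c_nn, d_np, d_pn) {
  counts <- c(c_pp = c_pp, c_nn = c_nn, d_np = d_np, d_pn = d_pn)
  for (nm in names(counts)) .check_count(counts[[nm]], nm)
  out <- list(
    c_pp = as.integer(c_pp), c_nn = as.integer(c_nn),
    d_np = as.integer(d_np), d_pn = as.integer(d_pn)
  )
  out$C <- out$c_pp + out$c_nn
  out$D <- out$d_np + out$d_pn
  out$n <- out$C + out$D
  structure(out, class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Paired prediction 2x2 table (baseline rows, updated columns)\n")
  m <- matrix(c(x$c_pp, x$d_np, x$d_pn, x$c_nn), 2, 2,
    dimnames = list(
      baseline = c("positive", "negative"),
      updated = c("positive", "negative")
    )
  )
  print(m)
  cat(sprintf(
    "n = %d, concordant C = %d, discordant D = %d\n", x$n, x$C, x$D
  ))
  invisible(x)
}

#' Adjudicated truth inside the discordant cells
#'
#' Records the human-adjudicated true-positive counts within the two
#' discordant cells: `tp_1d` truly positive samples among those the updated
#' model called positive and the baseline negative (`d_np`), and `tp_0d`
#' truly positive samples among those the baseline called positive and the
#' updated negative (`d_pn`). Every other discordant confusion count is
#' implied: each discordant sample is one model's error and the other's
#' success (see [implied_discordant_counts()]).
#'
#' @param tp_1d,tp_0d Non-negative integer counts.
#' @param table Optional [concordance_table()]; when given, bounds
#'   `tp_1d <= d_np` and `tp_0d <= d_pn` are enforced.
#' @return An object of class `discordant_adjudication`.
#' @export
discordant_adjudication <- function(tp_1d, tp_0d, table = NULL) {
  .check_count(tp_1d, "tp_1d")
  .check_count(tp_0d, "tp_0d")
  if (!is.null(table)) {
    stopifnot(inherits(table, "concordance_table"))
    if (tp_1d > table$d_np) {
      stop("tp_1d (", tp_1d, ") exceeds d_np (", table$d_np, ")", call. = FALSE)
    }
    if (tp_0d > table$d_pn) {
      stop("tp_0d (", tp_0d, ") exceeds d_pn (", table$d_pn, ")", call. = FALSE)
    }
  }
  structure(list(tp_1d = as.integer(tp_1d), tp_0d = as.integer(tp_0d)),
    class = "discordant_adjudication"
  )
}

#' @export
print.discordant_adjudication <- function(x, ...) {
  cat(sprintf(
    "Discordant adjudication: tp_1d = %d, tp_0d = %d\n", x$tp_1d, x$tp_0d
  ))
  invisible(x)
}

#' Full confusion counts implied by a discordant adjudication
#'
#' Within the discordant set every count is determined by the two
#' adjudicated true-positive counts: a truly positive sample in `d_np` is
#' the updated model's true positive and the baseline's false negative, and
#' so on. Returns all eight per-model discordant confusion counts.
#'
#' @param table A [concordance_table()].
#' @param adj A [discordant_adjudication()].
#' @return Named integer vector with elements `tp_1d`, `fp_1d`, `tn_1d`,
#'   `fn_1d`, `tp_0d`, `fp_0d`, `tn_0d`, `fn_0d`.
#' @export
implied_discordant_counts <- function(table, adj) {
  stopifnot(inherits(table, "concordance_table"))
  stopifnot(inherits(adj, "discordant_adjudication"))
  if (adj$tp_1d > table$d_np || adj$tp_0d > table$d_pn) {
    stop("adjudication counts exceed the table's discordant cells", call. = FALSE)
  }
  tn_0d <- table$d_np - adj$tp_1d
  tn_1d <- table$d_pn - adj$tp_0d
  c(
    tp_1d = adj$tp_1d, fp_1d = tn_0d, tn_1d = tn_1d, fn_1d = adj$tp_0d,
    tp_0d = adj$tp_0d, fp_0d = tn_1d, tn_0d = tn_0d, fn_0d = adj$tp_1d
  )
}

#' Baseline model performance assumptions
#'
#' The known operating characteristics of the baseline classifier, assumed
#' to generalise to the evaluation data: sensitivity `sens0`, specificity
#' `spec0`, and the positive-outcome prevalence `prev` of the evaluation
#' population. `prev_concentration` is the concentration `c` of the
#' Beta(c, c/prev - c) prevalence prior used by the bootstrap; its mean is
#' exactly `prev` and larger values encode tighter prior knowledge of the
#' prevalence.
#'
#' @param sens0,spec0 Proportions in (0, 1].
#' @param prev Proportion in (0, 1).
#' @param prev_concentration Positive real, default 100.
#' @return An object of class `baseline_assumptions`.
#' @examples
#' baseline_assumptions(sens0 = 0.988, spec0 = 0.727, prev = 0.615)
#' @export
baseline_assumptions <- function(sens0, spec0, prev, prev_concentration = 100) {
  .check_prop(sens0, "sens0", lo_open = TRUE)
  .check_prop(spec0, "spec0", lo_open = TRUE)
  .check_prop(prev, "prev", lo_open = TRUE, hi_open = TRUE)
  if (!is.numeric(prev_concentration) || length(prev_concentration) != 1 ||
    prev_concentration <= 0) {
    stop("prev_concentration must be a positive number", call. = FALSE)
  }
  # Beta(c, c/prev - c) needs a strictly positive second shape
  if (prev_concentration * (1 / prev - 1) <= 0) {
    stop("prev and prev_concentration give an invalid Beta prior", call. = FALSE)
  }
  structure(
    list(
      sens0 = sens0, spec0 = spec0, prev = prev,
      prev_concentration = prev_concentration
    ),
    class = "baseline_assumptions"
  )
}

#' @export
print.baseline_assumptions <- function(x, ...) {
  cat(sprintf(
    "Baseline assumptions: sens0 = %.3f, spec0 = %.3f, prev = %.3f (prior concentration %.1f)\n",
    x$sens0, x$spec0, x$prev, x$prev_concentration
  ))
  invisible(x)
}

#' Tabulate paired prediction records
#'
#' Cross-tabulates per-sample paired predictions into a
#' [concordance_table()] and extracts the adjudicated truth of the
#' discordant rows into a [discordant_adjudication()]. Every discordant row
#' (the two predictions differ) must carry a `true_label`; labels on
#' concordant rows are accepted and ignored for estimation — the method's
#' contract is that only discordant samples need adjudication.
#'
#' @param records A data frame with columns `sample_id`, `pred_baseline`,
#'   `pred_updated` (each prediction exactly 0 or 1) and optionally
#'   `true_label` (0, 1 or `NA`).
#' @return A list with elements `table` and `adjudication`.
#' @examples
#' recs <- data.frame(
#'   sample_id = c("a", "b", "c", "d"),
#'   pred_baseline = c(1, 0, 0, 1),
#'   pred_updated = c(1, 0, 1, 0),
#'   true_label = c(NA, NA, 1, 0)
#' )
#' tabulate_predictions(recs)
#' @export
tabulate_predictions <- function(records) {
  records <- .validate_records(records)
  disc <- records$pred_baseline != records$pred_updated
  unlabeled <- disc & is.na(records$true_label)
  if (any(unlabeled)) {
    ids <- records$sample_id[unlabeled]
    stop(
      "adjudicated true_label required for ", sum(unlabeled),
      " discordant sample(s): ",
      paste(utils::head(ids, 10), collapse = ", "),
      if (length(ids) > 10) ", ..." else "",
      call. = FALSE
    )
  }
  np <- disc & records$pred_updated == 1
  pn <- disc & records$pred_baseline == 1
  table <- concordance_table(
    c_pp = sum(!disc & records$pred_baseline == 1),
    c_nn = sum(!disc & records$pred_baseline == 0),
    d_np = sum(np),
    d_pn = sum(pn)
  )
  adj <- discordant_adjudication(
    tp_1d = sum(records$true_label[np] == 1),
    tp_0d = sum(records$true_label[pn] == 1),
    table = table
  )
  list(table = table, adjudication = adj)
}

#' Rows of a prediction set still needing adjudication
#'
#' Returns the discordant rows lacking a `true_label` — the adjudication
#' worklist. An empty result means [tabulate_predictions()] will succeed.
#'
#' @inheritParams tabulate_predictions
#' @return A data frame (possibly zero rows) with the same columns.
#' @export
adjudication_worklist <- function(records) {
  records <- .validate_records(records)
  disc <- records$pred_baseline != records$pred_updated
  out <- records[disc & is.na(records$true_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a sample size into assumed positives and negatives
#'
#' The assumed number of positive outcomes is `P = floor(n * prev)` and the
#' negatives are `N = n - P`. Flooring is exact when `n * prev` is an
#' integer up to floating-point error.
#'
#' @param n Total sample size, at least 1.
#' @param prev Assumed positive-outcome prevalence in (0, 1).
#' @return Named integer vector `c(P = , N = )`.
#' @examples
#' counts_from_prevalence(4302, 0.615) # P = 2645, N = 1657
#' @export
counts_from_prevalence <- function(n, prev) {
  .check_count(n, "n")
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  .check_prop(prev, "prev", lo_open = TRUE, hi_open = TRUE)
  p <- as.integer(floor(n * prev + 1e-9))
  c(P = p, N = as.integer(n) - p)
}

#' Discordant-pair estimate of the updated model's sensitivity
#'
#' Closed-form estimator using only the baseline sensitivity, the assumed
#' positive count, and the adjudicated discordant set:
#' `SENS1 = (sens0 * P - tp_0d + tp_1d) / P` with `P = floor(n * prev)`.
#' The concordant true positives cancel because both models share them.
#' Results outside `[0, 1]` (possible only under misspecified assumptions)
#' are clamped, with a warning and a `clamped` attribute.
#'
#' @param table A [concordance_table()].
#' @param adj A [discordant_adjudication()].
#' @param base A [baseline_assumptions()].
#' @return The estimated sensitivity, a proportion; attribute `clamped` is
#'   `TRUE` if clamping was applied.
#' @export
estimate_sensitivity <- function(table, adj, base) {
  stopifnot(inherits(table, "concordance_table"))
  stopifnot(inherits(base, "baseline_assumptions"))
  pn <- counts_from_prevalence(table$n, base$prev)
  if (pn[["P"]] < 1) {
    stop("assumed positive count P is zero; cannot estimate sensitivity",
      call. = FALSE
    )
  }
  cnt <- implied_discordant_counts(table, adj)
  est <- (base$sens0 * pn[["P"]] - cnt[["tp_0d"]] + cnt[["tp_1d"]]) / pn[["P"]]
  .clamp_unit(est, "sensitivity")
}

#' Discordant-pair estimate of the updated model's specificity
#'
#' Mirror of [estimate_sensitivity()] on the negative side:
#' `SPEC1 = (spec0 * N - tn_0d + tn_1d) / N` with `N = n - floor(n * prev)`,
#' `tn_0d = d_np - tp_1d` and `tn_1d = d_pn - tp_0d`.
#'
#' @inheritParams estimate_sensitivity
#' @return The estimated specificity, a proportion; attribute `clamped` is
#'   `TRUE` if clamping was applied.
#' @export
estimate_specificity <- function(table, adj, base) {
  stopifnot(inherits(table, "concordance_table"))
  stopifnot(inherits(base, "baseline_assumptions"))
  pn <- counts_from_prevalence(table$n, base$prev)
  if (pn[["N"]] < 1) {
    stop("assumed negative count N is zero; cannot estimate specificity",
      call. = FALSE
    )
  }
  cnt <- implied_discordant_counts(table, adj)
  est <- (base$spec0 * pn[["N"]] - cnt[["tn_0d"]] + cnt[["tn_1d"]]) / pn[["N"]]
  .clamp_unit(est, "specificity")
}

#' Fraction of adjudications avoided
#'
#' Relative to fully adjudicating all `n` samples, discordant pair analysis
#' labels only the `D` discordant ones, a saving of `1 - D/n`.
#'
#' @param table A [concordance_table()].
#' @return A proportion in `[0, 1]`.
#' @export
adjudication_reduction <- function(table) {
  stopifnot(inherits(table, "concordance_table"))
  if (table$n < 1) stop("empty table: n must be at least 1", call. = FALSE)
  1 - table$D / table$n
}

# ---- internal validation helpers -----------------------------------------

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
    x != floor(x)) {
    stop(name, " must be a single non-negative integer", call. = FALSE)
  }
  invisible(x)
}

.check_prop <- function(x, name, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > 0 else x >= 0) &&
    (if (hi_open) x < 1 else x <= 1)
  if (!ok) {
    stop(name, " must be a proportion in ",
      if (lo_open) "(" else "[", "0, 1", if (hi_open) ")" else "]",
      call. = FALSE
    )
  }
  invisible(x)
}

.clamp_unit <- function(est, what) {
  clamped <- est < 0 || est > 1
  if (clamped) {
    warning(
      "estimated ", what, " (", format(est, digits = 4),
      ") outside [0, 1]; clamped — check the baseline assumptions",
      call. = FALSE
    )
    est <- min(max(est, 0), 1)
  }
  structure(est, clamped = clamped)
}

.validate_records <- function(records) {
  if (!is.data.frame(records)) {
    stop("records must be a data frame", call. = FALSE)
  }
  needed <- c("sample_id", "pred_baseline", "pred_updated")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"true_label" %in% names(records)) records$true_label <- NA_integer_
  for (col in c("pred_baseline", "pred_updated")) {
    v <- records[[col]]
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      bad <- which(is.na(v) | !(v %in% c(0, 1)))
      stop(col, " must be exactly 0 or 1; offending row(s): ",
        paste(utils::head(bad, 10), collapse = ", "),
        call. = FALSE
      )
    }
  }
  lab <- records$true_label
  if (!all(is.na(lab) | lab %in% c(0, 1))) {
    bad <- which(!(is.na(lab) | lab %in% c(0, 1)))
    stop("true_label must be 0, 1 or missing; offending row(s): ",
      paste(utils::head(bad, 10), collapse = ", "),
      call. = FALSE
    )
  }
  records
}
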