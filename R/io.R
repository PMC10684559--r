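# File I/O for prediction records, tabulated counts, and reports.

#' Read paired prediction records from CSV
#'
#' Expects header `sample_id,pred_baseline,pred_updated,true_label`
#' (`true_label` optional and may be empty for concordant rows), UTF-8,
#' comma-separated. Malformed values are reported with their file line
#' number (header is line 1).
#'
#' @param path Path to the CSV file.
#' @return A validated data frame of prediction records.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- c("sample_id", "pred_baseline", "pred_updated")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"true_label" %in% names(df)) df$true_label <- ""
  parse_binary <- function(x, col, allow_blank = FALSE) {
    x <- trimws(x)
    blank <- x == "" | is.na(x)
    out <- suppressWarnings(as.integer(x))
    bad <- (!blank & (is.na(out) | !(out %in% c(0L, 1L)))) |
      (blank & !allow_blank)
    if (any(bad)) {
      stop(path, ": column ", col, " must be 0 or 1",
           if (allow_blank) " (or empty)", "; line(s) ",
           paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
           call. = FALSE)
    }
    out[blank] <- NA_integer_
    out
  }
  data.frame(
    sample_id = df$sample_id,
    pred_baseline = parse_binary(df$pred_baseline, "pred_baseline"),
    pred_updated = parse_binary(df$pred_updated, "pred_updated"),
    true_label = parse_binary(df$true_label, "true_label",
                              allow_blank = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Write paired prediction records to CSV
#'
#' Writes the same dialect [read_predictions()] consumes; missing labels
#' become empty fields. Write-then-read is an identity.
#'
#' @param records A data frame of prediction records.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_predictions <- function(records, path) {
  records <- .validate_records(records)
  out <- records[, c("sample_id", "pred_baseline", "pred_updated",
                     "true_label")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read tabulated counts from JSON
#'
#' For users entering already-tabulated data: a JSON object with keys
#' `c_pp`, `c_nn`, `d_np`, `d_pn`, `tp_0d`, `tp_1d`.
#'
#' @param path Path to the JSON file.
#' @return A list with `table` ([concordance_table()]) and `adjudication`
#'   ([discordant_adjudication()]).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("c_pp", "c_nn", "d_np", "d_pn", "tp_0d", "tp_1d")
  missing_keys <- setdiff(needed, names(x))
  if (length(missing_keys)) {
    stop(path, ": missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  table <- concordance_table(x$c_pp, x$c_nn, x$d_np, x$d_pn)
  adj <- discordant_adjudication(tp_1d = x$tp_1d, tp_0d = x$tp_0d,
                                 table = table)
  list(table = table, adjudication = adj)
}

#' Build a machine-readable evaluation report
#'
#' Assembles the full discordant-pair evaluation of a tabulated dataset:
#' point estimates with bootstrap CIs for both metrics (one shared set of
#' prevalence draws), the adjudication reduction, and provenance fields.
#'
#' @param table A [concordance_table()].
#' @param adj A [discordant_adjudication()].
#' @param base A [baseline_assumptions()].
#' @param cfg A [bootstrap_config()].
#' @return An object of class `dpa_report`: a list ready for JSON
#'   serialisation with elements `sensitivity` and `specificity` (each
#'   `metric`, `point`, `ci_lower`, `ci_upper`), `percent_reduction`,
#'   `counts`, `assumptions`, `k_samples`, `ci_level`, `seed`, `warnings`.
#' @export
dpa_report <- function(table, adj, base, cfg = bootstrap_config()) {
  sens <- estimate_with_ci(table, adj, base, cfg, metric = "sensitivity")
  spec <- estimate_with_ci(table, adj, base, cfg, metric = "specificity")
  structure(
    list(
      sensitivity = sens[c("metric", "point", "ci_lower", "ci_upper")],
      specificity = spec[c("metric", "point", "ci_lower", "ci_upper")],
      percent_reduction = 100 * adjudication_reduction(table),
      counts = list(
        c_pp = table$c_pp, c_nn = table$c_nn, d_np = table$d_np,
        d_pn = table$d_pn, n = table$n, D = table$D,
        tp_0d = adj$tp_0d, tp_1d = adj$tp_1d
      ),
      assumptions = list(
        sens0 = base$sens0, spec0 = base$spec0, prev = base$prev,
        prev_concentration = base$prev_concentration
      ),
      k_samples = cfg$k_samples, ci_level = cfg$ci_level,
      seed = if (is.null(cfg$seed)) NA else cfg$seed,
      warnings = c(sens$warnings, spec$warnings)
    ),
    class = "dpa_report"
  )
}

#' @export
print.dpa_report <- function(x, ...) {
  cat("Discordant pair analysis\n")
  cat(sprintf("  n = %d, adjudicated D = %d (%.1f%% reduction)\n",
              x$counts$n, x$counts$D, x$percent_reduction))
  fmt <- function(m) {
    sprintf("  %-12s %.1f (%.0f%% CI: %.1f, %.1f)\n",
            m$metric, 100 * m$point, 100 * x$ci_level,
            100 * m$ci_lower, 100 * m$ci_upper)
  }
  cat(fmt(x$sensitivity))
  cat(fmt(x$specificity))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write a report (or any list) as JSON
#'
#' Floating-point values are serialised at full precision; display rounding
#' happens only in the human-readable summary.
#'
#' @param x A list, e.g. a [dpa_report()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
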