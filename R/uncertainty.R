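#' Bootstrap configuration
#'
#' Settings for the multi-stage Monte Carlo bootstrap: the number of draws
#' `k_samples`, the two-sided confidence level `ci_level`, and an optional
#' RNG `seed` (when `NULL` the current RNG state is consumed).
#'
#' @param k_samples Number of Monte Carlo draws, default 10000.
#' @param ci_level Two-sided confidence level in (0, 1), default 0.95.
#' @param seed Optional integer seed.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(k_samples = 10000, ci_level = 0.95, seed = NULL) {
  .check_count(k_samples, "k_samples")
  if (k_samples < 1) stop("k_samples must be at least 1", call. = FALSE)
  .check_prop(ci_level, "ci_level", lo_open = TRUE, hi_open = TRUE)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
      stop("seed must be a single integer or NULL", call. = FALSE)
    }
    seed <- as.integer(seed)
  }
  structure(list(k_samples = as.integer(k_samples), ci_level = ci_level,
                 seed = seed),
            class = "bootstrap_config")
}

# One pass of the multi-stage scheme, stage-vectorised in the stated order:
# PREV_k, P_k, TP_0k, SENS_1k, then TN_0k, SPEC_1k. Both metric chains share
# the same prevalence/P_k draws within each k, so running the two chains
# from the same seed is consistent by construction. Draws with P_k = 0 or
# N_k = 0 are redrawn (negligible probability at realistic n).
.bootstrap_draws <- function(table, adj, base, cfg) {
  stopifnot(inherits(table, "concordance_table"))
  stopifnot(inherits(base, "baseline_assumptions"))
  stopifnot(inherits(cfg, "bootstrap_config"))
  if (table$n < 1) stop("empty table: n must be at least 1", call. = FALSE)
  cnt <- implied_discordant_counts(table, adj)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  n <- table$n
  k <- cfg$k_samples
  conc <- base$prev_concentration
  shape2 <- conc / base$prev - conc

  prev_k <- stats::rbeta(k, conc, shape2)
  p_k <- stats::rbinom(k, n, prev_k)
  bad <- p_k == 0L | p_k == n
  guard <- 0L
  while (any(bad)) {
    prev_k[bad] <- stats::rbeta(sum(bad), conc, shape2)
    p_k[bad] <- stats::rbinom(sum(bad), n, prev_k[bad])
    bad <- p_k == 0L | p_k == n
    guard <- guard + 1L
    if (guard > 1000L) {
      stop("could not draw a non-degenerate positive count; ",
           "n or the prevalence prior is too extreme", call. = FALSE)
    }
  }

  tp_0k <- stats::rbinom(k, p_k, base$sens0)
  a <- pmin(pmax(tp_0k - cnt[["tp_0d"]] + cnt[["tp_1d"]], 0L), p_k)
  sens <- stats::rbeta(k, a + 1, p_k - a + 1)

  n_k <- n - p_k
  tn_0k <- stats::rbinom(k, n_k, base$spec0)
  b <- pmin(pmax(tn_0k - cnt[["tn_0d"]] + cnt[["tn_1d"]], 0L), n_k)
  spec <- stats::rbeta(k, b + 1, n_k - b + 1)

  list(sensitivity = sens, specificity = spec)
}

#' Monte Carlo bootstrap draws of the updated model's sensitivity
#'
#' Propagates uncertainty in the prevalence and the baseline model's
#' performance through the discordant-pair estimator. For each of the K
#' draws: prevalence `PREV_k ~ Beta(c, c/prev - c)` (mean exactly `prev`,
#' concentration `c = prev_concentration`); positive count
#' `P_k ~ Binomial(n, PREV_k)`; baseline true positives
#' `TP_0k ~ Binomial(P_k, sens0)`; then the updated-model sensitivity
#' `SENS_1k ~ Beta(a + 1, P_k - a + 1)` with
#' `a = TP_0k - tp_0d + tp_1d` clamped into `[0, P_k]`.
#'
#' @param table A [concordance_table()].
#' @param adj A [discordant_adjudication()].
#' @param base A [baseline_assumptions()].
#' @param cfg A [bootstrap_config()].
#' @return Numeric vector of `k_samples` draws in `[0, 1]`, reproducible
#'   given `cfg$seed`.
#' @seealso [sample_specificity()], [estimate_with_ci()]
#' @export
sample_sensitivity <- function(table, adj, base, cfg = bootstrap_config()) {
  .bootstrap_draws(table, adj, base, cfg)$sensitivity
}

#' Monte Carlo bootstrap draws of the updated model's specificity
#'
#' Mirror of [sample_sensitivity()] on the negative side: within each draw
#' `N_k = n - P_k` (the prevalence draw is shared with the sensitivity
#' chain), `TN_0k ~ Binomial(N_k, spec0)`, and
#' `SPEC_1k ~ Beta(b + 1, N_k - b + 1)` with
#' `b = TN_0k - tn_0d + tn_1d` clamped into `[0, N_k]`.
#'
#' @inheritParams sample_sensitivity
#' @return Numeric vector of `k_samples` draws in `[0, 1]`.
#' @export
sample_specificity <- function(table, adj, base, cfg = bootstrap_config()) {
  .bootstrap_draws(table, adj, base, cfg)$specificity
}

#' Empirical confidence bounds from bootstrap draws
#'
#' Two-sided bounds at the `(1 - ci_level)/2` and `1 - (1 - ci_level)/2`
#' empirical quantiles, with linear interpolation between order statistics
#' (R quantile type 7).
#'
#' @param draws Numeric vector of at least 2 draws.
#' @param ci_level Two-sided confidence level in (0, 1).
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
ci_from_samples <- function(draws, ci_level = 0.95) {
  if (!is.numeric(draws) || length(draws) < 2) {
    stop("draws must be a numeric vector of at least 2 values", call. = FALSE)
  }
  .check_prop(ci_level, "ci_level", lo_open = TRUE, hi_open = TRUE)
  alpha <- (1 - ci_level) / 2
  q <- stats::quantile(draws, probs = c(alpha, 1 - alpha),
                       type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Point estimate with bootstrap confidence interval
#'
#' Combines the closed-form discordant-pair point estimate with the
#' multi-stage Monte Carlo bootstrap interval for one metric.
#'
#' @inheritParams sample_sensitivity
#' @param metric `"sensitivity"` or `"specificity"`.
#' @return An object of class `performance_estimate`: a list with `metric`,
#'   `point`, `ci_lower`, `ci_upper`, `k_samples`, `ci_level`, and
#'   `warnings` (character vector, e.g. when the point estimate was
#'   clamped).
#' @examples
#' fix <- tabulate_predictions(af_example_records())
#' base <- baseline_assumptions(0.988, 0.727, 0.615)
#' estimate_with_ci(fix$table, fix$adjudication, base,
#'   bootstrap_config(k_samples = 2000, seed = 1),
#'   metric = "sensitivity"
#' )
#' @export
estimate_with_ci <- function(table, adj, base, cfg = bootstrap_config(),
                             metric = c("sensitivity", "specificity")) {
  metric <- match.arg(metric)
  warnings <- character()
  point <- withCallingHandlers(
    if (metric == "sensitivity") {
      estimate_sensitivity(table, adj, base)
    } else {
      estimate_specificity(table, adj, base)
    },
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  draws <- .bootstrap_draws(table, adj, base, cfg)[[metric]]
  ci <- ci_from_samples(draws, cfg$ci_level)
  structure(
    list(
      metric = metric, point = as.numeric(point),
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
      k_samples = cfg$k_samples, ci_level = cfg$ci_level,
      warnings = warnings
    ),
    class = "performance_estimate"
  )
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: %.1f (%.0f%% CI: %.1f, %.1f)  [K = %d]\n",
    x$metric, 100 * x$point, 100 * x$ci_level,
    100 * x$ci_lower, 100 * x$ci_upper, x$k_samples
  ))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
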