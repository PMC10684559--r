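# Simulation-study drivers: repeatedly simulate paired evaluations with
# known truth, run the discordant-pair estimator and bootstrap on each, and
# aggregate MSE, CI width, CI coverage and adjudication savings over sweeps
# of between-model correlation, sample size, and true prevalence.

# Deterministic substream seeds: derived from the sweep value (not its
# position) so per-point results are independent of sweep order;
# individually reproducible; always < 2^31.
.point_seed <- function(seed, point_value) {
  as.integer((as.numeric(seed) + 7919 * (round(point_value * 1000) + 1)) %%
               2147483647)
}
.trial_seed <- function(point_seed, trial_index) {
  as.integer((as.numeric(point_seed) + 104729 * trial_index) %% 2147483647)
}

# simulate_trial without materialising per-sample records
.simulate_tally <- function(spec, n) {
  y <- stats::rbinom(n, 1L, spec$prev)
  npos <- sum(y)
  pred0 <- integer(n)
  pred1 <- integer(n)
  if (npos > 0) {
    pp <- correlated_bernoulli_pair(spec$sens0, spec$sens1, spec$rho, npos)
    pred0[y == 1L] <- pp[, 1]
    pred1[y == 1L] <- pp[, 2]
  }
  if (npos < n) {
    pn <- correlated_bernoulli_pair(1 - spec$spec0, 1 - spec$spec1,
                                    spec$rho, n - npos)
    pred0[y == 0L] <- pn[, 1]
    pred1[y == 0L] <- pn[, 2]
  }
  trial_tally(pred0, pred1, y)
}

#' Run one simulation trial of the discordant-pair workflow
#'
#' Simulates a paired evaluation of `n` samples with known truth, then (a)
#' computes the fully adjudicated observed sensitivity/specificity of the
#' updated model (the comparator), (b) computes the discordant-pair point
#' estimates using the supplied assumptions and only the discordant-set
#' adjudications, (c) computes bootstrap CIs, and (d) records the percent
#' adjudication reduction. Trials that realize no positives or no negatives
#' are flagged (estimates `NA`) and excluded from aggregation.
#'
#' @param pair A [model_pair_spec()] describing the generating truth.
#' @param n Samples per trial.
#' @param base A [baseline_assumptions()] fed to the estimator (possibly
#'   deliberately different from the generating truth).
#' @param k_samples Bootstrap draws per trial.
#' @param ci_level Two-sided confidence level.
#' @param seed Optional integer seed for the trial's RNG substream.
#' @return A one-row data frame with the estimates, comparators, CI bounds,
#'   true generating metrics, percent reduction and a `flagged` indicator.
#' @export
run_trial <- function(pair, n, base, k_samples = 2000, ci_level = 0.95,
                      seed = NULL) {
  stopifnot(inherits(pair, "model_pair_spec"))
  stopifnot(inherits(base, "baseline_assumptions"))
  if (!is.null(seed)) set.seed(seed)
  tally <- .simulate_tally(pair, as.integer(n))
  flagged <- tally$P == 0L || tally$N == 0L
  row <- data.frame(
    seed = if (is.null(seed)) NA_integer_ else seed,
    flagged = flagged,
    sens_est = NA_real_, sens_obs = NA_real_,
    sens_lo = NA_real_, sens_hi = NA_real_,
    spec_est = NA_real_, spec_obs = NA_real_,
    spec_lo = NA_real_, spec_hi = NA_real_,
    sens_true = pair$sens1, spec_true = pair$spec1,
    pct_reduction = 100 * (1 - tally$D / tally$n)
  )
  if (flagged) return(row)
  obs <- observed_metrics(tally, model = 1)
  table <- as_concordance_table(tally)
  adj <- as_discordant_adjudication(tally)
  cfg <- bootstrap_config(k_samples = k_samples, ci_level = ci_level)
  sens_est <- suppressWarnings(estimate_sensitivity(table, adj, base))
  spec_est <- suppressWarnings(estimate_specificity(table, adj, base))
  draws <- .bootstrap_draws(table, adj, base, cfg)
  ci_sens <- ci_from_samples(draws$sensitivity, ci_level)
  ci_spec <- ci_from_samples(draws$specificity, ci_level)
  row$sens_est <- as.numeric(sens_est)
  row$sens_obs <- obs[["sensitivity"]]
  row$sens_lo <- ci_sens[["lower"]]
  row$sens_hi <- ci_sens[["upper"]]
  row$spec_est <- as.numeric(spec_est)
  row$spec_obs <- obs[["specificity"]]
  row$spec_lo <- ci_spec[["lower"]]
  row$spec_hi <- ci_spec[["upper"]]
  row
}

#' Aggregate trial records into study point metrics
#'
#' Per metric: mean squared error of the discordant-pair estimate against
#' the comparator, mean CI width, and CI coverage (the fraction of trials
#' whose interval contains the comparator), plus the mean percent
#' adjudication reduction. The comparator is either each trial's fully
#' adjudicated observed updated-model metric (`"observed"`, default) or the
#' generating true parameter (`"true"`). Flagged trials are excluded and
#' counted.
#'
#' @param trials Data frame of rows from [run_trial()].
#' @param comparator `"observed"` or `"true"`.
#' @return A one-row data frame: `mse_sens`, `mse_spec`, `width_sens`,
#'   `width_spec`, `coverage_sens`, `coverage_spec`, `pct_reduction`,
#'   `n_trials_used`, `n_flagged`.
#' @export
aggregate_trials <- function(trials, comparator = c("observed", "true")) {
  comparator <- match.arg(comparator)
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  keep <- trials[!trials$flagged, , drop = FALSE]
  if (nrow(keep) == 0) {
    stop("all trials flagged (no realized positives or negatives)",
         call. = FALSE)
  }
  comp_sens <- if (comparator == "observed") keep$sens_obs else keep$sens_true
  comp_spec <- if (comparator == "observed") keep$spec_obs else keep$spec_true
  data.frame(
    mse_sens = mean((keep$sens_est - comp_sens)^2),
    mse_spec = mean((keep$spec_est - comp_spec)^2),
    width_sens = mean(keep$sens_hi - keep$sens_lo),
    width_spec = mean(keep$spec_hi - keep$spec_lo),
    coverage_sens = mean(keep$sens_lo <= comp_sens & comp_sens <= keep$sens_hi),
    coverage_spec = mean(keep$spec_lo <= comp_spec & comp_spec <= keep$spec_hi),
    pct_reduction = mean(keep$pct_reduction),
    n_trials_used = nrow(keep),
    n_flagged = sum(trials$flagged)
  )
}

# Shared sweep engine: one aggregated row per sweep point.
.run_sweep <- function(points, make_pair, make_base, n_for_point,
                       n_trials, k_samples, ci_level, seed, comparator,
                       sweep_name, verbose = FALSE) {
  res <- vector("list", length(points))
  for (i in seq_along(points)) {
    pair <- make_pair(points[i])
    base <- make_base(points[i])
    n <- n_for_point(points[i])
    ps <- .point_seed(seed, points[i])
    trials <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      trials[[t]] <- run_trial(pair, n, base,
        k_samples = k_samples, ci_level = ci_level,
        seed = .trial_seed(ps, t)
      )
    }
    agg <- aggregate_trials(do.call(rbind, trials), comparator = comparator)
    agg <- cbind(stats::setNames(data.frame(points[i]), sweep_name), agg)
    res[[i]] <- agg
    if (verbose) {
      message(sprintf(
        "%s = %s: reduction %.1f%%, coverage (sens %.3f, spec %.3f)",
        sweep_name, format(points[i]), agg$pct_reduction,
        agg$coverage_sens, agg$coverage_spec
      ))
    }
  }
  do.call(rbind, res)
}

#' Between-model correlation sweep
#'
#' Sweeps the latent correlation between the baseline and updated model
#' predictions while holding everything else at the study defaults
#' (sensitivities 0.988/0.990, specificities 0.727/0.882, prevalence 0.615,
#' n = 5000), with the estimator's assumptions matched to the truth.
#' Correlation chiefly drives the adjudication saving (more correlated
#' models disagree less) and the CI coverage.
#'
#' @param rho Grid of latent correlations.
#' @param pair A [model_pair_spec()] giving the non-swept truth.
#' @param n Samples per trial.
#' @param n_trials Trials per grid point.
#' @param k_samples Bootstrap draws per trial.
#' @param ci_level Two-sided confidence level.
#' @param seed Integer seed.
#' @param comparator Passed to [aggregate_trials()].
#' @param verbose Log one line per grid point to standard error.
#' @return Data frame, one row per grid point, with the sweep value and all
#'   [aggregate_trials()] columns.
#' @export
run_correlation_study <- function(rho = c(seq(0, 0.9, by = 0.1), 0.95, 0.99),
                                  pair = model_pair_spec(), n = 5000,
                                  n_trials = 10000, k_samples = 2000,
                                  ci_level = 0.95, seed = 1,
                                  comparator = "observed", verbose = FALSE) {
  base <- baseline_assumptions(pair$sens0, pair$spec0, pair$prev)
  .run_sweep(
    points = rho,
    make_pair = function(r) {
      model_pair_spec(pair$sens0, pair$sens1, pair$spec0, pair$spec1,
                      rho = r, prev = pair$prev)
    },
    make_base = function(r) base,
    n_for_point = function(r) n,
    n_trials = n_trials, k_samples = k_samples, ci_level = ci_level,
    seed = seed, comparator = comparator, sweep_name = "rho",
    verbose = verbose
  )
}

#' Sample-size sweep
#'
#' Sweeps the evaluation sample size at fixed correlation (default 0.90)
#' and prevalence 0.615, with matched assumptions. Sample size chiefly
#' drives the MSE and CI width of both metrics.
#'
#' @param n Grid of sample sizes.
#' @param rho Latent correlation held fixed.
#' @inheritParams run_correlation_study
#' @return Data frame, one row per grid point.
#' @export
run_samplesize_study <- function(n = seq(1000, 10000, by = 1000), rho = 0.9,
                                 pair = model_pair_spec(), n_trials = 10000,
                                 k_samples = 2000, ci_level = 0.95, seed = 1,
                                 comparator = "observed", verbose = FALSE) {
  base <- baseline_assumptions(pair$sens0, pair$spec0, pair$prev)
  swept_pair <- model_pair_spec(pair$sens0, pair$sens1, pair$spec0,
                                pair$spec1, rho = rho, prev = pair$prev)
  .run_sweep(
    points = n,
    make_pair = function(ni) swept_pair,
    make_base = function(ni) base,
    n_for_point = function(ni) ni,
    n_trials = n_trials, k_samples = k_samples, ci_level = ci_level,
    seed = seed, comparator = comparator, sweep_name = "n",
    verbose = verbose
  )
}

#' Prevalence-misspecification sweep
#'
#' Sweeps the true generating prevalence while the estimator keeps assuming
#' `prev_assumed` (default 0.615); correlation fixed (default 0.90),
#' n = 5000. Quantifies how sensitive the estimates and their CI coverage
#' are to a wrong prevalence assumption — the method's key operating
#' caveat: over-specifying prevalence within about 10 points is benign,
#' under-specifying it degrades coverage sharply.
#'
#' @param prev_true Grid of true generating prevalences.
#' @param prev_assumed Prevalence the estimator assumes at every point.
#' @param rho Latent correlation held fixed.
#' @inheritParams run_correlation_study
#' @return Data frame, one row per grid point.
#' @export
run_prevalence_study <- function(prev_true = seq(0.1, 0.9, by = 0.1),
                                 prev_assumed = 0.615, rho = 0.9,
                                 pair = model_pair_spec(), n = 5000,
                                 n_trials = 10000, k_samples = 2000,
                                 ci_level = 0.95, seed = 1,
                                 comparator = "observed", verbose = FALSE) {
  base <- baseline_assumptions(pair$sens0, pair$spec0, prev_assumed)
  .run_sweep(
    points = prev_true,
    make_pair = function(pv) {
      model_pair_spec(pair$sens0, pair$sens1, pair$spec0, pair$spec1,
                      rho = rho, prev = pv)
    },
    make_base = function(pv) base,
    n_for_point = function(pv) n,
    n_trials = n_trials, k_samples = k_samples, ci_level = ci_level,
    seed = seed, comparator = comparator, sweep_name = "prev_true",
    verbose = verbose
  )
}
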