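# Independent oracles used across tests.

# Brute-force confusion-matrix metrics of one model from fully labeled
# records (the consistency oracle for the discordant-pair estimators).
brute_force_metrics <- function(records, model = c("updated", "baseline")) {
  model <- match.arg(model)
  pred <- if (model == "updated") records$pred_updated else records$pred_baseline
  y <- records$true_label
  stopifnot(!anyNA(y))
  c(
    sensitivity = sum(pred == 1 & y == 1) / sum(y == 1),
    specificity = sum(pred == 0 & y == 0) / sum(y == 0)
  )
}

# P(Z1 <= a, Z2 <= b) for a standard bivariate normal, by trapezoid
# integration of the conditional-normal representation on a fixed grid —
# deliberately a different quadrature than the package's own routine.
orthant_oracle <- function(a, b, rho) {
  if (abs(rho) == 1) {
    if (rho == 1) return(pnorm(min(a, b)))
    return(max(0, pnorm(a) + pnorm(b) - 1))
  }
  z <- seq(-8, a, length.out = 20001)
  f <- dnorm(z) * pnorm((b - rho * z) / sqrt(1 - rho^2))
  sum((f[-1] + f[-length(f)]) / 2 * diff(z))
}

# Small fully-specified record builder.
make_records <- function(pred_baseline, pred_updated, true_label = NA) {
  data.frame(
    sample_id = sprintf("s%02d", seq_along(pred_baseline)),
    pred_baseline = as.integer(pred_baseline),
    pred_updated = as.integer(pred_updated),
    true_label = as.integer(rep(true_label, length.out = length(pred_baseline))),
    stringsAsFactors = FALSE
  )
}

example_assumptions <- function() baseline_assumptions(0.988, 0.727, 0.615)
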