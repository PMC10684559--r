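test_that("tabulation partitions records and extracts discordant truth", {
  recs <- make_records(
    pred_baseline = c(1, 0, 0, 1),
    pred_updated = c(1, 0, 1, 0),
    true_label = c(NA, NA, 1, 0)
  )
  out <- tabulate_predictions(recs)
  expect_equal(out$table$c_pp, 1L)
  expect_equal(out$table$c_nn, 1L)
  expect_equal(out$table$d_np, 1L)
  expect_equal(out$table$d_pn, 1L)
  expect_equal(out$adjudication$tp_1d, 1L)
  expect_equal(out$adjudication$tp_0d, 0L)

  empty <- tabulate_predictions(make_records(integer(0), integer(0)))
  expect_equal(empty$table$n, 0L)
  expect_equal(empty$adjudication$tp_1d, 0L)
  expect_equal(empty$adjudication$tp_0d, 0L)
})

test_that("discordant rows without labels are rejected by sample id", {
  recs <- make_records(c(1, 0), c(0, 0), c(NA, NA))
  expect_error(tabulate_predictions(recs), "s01")
  expect_equal(adjudication_worklist(recs)$sample_id, "s01")
})

test_that("non-binary predictions and labels are format errors", {
  expect_error(
    tabulate_predictions(make_records(c(1, 2), c(0, 0))),
    "pred_baseline"
  )
  expect_error(
    tabulate_predictions(make_records(c(1, 0), c(0, 0), c(5, NA))),
    "true_label"
  )
})

test_that("prevalence splits the sample size by flooring", {
  expect_equal(counts_from_prevalence(4302, 0.615), c(P = 2645L, N = 1657L))
  expect_equal(counts_from_prevalence(10, 0.5), c(P = 5L, N = 5L))
  expect_equal(counts_from_prevalence(1000, 0.1), c(P = 100L, N = 900L))
})

test_that("point estimators reproduce the worked ICM AF example", {
  fix <- tabulate_predictions(af_example_records())
  expect_equal(fix$table$c_pp, 2640L)
  expect_equal(fix$table$c_nn, 1355L)
  expect_equal(fix$table$d_np, 35L)
  expect_equal(fix$table$d_pn, 272L)
  expect_equal(fix$table$D, 307L)

  base <- example_assumptions()
  sens <- estimate_sensitivity(fix$table, fix$adjudication, base)
  spec <- estimate_specificity(fix$table, fix$adjudication, base)
  expect_equal(as.numeric(sens), (0.988 * 2645 - 25 + 33) / 2645)
  expect_equal(round(100 * as.numeric(sens), 1), 99.1)
  expect_equal(as.numeric(spec), (0.727 * 1657 - 2 + 247) / 1657)
  expect_equal(round(100 * as.numeric(spec), 1), 87.5)
  expect_equal(adjudication_reduction(fix$table), 1 - 307 / 4302)
})

test_that("hand-evaluated estimator cases match the closed forms", {
  # sens0 = 1, P = 10, tp_0d = 2, tp_1d = 0 -> (10 - 2 + 0)/10
  tab <- concordance_table(c_pp = 16, c_nn = 0, d_np = 2, d_pn = 2)
  adj <- discordant_adjudication(tp_1d = 0, tp_0d = 2, table = tab)
  base <- baseline_assumptions(1.0, 0.5, 0.5)
  expect_equal(as.numeric(estimate_sensitivity(tab, adj, base)), 0.8)

  # spec0 = 0.5, N = 4, tn_0d = 0, tn_1d = 2 -> (2 + 2)/4
  tab <- concordance_table(c_pp = 5, c_nn = 0, d_np = 1, d_pn = 2)
  adj <- discordant_adjudication(tp_1d = 1, tp_0d = 0, table = tab)
  base <- baseline_assumptions(0.5, 0.5, 0.5)
  expect_equal(as.numeric(estimate_specificity(tab, adj, base)), 1.0)
})

test_that("with no discordance the estimates are exactly the assumptions", {
  tab <- concordance_table(c_pp = 40, c_nn = 60, d_np = 0, d_pn = 0)
  adj <- discordant_adjudication(0, 0, table = tab)
  base <- baseline_assumptions(0.91, 0.83, 0.4)
  expect_equal(as.numeric(estimate_sensitivity(tab, adj, base)), 0.91)
  expect_equal(as.numeric(estimate_specificity(tab, adj, base)), 0.83)
})

test_that("estimates outside [0,1] are clamped with a warning", {
  tab <- concordance_table(c_pp = 10, c_nn = 10, d_np = 10, d_pn = 0)
  adj <- discordant_adjudication(tp_1d = 10, tp_0d = 0, table = tab)
  base <- baseline_assumptions(0.99, 0.5, 0.5)
  expect_warning(est <- estimate_sensitivity(tab, adj, base), "clamped")
  expect_equal(as.numeric(est), 1)
  expect_true(attr(est, "clamped"))
})

test_that("full-label consistency oracle: empirical assumptions recover the updated model's observed metrics", {
  pair <- model_pair_spec(rho = 0.5)
  for (seed in 1:5) {
    sim <- simulate_trial(pair, 2000, seed = seed)
    obs0 <- brute_force_metrics(sim$records, "baseline")
    obs1 <- brute_force_metrics(sim$records, "updated")
    prev_emp <- sum(sim$records$true_label) / nrow(sim$records)
    base <- baseline_assumptions(obs0[["sensitivity"]],
                                 obs0[["specificity"]], prev_emp)
    tab <- tabulate_predictions(sim$records)
    expect_equal(
      as.numeric(estimate_sensitivity(tab$table, tab$adjudication, base)),
      obs1[["sensitivity"]]
    )
    expect_equal(
      as.numeric(estimate_specificity(tab$table, tab$adjudication, base)),
      obs1[["specificity"]]
    )
  }
})

test_that("swapping model roles recovers the baseline's assumed metrics", {
  fix <- tabulate_predictions(af_example_records())
  base <- example_assumptions()
  sens1 <- as.numeric(estimate_sensitivity(fix$table, fix$adjudication, base))
  spec1 <- as.numeric(estimate_specificity(fix$table, fix$adjudication, base))
  # transpose the table, swap the adjudicated cells, assume the updated
  # model's estimated metrics as the new baseline
  tab_sw <- concordance_table(
    c_pp = fix$table$c_pp, c_nn = fix$table$c_nn,
    d_np = fix$table$d_pn, d_pn = fix$table$d_np
  )
  adj_sw <- discordant_adjudication(
    tp_1d = fix$adjudication$tp_0d, tp_0d = fix$adjudication$tp_1d,
    table = tab_sw
  )
  base_sw <- baseline_assumptions(sens1, spec1, base$prev)
  expect_equal(
    as.numeric(estimate_sensitivity(tab_sw, adj_sw, base_sw)), base$sens0
  )
  expect_equal(
    as.numeric(estimate_specificity(tab_sw, adj_sw, base_sw)), base$spec0
  )
})

test_that("implied discordant counts satisfy the net-difference identity", {
  set.seed(7)
  for (i in 1:50) {
    d_np <- sample(0:30, 1)
    d_pn <- sample(0:30, 1)
    tab <- concordance_table(c_pp = 10, c_nn = 10, d_np = d_np, d_pn = d_pn)
    adj <- discordant_adjudication(
      tp_1d = sample(0:d_np, 1), tp_0d = sample(0:d_pn, 1), table = tab
    )
    cnt <- implied_discordant_counts(tab, adj)
    expect_equal(
      cnt[["tn_1d"]] - cnt[["tn_0d"]],
      (d_pn - d_np) + (cnt[["tp_1d"]] - cnt[["tp_0d"]])
    )
    # each discordant cell decomposes into one model's error/success pair
    expect_equal(cnt[["tp_1d"]] + cnt[["fp_1d"]], d_np)
    expect_equal(cnt[["tn_0d"]] + cnt[["fn_0d"]], d_np)
    expect_equal(cnt[["tn_1d"]] + cnt[["fn_1d"]], d_pn)
    expect_equal(cnt[["tp_0d"]] + cnt[["fp_0d"]], d_pn)
  }
})

test_that("adjudication bounds against the table are enforced", {
  tab <- concordance_table(1, 1, 2, 3)
  expect_error(discordant_adjudication(3, 0, table = tab), "d_np")
  expect_error(discordant_adjudication(0, 4, table = tab), "d_pn")
  expect_error(adjudication_reduction(concordance_table(0, 0, 0, 0)), "empty")
})
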