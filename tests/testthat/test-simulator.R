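test_that("comonotone and independent copulas behave as expected", {
  x <- correlated_bernoulli_pair(0.7, 0.7, rho = 1, m = 5000, seed = 1)
  expect_true(all(x[, 1] == x[, 2]))
  expect_equal(mean(x[, 1]), 0.7, tolerance = 4 * sqrt(0.21 / 5000))

  x <- correlated_bernoulli_pair(0.5, 0.5, rho = 0, m = 1e5, seed = 2)
  p11 <- mean(x[, 1] == 1 & x[, 2] == 1)
  expect_lt(abs(p11 - 0.25), 4 * sqrt(0.25 * 0.75 / 1e5))

  x <- correlated_bernoulli_pair(0.3, 0.3, rho = -1, m = 5000, seed = 3)
  expect_true(all(x[, 1] + x[, 2] <= 1)) # countermonotone: never both 1

  x <- correlated_bernoulli_pair(0, 1, rho = 0.5, m = 100, seed = 4)
  expect_true(all(x[, 1] == 0) && all(x[, 2] == 1))

  expect_equal(nrow(correlated_bernoulli_pair(0.5, 0.5, 0, 0)), 0)
})

test_that("joint cell probabilities match the bivariate-normal orthant oracle", {
  grid <- expand.grid(p1 = c(0.3, 0.727), p2 = c(0.6, 0.882),
                      rho = c(0.2, 0.9))
  m <- 2e5
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    x <- correlated_bernoulli_pair(g$p1, g$p2, g$rho, m, seed = 100 + i)
    emp <- mean(x[, 1] == 1 & x[, 2] == 1)
    expected <- orthant_oracle(qnorm(g$p1), qnorm(g$p2), g$rho)
    se <- sqrt(expected * (1 - expected) / m)
    expect_equal(emp, expected, tolerance = 4 * se / expected)
    expect_equal(mean(x[, 1]), g$p1, tolerance = 4 * sqrt(g$p1 * (1 - g$p1) / m) / g$p1)
    expect_equal(mean(x[, 2]), g$p2, tolerance = 4 * sqrt(g$p2 * (1 - g$p2) / m) / g$p2)
  }

  # the heavy case at tighter relative error
  x <- correlated_bernoulli_pair(0.3, 0.6, 0.9, 1e6, seed = 99)
  emp <- mean(x[, 1] == 1 & x[, 2] == 1)
  expected <- orthant_oracle(qnorm(0.3), qnorm(0.6), 0.9)
  expect_lt(abs(emp - expected), 3 * sqrt(expected * (1 - expected) / 1e6))
})

test_that("package orthant routine agrees with the independent quadrature", {
  for (rho in c(-0.8, 0, 0.5, 0.99)) {
    expect_equal(
      bivariate_normal_orthant(qnorm(0.3), qnorm(0.6), rho),
      orthant_oracle(qnorm(0.3), qnorm(0.6), rho),
      tolerance = 1e-6
    )
  }
})

test_that("implied phi is zero at independence and one for identical margins at rho = 1", {
  expect_equal(implied_phi(0.4, 0.7, 0), 0, tolerance = 1e-10)
  expect_equal(implied_phi(0.6, 0.6, 1), 1, tolerance = 1e-8)
  expect_gt(implied_phi(0.3, 0.6, 0.9), 0)
})

test_that("simulated trials satisfy every tally decomposition identity", {
  pair <- model_pair_spec(rho = 0.6)
  for (seed in 1:3) {
    tl <- simulate_trial(pair, 3000, seed = seed)$tally
    expect_equal(tl$c_pp + tl$c_nn + tl$d_np + tl$d_pn, tl$n)
    expect_equal(tl$P + tl$N, tl$n)
    # 2x2 cells decompose per model
    expect_equal(tl$tp_0c + tl$fp_0c, tl$c_pp)
    expect_equal(tl$tp_1c + tl$fp_1c, tl$c_pp)
    expect_equal(tl$tn_0c + tl$fn_0c, tl$c_nn)
    expect_equal(tl$tn_1c + tl$fn_1c, tl$c_nn)
    expect_equal(tl$tn_0d + tl$fn_0d, tl$d_np)
    expect_equal(tl$tp_1d + tl$fp_1d, tl$d_np)
    expect_equal(tl$tp_0d + tl$fp_0d, tl$d_pn)
    expect_equal(tl$tn_1d + tl$fn_1d, tl$d_pn)
    # concordant truth counts are shared between models
    expect_equal(tl$tp_0c, tl$tp_1c)
    expect_equal(tl$tn_0c, tl$tn_1c)
  }
})

test_that("identical comonotone models never disagree", {
  pair <- model_pair_spec(sens0 = 0.95, sens1 = 0.95,
                          spec0 = 0.8, spec1 = 0.8, rho = 1)
  for (seed in 1:3) {
    expect_equal(simulate_trial(pair, 2000, seed = seed)$tally$D, 0)
  }
})

test_that("discordance rate at independence matches the closed form", {
  pair <- model_pair_spec(rho = 0)
  expected <- 0.615 * (0.988 * 0.01 + 0.012 * 0.99) +
    0.385 * (0.727 * 0.118 + 0.273 * 0.882)
  tl <- simulate_trial(pair, 1e5, seed = 10)$tally
  expect_equal(tl$D / tl$n, expected,
               tolerance = 4 * sqrt(expected / 1e5) / expected)
})

test_that("expected discordance is non-increasing in the latent correlation", {
  rate <- sapply(c(0, 0.3, 0.6, 0.9, 0.99), function(r) {
    tl <- simulate_trial(model_pair_spec(rho = r), 5e4, seed = 21)$tally
    tl$D / tl$n
  })
  expect_true(all(diff(rate) < 0))
})

test_that("the bundled example reconstruction is deterministic and matches the published counts", {
  a <- af_example_records()
  b <- af_example_records()
  expect_identical(a, b)
  expect_equal(nrow(a), 4302)
  tab <- tabulate_predictions(a)
  expect_equal(
    c(tab$table$c_pp, tab$table$c_nn, tab$table$d_np, tab$table$d_pn),
    c(2640, 1355, 35, 272)
  )
  expect_equal(tab$table$D, 307)
  expect_true(all(is.na(a$true_label[a$pred_baseline == a$pred_updated])))
})

test_that("observed metrics agree with the brute-force oracle", {
  sim <- simulate_trial(model_pair_spec(rho = 0.4), 4000, seed = 5)
  expect_equal(observed_metrics(sim$tally, model = 1),
               brute_force_metrics(sim$records, "updated"))
  expect_equal(observed_metrics(sim$tally, model = 0),
               brute_force_metrics(sim$records, "baseline"))
})
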