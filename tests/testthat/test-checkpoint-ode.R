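test_that("the spherical accessibility law matches its closed form", {
  expect_equal(accessible_fraction(0), 0)
  expect_equal(accessible_fraction(216), 108)   # 216^(1/3) = 6, denominator 2
  expect_equal(accessible_fraction(22000), 22000 / (1 + 22000^(1 / 3) / 6))
  expect_lt(abs(accessible_fraction(22000) - 3880), 5)
  # surface-shell asymptote: Cacc -> 6 C^(2/3)
  C <- 10^(9:12)
  expect_true(all(abs(accessible_fraction(C) / (6 * C^(2 / 3)) - 1) <
                    10 / C^(1 / 3)))
  expect_true(all(accessible_fraction(C) <= C))
  expect_error(accessible_fraction(-1), ">= 0")
})

test_that("rate constructors and scenario masks enforce the model setup", {
  expect_error(rate_parameters(-1, 0, 0, 0, 0), ">= 0")
  r <- default_rates()
  expect_equal(r$time_unit, "per_hour")

  combo <- apply_scenario(r, "combo")
  expect_equal(c(combo$gamma, combo$beta, combo$alpha), c(0, 0, 0))
  pd1 <- apply_scenario(r, "anti_pd1")
  expect_equal(pd1$beta, 0)
  expect_equal(pd1$gamma, r$gamma)
  ctla4 <- apply_scenario(r, "anti_ctla4")
  expect_equal(ctla4$gamma, 0)
  expect_equal(ctla4$beta, r$beta)
  untr <- apply_scenario(r, "untreated")
  expect_equal(untr$sigma, r$sigma)
})

test_that("unit conversion scales first-order rates by the step length", {
  r <- default_rates()
  s <- convert_rate_units(r, step_h = 0.25)
  expect_equal(s$gamma, 2.4e-6)
  expect_equal(s$sigma, 2.2e-7)
  expect_equal(s$time_unit, "per_step")
  back <- convert_rate_units(s, step_h = 0.25, to = "per_hour")
  for (p in c("sigma", "gamma", "beta", "xi", "alpha")) {
    expect_equal(back[[p]], r[[p]], tolerance = 1e-14)
  }
})

test_that("derivatives match hand-evaluated algebra", {
  zero <- rate_parameters(0, 0, 0, 0, 0)
  st <- immune_state(Lu = 1, Lp = 0.5, Le = 0.2, C = 216)
  expect_true(all(derivatives(st, zero) == 0))

  # expression-only dynamics
  alpha_only <- rate_parameters(0, 0, 0, 0, alpha = 0.22)
  d <- derivatives(immune_state(Lu = 1, C = 216), alpha_only)
  expect_equal(d[["Lu"]], -0.22)
  expect_equal(d[["Lp"]], 0.22)
  expect_equal(sum(abs(d[c("Le", "C", "I_ctla4", "I_pd1", "I_other")])), 0)

  # untreated at the reference rates, Lu = Lp = Le = 1, C = 216, Cacc = 108
  r <- default_rates()
  st1 <- immune_state(Lu = 1, Lp = 1, Le = 1, C = 216)
  d1 <- derivatives(st1, r, scenario = "untreated")
  g <- 9.6e-6; b <- 6.33e-5; x <- 5.5e-7; al <- 0.22; sg <- 8.8e-7
  expect_equal(d1[["Lu"]], -g * 108 - al - x * 216, tolerance = 1e-12)
  expect_equal(d1[["Lp"]], -g * 108 - al + al - x * 216, tolerance = 1e-12)
  expect_equal(d1[["Le"]], -g * 108 - b * 108 + al - x * 216,
               tolerance = 1e-12)
  expect_equal(d1[["C"]], -sg * 108 * 3, tolerance = 1e-12)
  expect_equal(d1[["I_ctla4"]], g * 108 * 3, tolerance = 1e-12)
  expect_equal(d1[["I_pd1"]], b * 108, tolerance = 1e-12)
  expect_equal(d1[["I_other"]], x * 216 * 3, tolerance = 1e-12)
  expect_equal(d1[["D_tumor"]], -d1[["C"]])
  # the alpha flux cancels in the total activity balance
  expect_equal(d1[["Lu"]] + d1[["Lp"]] + d1[["Le"]],
               -(d1[["I_ctla4"]] + d1[["I_pd1"]] + d1[["I_other"]]),
               tolerance = 1e-12)
})

test_that("integration requires per-hour rates and reproduces closed forms", {
  per_step <- convert_rate_units(default_rates(), 0.25)
  expect_error(integrate_checkpoint(per_step, "combo", immune_state(1),
                                    t_end = 1), "convert")

  zero <- rate_parameters(0, 0, 0, 0, 0)
  st <- immune_state(Lu = 1, Lp = 0.3, Le = 0.1, C = 500)
  tr <- integrate_checkpoint(zero, "untreated", st, t_end = 10, dt = 1)
  expect_true(all(abs(tr$L_total - 1.4) < 1e-12))
  expect_true(all(tr$C == 500))

  # xi-only with sigma = 0: L(t) = L0 exp(-xi C t)
  xi_only <- rate_parameters(0, 0, 0, xi = 1e-4, alpha = 0)
  tr2 <- integrate_checkpoint(xi_only, "untreated", immune_state(2, C = 1000),
                              t_end = 50, dt = 0.5)
  ref <- 2 * exp(-1e-4 * 1000 * tr2$t_h)
  expect_lt(max(abs(tr2$L_total - ref) / ref), 1e-6)

  # alpha-only: Le(t) = L0 (1 - e^(-alpha t)(1 + alpha t)), the Erlang-2 lag
  al <- rate_parameters(0, 0, 0, 0, alpha = 0.22)
  tr3 <- integrate_checkpoint(al, "untreated", immune_state(1, C = 216),
                              t_end = 40, dt = 0.5)
  ref3 <- 1 - exp(-0.22 * tr3$t_h) * (1 + 0.22 * tr3$t_h)
  expect_lt(max(abs(tr3$Le - ref3)), 1e-6)
})

test_that("activity and tumor accounting are conserved along solutions", {
  set.seed(11)
  for (i in 1:6) {
    r <- rate_parameters(10^stats::runif(1, -8, -5), 10^stats::runif(1, -7, -4),
                         10^stats::runif(1, -6, -3), 10^stats::runif(1, -8, -5),
                         10^stats::runif(1, -2, 0.5))
    sc <- sample(c("combo", "anti_pd1", "anti_ctla4", "untreated"), 1)
    st <- immune_state(Lu = stats::runif(1, 0.5, 3), Lp = stats::runif(1),
                       Le = stats::runif(1), C = 10^stats::runif(1, 2, 4.5))
    tr <- integrate_checkpoint(r, sc, st, t_end = 130, dt = 10)
    L0 <- st[["Lu"]] + st[["Lp"]] + st[["Le"]]
    expect_lt(max(abs(tr$L_total + tr$I_ctla4 + tr$I_pd1 + tr$I_other - L0)) /
                L0, 1e-6)
    expect_lt(max(abs(tr$C + tr$D_tumor - st[["C"]])) / st[["C"]], 1e-6)
    expect_true(all(diff(tr$L_total) <= 1e-9))
    expect_true(all(diff(tr$C) <= 1e-9))
  }
})

test_that("a fast expression rate collapses the delay between scenarios", {
  # with alpha large, anti-CTLA-4 decay (via beta) approaches the anti-PD-1
  # decay with gamma playing beta's role
  b <- 2e-5
  st <- immune_state(Lu = 1, C = 5000)
  fast <- rate_parameters(0, gamma = 0, beta = b, xi = 1e-7, alpha = 50)
  tr_ctla4 <- integrate_checkpoint(fast, "anti_ctla4", st, t_end = 100, dt = 2)
  asg <- rate_parameters(0, gamma = b, beta = 0, xi = 1e-7, alpha = 0)
  tr_pd1 <- integrate_checkpoint(asg, "anti_pd1", st, t_end = 100, dt = 2)
  late <- tr_ctla4$t_h >= 10
  expect_lt(max(abs(tr_ctla4$L_total[late] - tr_pd1$L_total[late]) /
                  tr_pd1$L_total[late]), 0.02)
})

test_that("halving the output step does not change the solution", {
  r <- default_rates()
  st <- immune_state(Lu = 3.8e4, C = 22000)
  tr1 <- integrate_checkpoint(r, "combo", st, t_end = 130, dt = 0.25)
  tr2 <- integrate_checkpoint(r, "combo", st, t_end = 130, dt = 0.125)
  common <- match(tr1$t_h, tr2$t_h)
  expect_lt(max(abs(tr1$C - tr2$C[common]) / tr1$C), 1e-4)
  expect_lt(max(abs(tr1$L_total - tr2$L_total[common]) /
                  pmax(tr1$L_total, 1e-9)), 1e-4)
})

test_that("the cumulative inactivation ratio handles blocked channels", {
  st <- immune_state(Lu = 1, C = 5000)
  r <- default_rates()
  tr_combo <- integrate_checkpoint(r, "combo", st, t_end = 50, dt = 5)
  ci <- cumulative_inactivation_ratio(tr_combo)
  expect_true(ci$infinite || ci$I_ctla4 == 0)

  tr_pd1 <- integrate_checkpoint(r, "anti_pd1", st, t_end = 50, dt = 5)
  ci2 <- cumulative_inactivation_ratio(tr_pd1)
  expect_true(ci2$infinite)   # beta blocked: nothing in the PD-1 tally

  tr_ctla4 <- integrate_checkpoint(r, "anti_ctla4", st, t_end = 50, dt = 5)
  ci3 <- cumulative_inactivation_ratio(tr_ctla4)
  expect_false(ci3$infinite)
  expect_equal(ci3$ratio, 0)  # gamma blocked: CTLA-4 tally empty

  expect_s3_class(autoplot(tr_ctla4), "patchwork")
})
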