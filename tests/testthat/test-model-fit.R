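test_that("observations validate their inputs", {
  expect_error(ode_observation(tibble::tibble(t_h = numeric(0),
                                              activity = numeric(0)),
                               c0 = 100, c_final = 50, condition = "combo"),
               "empty")
  expect_error(ode_observation(tibble::tibble(t_h = 1, activity = 1),
                               c0 = 0, c_final = 50, condition = "combo"))
})

test_that("the loss is zero at the generating truth and quadratic in residuals", {
  obs <- generate_observation_triple(noise = 0, count_noise = 0, seed = 1)$combo
  truth <- default_rates()
  # zero up to the integrator-tolerance mismatch between the
  # generating and fitting solvers (activity is of order 1e4)
  expect_lt(checkpoint_loss(truth, obs), 1e-3)

  # synthetic residual pattern: doubling it quadruples the activity term
  sim_act <- obs$activity$activity
  eps <- 0.02 * sin(seq_along(sim_act))
  mk <- function(k) {
    a <- obs$activity
    a$activity <- sim_act * (1 + k * eps)
    a$se <- NA_real_   # unit weights
    ode_observation(a, c0 = obs$c0, c_final = obs$c_final,
                    condition = "combo")
  }
  l1 <- checkpoint_loss(truth, mk(1))
  l2 <- checkpoint_loss(truth, mk(2))
  expect_equal(unname(l2 / l1), 4, tolerance = 0.01)
})

test_that("the generating rates are a local minimum of the loss", {
  obs <- generate_observation_triple(noise = 0, count_noise = 0, seed = 2)$anti_pd1
  truth <- default_rates()
  l0 <- checkpoint_loss(truth, obs)
  set.seed(14)
  for (i in 1:50) {
    f <- exp(stats::runif(5, log(0.5), log(1.5)))
    pert <- rate_parameters(truth$sigma * f[1], truth$gamma * f[2],
                            truth$beta * f[3], truth$xi * f[4],
                            truth$alpha * f[5])
    expect_gt(checkpoint_loss(pert, obs), l0)
  }
})

test_that("stage preconditions and ordering are enforced", {
  obs <- generate_observation_triple(noise = 0, count_noise = 0, seed = 1)
  expect_error(fit_stage_combo(obs$anti_pd1), "combo")
  expect_error(fit_stage_pd1_blockade(obs$combo, xi = 1e-7, sigma = 1e-7),
               "anti_pd1")
  expect_error(fit_stage_ctla4_blockade(obs$combo, xi = 1e-7, sigma = 1e-7),
               "anti_ctla4")
  expect_error(staged_fit(obs$anti_pd1, obs$anti_pd1, obs$anti_ctla4),
               "combo")
})

test_that("single stages recover their generating rates from clean data", {
  obs <- generate_observation_triple(noise = 0, count_noise = 0, seed = 1)
  s2 <- fit_stage_pd1_blockade(obs$anti_pd1, xi = 5.5e-7, sigma = 8.8e-7,
                               n_starts = 2, seed = 1)
  expect_lt(abs(s2$estimates[["gamma"]] - 9.6e-6) / 9.6e-6, 0.05)
  expect_true(s2$convergence)
  # validation report: simulated final count close to the observed one
  expect_lt(abs(s2$c_final_sim - obs$anti_pd1$c_final) /
              obs$anti_pd1$c_final, 0.02)

  s3 <- fit_stage_ctla4_blockade(obs$anti_ctla4, xi = 5.5e-7, sigma = 8.8e-7,
                                 n_starts = 2, seed = 1)
  expect_lt(abs(s3$estimates[["alpha"]] - 0.22) / 0.22, 0.10)
  expect_lt(abs(s3$estimates[["beta"]] - 6.33e-5) / 6.33e-5, 0.10)
})

test_that("a zero generating rate is flagged at the lower bound", {
  no_gamma <- rate_parameters(8.8e-7, gamma = 0, beta = 6.33e-5, xi = 5.5e-7,
                              alpha = 0.22)
  obs <- generate_ode_observations(no_gamma, "anti_pd1",
                                   immune_state(Lu = 2.9e4, C = 22000),
                                   noise = 0, seed = 1)
  fit <- fit_stage_pd1_blockade(obs, xi = 5.5e-7, sigma = 8.8e-7,
                                n_starts = 2, seed = 1)
  expect_true(fit$at_lower_bound[["gamma"]])
})

test_that("truncating to the pre-decline plateau flattens the alpha profile", {
  obs_full <- generate_observation_triple(noise = 0.05, count_noise = 0,
                                          seed = 3)$anti_ctla4
  act <- obs_full$activity
  obs_tr <- ode_observation(act[act$t_h <= 8, ], c0 = obs_full$c0,
                            c_final = obs_full$c_final,
                            condition = "anti_ctla4")
  f_full <- fit_stage_ctla4_blockade(obs_full, xi = 5.5e-7, sigma = 8.8e-7,
                                     n_starts = 2, seed = 1)
  f_tr <- fit_stage_ctla4_blockade(obs_tr, xi = 5.5e-7, sigma = 8.8e-7,
                                   n_starts = 2, seed = 1)
  pf_full <- loss_profile(f_full, "alpha", factors = c(0.5, 2))
  pf_tr <- loss_profile(f_tr, "alpha", factors = c(0.5, 2))
  expect_lt(max(pf_tr$rel_increase), max(pf_full$rel_increase) / 3)
})

test_that("the staged protocol chains stages and reports both unit systems", {
  obs <- generate_observation_triple(noise = 0, count_noise = 0, seed = 1)
  fit <- staged_fit(obs$combo, obs$anti_pd1, obs$anti_ctla4, n_starts = 2,
                    seed = 1)
  expect_named(fit$stages, c("combo", "anti_pd1", "anti_ctla4"))
  # provenance chaining: downstream stages carry stage-1 rates as fixed
  expect_equal(fit$stages$anti_pd1$fixed[["xi"]],
               fit$stages$combo$estimates[["xi"]])
  expect_equal(fit$stages$anti_ctla4$fixed[["sigma"]],
               fit$stages$combo$estimates[["sigma"]])
  rep <- tidy(fit)
  expect_setequal(rep$parameter, c("sigma", "gamma", "beta", "xi", "alpha"))
  expect_equal(rep$per_step, rep$per_hour * 0.25, tolerance = 1e-12)
  gl <- glance(fit)
  expect_true(gl$converged)
  td2 <- tidy(fit$stages$combo)
  expect_true(all(c("term", "estimate", "stage") %in% names(td2)))
})
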