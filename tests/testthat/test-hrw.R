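test_that("the AR(1) step likelihood matches hand-computed densities", {
  # zero residual: density is the bivariate normal maximum 1/(2 pi a^2)
  for (a in c(0.5, 1, 2)) {
    expect_equal(step_likelihood(c(0.3, -0.2) * 0.7, c(0.3, -0.2), q = 0.7,
                                 a = a),
                 1 / (2 * pi * a^2), tolerance = 1e-12)
  }
  # u_prev = 0 removes the persistence term entirely
  dens <- step_likelihood(c(1, 1), c(0, 0), q = seq(-1, 1, by = 0.25), a = 1)
  expect_true(all(abs(dens - dens[1]) < 1e-15))
  # hand evaluation: u_t = (1,0), u_prev = (1,0), q = 0.5, a = 1
  expect_equal(step_likelihood(c(1, 0), c(1, 0), 0.5, 1, log = TRUE),
               -log(2 * pi) - 0.125, tolerance = 1e-12)
  expect_error(step_likelihood(c(1, 0), c(1, 0), 0.5, 0), "a must be > 0")
})

test_that("the parameter grid spans the documented domains", {
  g <- parameter_grid(n_q = 21, n_a = 31, a_max = 5)
  expect_equal(range(g$q), c(-1, 1))
  expect_true(all(g$a > 0))
  expect_true(all(diff(g$a) > 0))
  expect_equal(max(g$a), 5)
  glin <- parameter_grid(a_max = 4, log_a = FALSE)
  expect_equal(diff(range(diff(glin$a))), 0, tolerance = 1e-12)
})

test_that("every per-step posterior is a normalised distribution", {
  pr <- ar_profile(q = 0.3, a = 1.5, n_steps = 40)
  d <- to_displacements(simulate_ar1(pr, seed = 3))
  for (sm in c(FALSE, TRUE)) {
    res <- sequential_infer(d, forget_sd = 1, smooth = sm,
                            return_posterior = TRUE)
    sums <- apply(res$posterior, 1, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(res$posterior >= 0))
    # posterior means lie inside the credible intervals
    expect_true(all(res$track$q_mean >= res$track$q_lo - 1e-12 &
                    res$track$q_mean <= res$track$q_hi + 1e-12))
    expect_true(all(res$track$a_mean > 0))
  }
})

test_that("with forgetting disabled the filter equals direct enumeration", {
  # oracle: running normalised products of step likelihoods over the grid,
  # computed with explicit loops over grid cells
  set.seed(9)
  u <- matrix(rnorm(10), 5, 2)
  g <- parameter_grid(n_q = 5, n_a = 5, a_max = 3)
  res <- sequential_infer(tibble::tibble(ux = u[, 1], uy = u[, 2]),
                          grid = g, forget_sd = 0, return_posterior = TRUE)
  logp <- matrix(0, 5, 5)
  u_prev <- c(0, 0)
  for (t in 1:5) {
    for (i in 1:5) {
      for (j in 1:5) {
        logp[i, j] <- logp[i, j] +
          step_likelihood(u[t, ], u_prev, g$q[i], g$a[j], log = TRUE)
      }
    }
    oracle <- exp(logp - max(logp))
    oracle <- oracle / sum(oracle)
    expect_equal(res$posterior[t, , ], oracle, tolerance = 1e-9)
    u_prev <- u[t, ]
  }
})

test_that("a single step with zero previous displacement leaves q flat", {
  res <- sequential_infer(tibble::tibble(ux = 0.8, uy = -0.3),
                          grid = parameter_grid(n_q = 11, n_a = 11, a_max = 3),
                          u0 = c(0, 0), return_posterior = TRUE)
  q_marg <- rowSums(res$posterior[1, , ])
  expect_true(all(abs(q_marg - q_marg[1]) < 1e-12))
})

test_that("an all-zero series drives activity to the smallest grid value", {
  g <- parameter_grid(n_q = 11, n_a = 21, a_max = 2)
  tr <- sequential_infer(tibble::tibble(ux = rep(0, 15), uy = rep(0, 15)),
                         grid = g, forget_sd = 0.5)
  expect_lt(tr$a_mean[15], g$a[3])
})

test_that("without forgetting the posterior concentrates over time", {
  widths <- replicate(5, {
    pr <- ar_profile(q = 0.4, a = 1, n_steps = 150)
    d <- to_displacements(simulate_ar1(pr, seed = sample.int(1e6, 1)))
    tr <- sequential_infer(d, forget_sd = 0)
    c(early = mean(tr$a_hi[10:20] - tr$a_lo[10:20]),
      late = mean(tr$a_hi[140:150] - tr$a_lo[140:150]))
  })
  set.seed(100)
  expect_lt(mean(widths["late", ]), mean(widths["early", ]))
})

test_that("constant-parameter walks are recovered by the filter", {
  pr <- ar_profile(q = 0.5, a = 2, n_steps = 500)
  hits <- sapply(1:8, function(s) {
    d <- to_displacements(simulate_ar1(pr, seed = 100 + s))
    tr <- sequential_infer(d)
    abs(mean(tr$q_mean) - 0.5) <= 0.1 && abs(mean(tr$a_mean) - 2) <= 0.1
  })
  expect_gte(mean(hits), 0.85)
})

test_that("population activity averages cells with standard errors", {
  t1 <- tibble::tibble(cell_id = "a", step = 1:5, q_mean = 0.2, q_lo = 0,
                       q_hi = 0.4, a_mean = 1, a_lo = 0.5, a_hi = 1.5,
                       a_gmean = 1)
  t2 <- dplyr::mutate(t1, cell_id = "b", a_mean = 3)
  pop <- population_activity(dplyr::bind_rows(t1, t2))
  expect_equal(unique(pop$cell_id), "population")
  expect_equal(pop$a_mean, rep(2, 5))
  expect_equal(pop$a_se, rep(1, 5))
  expect_equal(pop$n_cells, rep(2L, 5))

  # identical tracks: population equals the track, zero standard error
  pop1 <- population_activity(dplyr::bind_rows(t1, dplyr::mutate(t1, cell_id = "c")))
  expect_equal(pop1$a_mean, t1$a_mean)
  expect_equal(pop1$a_se, rep(0, 5))

  # cells of different lengths: steps with no cells are omitted
  t3 <- dplyr::mutate(t1[1:3, ], cell_id = "d")
  pop2 <- population_activity(dplyr::bind_rows(t1, t3))
  expect_equal(pop2$n_cells, c(2L, 2L, 2L, 1L, 1L))
})

test_that("parameter tracks plot", {
  pr <- ar_profile(q = 0, a = 1, n_steps = 30)
  tr <- sequential_infer(to_displacements(simulate_ar1(pr, seed = 1)))
  expect_s3_class(autoplot(tr), "ggplot")
})
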