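test_that("system size estimate counts distinct ids ever seen", {
  expect_equal(estimate_system_size(tiny_table()),
               list(n = 4L, n0 = 3L, p = 3 / 4))
  sz <- estimate_system_size(static_table())
  expect_equal(sz$n, 3L)
  expect_equal(sz$p, 1)
  # on simulator output N grows with the window when nu > 0
  n_at <- sapply(c(10, 40), function(T) {
    estimate_system_size(simulate_rank_model(
      model_params(60, 40, 0.1, 0.3, T, seed = 2)))$n
  })
  expect_gt(n_at[2L], n_at[1L])
})

test_that("forward-inverse round trip recovers (tau, nu) on a grid", {
  grid <- expand.grid(tau = c(0.01, 0.1, 0.5, 1),
                      nu = c(0.01, 0.2, 1),
                      p = c(0.1, 0.5, 0.8, 0.99))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    fit <- fit_parameters(mean_flux_theory(g$tau, g$nu, g$p),
                          mean_turnover_theory(g$tau, g$nu, g$p), g$p)
    expect_true(fit$converged)
    expect_lt(fit$residual, 1e-8)
    expect_equal(fit$tau_hat, g$tau, tolerance = 1e-6)
    expect_equal(fit$nu_hat, g$nu, tolerance = 1e-6)
  }
})

test_that("fit edge cases follow the documented conventions", {
  f0 <- fit_parameters(0, 0, 0.5)
  expect_equal(c(f0$tau_hat, f0$nu_hat), c(0, 0))
  expect_true(f0$converged)

  finf <- fit_parameters(0, 0.1, 0.5)   # F = 0 cannot show turnover
  expect_false(finf$converged)
  expect_match(finf$note, "infeasible")

  fp1 <- fit_parameters(0.2, -log(1 - 0.2), 1)  # p = 1: only replacement
  expect_equal(fp1$tau_hat, 0)
  expect_equal(fp1$nu_hat, -log(0.8))
  expect_match(fp1$note, "unidentifiable")

  # infeasible pair far off the model image -> least squares, flagged
  fls <- fit_parameters(0.9, 1e-4, 0.99)
  expect_false(fls$converged)
  expect_true(fls$tau_hat >= 0 && fls$nu_hat >= 0)
})

test_that("parameter recovery is nearly unbiased at small rates", {
  # at small per-observation rates the closed forms are asymptotically
  # exact; the documented tau bias grows with nu (see the vignette)
  tau <- 0.05; nu <- 0.02; n <- 500; n0 <- 400
  fits <- sapply(1:8, function(seed) {
    tab <- simulate_rank_model(model_params(n, n0, tau, nu, 400,
                                            seed = seed))
    ft <- flux_turnover(tab)
    fit <- fit_parameters(ft$mean_flux, ft$mean_turnover_rate, n0 / n)
    c(fit$tau_hat, fit$nu_hat)
  })
  nu_mean <- mean(fits[2L, ]); nu_se <- sd(fits[2L, ]) / sqrt(8)
  expect_lt(abs(nu_mean - nu), max(3 * nu_se, 0.05 * nu))
  # tau carries a systematic positive bias (flux from diffusive crossings
  # of the list boundary that the closed form neglects); documented
  # envelope, see the methods vignette
  expect_gt(mean(fits[1L, ]), tau)
  expect_lt(mean(fits[1L, ]), 1.5 * tau)
})

test_that("rescaling reproduces the universal curve identically on-model", {
  # the example point tau=0.05, nu=0.1, p=0.25 sits exactly on the curve
  od <- mean_turnover_theory(0.05, 0.1, 0.25)
  expect_equal(od, 2 / 15)
  rs <- rescale_parameters(0.05, 0.1, 0.25, od)
  expect_equal(rs$tau_r, 2)
  expect_equal(rs$nu_r, 0.5)
  expect_equal(rs$product, 1, tolerance = 1e-12)
  expect_equal(rs$curve_distance, 0, tolerance = 1e-10)

  expect_equal(rescale_parameters(0.3, 0.05, 0.5, 0.1)$nu_r, 0)
  expect_error(rescale_parameters(0.1, 0.1, 1, 0.1), "strictly inside")
  expect_error(rescale_parameters(0.1, 0.1, 0.5, 0), "positive")
})

test_that("brute-force scan confirms the on-curve locus at p = 0.25", {
  # independent check (dense grid, no fitting): with nu = 0.1, p = 0.25,
  # tau_r * nu_r - 1 changes sign at tau = 0.05 and nowhere else nearby
  taus <- seq(0.001, 0.2, by = 1e-4)
  prod <- sapply(taus, function(tau) {
    od <- mean_turnover_theory(tau, 0.1, 0.25)
    rescale_parameters(tau, 0.1, 0.25, od)$product
  })
  sign_flip <- which(diff(sign(prod - 1)) != 0)
  expect_length(sign_flip, 1L)
  expect_equal(taus[sign_flip], 0.05, tolerance = 1e-3)
})

test_that("regime classification agrees with the weight argmax", {
  expect_equal(regime_classify(0.1, 0.2)$label, "diffusion")
  expect_equal(regime_classify(3, 0.05)$label, "levy")
  expect_equal(regime_classify(0.1, 3)$label, "replacement")
  set.seed(7)
  for (i in 1:200) {
    tau <- runif(1, 0, 4); nu <- runif(1, 0, 4)
    w <- regime_weights(tau, nu)
    lab <- c("levy", "diffusion", "replacement")[
      which.max(c(w$w_levy, w$w_diff, w$w_repl))]
    expect_equal(regime_classify(tau, nu)$label, lab)
  }
})

test_that("regime scan stays on the curve and crosses regimes", {
  sc <- regime_scan(0.3, 0.05, n_points = 60, tau_r_range = c(1e-2, 1e3))
  expect_true(all(abs(sc$tau_r * sc$nu_r - 1) < 1e-6))
  expect_equal(sc$w_levy + sc$w_diff + sc$w_repl, rep(1, nrow(sc)))
  expect_true(all(diff(sc$tau) > 0))
  # along the scan tau increases and nu decreases, so W_levy is monotone
  expect_true(all(diff(sc$w_levy) >= -1e-12))
  # both extremes present -> a levy crossover exists along the curve
  expect_equal(sc$regime[1L], "replacement")
  expect_equal(sc$regime[nrow(sc)], "levy")
  expect_true("diffusion" %in% sc$regime)
})

test_that("subsampling analysis row k = 1 reproduces the plain fit", {
  tab <- simulate_rank_model(model_params(120, 90, 0.1, 0.05, 120,
                                          seed = 6))
  rep <- subsampling_analysis(tab, c(1, 2, 4))
  fit <- fit_rank_table(tab)
  expect_equal(rep$tau_hat[1L], fit$tau_hat)
  expect_equal(rep$nu_hat[1L], fit$nu_hat)
  expect_equal(rep$replacement_rate[1L], fit$nu_hat)
  expect_equal(rep$t_eff, c(120L, 60L, 30L))
})

test_that("replacement rate is stable and tau_r shrinks under subsampling", {
  # finely sampled open system (small per-interval rates; see vignette)
  rates <- sapply(1:3, function(seed) {
    tab <- simulate_rank_model(model_params(500, 400, 0.05, 0.02, 600,
                                            seed = seed))
    rep <- subsampling_analysis(tab, c(1, 2, 4, 8))
    expect_true(all(diff(rep$tau_r) < 0))  # moves down the curve
    (max(rep$replacement_rate) - min(rep$replacement_rate)) /
      mean(rep$replacement_rate)
  })
  expect_lt(mean(rates), 0.2)
})

test_that("bootstrap curve test is calibrated on model-generated data", {
  fit1 <- fit_rank_table(simulate_rank_model(
    model_params(150, 100, 0.1, 0.05, 150, seed = 40)))
  expect_error(bootstrap_curve_test(fit1, 150, n_boot = 0), "at least 1")
  flags <- sapply(1:4, function(s) {
    tab <- simulate_rank_model(model_params(150, 100, 0.1, 0.05, 150,
                                            seed = 40 + s))
    res <- bootstrap_curve_test(fit_rank_table(tab), 150, n_boot = 30,
                                seed = s)
    expect_false(res$unreliable)
    res$exceed_flag
  })
  expect_lte(sum(flags), 1L)  # on-model data rarely flagged at alpha=.05
})

test_that("curve distance is blind to shocks that keep time averages", {
  # F is a time average and o_dot an endpoint slope, so a mid-series rate
  # switch lands on the image of some stationary model and cannot be
  # separated by the curve test (see the vignette); the shocked series
  # must therefore still pass as on-curve.
  shock <- simulate_rank_schedule(150, 100,
                                  tau = c(rep(0.02, 75L), rep(0.9, 74L)),
                                  nu = rep(0.05, 149L), seed = 41)
  fit_s <- fit_rank_table(shock)
  expect_true(fit_s$converged)
  res <- bootstrap_curve_test(fit_s, n_obs(shock), n_boot = 30, seed = 12)
  expect_false(res$exceed_flag)
})
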