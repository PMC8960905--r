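test_that("levy term and survival evaluate to their closed forms", {
  expect_equal(levy_term(0.5, 0, 100), 0)
  expect_equal(levy_term(50, 1, 100), 1 / 100, tolerance = 1e-12)
  expect_equal(levy_term(0.1, 1, 100), (1 - exp(-0.1)) / 100)
  expect_equal(levy_term(0.1, 1, 100), 9.516258e-4, tolerance = 1e-6)
  expect_error(levy_term(-0.1, 1, 100), "non-negative")

  expect_equal(survival_probability(0.3, 0), 1)
  expect_equal(survival_probability(0, 7), 1)
  expect_equal(survival_probability(0.2, 5), exp(-1))
})

test_that("Gaussian kernel: normalization, symmetry, spread, degeneracy", {
  d <- diffusion_kernel_gaussian(0.1, 100, 0.5, 5)
  expect_equal(sum(d), exp(-0.5), tolerance = 1e-12)
  # symmetric about x = 0.5: cell 50 + k pairs with cell 50 - k
  expect_equal(d[1:99], rev(d[1:99]), tolerance = 1e-12)
  # sd = sqrt(2 * 0.001 * 0.25 * 5) = 0.05; check via the kernel moments
  x <- seq_len(100) / 100
  m <- sum(x * d) / sum(d)
  s <- sqrt(sum((x - m)^2 * d) / sum(d))
  expect_equal(m, 0.5, tolerance = 1e-6)
  expect_equal(s, 0.05, tolerance = 0.01)
  # degenerate cases collapse to the source cell
  expect_equal(which.max(diffusion_kernel_gaussian(0.1, 100, 1, 5)), 100L)
  expect_equal(sum(diffusion_kernel_gaussian(0, 100, 0.3, 7)), 1)
  d0 <- diffusion_kernel_gaussian(0.2, 50, 0.3, 0)
  expect_equal(d0[15L], 1)
})

test_that("PDE kernel conserves mass and matches the Gaussian at small at", {
  for (case in list(c(0.1, 100, 0.5, 5), c(0.05, 200, 0.3, 3),
                    c(0.2, 100, 0.7, 1))) {
    tau <- case[1]; n <- case[2]; r <- case[3]; t <- case[4]
    pde <- diffusion_kernel_pde(tau, n, r, t)
    expect_equal(sum(pde), exp(-tau * t), tolerance = 1e-8)
    expect_true(all(pde >= 0))
    gau <- diffusion_kernel_gaussian(tau, n, r, t)
    expect_lt(max(abs(pde - gau)), 0.05 * max(gau))
  }
  # alpha = 0: the delta survives any t
  expect_equal(which.max(diffusion_kernel_pde(0, 50, 0.5, 4)), 25L)
  # fine grid with mass-conserving down-binning
  fine <- diffusion_kernel_pde(0.1, 100, 0.5, 5, grid_size = 400)
  expect_equal(length(fine), 100L)
  expect_equal(sum(fine), exp(-0.5), tolerance = 1e-8)
  expect_error(diffusion_kernel_pde(0.1, 100, 0.5, 5, grid_size = 150),
               "multiple")
})

test_that("displacement kernel obeys the normalization chain", {
  grid_cases <- expand.grid(tau = c(0.05, 0.3), nu = c(0, 0.4),
                            n = c(50, 150), r = c(0.25, 0.9),
                            t = c(1, 6))
  for (i in seq_len(nrow(grid_cases))) {
    g <- grid_cases[i, ]
    for (backend in c("gaussian", "pde")) {
      k <- displacement_probability(g$tau, g$nu, g$n, g$r, g$t,
                                    backend = backend)
      expect_equal(sum(k$levy_mass + k$diffusion_mass), 1,
                   tolerance = 1e-6)
      expect_equal(sum(k$diffusion_mass), exp(-g$tau * g$t),
                   tolerance = 1e-6)
      expect_equal(sum(k$total), exp(-g$nu * g$t), tolerance = 1e-6)
      expect_true(all(k$total >= 0))
    }
  }
})

test_that("displacement kernel limits", {
  # tau = 0: a pure decaying delta at r
  k <- displacement_probability(0, 0.3, 80, 0.5, 2)
  expect_equal(k$total[40L], exp(-0.6))
  expect_equal(sum(k$total) - k$total[40L], 0)
  # nu very large: everything is replaced
  k2 <- displacement_probability(0.1, 50, 100, 0.5, 1)
  expect_lt(sum(k2$total), 1e-20)
})

test_that("mean flux and turnover closed forms and limits", {
  expect_equal(mean_flux_theory(0, 0, 0.5), 0)
  expect_equal(mean_flux_theory(80, 0, 0.3), 1 - 0.3, tolerance = 1e-12)
  expect_equal(mean_flux_theory(0.1, 0.2, 0.8), 0.1968518,
               tolerance = 1e-6)
  expect_equal(mean_turnover_theory(0.1, 0, 0.8), 0)
  expect_equal(mean_turnover_theory(0.3, 0.2, 1), 0.2)
  expect_equal(mean_turnover_theory(0.1, 0.2, 0.8), 0.06 / 0.28)
  expect_error(mean_flux_theory(0.1, 0.2, 0), "\\(0, 1\\]")
  expect_error(mean_turnover_theory(-1, 0.2, 0.5), "non-negative")
})

test_that("flux and turnover are monotone in nu at fixed tau, p", {
  nus <- seq(0, 2, length.out = 40)
  for (tau in c(0, 0.1, 1)) {
    for (p in c(0.2, 0.8)) {
      expect_true(all(diff(mean_flux_theory(tau, nus, p)) >= 0))
      expect_true(all(diff(mean_turnover_theory(tau, nus, p)) >= 0))
    }
  }
})

test_that("regime weights: closed forms, normalization, limits", {
  w <- regime_weights(0.1, 0.2)
  expect_equal(w$w_levy, 0.07791, tolerance = 1e-4)
  expect_equal(w$w_diff, 0.74082, tolerance = 1e-4)
  expect_equal(w$w_repl, 0.18127, tolerance = 1e-4)
  expect_equal(w$w_levy + w$w_diff + w$w_repl, 1)
  expect_equal(regime_weights(0, 0)$w_diff, 1)
  expect_gt(regime_weights(0.1, 50)$w_repl, 1 - 1e-12)
  set.seed(1)
  tn <- matrix(runif(2000, 0, 5), ncol = 2)
  ww <- regime_weights(tn[, 1L], tn[, 2L])
  expect_equal(ww$w_levy + ww$w_diff + ww$w_repl, rep(1, 1000))
})

test_that("theory matches Monte-Carlo displacement at moderate precision", {
  # tau = 0.1, nu = 0.2, N = 100, r = 0.5: the configuration of the model
  # validation figure, at reduced realization count for the unit suite.
  pp <- model_params(100, 80, 0.1, 0.2, 6, seed = 31)
  nreal <- 2e4
  tr <- track_displacements(pp, 0.5, c(1, 5), n_realizations = nreal)
  for (lg in c(1, 5)) {
    h <- tr$histograms[[paste0("lag", lg)]]
    k <- displacement_probability(0.1, 0.2, 100, 0.5, lg, backend = "pde")
    se <- sqrt(pmax(k$total * (1 - k$total), 1e-12) / nreal)
    expect_true(all(abs(h$mass - k$total) < 3.5 * se + 1e-9))
  }
})
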