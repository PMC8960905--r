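# Closed-form theory of the displacement-replacement model.
#
# An element at normalized rank r = R/N that has not been replaced by lag t
# (probability exp(-nu*t)) either has jumped at least once -- in which case
# its position is uniform, the Levy term L_t = (1 - exp(-tau*t))/N -- or
# has never jumped (probability exp(-tau*t)) and has diffused around r
# under the Wright-Fisher-type degenerate diffusion
# dD/dt = alpha x (1-x) d^2 D/dx^2 with alpha = tau/N.  The displacement
# probability is P(x, t) = exp(-nu*t) * (L_t + D(x, t)).

.check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(vals[[nm]] < 0)) stop(sprintf("`%s` must be non-negative", nm))
  invisible(TRUE)
}

#' Levy term of the displacement kernel
#'
#' Rank-independent probability `(1 - exp(-tau * t)) / n` that an element
#' has jumped to any given rank by lag `t`.
#'
#' @param tau displacement rate, >= 0.
#' @param t lag (observation steps), >= 0.
#' @param n system size.
#' @return Probability per rank cell.
#' @export
levy_term <- function(tau, t, n) {
  .check_nonneg(tau = tau, t = t)
  stopifnot(n >= 1)
  (1 - exp(-tau * t)) / n
}

#' Replacement survival probability
#'
#' Probability `exp(-nu * t)` that an element has not yet been replaced
#' after lag `t`.
#'
#' @param nu replacement rate, >= 0.
#' @param t lag, >= 0.
#' @return Probability.
#' @export
survival_probability <- function(nu, t) {
  .check_nonneg(nu = nu, t = t)
  exp(-nu * t)
}

.delta_mass <- function(n, r, total) {
  mass <- numeric(n)
  mass[max(1L, min(n, as.integer(round(r * n))))] <- total
  mass
}

#' Gaussian approximation of the diffusion kernel
#'
#' The never-jumped component of the displacement kernel: a Gaussian with
#' mean `r` and standard deviation `sqrt(2 * alpha * r * (1-r) * t)`
#' (`alpha = tau/n`), integrated over the rank cells `((i-1/2)/n, (i+1/2)/n]`,
#' truncated to (0, 1] and renormalized so the cell masses sum to
#' `exp(-tau * t)`.  When `t * r * (1 - r) = 0` the kernel degenerates to
#' all surviving-diffusion mass in the cell containing `r`.
#'
#' @param tau displacement rate.
#' @param n system size (grid has `n` cells of width 1/n).
#' @param r normalized source rank in (0, 1].
#' @param t lag, >= 0.
#' @return Numeric vector of cell masses `D_{x,t}` summing to `exp(-tau*t)`.
#' @export
diffusion_kernel_gaussian <- function(tau, n, r, t) {
  .check_nonneg(tau = tau, t = t)
  stopifnot(n >= 1, r > 0, r <= 1)
  total <- exp(-tau * t)
  sd <- sqrt(2 * (tau / n) * r * (1 - r) * t)
  if (sd == 0) return(.delta_mass(n, r, total))
  edges <- (seq_len(n + 1L) - 0.5) / n  # cell i covers (edges[i], edges[i+1]]
  edges[1L] <- 0                        # truncate to (0, 1] ...
  edges[n + 1L] <- 1
  mass <- diff(pnorm(edges, mean = r, sd = sd))
  mass * (total / sum(mass))            # ... and renormalize to exp(-tau t)
}

#' Finite-difference solution of the diffusion kernel
#'
#' Solves the degenerate diffusion equation in conservative (flux) form by
#' implicit Euler steps on a uniform grid, starting from a delta at `r`,
#' then scales the conserved shape by `exp(-tau * t)`.  The diffusivity
#' `alpha x (1 - x)` vanishes at the boundaries, so zero-flux ends are the
#' natural closure and total mass is conserved to solver precision before
#' the decay factor is applied.  If `grid_size > n`, the fine solution is
#' aggregated onto the model grid mass-conservingly.
#'
#' @param tau displacement rate.
#' @param n system size defining `alpha = tau/n` and the output grid.
#' @param r normalized source rank in (0, 1].
#' @param t lag, > 0 (t = 0 returns the scaled delta).
#' @param grid_size number of cells used by the solver (a multiple of `n`;
#'   default `n`).
#' @param dt_solver solver time step (default `t / 400`).
#' @return Numeric vector of `n` cell masses summing to `exp(-tau*t)`.
#' @export
diffusion_kernel_pde <- function(tau, n, r, t, grid_size = n,
                                 dt_solver = NULL) {
  .check_nonneg(tau = tau, t = t)
  stopifnot(n >= 1, r > 0, r <= 1, grid_size >= 3)
  if (grid_size %% n != 0)
    stop("`grid_size` must be a multiple of `n` for mass-conserving binning")
  total <- exp(-tau * t)
  if (t == 0 || tau == 0) return(.delta_mass(n, r, total))
  g <- as.integer(grid_size)
  dx <- 1 / g
  x <- seq_len(g) / g
  alpha <- tau / n
  cc <- alpha * x * (1 - x)
  if (is.null(dt_solver)) dt_solver <- t / 400
  n_steps <- max(1L, ceiling(t / dt_solver))
  dt <- t / n_steps
  # flux form: dD_i/dt = (c_{i+1} D_{i+1} - 2 c_i D_i + c_{i-1} D_{i-1})/dx^2
  # with the one-sided stencil at the ends (zero boundary flux); column sums
  # of A are exactly zero, so implicit Euler conserves mass exactly.
  main <- -2 * cc / dx^2
  main[1L] <- -cc[1L] / dx^2
  main[g] <- -cc[g] / dx^2
  upper <- cc[-1L] / dx^2       # A[i, i+1] = c_{i+1}/dx^2
  lower <- cc[-g] / dx^2        # A[i+1, i] = c_i/dx^2
  M <- Matrix::bandSparse(g, g, k = c(-1L, 0L, 1L),
                          diagonals = list(-dt * lower, 1 - dt * main,
                                           -dt * upper))
  lu <- Matrix::lu(M)
  d <- .delta_mass(g, r, 1)
  for (s in seq_len(n_steps)) {
    d <- as.numeric(Matrix::solve(lu, d))
  }
  if (any(!is.finite(d)))
    stop("numerical error: implicit solve produced non-finite values")
  d[d < 0] <- 0
  if (g > n) d <- as.numeric(rowsum(d, rep(seq_len(n), each = g %/% n)))
  d * (total / sum(d))
}

#' Displacement probability kernel P(x, t)
#'
#' Combines the Levy term and a diffusion kernel into the full displacement
#' probability `P(x, t) = exp(-nu*t) * (L_t + D_{x,t})` on the model grid
#' `x = (1..n)/n`.  Before the replacement factor the masses sum to 1;
#' after it they sum to `exp(-nu*t)` (the survival probability).
#'
#' @param tau,nu model rates, >= 0.
#' @param n system size.
#' @param r normalized source rank in (0, 1].
#' @param t lag, >= 0.
#' @param backend `"gaussian"` (default) or `"pde"` diffusion kernel.
#' @param ... passed to [diffusion_kernel_pde()].
#' @return An object of class `theory_kernel` with fields `grid`, `dx`,
#'   `source`, `lag`, `alpha`, `levy_mass`, `diffusion_mass`, `total`.
#' @export
displacement_probability <- function(tau, nu, n, r, t,
                                     backend = c("gaussian", "pde"), ...) {
  backend <- match.arg(backend)
  .check_nonneg(tau = tau, nu = nu, t = t)
  stopifnot(n >= 1, r > 0, r <= 1)
  levy <- rep(levy_term(tau, t, n), n)
  diff_mass <- switch(backend,
                      gaussian = diffusion_kernel_gaussian(tau, n, r, t),
                      pde = diffusion_kernel_pde(tau, n, r, t, ...))
  structure(
    list(grid = seq_len(n) / n, dx = 1 / n, source = r, lag = t,
         alpha = tau / n, backend = backend,
         levy_mass = levy, diffusion_mass = diff_mass,
         total = exp(-nu * t) * (levy + diff_mass)),
    class = "theory_kernel")
}

#' @export
print.theory_kernel <- function(x, ...) {
  cat(sprintf(paste0("theory kernel (%s): r = %.4g, t = %g, N = %d; ",
                     "sum P = %.6g (= exp(-nu t))\n"),
              x$backend, x$source, x$lag, length(x$grid), sum(x$total)))
  invisible(x)
}

#' Mean flux of the model
#'
#' `F = 1 - exp(-nu) * (p + (1 - p) * exp(-tau))`: the probability that an
#' element enters or leaves the top-`N0` list in one observation step, for
#' relative list size `p = N0/N`.
#'
#' @param tau,nu model rates, >= 0 (vectorized).
#' @param p relative list size in (0, 1].
#' @return Mean flux in \[0, 1).
#' @export
mean_flux_theory <- function(tau, nu, p) {
  .check_nonneg(tau = tau, nu = nu)
  if (any(p <= 0 | p > 1)) stop("`p` must be in (0, 1]")
  1 - exp(-nu) * (p + (1 - p) * exp(-tau))
}

#' Mean turnover rate of the model
#'
#' `o_dot = nu * (nu + tau) / (nu + p * tau)`: the per-observation growth
#' rate of the number of distinct elements ever seen in the list, relative
#' to `N0`.  `nu = 0` gives 0 by continuity.
#'
#' @param tau,nu model rates, >= 0 (vectorized).
#' @param p relative list size in (0, 1].
#' @return Mean turnover rate, >= 0.
#' @export
mean_turnover_theory <- function(tau, nu, p) {
  .check_nonneg(tau = tau, nu = nu)
  if (any(p <= 0 | p > 1)) stop("`p` must be in (0, 1]")
  out <- nu * (nu + tau)
  den <- nu + p * tau
  ifelse(nu == 0, 0, out / den)
}

#' Regime weights of the model
#'
#' Probabilities that, between consecutive observations, an element
#' performs a Levy walk (`w_levy = exp(-nu) * (1 - exp(-tau))`), changes
#' rank by diffusion only (`w_diff = exp(-nu) * exp(-tau)`), or is replaced
#' (`w_repl = 1 - exp(-nu)`).  The three sum to 1 exactly.
#'
#' @param tau,nu model rates, >= 0 (vectorized).
#' @return A data frame with columns `w_levy`, `w_diff`, `w_repl`.
#' @export
regime_weights <- function(tau, nu) {
  .check_nonneg(tau = tau, nu = nu)
  data.frame(w_levy = exp(-nu) * (1 - exp(-tau)),
             w_diff = exp(-nu) * exp(-tau),
             w_repl = 1 - exp(-nu))
}
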