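# Fitting the displacement-replacement model to measured (F, o_dot, p),
# rescaling onto the universal curve tau_r * nu_r = 1, regime
# classification, subsampling and parametric-bootstrap analyses.

#' Estimate the system size from a rank table
#'
#' Approximates the system size N by `N_{T-1}`, the number of distinct
#' elements ever seen in the list during the observation window, and sets
#' `p = N0 / N`.  This is an observation-window-dependent approximation: on
#' simulator output N keeps growing with T whenever the replacement rate is
#' positive.
#'
#' @param table a [rank_table()].
#' @return `list(n, n0, p)`.
#' @export
estimate_system_size <- function(table) {
  stopifnot(inherits(table, "rank_table"))
  n <- length(unique(as.vector(table$occupants)))
  list(n = n, n0 = list_size(table), p = list_size(table) / n)
}

# closed-form tau from the mean-flux equation at trial nu:
# exp(-tau) = ((1 - F) e^nu - p) / (1 - p)
.tau_of_nu <- function(nu, F_obs, p) {
  arg <- ((1 - F_obs) * exp(nu) - p) / (1 - p)
  if (arg <= 0) return(Inf)
  max(0, -log(arg))
}

#' Estimate (tau, nu) from measured mean flux and turnover rate
#'
#' Inverts the two closed-form observables -- mean flux
#' `F = 1 - exp(-nu)(p + (1-p) exp(-tau))` and mean turnover rate
#' `o_dot = nu (nu + tau) / (nu + p tau)` -- for `(tau, nu) >= 0` by nested
#' 1-D bracketing: the flux equation gives `tau(nu)` in closed form, and a
#' bounded root search in `nu` on `[max(0, log(p/(1-F))), -log(1-F)]`
#' solves the turnover equation.  When the turnover residual has more than
#' one zero (a spurious solution with diverging tau can appear at the
#' lower nu bound), the largest-nu root is returned.  Observed pairs
#' outside the model's image fall back to constrained least squares
#' (relative errors) with `converged = FALSE`.
#'
#' @param F_obs observed mean flux in \[0, 1).
#' @param o_dot_obs observed mean turnover rate, >= 0.
#' @param p relative list size N0/N in (0, 1].
#' @return An object of class `rank_fit`: `tau_hat`, `nu_hat`, `p`,
#'   `F_obs`, `o_dot_obs`, `residual` (max absolute error over the two
#'   equations), `converged`, `method`, `note`.
#' @export
fit_parameters <- function(F_obs, o_dot_obs, p) {
  stopifnot(F_obs >= 0, F_obs < 1, o_dot_obs >= 0, p > 0, p <= 1)
  mk <- function(tau, nu, converged, method, note = NA_character_) {
    res <- max(abs(mean_flux_theory(tau, nu, p) - F_obs),
               abs(mean_turnover_theory(tau, nu, p) - o_dot_obs))
    structure(list(tau_hat = tau, nu_hat = nu, p = p,
                   F_obs = F_obs, o_dot_obs = o_dot_obs,
                   residual = res, converged = converged,
                   method = method, note = note),
              class = "rank_fit")
  }
  if (F_obs == 0) {
    note <- if (o_dot_obs > 0)
      "infeasible: F = 0 with o_dot > 0 has no model solution" else
      "tau unidentifiable at F = 0; least-squares convention (0, 0)"
    return(mk(0, 0, converged = o_dot_obs == 0, method = "closed_form",
              note = note))
  }
  if (p == 1) {
    # closed window: flux can only come from replacement; tau drops out
    nu <- -log(1 - F_obs)
    fit <- mk(0, nu, converged = FALSE, method = "closed_form",
              note = "p = 1 with F > 0: tau unidentifiable, returned as 0")
    fit$converged <- fit$residual < 1e-8
    return(fit)
  }
  nu_hi <- -log(1 - F_obs)
  nu_lo <- max(0, log(p / (1 - F_obs)))
  g <- function(nu) {
    tau <- .tau_of_nu(nu, F_obs, p)
    if (!is.finite(tau)) return(nu / p - o_dot_obs)  # tau -> Inf limit
    mean_turnover_theory(tau, nu, p) - o_dot_obs
  }
  eps <- 1e-12 * max(1, nu_hi)
  lo <- nu_lo + eps
  # The turnover residual g can have two zeros: a spurious one hugging the
  # lower nu bound (where tau(nu) diverges and tau is effectively
  # unidentifiable) and the genuine one.  Scan for every sign change and
  # keep the largest-nu (smallest-tau) root.
  ns <- seq(lo, nu_hi, length.out = 400L)
  gs <- vapply(ns, g, numeric(1))
  flips <- which(diff(sign(gs)) != 0 & is.finite(gs[-1L]) &
                   is.finite(gs[-length(gs)]))
  if (length(flips)) {
    i <- max(flips)
    root <- uniroot(g, c(ns[i], ns[i + 1L]), tol = 1e-14)
    nu <- root$root
    # Newton polish: uniroot's interval tolerance can leave the turnover
    # residual just above the 1e-8 convergence contract
    for (it in 1:4) {
      gv <- g(nu)
      h <- max(1e-9, 1e-7 * nu)
      dg <- (g(nu + h) - g(nu - h)) / (2 * h)
      if (!is.finite(dg) || dg == 0) break
      nu_new <- nu - gv / dg
      if (!is.finite(nu_new) || nu_new <= nu_lo || nu_new > nu_hi) break
      nu <- nu_new
      if (abs(gv) < 1e-13) break
    }
    tau <- .tau_of_nu(nu, F_obs, p)
    fit <- mk(tau, nu, converged = TRUE, method = "nested_bracket")
    if (fit$residual >= 1e-8) fit$converged <- FALSE
    return(fit)
  }
  # infeasible (F, o_dot): nearest model point in relative least squares
  obj <- function(par) {
    tau <- exp(par[1L]) - 1
    nu <- exp(par[2L]) - 1
    if (tau < 0 || nu < 0) return(1e10)
    ((mean_flux_theory(tau, nu, p) - F_obs) / max(F_obs, 1e-6))^2 +
      ((mean_turnover_theory(tau, nu, p) - o_dot_obs) /
         max(o_dot_obs, 1e-6))^2
  }
  start <- c(log(1 + max(F_obs, 1e-3)), log(1 + max(o_dot_obs, 1e-3)))
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  tau <- exp(opt$par[1L]) - 1
  nu <- exp(opt$par[2L]) - 1
  fit <- mk(tau, nu, converged = FALSE, method = "least_squares",
            note = "observed (F, o_dot) outside the model's image")
  fit$converged <- fit$residual < 1e-8
  fit
}

#' @export
print.rank_fit <- function(x, ...) {
  cat(sprintf(paste0("rank_fit: tau = %.6g, nu = %.6g (p = %.4g, ",
                     "F = %.4g, o_dot = %.4g)\n  residual = %.3g, %s, %s\n"),
              x$tau_hat, x$nu_hat, x$p, x$F_obs, x$o_dot_obs, x$residual,
              if (x$converged) "converged" else "NOT converged", x$method))
  if (!is.na(x$note)) cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

#' Measure and fit a rank table in one call
#'
#' Measures `(F, o_dot)` with [flux_turnover()], estimates `(N, p)` with
#' [estimate_system_size()] and inverts the model with [fit_parameters()].
#'
#' @param table a [rank_table()].
#' @param p optional known relative list size; default uses the
#'   `N = N_{T-1}` estimate.
#' @return A `rank_fit` with `n`, `n0` attached.
#' @export
fit_rank_table <- function(table, p = NULL) {
  ft <- flux_turnover(table)
  sz <- estimate_system_size(table)
  if (is.null(p)) p <- sz$p
  fit <- fit_parameters(ft$mean_flux, ft$mean_turnover_rate, p)
  fit$n <- sz$n
  fit$n0 <- sz$n0
  fit
}

#' Rescale fitted parameters onto the universal-curve coordinates
#'
#' `tau_r = tau / (p (1 - p) o_dot)` and `nu_r = (nu - p o_dot) / o_dot`,
#' defined for open lists only (`p` strictly inside (0, 1) and
#' `o_dot > 0`).  On-model parameter sets satisfy the universal curve
#' `tau_r * nu_r = 1`; `curve_distance = |log10(tau_r * nu_r)|` measures
#' the departure from it.
#'
#' @param tau,nu model rates.
#' @param p relative list size, strictly in (0, 1).
#' @param o_dot observed mean turnover rate, > 0.
#' @return An object of class `rescaled_params`: `tau_r`, `nu_r`,
#'   `product`, `curve_distance`.
#' @export
rescale_parameters <- function(tau, nu, p, o_dot) {
  .check_nonneg(tau = tau, nu = nu)
  if (p <= 0 || p >= 1)
    stop("not rescalable: `p` must be strictly inside (0, 1)")
  if (o_dot <= 0)
    stop("not rescalable: `o_dot` must be positive (open list)")
  tau_r <- tau / (p * (1 - p) * o_dot)
  nu_r <- (nu - p * o_dot) / o_dot
  prod <- tau_r * nu_r
  structure(list(tau_r = tau_r, nu_r = nu_r, product = prod,
                 curve_distance = abs(log10(abs(prod)))),
            class = "rescaled_params")
}

#' @export
print.rescaled_params <- function(x, ...) {
  cat(sprintf("rescaled: tau_r = %.6g, nu_r = %.6g, tau_r*nu_r = %.6g (|log10| = %.4g)\n",
              x$tau_r, x$nu_r, x$product, x$curve_distance))
  invisible(x)
}

#' Classify the dominant rank-change mechanism
#'
#' Argmax of the three regime weights; ties (measure zero) are broken with
#' fixed priority diffusion > levy > replacement.
#'
#' @param tau,nu model rates, >= 0.
#' @return `list(label, weights)` with `label` one of `"levy"`,
#'   `"diffusion"`, `"replacement"`.
#' @export
regime_classify <- function(tau, nu) {
  w <- regime_weights(tau, nu)
  ordered <- c(diffusion = w$w_diff, levy = w$w_levy,
               replacement = w$w_repl)
  list(label = names(ordered)[which.max(ordered)], weights = w)
}

#' Scan regime weights along the universal curve
#'
#' Traverses the one-parameter family of models compatible with a fixed
#' `(p, o_dot)` and the universal curve: for each rescaled parameter
#' `tau_r` on a log-spaced grid, sets `nu_r = 1 / tau_r` and inverts the
#' rescaling to `tau = tau_r p (1 - p) o_dot`, `nu = (nu_r + p) o_dot`,
#' then evaluates the regime weights.  Rows with an inadmissible
#' `(tau, nu)` are skipped.
#'
#' @param p relative list size, strictly in (0, 1).
#' @param o_dot mean turnover rate, > 0.
#' @param n_points number of grid points.
#' @param tau_r_range range of `tau_r` scanned (log-spaced).
#' @return A data frame (ordered by `tau_r`) with columns `tau_r`, `nu_r`,
#'   `tau`, `nu`, `w_levy`, `w_diff`, `w_repl`, `regime`.
#' @export
regime_scan <- function(p, o_dot, n_points = 50L,
                        tau_r_range = c(1e-2, 1e2)) {
  if (p <= 0 || p >= 1) stop("`p` must be strictly inside (0, 1)")
  if (o_dot <= 0) stop("`o_dot` must be positive")
  tau_r <- exp(seq(log(tau_r_range[1L]), log(tau_r_range[2L]),
                   length.out = n_points))
  nu_r <- 1 / tau_r
  tau <- tau_r * p * (1 - p) * o_dot
  nu <- (nu_r + p) * o_dot
  keep <- tau >= 0 & nu >= 0
  if (!all(keep))
    message(sprintf("regime_scan: skipped %d inadmissible grid points",
                    sum(!keep)))
  w <- regime_weights(tau[keep], nu[keep])
  # columns in tie-break priority order: diffusion > levy > replacement
  lab <- c("diffusion", "levy", "replacement")[
    max.col(cbind(w$w_diff, w$w_levy, w$w_repl), ties.method = "first")]
  data.frame(tau_r = tau_r[keep], nu_r = nu_r[keep], tau = tau[keep],
             nu = nu[keep], w, regime = lab)
}

#' Subsampling analysis of a rank table
#'
#' For each subsampling factor `k`: keep every k-th observation,
#' re-measure `(F, o_dot)`, re-estimate `(N, p)`, refit `(tau, nu)`,
#' rescale (when the list is open), and compute the replacement rate per
#' unit real time `nu_hat / (k * ell)`.
#'
#' @param table a [rank_table()].
#' @param k_values integer subsampling factors (all `< T`).
#' @return A data frame with one row per `k`: `k`, `t_eff`, `F`, `o_dot`,
#'   `n`, `p`, `tau_hat`, `nu_hat`, `converged`, `tau_r`, `nu_r`
#'   (NA when not rescalable), `replacement_rate`.
#' @export
subsampling_analysis <- function(table, k_values = c(1L, 2L, 4L, 8L)) {
  stopifnot(inherits(table, "rank_table"))
  ell <- table$interval_length
  rows <- lapply(sort(unique(as.integer(k_values))), function(k) {
    sub <- if (k == 1L) table else subsample(table, k)
    fit <- fit_rank_table(sub)
    tau_r <- nu_r <- NA_real_
    if (fit$p > 0 && fit$p < 1 && fit$o_dot_obs > 1e-3) {
      rs <- rescale_parameters(fit$tau_hat, fit$nu_hat, fit$p,
                               fit$o_dot_obs)
      tau_r <- rs$tau_r
      nu_r <- rs$nu_r
    }
    data.frame(k = k, t_eff = n_obs(sub), F = fit$F_obs,
               o_dot = fit$o_dot_obs, n = fit$n, p = fit$p,
               tau_hat = fit$tau_hat, nu_hat = fit$nu_hat,
               converged = fit$converged, tau_r = tau_r, nu_r = nu_r,
               replacement_rate = fit$nu_hat / (k * ell))
  })
  do.call(rbind, rows)
}

#' Parametric bootstrap test of distance to the universal curve
#'
#' Simulates `n_boot` replicate rank tables at the fitted parameters,
#' refits each (re-estimating N per replicate, mirroring the
#' observation-window effect), and compares the data's
#' `curve_distance = |log10(tau_r nu_r)|` with the bootstrap distribution.
#' `exceed_flag` is `TRUE` when the data lies farther from the curve than
#' the `(1 - alpha)` bootstrap quantile.
#'
#' @param fit a `rank_fit` from [fit_rank_table()] (needs `n`, `n0`).
#' @param t_obs number of observations for the replicates (use the data's T).
#' @param n_boot number of bootstrap replicates, >= 1.
#' @param seed RNG seed for the replicate simulations.
#' @param alpha test level (default 0.05).
#' @return `list(data_distance, bootstrap_distances, exceed_flag,
#'   n_failed, unreliable)`; `unreliable` is set when more than 20% of the
#'   replicate fits failed.
#' @export
bootstrap_curve_test <- function(fit, t_obs, n_boot = 200L, seed = 1L,
                                 alpha = 0.05) {
  stopifnot(inherits(fit, "rank_fit"))
  if (n_boot < 1) stop("`n_boot` must be at least 1")
  if (is.null(fit$n) || is.null(fit$n0))
    stop("`fit` must come from fit_rank_table() (needs n and n0)")
  if (fit$p <= 0 || fit$p >= 1 || fit$o_dot_obs <= 0)
    stop("not rescalable: the curve test needs an open list")
  data_dist <- rescale_parameters(fit$tau_hat, fit$nu_hat, fit$p,
                                  fit$o_dot_obs)$curve_distance
  dists <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    par_b <- model_params(fit$n, fit$n0, min(1, fit$tau_hat),
                          min(1, fit$nu_hat), t_obs,
                          seed = (seed + b - 1L) %% .Machine$integer.max)
    tab_b <- simulate_rank_model(par_b)
    fit_b <- tryCatch(fit_rank_table(tab_b), error = function(e) NULL)
    if (is.null(fit_b) || fit_b$p <= 0 || fit_b$p >= 1 ||
        fit_b$o_dot_obs <= 0)
      next
    dists[b] <- rescale_parameters(fit_b$tau_hat, fit_b$nu_hat, fit_b$p,
                                   fit_b$o_dot_obs)$curve_distance
  }
  ok <- dists[is.finite(dists)]
  n_failed <- n_boot - length(ok)
  unreliable <- n_failed > 0.2 * n_boot
  if (unreliable)
    warning(sprintf("curve test unreliable: %d/%d replicate fits failed",
                    n_failed, n_boot))
  exceed <- length(ok) > 0 &&
    data_dist > quantile(ok, 1 - alpha, names = FALSE)
  list(data_distance = data_dist, bootstrap_distances = ok,
       exceed_flag = exceed, n_failed = n_failed, unreliable = unreliable)
}
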