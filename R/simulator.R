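# Stochastic displacement-replacement dynamics: N ranked elements, a
# top-N0 observation window, and two per-micro-step Bernoulli probabilities
# (tau: uniform jump displacing intervening elements; nu: replacement by a
# brand-new element at the same rank).  One observation step = N
# micro-steps of duration 1/N.

#' Parameters of the displacement-replacement model
#'
#' @param n system size N.
#' @param n0 list size N0 (top of the list that is observed), `1 <= n0 <= n`.
#' @param tau displacement probability per micro-step, in \[0, 1\].
#' @param nu replacement probability per micro-step, in \[0, 1\].
#' @param t_obs number of observations T (>= 2).
#' @param seed RNG seed; all randomness of a run flows from it.
#' @return An object of class `model_params`; field `p = n0/n`.
#' @export
model_params <- function(n, n0 = n, tau = 0, nu = 0, t_obs = 2L, seed = 1L) {
  stopifnot(n >= 1, n0 >= 1, n0 <= n, n %% 1 == 0, n0 %% 1 == 0,
            tau >= 0, tau <= 1, nu >= 0, nu <= 1,
            t_obs >= 2, t_obs %% 1 == 0)
  structure(list(n = as.integer(n), n0 = as.integer(n0), tau = tau, nu = nu,
                 t_obs = as.integer(t_obs), seed = as.integer(seed),
                 p = n0 / n),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: N = %d, N0 = %d (p = %.4g), tau = %g, nu = %g, T = %d, seed = %d\n",
    x$n, x$n0, x$p, x$tau, x$nu, x$t_obs, x$seed))
  invisible(x)
}

.id_strings <- function(ids) sprintf("e%d", ids)

#' Simulate the displacement-replacement model
#'
#' Runs `n` micro-steps per observation interval and records the ids of the
#' top `n0` ranks at t = 0, 1, ..., T-1.  Fresh ids come from a monotone
#' counter, so every replacement introduces a globally new element.
#' Deterministic given `params$seed`.
#'
#' @param params a [model_params()].
#' @return A [rank_table()] with `interval_length = 1`.
#' @export
simulate_rank_model <- function(params) {
  stopifnot(inherits(params, "model_params"))
  simulate_rank_schedule(params$n, params$n0,
                         rep(params$tau, params$t_obs - 1L),
                         rep(params$nu, params$t_obs - 1L),
                         seed = params$seed)
}

#' Simulate the model under a per-interval rate schedule
#'
#' Generalization of [simulate_rank_model()] in which `tau` and `nu` may
#' change from one observation interval to the next (e.g. a mid-series
#' shock used to probe non-stationarity).
#'
#' @param n,n0 system and list sizes.
#' @param tau,nu numeric vectors of per-micro-step probabilities, one entry
#'   per observation interval (length T-1).
#' @param seed RNG seed.
#' @return A [rank_table()] with `T = length(tau) + 1` observations.
#' @export
simulate_rank_schedule <- function(n, n0, tau, nu, seed = 1L) {
  stopifnot(n >= 1, n0 >= 1, n0 <= n, length(tau) == length(nu),
            length(tau) >= 1, all(tau >= 0), all(tau <= 1),
            all(nu >= 0), all(nu <= 1))
  set.seed(seed)
  ids <- cpp_simulate(as.integer(n), as.integer(n0), as.numeric(tau),
                      as.numeric(nu), length(tau) + 1L)
  occ <- matrix(.id_strings(ids), nrow = nrow(ids))
  rank_table(occ, interval_length = 1)
}

#' One micro-step of the model (reference implementation)
#'
#' Pure-R version of the elementary update, drawing from R's RNG in the
#' same order as the compiled simulator: with probability `tau` a uniform
#' element is removed and re-inserted at a uniform target rank (a no-op
#' when source equals target); independently, with probability `nu`, a
#' uniform element's id is overwritten with a fresh id at the same rank.
#' Used as the oracle against which the compiled path is tested.
#'
#' @param order integer vector of element ids, position = rank.
#' @param tau,nu per-micro-step probabilities.
#' @param next_id next fresh id (integer counter).
#' @return `list(order, next_id)` after one micro-step.
#' @export
step_rank_model <- function(order, tau, nu, next_id) {
  n <- length(order)
  draw <- function() {
    i <- floor(runif(1L) * n) + 1L
    if (i > n) n else as.integer(i)
  }
  if (runif(1L) < tau) {
    src <- draw()
    dst <- draw()
    if (src != dst) {
      id <- order[src]
      order <- append(order[-src], id, after = dst - 1L)
    }
  }
  if (runif(1L) < nu) {
    order[draw()] <- next_id
    next_id <- next_id + 1L
  }
  list(order = order, next_id = next_id)
}

#' Monte-Carlo displacement tracking of a single element
#'
#' Follows an element that starts at normalized rank `r` through
#' `n_realizations` independent runs of the full-system dynamics and
#' histograms its normalized rank at the requested lags.  Replaced elements
#' stop being counted and form the mass deficit, so the histograms estimate
#' the displacement probability P(x, t) of the theory; the survival
#' fraction estimates `exp(-nu * t)` and the never-jumped fraction
#' estimates `exp(-tau * t)`.
#'
#' @param params a [model_params()] (`n0` and `t_obs` are not used).
#' @param r normalized source rank in (0, 1]; the start rank is `round(r*n)`.
#' @param lags vector of non-negative integer lags (observation steps).
#' @param n_realizations number of Monte-Carlo runs (a `low_n` flag is set
#'   below 100).
#' @return A list of class `displacement_tracking`: one
#'   `displacement_histogram` per lag (grid `(1..N)/N`), each carrying
#'   `survival`, `survival_expected`, `never_jumped` and
#'   `never_jumped_expected`; plus `low_n`.
#' @export
track_displacements <- function(params, r, lags, n_realizations = 1e4) {
  stopifnot(inherits(params, "model_params"), r > 0, r <= 1,
            all(lags >= 0), all(lags %% 1 == 0), n_realizations >= 1)
  n <- params$n
  start <- max(1L, min(n, as.integer(round(r * n))))
  lags <- as.integer(lags)
  pos <- sort(unique(lags[lags > 0L]))
  set.seed(params$seed)
  if (length(pos)) {
    res <- cpp_track(n, params$tau, params$nu, pos, start,
                     as.integer(n_realizations))
  }
  grid <- seq_len(n) / n
  hists <- lapply(lags, function(lg) {
    if (lg == 0L) {
      counts <- integer(n)
      counts[start] <- as.integer(n_realizations)
      surv <- nj <- n_realizations
    } else {
      li <- match(lg, pos)
      counts <- res$counts[li, ]
      surv <- res$survivors[li]
      nj <- res$never_jumped[li]
    }
    .new_histogram(
      lag = lg, source_rank = start / n, grid = grid,
      mass = counts / n_realizations, counts = counts,
      n_tracked = as.integer(n_realizations),
      normalization = "by_system_N",
      extra = list(survival = surv / n_realizations,
                   survival_expected = exp(-params$nu * lg),
                   # among survivors, matching sum(D_{x,t}) = exp(-tau t)
                   never_jumped = if (surv > 0) nj / surv else NA_real_,
                   never_jumped_expected = exp(-params$tau * lg)))
  })
  names(hists) <- paste0("lag", lags)
  structure(list(histograms = hists, params = params, r = start / n,
                 n_realizations = as.integer(n_realizations),
                 low_n = n_realizations < 100),
            class = "displacement_tracking")
}

#' Preset parameter sets spanning the model's regimes
#'
#' Small, documented presets used for fixtures and examples: `closed`
#' (list covers the whole system, no replacement), `open-levy`
#' (jump-dominated), `open-diffusive` (diffusion-dominated) and
#' `replacement` (replacement-dominated).
#'
#' @param preset one of `"closed"`, `"open-levy"`, `"open-diffusive"`,
#'   `"replacement"`.
#' @param t_obs number of observations (default 50).
#' @param seed RNG seed.
#' @return A [model_params()].
#' @export
preset_params <- function(preset = c("closed", "open-levy", "open-diffusive",
                                     "replacement"),
                          t_obs = 50L, seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "closed"         = model_params(100, 100, tau = 0.2, nu = 0,
                                    t_obs = t_obs, seed = seed),
    "open-levy"      = model_params(200, 50, tau = 2,   nu = 0.05,
                                    t_obs = t_obs, seed = seed),
    "open-diffusive" = model_params(100, 80, tau = 0.1, nu = 0.2,
                                    t_obs = t_obs, seed = seed),
    "replacement"    = model_params(100, 80, tau = 0.1, nu = 2,
                                    t_obs = t_obs, seed = seed))
}
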