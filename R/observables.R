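# Empirical rank observables: flux, turnover, per-rank change probability,
# and displacement histograms.

#' Rank flux and turnover of a rank table
#'
#' Flux `F_t` is the probability that an element enters (equivalently, since
#' the list size is fixed, leaves) the list between observations t-1 and t;
#' the mean flux `F` is its average over t = 1..T-1.  Turnover `o_t` is the
#' number `N_t` of distinct elements ever seen in the list up to time t,
#' divided by the list size `N0`; the mean turnover rate is
#' `o_dot = (o_{T-1} - o_0) / (T - 1)`.
#'
#' @param table a [rank_table()].
#' @return An object of class `flux_turnover` with fields `flux_series`
#'   (`F_t`, t = 1..T-1), `mean_flux`, `turnover_series` (`o_t`, t =
#'   0..T-1), `new_element_counts` (`N_t`), `mean_turnover_rate`, `n_obs`,
#'   `list_size`.
#' @export
flux_turnover <- function(table) {
  stopifnot(inherits(table, "rank_table"))
  occ <- table$occupants
  T_obs <- nrow(occ)
  n0 <- ncol(occ)
  flux <- vapply(seq_len(T_obs - 1L), function(t) {
    sum(!(occ[t + 1L, ] %in% occ[t, ])) / n0
  }, numeric(1))
  # cumulative count of distinct ids in time-major order
  firsts <- !duplicated(as.vector(t(occ)))
  n_t <- cumsum(firsts)[seq_len(T_obs) * n0]
  o_t <- n_t / n0
  structure(
    list(flux_series = flux, mean_flux = mean(flux),
         turnover_series = o_t, new_element_counts = n_t,
         mean_turnover_rate = (o_t[T_obs] - o_t[1L]) / (T_obs - 1L),
         n_obs = T_obs, list_size = n0),
    class = "flux_turnover")
}

#' @rdname flux_turnover
#' @export
rank_flux <- function(table) flux_turnover(table)

#' @rdname flux_turnover
#' @export
rank_turnover <- function(table) flux_turnover(table)

#' @export
print.flux_turnover <- function(x, ...) {
  cat(sprintf("flux/turnover summary (T = %d, N0 = %d)\n", x$n_obs,
              x$list_size))
  cat(sprintf("  mean flux F        = %.6g\n", x$mean_flux))
  cat(sprintf("  mean turnover rate = %.6g (o_{T-1} = %.6g)\n",
              x$mean_turnover_rate, tail(x$turnover_series, 1L)))
  invisible(x)
}

#' Per-rank change probability
#'
#' `C(R)` is the fraction of the T-1 transitions in which the occupant of
#' rank cell `R` differs between consecutive observations.
#'
#' @param table a [rank_table()].
#' @return Numeric vector of length `N0`, named by rank.
#' @export
rank_change <- function(table) {
  stopifnot(inherits(table, "rank_table"))
  occ <- table$occupants
  T_obs <- nrow(occ)
  ch <- colMeans(occ[-1L, , drop = FALSE] != occ[-T_obs, , drop = FALSE])
  setNames(ch, seq_len(ncol(occ)))
}

.new_histogram <- function(lag, source_rank, grid, mass, counts, n_tracked,
                           normalization, smoothed = FALSE, extra = list()) {
  dx <- if (length(grid) > 1L) grid[2L] - grid[1L] else grid[1L]
  structure(
    c(list(lag = lag, source_rank = source_rank, grid = grid, dx = dx,
           mass = mass, counts = counts, n_tracked = n_tracked,
           deficit = 1 - sum(mass), normalization = normalization,
           smoothed = smoothed), extra),
    class = "displacement_histogram")
}

#' @export
print.displacement_histogram <- function(x, ...) {
  cat(sprintf(paste0("displacement histogram: lag %g, source r = %.4g, ",
                     "%d cells, mass %.4g (deficit %.4g), n = %d%s\n"),
              x$lag, x$source_rank, length(x$grid), sum(x$mass), x$deficit,
              x$n_tracked, if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

#' Empirical displacement histogram from a rank table
#'
#' For every reference observation t0 and every element occupying one of
#' `source_ranks` at t0, records the element's normalized rank at
#' t0 + `lag` if it is still listed; elements that left the list contribute
#' to the mass deficit (total mass < 1).  All valid t0 are pooled
#' (stationarity is assumed).
#'
#' @param table a [rank_table()].
#' @param lag number of observation steps (0 <= lag <= T-1).
#' @param source_ranks integer vector of source ranks pooled into one bin.
#' @param normalization `"by_list_N0"` (default; ranks divided by the list
#'   size) or `"by_system_N"` (divided by the system size `n_system`,
#'   needed to overlay data on the model theory).
#' @param n_system system size N for `"by_system_N"`; defaults to the
#'   number of distinct ids ever seen.
#' @return A `displacement_histogram` whose grid covers (0, 1] in steps of
#'   1/denominator; cells beyond `N0`/denominator are structurally zero.
#' @export
displacement_histogram <- function(table, lag, source_ranks,
                                   normalization = c("by_list_N0",
                                                     "by_system_N"),
                                   n_system = NULL) {
  stopifnot(inherits(table, "rank_table"))
  normalization <- match.arg(normalization)
  T_obs <- n_obs(table)
  n0 <- list_size(table)
  if (lag < 0 || lag > T_obs - 1L) stop("`lag` must be in 0..T-1")
  source_ranks <- as.integer(source_ranks)
  if (any(source_ranks < 1L | source_ranks > n0))
    stop("`source_ranks` must lie in 1..N0")
  denom <- if (normalization == "by_list_N0") n0 else {
    if (is.null(n_system))
      n_system <- length(unique(as.vector(table$occupants)))
    as.integer(n_system)
  }
  occ <- table$occupants
  counts <- integer(denom)
  n_tracked <- 0L
  for (t0 in seq_len(T_obs - lag)) {
    dest <- match(occ[t0, source_ranks], occ[t0 + lag, ])
    dest <- dest[!is.na(dest)]
    counts[seq_len(n0)] <- counts[seq_len(n0)] +
      tabulate(dest, nbins = n0)
    n_tracked <- n_tracked + length(source_ranks)
  }
  mass <- if (n_tracked > 0L) counts / n_tracked else rep(0, denom)
  .new_histogram(lag = lag,
                 source_rank = mean(source_ranks) / denom,
                 grid = seq_len(denom) / denom, mass = mass,
                 counts = counts, n_tracked = n_tracked,
                 normalization = normalization)
}

# Savitzky-Golay projection matrix for a centred window: row i gives the
# weights of the degree-`polyorder` least-squares fit evaluated at offset i.
.savgol_matrix <- function(window, polyorder) {
  h <- (window - 1L) / 2L
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  A %*% solve(crossprod(A), t(A))
}

#' Savitzky-Golay smoothing of a displacement histogram
#'
#' Applies a Savitzky-Golay filter (local polynomial least squares) to the
#' mass vector; window ends are handled by evaluating the boundary window
#' fits at their off-centre positions.  Negative filtered values are
#' clipped to zero.
#'
#' @param hist a `displacement_histogram`.
#' @param window odd window length, `polyorder < window <` grid length.
#' @param polyorder polynomial order of the local fit.
#' @return The smoothed `displacement_histogram` (`smoothed = TRUE`).
#' @export
smooth_histogram <- function(hist, window = 11L, polyorder = 3L) {
  stopifnot(inherits(hist, "displacement_histogram"))
  n <- length(hist$mass)
  if (window %% 2L != 1L) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be smaller than `window`")
  if (window >= n) stop("`window` must be smaller than the grid length")
  P <- .savgol_matrix(window, polyorder)
  h <- (window - 1L) %/% 2L
  y <- hist$mass
  sm <- y
  centre <- P[h + 1L, ]
  for (i in seq(h + 1L, n - h)) sm[i] <- sum(centre * y[i - h:(-h)])
  sm[seq_len(h)] <- (P %*% y[seq_len(window)])[seq_len(h)]
  sm[seq(n - h + 1L, n)] <-
    (P %*% y[seq(n - window + 1L, n)])[seq(window - h + 1L, window)]
  sm[sm < 0] <- 0
  out <- hist
  out$mass <- sm
  out$deficit <- 1 - sum(sm)
  out$smoothed <- TRUE
  out
}
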