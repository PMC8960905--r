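# Canonical data model for longitudinal ranking lists.
#
# A rank_table stores the occupants of a fixed-size ranking list as a
# T x N0 character matrix (rows = observations, columns = ranks 1..N0,
# rank 1 = best).  Times are re-indexed internally to 0..T-1; the original
# labels are kept as metadata.  Scores, when present, are stored in a
# parallel numeric matrix and must be non-increasing across each row.

#' Construct a longitudinal rank table
#'
#' @param occupants character matrix, `T x N0`: `occupants[t, R]` is the id
#'   of the element at rank `R` (1 = best) in the `t`-th observation.
#' @param scores optional numeric matrix of the same shape with the score of
#'   each occupant; rows must be non-increasing (ties allowed).
#' @param time_labels optional vector of original time labels (length `T`).
#' @param interval_length real time spanned by one observation step
#'   (user-declared units, default 1).
#'
#' @return An object of class `rank_table` with fields `occupants`,
#'   `scores`, `times` (0..T-1), `time_labels`, `interval_length`.
#' @export
rank_table <- function(occupants, scores = NULL, time_labels = NULL,
                       interval_length = 1) {
  if (!is.matrix(occupants) || !is.character(occupants))
    stop("`occupants` must be a character matrix (times x ranks)")
  T_obs <- nrow(occupants)
  n0 <- ncol(occupants)
  if (T_obs < 2L) stop("a rank table needs at least T = 2 observations")
  if (n0 < 1L) stop("list size N0 must be at least 1")
  if (anyNA(occupants) || any(occupants == ""))
    stop("every (time, rank) cell must hold a non-empty element id")
  for (t in seq_len(T_obs)) {
    dup <- occupants[t, ][duplicated(occupants[t, ])]
    if (length(dup))
      stop(sprintf("element '%s' appears more than once at time %d",
                   dup[[1L]], t - 1L))
  }
  if (!is.null(scores)) {
    if (!is.matrix(scores) || !identical(dim(scores), dim(occupants)))
      stop("`scores` must be a numeric matrix with the shape of `occupants`")
    if (any(!is.finite(scores))) stop("scores must be finite")
    bad <- which(apply(scores, 1L, function(s) any(diff(s) > 0)))
    if (length(bad))
      stop(sprintf("scores must be non-increasing within each time (time %d)",
                   bad[[1L]] - 1L))
  }
  if (is.null(time_labels)) time_labels <- seq_len(T_obs) - 1L
  if (length(time_labels) != T_obs)
    stop("`time_labels` must have one entry per observation")
  if (!is.numeric(interval_length) || length(interval_length) != 1L ||
      interval_length <= 0)
    stop("`interval_length` must be a single positive number")
  structure(
    list(occupants = occupants, scores = scores,
         times = seq_len(T_obs) - 1L, time_labels = time_labels,
         interval_length = as.numeric(interval_length)),
    class = "rank_table")
}

#' Number of observations of a rank table
#' @param x a `rank_table`.
#' @return Integer `T`.
#' @export
n_obs <- function(x) nrow(x$occupants)

#' List size (number of ranks) of a rank table
#' @param x a `rank_table`.
#' @return Integer `N0`.
#' @export
list_size <- function(x) ncol(x$occupants)

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("rank_table: T = %d observations, N0 = %d ranks, ell = %g%s\n",
              n_obs(x), list_size(x), x$interval_length,
              if (is.null(x$scores)) "" else ", with scores"))
  cat(sprintf("  distinct elements ever listed: %d\n",
              length(unique(as.vector(x$occupants)))))
  invisible(x)
}

#' @export
`==.rank_table` <- function(e1, e2) {
  identical(unname(e1$occupants), unname(e2$occupants)) &&
    identical(is.null(e1$scores), is.null(e2$scores)) &&
    (is.null(e1$scores) || isTRUE(all.equal(unname(e1$scores),
                                            unname(e2$scores)))) &&
    isTRUE(all.equal(e1$interval_length, e2$interval_length))
}

.rank_sep <- function(dialect) if (dialect == "tsv") "\t" else ","

#' Read a rank table from a long-format TSV/CSV file
#'
#' Expected columns: `time` (sortable label), `rank` (integer, 1 = best),
#' `element` (string id), optional `score` (numeric).  Times are re-indexed
#' to 0..T-1 in ascending order of their labels; gaps in the source
#' timestamps are the caller's responsibility.
#'
#' @param path path to an existing file.
#' @param dialect `"tsv"` or `"csv"`.
#' @param interval_length real time per observation step (default 1).
#' @return A [rank_table()].
#' @export
read_rank_table <- function(path, dialect = c("tsv", "csv"),
                            interval_length = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = .rank_sep(dialect), header = TRUE,
                          colClasses = list(character = "element"))
  need <- c("time", "rank", "element")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  if (!is.numeric(dt$rank) || any(dt$rank %% 1 != 0))
    stop("parse error: column `rank` must contain integers")
  rank <- as.integer(dt$rank)
  tlab <- sort(unique(dt$time))
  tidx <- match(dt$time, tlab)
  T_obs <- length(tlab)
  n0 <- max(rank)
  dup <- which(duplicated(cbind(tidx, rank)))
  if (length(dup))
    stop(sprintf("duplicate (time, rank) cell: time %s, rank %d",
                 as.character(dt$time[dup[[1L]]]), rank[dup[[1L]]]))
  if (any(rank < 1L)) stop("parse error: ranks must be >= 1")
  counts <- tabulate(tidx, nbins = T_obs)
  if (any(counts != n0))
    stop(sprintf("gap error: time %s has %d of %d ranks",
                 as.character(tlab[which(counts != n0)[1L]]),
                 counts[which(counts != n0)[1L]], n0))
  cover <- rowsum(rank, tidx)
  if (any(cover != n0 * (n0 + 1) / 2))
    stop("gap error: ranks are not contiguous 1..N0 at some time")
  occ <- matrix(NA_character_, T_obs, n0)
  occ[cbind(tidx, rank)] <- dt$element
  sc <- NULL
  if ("score" %in% names(dt)) {
    sc <- matrix(NA_real_, T_obs, n0)
    sc[cbind(tidx, rank)] <- as.numeric(dt$score)
  }
  rank_table(occ, scores = sc, time_labels = tlab,
             interval_length = interval_length)
}

#' Write a rank table to a long-format TSV/CSV file
#'
#' Rows are emitted in canonical order (time, then rank); scores, when
#' present, are printed with 17 significant digits so the file round-trips
#' to an equal table.
#'
#' @param table a [rank_table()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_rank_table <- function(table, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "rank_table"))
  T_obs <- n_obs(table)
  n0 <- list_size(table)
  out <- data.table::data.table(
    time = rep(table$time_labels, each = n0),
    rank = rep(seq_len(n0), times = T_obs),
    element = as.vector(t(table$occupants)))
  if (!is.null(table$scores))
    out$score <- sprintf("%.17g", as.vector(t(table$scores)))
  data.table::fwrite(out, path, sep = .rank_sep(dialect), quote = FALSE)
  invisible(path)
}

#' Convert a score table to a rank table
#'
#' Rank 1 is assigned to the highest score at each time; exactly `n0` ranks
#' are kept.  Score ties are broken deterministically: by default by the
#' element's rank at the previous observation (absent elements last), then
#' lexicographically by id; `tie_rule = "id_only"` skips the memory step.
#'
#' @param scores data frame with columns `time`, `element`, `score`
#'   (one score per (time, element) pair; at least `n0` elements per time).
#' @param n0 list size to keep.
#' @param tie_rule `"previous_rank_then_id"` (default) or `"id_only"`.
#' @param interval_length real time per observation step (default 1).
#' @return A [rank_table()] with scores attached.
#' @export
ranks_from_scores <- function(scores, n0,
                              tie_rule = c("previous_rank_then_id", "id_only"),
                              interval_length = 1) {
  tie_rule <- match.arg(tie_rule)
  scores <- as.data.frame(scores)
  need <- c("time", "element", "score")
  if (!all(need %in% names(scores)))
    stop("`scores` needs columns time, element, score")
  if (any(!is.finite(scores$score))) stop("scores must be finite")
  if (anyDuplicated(scores[c("time", "element")]))
    stop("more than one score for some (time, element) pair")
  tlab <- sort(unique(scores$time))
  T_obs <- length(tlab)
  occ <- matrix(NA_character_, T_obs, n0)
  sc <- matrix(NA_real_, T_obs, n0)
  prev_rank <- NULL
  for (ti in seq_len(T_obs)) {
    sub <- scores[scores$time == tlab[ti], ]
    if (nrow(sub) < n0)
      stop(sprintf("coverage error: time %s has %d < %d scored elements",
                   as.character(tlab[ti]), nrow(sub), n0))
    pr <- rep(Inf, nrow(sub))
    if (tie_rule == "previous_rank_then_id" && !is.null(prev_rank)) {
      hit <- match(sub$element, names(prev_rank))
      pr[!is.na(hit)] <- prev_rank[hit[!is.na(hit)]]
    }
    ord <- order(-sub$score, pr, sub$element)
    top <- sub[ord[seq_len(n0)], ]
    occ[ti, ] <- as.character(top$element)
    sc[ti, ] <- top$score
    prev_rank <- setNames(seq_len(n0), occ[ti, ])
  }
  rank_table(occ, scores = sc, time_labels = tlab,
             interval_length = interval_length)
}

#' Keep every k-th observation of a rank table
#'
#' Retains observations 0, k, 2k, ...; the subsampled table has
#' `T_eff = ceiling(T / k)` observations and interval length `k * ell`.
#'
#' @param x a `rank_table`.
#' @param k positive integer subsampling factor, `k < T`.
#' @return A `rank_table` with `T_eff` observations.
#' @export
subsample <- function(x, k) UseMethod("subsample")

#' @export
subsample.rank_table <- function(x, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k %% 1 != 0)
    stop("`k` must be a single positive integer")
  T_obs <- n_obs(x)
  if (k >= T_obs)
    stop(sprintf("k = %d leaves fewer than 2 of the %d observations", k, T_obs))
  keep <- seq(1L, T_obs, by = k)
  rank_table(x$occupants[keep, , drop = FALSE],
             scores = if (is.null(x$scores)) NULL
                      else x$scores[keep, , drop = FALSE],
             time_labels = x$time_labels[keep],
             interval_length = x$interval_length * k)
}
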