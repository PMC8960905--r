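# Fixtures are built in code; nothing is read from disk.

# the 2-time, 3-rank worked example used across the unit tests:
# t0 = (A, B, C), t1 = (A, C, D)
tiny_table <- function() {
  rank_table(matrix(c("A", "B", "C",
                      "A", "C", "D"), nrow = 2, byrow = TRUE))
}

# a static table (no change at all)
static_table <- function(t_obs = 4, n0 = 3) {
  ids <- if (n0 <= 26) LETTERS[seq_len(n0)] else sprintf("E%03d", seq_len(n0))
  rank_table(matrix(rep(ids, t_obs), nrow = t_obs, byrow = TRUE))
}

# write a long-format file from rows of (time, rank, element)
write_long <- function(rows, path, header = "time\trank\telement") {
  writeLines(c(header, rows), path)
  path
}

expect_valid_rank_table <- function(tab) {
  expect_s3_class(tab, "rank_table")
  occ <- tab$occupants
  expect_true(nrow(occ) >= 2)
  for (t in seq_len(nrow(occ)))
    expect_false(anyDuplicated(occ[t, ]) > 0)
  if (!is.null(tab$scores))
    expect_true(all(apply(tab$scores, 1, function(s) all(diff(s) <= 0))))
  invisible(tab)
}
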