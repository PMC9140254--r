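test_that("column_frequencies counts residues and honours the gap policy", {
  aln <- make_msa(list(r1 = "AA-", r2 = "AV-", r3 = "AV-", r4 = "AV-"))
  f <- column_frequencies(aln, 1)
  expect_equal(unname(f["A"]), 1)
  expect_equal(sum(f), 1)
  f2 <- column_frequencies(aln, 2)
  expect_equal(unname(f2[c("A", "V")]), c(0.25, 0.75))
  f3 <- column_frequencies(aln, 3)
  expect_true(isTRUE(attr(f3, "all_gap")))
  expect_equal(sum(f3), 0)
  expect_error(column_frequencies(aln, 4), "out of range")
  # gap-as-21st-symbol policy keeps the gap in the denominator
  g <- column_frequencies(make_msa(list(a = "A", b = "-")), 1,
                          gap_policy = "gap21")
  expect_equal(unname(g[c("A", "-")]), c(0.5, 0.5))
})

test_that("Schneider entropy matches its closed forms", {
  expect_equal(schneider_entropy(c(1, rep(0, 19))), 0, tolerance = 1e-12)
  expect_equal(schneider_entropy(rep(1 / 20, 20)), 1, tolerance = 1e-12)
  expect_equal(schneider_entropy(c(0.5, 0.5, rep(0, 18))),
               log(2) / log(20), tolerance = 1e-12)
  expect_error(schneider_entropy(rep(0, 20)), "undefined")
})

test_that("entropy stays in [0, 1] for random frequency vectors", {
  set.seed(501)
  for (i in 1:10000) {
    f <- stats::rgamma(20, shape = stats::runif(1, 0.05, 5))
    if (sum(f) == 0) next
    s <- schneider_entropy(f)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("entropy_profile computes per-column values with NA for all-gap", {
  aln <- make_msa(list(a = "AA-", b = "AV-", c = "AL-", d = "AW-"))
  p <- entropy_profile(aln)
  expect_equal(p$values[1], 0)
  expect_equal(p$values[2], log(4) / log(20), tolerance = 1e-12)
  expect_true(is.na(p$values[3]))
  expect_equal(p$n_nongap, c(4L, 4L, 0L))
})

test_that("a single-sequence alignment has zero entropy at every column", {
  p <- entropy_profile(make_msa(list(only = "MKVW")))
  expect_equal(p$values, rep(0, 4))
})

test_that("profile is invariant to row order and row duplication", {
  set.seed(502)
  rows <- replicate(12, paste0(sample(c(AA_STANDARD, "-"), 30, replace = TRUE),
                               collapse = ""))
  aln <- msa(paste0("s", 1:12), rows)
  perm <- sample.int(12)
  aln_perm <- msa(paste0("s", 1:12), rows[perm])
  expect_equal(entropy_profile(aln)$values, entropy_profile(aln_perm)$values)
  # duplicating every row leaves the (unweighted) profile unchanged
  aln_dup <- msa(paste0("s", 1:24), c(rows, rows))
  expect_equal(entropy_profile(aln)$values, entropy_profile(aln_dup)$values)
})

test_that("profile agrees with a brute-force implementation on random alignments", {
  set.seed(503)
  for (rep in 1:25) {
    n <- sample(2:15, 1)
    w <- sample(5:40, 1)
    rows <- replicate(n, paste0(sample(c(AA_STANDARD, "-"), w,
                                       replace = TRUE, prob = c(rep(1, 20), 5)),
                                collapse = ""))
    aln <- msa(paste0("s", seq_len(n)), rows)
    got <- entropy_profile(aln)$values
    m <- as.matrix(aln)
    want <- vapply(seq_len(w), function(j) oracle_column_entropy(m[, j]),
                   numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("trim_columns keeps exactly the reference-covered columns", {
  aln <- make_msa(list(ref = "A-C", other = "AAA"), refs = "ref")
  expect_equal(as.integer(trim_columns(aln)), c(1L, 3L))
  gapless <- make_msa(list(ref = "ACD", other = "AAA"), refs = "ref")
  expect_equal(as.integer(trim_columns(gapless)), 1:3)
  # a column covered only by non-reference rows is dropped
  aln2 <- make_msa(list(r1 = "A--", r2 = "-A-", other = "AAA"),
                   refs = c("r1", "r2"))
  expect_equal(as.integer(trim_columns(aln2)), c(1L, 2L))
  expect_error(trim_columns(make_msa(list(a = "AC"))), "reference")
})

test_that("trim_columns ignores reference order and non-reference edits", {
  aln <- make_msa(list(r1 = "A--C", r2 = "-V-C", x = "WWWW"),
                  refs = c("r1", "r2"))
  aln_swapped <- make_msa(list(r2 = "-V-C", r1 = "A--C", x = "WWWW"),
                          refs = c("r2", "r1"))
  aln_edited <- make_msa(list(r1 = "A--C", r2 = "-V-C", x = "--Y-"),
                         refs = c("r1", "r2"))
  expect_equal(as.integer(trim_columns(aln)),
               as.integer(trim_columns(aln_swapped)))
  expect_equal(as.integer(trim_columns(aln)),
               as.integer(trim_columns(aln_edited)))
})

test_that("entropy and mask TSV writers round-trip", {
  aln <- make_msa(list(ref = "A-C", other = "AVC"), refs = "ref")
  p <- entropy_profile(aln)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_entropy_tsv(p, path)
  back <- read.delim(path)
  expect_equal(back$entropy, p$values)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_mask_tsv(trim_columns(aln), mpath)
  expect_equal(read.delim(mpath)$column, c(1L, 3L))
})
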