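occ <- function(o, id = "T", source = "crystal", n_frames = NA_integer_) {
  occurrence_table(id, source,
                   data.frame(chain = "A", resseq = seq_along(o),
                              resname = "ALA", occurrence = o),
                   n_frames = n_frames)
}

test_that("apply_threshold uses the strict o > max(o) * tau rule", {
  t1 <- occ(c(10, 5, 1))
  expect_setequal(apply_threshold(t1, 0.4), c("A:1", "A:2"))
  t2 <- occ(c(10, 4, 1))
  expect_setequal(apply_threshold(t2, 0.4), "A:1")     # 4 > 4 is false
  t3 <- occ(rep(7, 5))
  expect_length(apply_threshold(t3, 0.9), 5L)          # max always survives
  expect_error(apply_threshold(t1, 0), "strictly between")
  expect_error(apply_threshold(t1, 1), "strictly between")
})

test_that("thresholding is antitone in tau", {
  set.seed(801)
  for (i in 1:100) {
    tab <- random_occurrence_table("T", n = sample(3:15, 1))
    taus <- sort(runif(2, 0.01, 0.99))
    lo <- apply_threshold(tab, taus[1])
    hi <- apply_threshold(tab, taus[2])
    expect_true(all(hi %in% lo))
  }
})

test_that("occurrence_table enforces its invariants", {
  expect_error(occ(c(0, 3)), ">= 1")
  expect_error(occ(c(3, 5), source = "md"), "n_frames")
  expect_error(occ(c(3, 50), source = "md", n_frames = 10), "exceeds")
  ok <- occ(c(3, 5), source = "md", n_frames = 10)
  expect_equal(ok$n_frames, 10)
})

test_that("Jaccard distance follows the set formula", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a", "b"), c("c", "d")), 1)
  expect_equal(jaccard_distance(c("r1", "r2", "r3"), c("r2", "r3", "r4")), 0.5)
  expect_error(jaccard_distance(character(), character()), "undefined")
})

test_that("Jaccard metric axioms hold exhaustively on a 6-element universe", {
  universe <- letters[1:6]
  subsets <- lapply(0:63, function(m) universe[bitwAnd(m, 2^(0:5)) > 0])
  n <- length(subsets)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (length(subsets[[i]]) == 0 && length(subsets[[j]]) == 0) next
    d[i, j] <- jaccard_distance(subsets[[i]], subsets[[j]])
  }
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))                              # symmetry
  expect_equal(diag(d), rep(0, n))                   # identity
  off <- d[-1, -1]                                   # distinct non-empty sets
  expect_true(all(off[row(off) != col(off)] > 0))
  triangle_ok <- vapply(seq_len(n), function(k) {    # d_ij <= d_ik + d_kj
    all(d <= outer(d[, k], d[k, ], `+`) + 1e-12)
  }, logical(1))
  expect_true(all(triangle_ok))
})

test_that("the dual-threshold grid has 361 cells and finds the optimum", {
  expect_equal(length(tau_grid())^2, 361L)
  a <- occ(c(40, 30, 20, 5, 2))
  sc <- scan_thresholds(a, a)
  expect_equal(sc$d_min, 0)
  expect_equal(dim(sc$grid), c(19L, 19L))
  expect_true(sc$tau_a %in% tau_grid() && sc$tau_b %in% tau_grid())
})

test_that("grid ties break toward the lexicographically smallest taus", {
  a <- occ(c(10, 10, 10))
  b <- occ(c(7, 7, 7))
  sc <- scan_thresholds(a, b)   # every cell gives d = 0
  expect_equal(sc$d_min, 0)
  expect_equal(c(sc$tau_a, sc$tau_b), c(0.05, 0.05))
})

test_that("scan_thresholds equals the brute-force oracle on random tables", {
  set.seed(802)
  for (i in 1:30) {
    a <- random_occurrence_table("A", n = 10)
    b <- random_occurrence_table("B", n = 10)
    got <- scan_thresholds(a, b)
    want <- oracle_scan(a, b)
    expect_equal(got$d_min, want$d)
    expect_equal(got$tau_a, want$ta)
    expect_equal(got$tau_b, want$tb)
  }
})

test_that("match_tunnels pairs a single crystal/MD pair directly", {
  a <- occ(c(30, 20, 10), id = "C1")
  b <- occ(c(900, 600, 200), id = "M1", source = "md", n_frames = 1000)
  m <- match_tunnels(list(a), list(b))
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$distance, scan_thresholds(a, b)$d_min)
  expect_length(m$unpaired_crystal, 0)
})

test_that("matching is invariant to input table order", {
  set.seed(803)
  g <- gen_occurrence_tables(n_tunnels = 3, seed = 803)
  m1 <- match_tunnels(g$crystal, g$md)
  m2 <- match_tunnels(rev(g$crystal), rev(g$md))
  key <- function(p) sort(paste(p$crystal_id, p$md_id))
  expect_equal(key(m1$pairs), key(m2$pairs))
})

test_that("planted correspondences are recovered under fringe noise", {
  hits <- 0L
  for (s in 1:20) {
    g <- gen_occurrence_tables(n_tunnels = 4, noise = 0.1, seed = 9000 + s)
    m <- match_tunnels(g$crystal, g$md)
    got <- m$pairs[order(m$pairs$crystal_id), c("crystal_id", "md_id")]
    rownames(got) <- NULL
    want <- g$pairing[order(g$pairing$crystal_id), ]
    rownames(want) <- NULL
    if (identical(got, want)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("occurrence tables round-trip through TSV", {
  g <- gen_occurrence_tables(n_tunnels = 2, seed = 804)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_occurrence_tsv(c(g$crystal, g$md), path)
  back <- read_occurrence_tsv(path)
  expect_length(back, 4L)
  expect_equal(back[["T1"]]$residues$occurrence,
               g$crystal[[1]]$residues$occurrence)
  expect_equal(back[[g$md[[1]]$tunnel_id]]$n_frames, g$md[[1]]$n_frames)
})
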