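test_that("median distance follows the strict sign rule", {
  expect_equal(median_distance(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)), -0.3)
  expect_equal(median_distance(c(0.2, 0.5), c(0.5, 0.2)), 0)
  expect_equal(median_distance(0.9, 0.1), 0.8)
  expect_error(median_distance(numeric(), c(0.1)), "empty")
})

test_that("median distance is antisymmetric", {
  set.seed(701)
  for (i in 1:50) {
    a <- runif(sample(1:30, 1)); b <- runif(sample(1:30, 1))
    expect_equal(median_distance(a, b), -median_distance(b, a))
  }
})

test_that("Epps-Singleton statistic matches the reference values", {
  # frozen from scipy.stats.epps_singleton_2samp on the same inputs
  x1 <- sqrt(1:20); y1 <- log(1:25)
  r1 <- epps_singleton_test(x1, y1)
  expect_equal(r1$statistic, 16.305181483054383, tolerance = 1e-8)
  expect_equal(r1$pvalue, 0.0026358389484193233, tolerance = 1e-8)

  x2 <- rep(c(0.1, 0.2, 0.9), 10); y2 <- seq(0.05, 0.95, length.out = 15)
  r2 <- epps_singleton_test(x2, y2)
  expect_equal(r2$statistic, 20.24461278676334, tolerance = 1e-8)
  expect_equal(r2$pvalue, 0.00044682045237189066, tolerance = 1e-8)

  x3 <- sin(1:60)^2; y3 <- sin((1:80) + 0.3)^2 + 0.1
  r3 <- epps_singleton_test(x3, y3)
  expect_equal(r3$statistic, 13.001524705360247, tolerance = 1e-8)
  expect_equal(r3$pvalue, 0.011268346368865005, tolerance = 1e-8)
})

test_that("Epps-Singleton edge behaviour: identity, symmetry, separation", {
  set.seed(702)
  x <- runif(50)
  same <- epps_singleton_test(x, x)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$pvalue, 1, tolerance = 1e-10)
  y <- runif(60)
  ab <- epps_singleton_test(x, y); ba <- epps_singleton_test(y, x)
  expect_equal(ab$statistic, ba$statistic, tolerance = 1e-10)
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-10)
  lo <- 0.05 + rnorm(100, sd = 0.01); hi <- 0.95 + rnorm(100, sd = 0.01)
  expect_lt(epps_singleton_test(lo, hi)$pvalue, 0.001)
})

test_that("Epps-Singleton returns missing markers, not errors, when degenerate", {
  small <- epps_singleton_test(c(0.1, 0.2, 0.3), runif(30))
  expect_true(is.na(small$statistic))
  expect_match(small$reason, "sample size")
  const <- epps_singleton_test(rep(0.5, 30), rep(0.5, 40))
  expect_true(is.na(const$pvalue))
  expect_match(const$reason, "interquartile")
})

test_that("classify_compartment labels planted compartments correctly", {
  set.seed(703)
  g <- gen_msa(n_seqs = 300, n_cols = 200, seed = 703)
  prof <- entropy_profile(g$msa)
  mask <- trim_columns(g$msa)
  cons <- intersect(which(g$truth$class == "conserved"), as.integer(mask))
  vari <- intersect(which(g$truth$class == "variable"), as.integer(mask))
  rc <- classify_compartment("planted_cons", cons,
                             background_columns(mask, cons), prof)
  expect_equal(rc$label, "conserved")
  expect_lt(rc$median_distance, 0)
  expect_lt(rc$es_pvalue, 0.05)
  rv <- classify_compartment("planted_var", vari,
                             background_columns(mask, vari), prof)
  expect_equal(rv$label, "variable")
  expect_gt(rv$median_distance, 0)
  expect_lt(rv$es_pvalue, 0.05)
})

test_that("a random compartment drawn from the background is null-like", {
  set.seed(704)
  md <- numeric(200); pv <- numeric(200)
  g <- gen_msa(n_seqs = 150, n_cols = 250, seed = 704)
  prof <- entropy_profile(g$msa)
  mask <- trim_columns(g$msa)
  for (i in 1:200) {
    comp <- sample(as.integer(mask), 40)
    r <- classify_compartment("rand", comp, background_columns(mask, comp),
                              prof)
    md[i] <- r$median_distance
    pv[i] <- r$es_pvalue
  }
  expect_lt(abs(median(md)), 0.05)
  # p-values roughly uniform: type-I near nominal at 0.05
  expect_gt(mean(pv < 0.05), 0.005)
  expect_lt(mean(pv < 0.05), 0.15)
})

test_that("subgroup residue sets are disjoint and union to the compartment", {
  set.seed(705)
  g <- gen_msa(n_seqs = 60, n_cols = 120, seed = 705)
  s <- gen_structure(g$msa, g$truth, seed = 706)
  prof <- entropy_profile(g$msa)
  mask <- trim_columns(g$msa)
  mp <- map_structure_to_msa(s$structure, g$msa, "REF1")
  rep <- compartment_variability(s$compartments, mp, s$annotations, prof, mask)
  for (nm in unique(rep$name)) {
    rows <- rep[rep$name == nm, ]
    n_all <- rows$n_comp[rows$subgroup == "all"]
    expect_equal(rows$n_comp[rows$subgroup == "no_surface"] +
                   rows$n_comp[rows$subgroup == "surface_only"], n_all)
  }
  # an empty subgroup still yields a row, with missing markers
  empty_rows <- rep[rep$n_comp == 0, ]
  if (nrow(empty_rows) > 0) {
    expect_true(all(is.na(empty_rows$es_pvalue)))
  }
})

test_that("cdf_pairing matches values by closest empirical CDF", {
  # identical lists pair each value with itself
  v <- c(0.1, 0.4, 0.7)
  p <- cdf_pairing(v, v)
  expect_equal(p$bg_val, sort(v))
  # single tunnel value at CDF 1.0 prefers the background value at CDF 1.0
  p2 <- cdf_pairing(0.2, c(0.1, 0.5))
  expect_equal(p2$bg_val, 0.5)
  # output length equals the tunnel length
  set.seed(707)
  p3 <- cdf_pairing(runif(7), runif(20))
  expect_equal(nrow(p3), 7L)
  expect_equal(anyDuplicated(paste(p3$bg_val, p3$bg_cdf)), 0L)
  expect_error(cdf_pairing(numeric(), 1), "empty")
  expect_error(cdf_pairing(runif(5), runif(3)), "without replacement")
})
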