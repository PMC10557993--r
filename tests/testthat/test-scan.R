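planted_xor_data <- function(n = 4000, seed = 41) {
  set.seed(seed)
  a <- rbinom(n, 1, 0.5)
  b <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(a == 1, b == 1))
  flip <- rbinom(n, 1, 0.05) == 1
  y[flip] <- 1L - y[flip]
  data.frame(a = a, b = b, y = y,
             z1 = rbinom(n, 1, 0.2), z2 = rbinom(n, 1, 0.3))
}

test_that("triangle filter keeps pairwise-quiet triples and drops loud ones", {
  d <- planted_xor_data()
  cand <- triangle_filter(d, 0.05)
  keys <- paste(cand$var_a, cand$var_b, cand$var_c)
  expect_true("a b y" %in% keys)
  expect_true(all(cand$mi_ab < 0.05 & cand$mi_ac < 0.05 & cand$mi_bc < 0.05))
  # labels sorted within rows, rows lexicographic
  expect_true(all(cand$var_a < cand$var_b & cand$var_b < cand$var_c))
  expect_identical(keys, sort(keys))

  # a duplicated column has MI = H > threshold with its twin: triples excluded
  d$a2 <- d$a
  cand2 <- triangle_filter(d, 0.05)
  expect_false(any(cand2$var_a == "a" & cand2$var_b == "a2"))
  # Inf threshold keeps every combination
  expect_equal(nrow(triangle_filter(d, Inf)), choose(ncol(d), 3))
  expect_error(triangle_filter(d[, 1:2]), "at least 3")
})

test_that("permutation p-values are deterministic and order-invariant", {
  d <- planted_xor_data()
  r1 <- permutation_pvalue(d, c("a", "b", "y"), permutations = 200, seed = 5)
  r2 <- permutation_pvalue(d, c("a", "b", "y"), permutations = 200, seed = 5)
  expect_identical(r1, r2)
  r3 <- permutation_pvalue(d, c("y", "a", "b"), permutations = 200, seed = 5)
  expect_equal(r3$p_value, r1$p_value)
  expect_equal(r3$omega, r1$omega, tolerance = 1e-12)
  # planted XOR is detected at the smallest achievable p
  expect_equal(r1$p_value, 1 / 201)
  expect_lt(r1$omega, -0.5)
  expect_error(permutation_pvalue(d, c("a", "b")), "three distinct")
  expect_error(permutation_pvalue(d, c("a", "a", "b")), "three distinct")
  expect_error(permutation_pvalue(d, c("a", "b", "y"), permutations = 10),
               "at least 99")
})

test_that("counts and shuffle engines draw the same null distribution", {
  d <- planted_xor_data(n = 1500, seed = 43)
  rc <- permutation_pvalue(d, c("a", "z1", "z2"), permutations = 2000,
                           seed = 7, engine = "counts")
  rs <- permutation_pvalue(d, c("a", "z1", "z2"), permutations = 2000,
                           seed = 7, engine = "shuffle")
  expect_equal(rc$omega, rs$omega, tolerance = 1e-12)
  # same null law, different draws: moments agree within Monte-Carlo error
  expect_lt(abs(rc$null_mean - rs$null_mean),
            4 * sqrt(rc$null_sd^2 + rs$null_sd^2) / sqrt(2000))
  expect_lt(abs(rc$null_sd - rs$null_sd), 0.25 * rc$null_sd)
})

test_that("the permutation test is calibrated on independent columns", {
  set.seed(61)
  hits <- 0L
  reps <- 120L
  for (i in seq_len(reps)) {
    d <- data.frame(a = rbinom(400, 1, 0.3), b = rbinom(400, 1, 0.5),
                    c = rbinom(400, 1, 0.2))
    r <- permutation_pvalue(d, c("a", "b", "c"), permutations = 199, seed = i)
    if (r$p_value <= 0.05) hits <- hits + 1L
  }
  # binomial(120, 0.05) 99.9% upper bound
  expect_lte(hits, 15L)
})

test_that("degenerate (constant) columns are flagged, not tested", {
  d <- data.frame(a = rep(1L, 100), b = rbinom(100, 1, 0.5),
                  c = rbinom(100, 1, 0.5))
  expect_warning(r <- permutation_pvalue(d, c("a", "b", "c")), "degenerate")
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
})

test_that("bh_adjust matches the brute-force oracle", {
  expect_equal(round(bh_adjust(c(0.01, 0.04, 0.03, 0.20)), 4),
               c(0.0400, 0.0533, 0.0533, 0.2000))
  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.02), 0.02)
  expect_length(bh_adjust(numeric()), 0)
  expect_error(bh_adjust(c(0.1, 1.3)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("scan_synergy finds the planted triplet and is reproducible", {
  d <- planted_xor_data()
  scan <- scan_synergy(d, permutations = 500, seed = 3)
  expect_s3_class(scan, "synergy_scan")
  top <- scan[1, ]
  expect_equal(c(top$var_a, top$var_b, top$var_c), c("a", "b", "y"))
  expect_true(top$significant)
  expect_lt(top$o_information_bits, -0.5)
  # every significant triplet is synergistic (Omega < 0): one-sided test
  expect_true(all(scan$o_information_bits[scan$significant] < 0))
  # q-values are sorted and consistent with BH over the candidate p-values
  expect_false(is.unsorted(scan$q_value))
  expect_equal(sort(scan$q_value), sort(bh_adjust(scan$p_value)))
  expect_identical(as.data.frame(scan_synergy(d, permutations = 500, seed = 3)),
                   as.data.frame(scan))

  with_alpha <- scan_synergy(d, permutations = 500, seed = 3, alpha = 0.05)
  expect_true("significant_alpha" %in% names(with_alpha))
  expect_error(scan_synergy(d, fdr_q = 0), "fdr_q")
  expect_error(scan_synergy(d[, 1:2]), "at least 3")
})

test_that("an empty candidate set yields an empty, well-typed scan", {
  d <- data.frame(a = c(0L, 1L, 0L, 1L), b = c(0L, 1L, 0L, 1L),
                  c = c(1L, 0L, 1L, 0L))
  scan <- scan_synergy(d, mi_threshold = 0.01, permutations = 99)
  expect_equal(nrow(scan), 0)
  expect_true(all(c("o_information_bits", "p_value", "q_value", "significant")
                  %in% names(scan)))
})

test_that("conditional profiles show the synergy signature", {
  d <- planted_xor_data(n = 20000, seed = 47)
  prof <- conditional_profile(d, "y", c("a", "b"))
  expect_equal(nrow(prof), 5)
  uncond <- prof$p_target[is.na(prof$a)]
  expect_equal(uncond, mean(d$y))
  # XOR: y is on when exactly one input is on
  on_cells <- prof$p_target[!is.na(prof$a) & xor(prof$a == 1, prof$b == 1)]
  off_cells <- prof$p_target[!is.na(prof$a) & !xor(prof$a == 1, prof$b == 1)]
  expect_true(all(on_cells > 0.9))
  expect_true(all(off_cells < 0.1))

  one <- conditional_profile(d, "y", "a")
  expect_equal(nrow(one), 3)
  # single conditionals sit near the marginal: pairwise invisibility
  expect_true(all(abs(one$p_target - mean(d$y)) < 0.05))

  # empty conditioning cells are NA with n = 0
  d2 <- data.frame(a = c(0L, 0L, 1L, 1L), b = c(0L, 0L, 1L, 1L),
                   y = c(0L, 1L, 0L, 1L))
  prof2 <- conditional_profile(d2, "y", c("a", "b"))
  empty <- prof2[!is.na(prof2$a) & prof2$a != prof2$b, ]
  expect_equal(empty$n, c(0L, 0L))
  expect_true(all(is.na(empty$p_target)))

  expect_error(conditional_profile(d, "y", c("a", "b", "z1")), "one or two")
  expect_error(conditional_profile(d, "y", "y"), "differ")
})
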