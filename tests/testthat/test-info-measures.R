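test_that("entropy matches closed forms", {
  fair <- data.frame(x = c(0L, 1L, 0L, 1L))
  expect_equal(as.numeric(entropy(fair, "x")), 1)
  expect_equal(as.numeric(entropy(data.frame(x = rep(1L, 5)), "x")), 0)
  # binary variable with p = 0.25: -sum(p log2 p)
  quarter <- data.frame(x = c(1L, 0L, 0L, 0L))
  expect_equal(as.numeric(entropy(quarter, "x")),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(entropy(quarter, "x")), 4), 0.8113)
  expect_error(entropy(fair, "zz"), "unknown variable")
})

test_that("mutual information captures the XOR structure exactly", {
  jt <- joint_distribution(xor_network())
  expect_equal(as.numeric(mutual_information(jt, "A", "Y")), 0, tolerance = 1e-12)
  expect_equal(as.numeric(mutual_information(jt, "B", "Y")), 0, tolerance = 1e-12)
  expect_equal(as.numeric(mutual_information(jt, c("A", "B"), "Y")), 1,
               tolerance = 1e-12)
  # symmetry and independence
  expect_equal(as.numeric(mutual_information(jt, "Y", c("A", "B"))), 1,
               tolerance = 1e-12)
  expect_equal(as.numeric(mutual_information(jt, "A", "B")), 0, tolerance = 1e-12)
  expect_error(mutual_information(jt, c("A", "B"), "A"), "disjoint")
})

test_that("total and dual total correlation follow their definitions", {
  jt <- joint_distribution(xor_network())
  expect_equal(as.numeric(total_correlation(jt, c("A", "B", "Y"))), 1,
               tolerance = 1e-12)
  expect_equal(as.numeric(dual_total_correlation(jt, c("A", "B", "Y"))), 2,
               tolerance = 1e-12)

  cj <- copies_joint()
  expect_equal(as.numeric(total_correlation(cj, c("X1", "X2", "X3"))), 2,
               tolerance = 1e-12)

  indep <- bayes_net(list(A = cpt(character(), 0.3), B = cpt(character(), 0.6)))
  ji <- joint_distribution(indep)
  expect_equal(as.numeric(total_correlation(ji, c("A", "B"))), 0, tolerance = 1e-12)
  expect_equal(as.numeric(dual_total_correlation(ji, c("A", "B"))), 0,
               tolerance = 1e-12)
  expect_error(total_correlation(ji, "A"), "at least 2")
})

test_that("O-information separates synergy from redundancy", {
  jt <- joint_distribution(xor_network())
  expect_equal(as.numeric(o_information(jt, c("A", "B", "Y"))), -1,
               tolerance = 1e-12)
  expect_equal(as.numeric(o_information(copies_joint(), c("X1", "X2", "X3"))), 1,
               tolerance = 1e-12)
  indep3 <- bayes_net(list(A = cpt(character(), 0.3),
                           B = cpt(character(), 0.6),
                           C = cpt(character(), 0.5)))
  expect_equal(as.numeric(o_information(joint_distribution(indep3), c("A", "B", "C"))),
               0, tolerance = 1e-12)
  expect_error(o_information(jt, c("A", "B")), "at least 3")
})

test_that("O-information equals TC minus DTC on arbitrary joints", {
  set.seed(31)
  for (rep in 1:10) {
    p <- stats::runif(8)
    p <- p / sum(p)
    states <- as.matrix(expand.grid(rep(list(0:1), 3))[, 3:1])
    jt <- joint_table(c("a", "b", "c"), states, p)
    expect_equal(
      as.numeric(o_information(jt, c("a", "b", "c"))),
      as.numeric(total_correlation(jt, c("a", "b", "c"))) -
        as.numeric(dual_total_correlation(jt, c("a", "b", "c"))),
      tolerance = 1e-12
    )
  }
})

test_that("whole-minus-sum synergy is 1 bit for XOR and non-positive for a copy", {
  jt <- joint_distribution(xor_network())
  expect_equal(as.numeric(wms_synergy(jt, c("A", "B"), "Y")), 1, tolerance = 1e-12)

  copy_net <- bayes_net(list(
    A = cpt(character(), 0.5), B = cpt(character(), 0.5),
    Y = cpt(c("A", "B"), c(0, 0, 1, 1))  # Y copies A
  ))
  expect_lte(as.numeric(wms_synergy(joint_distribution(copy_net), c("A", "B"), "Y")),
             1e-12)

  indep_y <- bayes_net(list(
    A = cpt(character(), 0.5), B = cpt(character(), 0.5),
    Y = cpt(character(), 0.4)
  ))
  expect_equal(as.numeric(wms_synergy(joint_distribution(indep_y), c("A", "B"), "Y")),
               0, tolerance = 1e-12)
  expect_error(wms_synergy(jt, c("A", "A"), "Y"), "distinct")
})

test_that("plug-in estimates converge to exact values", {
  net <- xor_network()
  d <- as.data.frame(sample_network(net, 100000, seed = 2))
  expect_equal(as.numeric(o_information(d, c("A", "B", "Y"))), -1, tolerance = 0.005)
  expect_equal(as.numeric(mutual_information(d, c("A", "B"), "Y")), 1,
               tolerance = 0.005)
  expect_lt(abs(as.numeric(mutual_information(d, "A", "Y"))), 0.005)
  expect_identical(attr(entropy(d, "A"), "estimator"), "plugin")
  expect_identical(attr(entropy(joint_distribution(net), "A"), "estimator"),
                   "exact")
})

test_that("entropy rejects missing data and supports Miller-Madow", {
  d <- data.frame(x = c(0L, 1L, NA, 1L))
  expect_error(entropy(d, "x"), "missing")
  d2 <- data.frame(x = c(0L, 1L, 0L, 1L))
  expect_gt(as.numeric(entropy(d2, "x", correction = "miller-madow")),
            as.numeric(entropy(d2, "x")))
})

test_that("mi_matrix is symmetric with zero diagonal and detects copies", {
  d <- data.frame(a = c(0L, 1L, 0L, 1L, 1L, 0L),
                  b = c(0L, 1L, 0L, 1L, 1L, 0L),
                  c = c(1L, 0L, 0L, 1L, 0L, 1L))
  m <- mi_matrix(d)
  expect_equal(unclass(m), t(unclass(m)), tolerance = 1e-12)
  expect_equal(unname(diag(m)), rep(0, 3))
  # duplicated column pair: MI(X; X) = H(X)
  expect_equal(m["a", "b"], as.numeric(entropy(d, "a")), tolerance = 1e-12)

  set.seed(5)
  ind <- as.data.frame(matrix(rbinom(10000 * 4, 1, 0.3), ncol = 4,
                              dimnames = list(NULL, paste0("v", 1:4))))
  mi <- mi_matrix(ind)
  expect_lt(max(mi[upper.tri(mi)]), 0.01)
})

test_that("mi matrix round-trips through TSV and tidies to long form", {
  d <- data.frame(a = c(0L, 1L, 0L, 1L), b = c(1L, 1L, 0L, 0L),
                  c = c(1L, 0L, 1L, 0L))
  m <- mi_matrix(d)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mi_matrix(m, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$label, colnames(m))
  expect_equal(back$a, unname(round(m[, "a"], 6)))
  long <- tidy(m)
  expect_equal(nrow(long), 3)
  expect_equal(long$mi_bits[long$var_a == "a" & long$var_b == "b"], m["a", "b"])
})
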