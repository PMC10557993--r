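test_that("validation reports cycles, incomplete CPTs and out-of-range rows", {
  expect_length(validate_network(xor_network()), 0)
  expect_length(validate_network(build_reference_network("optimized")), 0)

  two_cycle <- bayes_net(list(
    S2 = cpt("S3", c(0.2, 0.8)),
    S3 = cpt("S2", c(0.1, 0.9))
  ))
  v <- validate_network(two_cycle)
  expect_length(v, 1)
  expect_match(v, "cycle")
  expect_match(v, "S2")
  expect_match(v, "S3")

  bad_prob <- bayes_net(list(A = cpt(character(), 1.2)))
  v <- validate_network(bad_prob)
  expect_length(v, 1)
  expect_match(v, "out of \\[0, 1\\]")

  short_cpt <- bayes_net(list(
    A = cpt(character(), 0.5),
    B = cpt("A", 0.5)  # needs two rows
  ))
  expect_match(validate_network(short_cpt), "expected 2")
})

test_that("topological order puts parents first with lexicographic ties", {
  net <- build_reference_network("optimized")
  ord <- topological_order(net)
  expect_equal(ord[1:2], c("S1", "S2"))
  expect_identical(ord, topological_order(net))
  for (nm in net$nodes) {
    for (p in net$cpts[[nm]]$parents) {
      expect_lt(match(p, ord), match(nm, ord))
    }
  }
  expect_equal(topological_order(bayes_net(list(A = cpt(character(), 0.5)))), "A")
  expect_equal(topological_order(chain_network()), c("S2", "S3", "D3"))
  expect_error(topological_order(bayes_net(list(
    A = cpt("B", c(0, 1)), B = cpt("A", c(0, 1))
  ))), "cycle")
})

test_that("joint distribution multiplies CPT factors and normalises", {
  single <- bayes_net(list(S = cpt(character(), 0.3)))
  jt <- joint_distribution(single)
  expect_equal(jt$prob, c(0.7, 0.3))

  pair <- bayes_net(list(A = cpt(character(), 0.5), B = cpt(character(), 0.5)))
  expect_equal(joint_distribution(pair)$prob, rep(0.25, 4))

  # XOR gadget: four equally likely consistent states, four impossible ones
  jt <- joint_distribution(xor_network())
  expect_equal(sum(jt$prob), 1, tolerance = 1e-12)
  consistent <- xor(jt$states[, "A"] == 1, jt$states[, "B"] == 1) ==
    (jt$states[, "Y"] == 1)
  expect_equal(jt$prob[consistent], rep(0.25, 4))
  expect_equal(jt$prob[!consistent], rep(0, 4))

  big <- bayes_net(setNames(
    lapply(1:21, function(i) cpt(character(), 0.5)),
    paste0("N", sprintf("%02d", 1:21))
  ))
  expect_error(joint_distribution(big), "sample_network")
})

test_that("marginals match priors and closed forms", {
  single <- bayes_net(list(S = cpt(character(), 0.3)))
  expect_equal(marginals(joint_distribution(single)), c(S = 0.3))
  # XOR of fair inputs is maximally uncertain
  expect_equal(unname(marginals(joint_distribution(xor_network()))["Y"]), 0.5)
  # OR of two independent fair bits
  or_net <- bayes_net(list(
    A = cpt(character(), 0.5), B = cpt(character(), 0.5),
    Y = cpt(c("A", "B"), c(0, 1, 1, 1))
  ))
  expect_equal(unname(marginals(joint_distribution(or_net))["Y"]), 0.75)
})

test_that("ancestral sampling is reproducible and matches the joint law", {
  net <- build_reference_network("optimized")
  s1 <- sample_network(net, 200, seed = 11)
  s2 <- sample_network(net, 200, seed = 11)
  expect_identical(as.data.frame(s1), as.data.frame(s2))

  s <- sample_network(net, 100000, seed = 4)
  m_exact <- marginals(joint_distribution(net))
  for (nm in names(m_exact)) {
    se <- sqrt(m_exact[nm] * (1 - m_exact[nm]) / nrow(s))
    expect_lt(abs(mean(s[[nm]]) - m_exact[nm]), 4 * se + 1e-12)
  }

  # deterministic OR: D1 active whenever S1 is
  expect_true(all(s$D1[s$S1 == 1] == 1))

  expect_error(sample_network(net, 0, seed = 1), "count")
  expect_error(sample_network(net, 10, seed = "x"), "seed")
})

test_that("recorded noises reconstruct every sampled state exactly", {
  net <- build_reference_network("optimized")
  s <- sample_network(net, 25, seed = 9)
  for (i in seq_len(nrow(s))) {
    expect_true(check_realization(net, realization(s, i)))
  }
})
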