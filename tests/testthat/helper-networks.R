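# small fixture networks used across test files

xor_network <- function(p_a = 0.5, p_b = 0.5) {
  bayes_net(list(
    A = cpt(character(), p_a),
    B = cpt(character(), p_b),
    Y = cpt(c("A", "B"), c(0, 1, 1, 0))
  ))
}

# three perfectly redundant copies of one fair bit
copies_joint <- function() {
  states <- as.matrix(expand.grid(rep(list(0:1), 3))[, 3:1])
  prob <- ifelse(rowSums(states) %in% c(0, 3), 0.5, 0)
  joint_table(c("X1", "X2", "X3"), states, prob)
}

chain_network <- function() {
  bayes_net(list(
    S2 = cpt(character(), 0.5),
    S3 = cpt("S2", c(0.1, 0.9)),
    D3 = cpt("S3", c(0.05, 0.95))
  ))
}

# reference realization with every sign active, consistent with both
# reference-network variants (roots on, S3 on but fragile to do(S2 = 0),
# S4/S6 on through their canonical CPTs, diseases on through the OR gates)
all_active_realization <- function() {
  new_realization(
    states = c(S1 = 1L, S2 = 1L, S3 = 1L, S4 = 1L, S5 = 1L, S6 = 1L,
               D1 = 1L, D2 = 1L, D3 = 1L),
    noises = c(S1 = 0.01, S2 = 0.01, S5 = 0.01, S3 = 0.05, S4 = 0.45,
               S6 = 0.45, D1 = 0.5, D2 = 0.5, D3 = 0.5)
  )
}

# brute-force Benjamini-Hochberg step-up, the independent oracle for bh_adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
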