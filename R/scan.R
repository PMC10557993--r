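#' Filter candidate triplets by low dyadic mutual information
#'
#' Pairwise association analyses are blind to variable triples whose members
#' are pairwise (nearly) independent; those are exactly the triples where
#' higher-order structure can hide. This filter keeps every unordered triple
#' whose three pairwise plug-in MIs are each strictly below `mi_threshold`.
#'
#' @param data Data frame of 0/1 columns (at least three).
#' @param mi_threshold Pairwise MI threshold in bits (default 0.05).
#' @return Tibble with columns `var_a`, `var_b`, `var_c` (labels sorted within
#'   each row, rows in lexicographic order) and the three pairwise MIs
#'   `mi_ab`, `mi_ac`, `mi_bc`.
#' @export
triangle_filter <- function(data, mi_threshold = 0.05) {
  check_binary_data(data)
  if (ncol(data) < 3L) abort("`data` must have at least 3 columns.")
  if (mi_threshold < 0) abort("`mi_threshold` must be >= 0.")
  mim <- unclass(mi_matrix(data))
  labs <- sort(colnames(mim))
  trips <- utils::combn(labs, 3L)
  keep <- apply(trips, 2L, function(t) {
    mim[t[1], t[2]] < mi_threshold &&
      mim[t[1], t[3]] < mi_threshold &&
      mim[t[2], t[3]] < mi_threshold
  })
  trips <- trips[, keep, drop = FALSE]
  tibble::tibble(
    var_a = trips[1, ], var_b = trips[2, ], var_c = trips[3, ],
    mi_ab = mim[cbind(trips[1, ], trips[2, ])],
    mi_ac = mim[cbind(trips[1, ], trips[3, ])],
    mi_bc = mim[cbind(trips[2, ], trips[3, ])]
  )
}

# O-information (bits) of a triplet from its 2x2x2 cell counts.
# `cells` is a B x 8 matrix in the order
# (111, 110, 101, 100, 011, 010, 001, 000) for bits (a, b, c).
omega_from_cells <- function(cells) {
  n <- rowSums(cells)
  h_abc <- row_entropy_counts(cells)
  a1 <- cells[, 1] + cells[, 2] + cells[, 3] + cells[, 4]
  b1 <- cells[, 1] + cells[, 2] + cells[, 5] + cells[, 6]
  c1 <- cells[, 1] + cells[, 3] + cells[, 5] + cells[, 7]
  h_a <- row_entropy_counts(cbind(a1, n - a1))
  h_b <- row_entropy_counts(cbind(b1, n - b1))
  h_c <- row_entropy_counts(cbind(c1, n - c1))
  h_ab <- row_entropy_counts(cbind(cells[, 1] + cells[, 2],
                                   cells[, 3] + cells[, 4],
                                   cells[, 5] + cells[, 6],
                                   cells[, 7] + cells[, 8]))
  h_ac <- row_entropy_counts(cbind(cells[, 1] + cells[, 3],
                                   cells[, 2] + cells[, 4],
                                   cells[, 5] + cells[, 7],
                                   cells[, 6] + cells[, 8]))
  h_bc <- row_entropy_counts(cbind(cells[, 1] + cells[, 5],
                                   cells[, 2] + cells[, 6],
                                   cells[, 3] + cells[, 7],
                                   cells[, 4] + cells[, 8]))
  # Omega = (n_vars - 2) H(X) + sum_i [H(X_i) - H(X_{-i})], n_vars = 3
  h_abc + (h_a - h_bc) + (h_b - h_ac) + (h_c - h_ab)
}

triplet_cells <- function(a, b, c) {
  idx <- a * 4L + b * 2L + c + 1L          # 000 -> 1 ... 111 -> 8
  counts <- tabulate(idx, nbins = 8L)
  matrix(counts[8:1], nrow = 1)            # reorder to 111 ... 000
}

# Null cell counts under independent row-shuffling of the three columns.
# Shuffling b and c independently against a is equivalent to drawing the
# 2x2x2 table by sequential hypergeometrics given the fixed column totals,
# which costs O(1) per permutation instead of O(n).
null_cells_counts <- function(a, b, c, B) {
  n <- length(a)
  na <- sum(a); nb <- sum(b); nc <- sum(c)
  ab11 <- stats::rhyper(B, na, n - na, nb)
  ab10 <- na - ab11
  ab01 <- nb - ab11
  ab00 <- n - na - nb + ab11
  x111 <- stats::rhyper(B, ab11, n - ab11, nc)
  x101 <- stats::rhyper(B, ab10, n - ab11 - ab10, nc - x111)
  x011 <- stats::rhyper(B, ab01, ab00, nc - x111 - x101)
  x001 <- nc - x111 - x101 - x011
  cbind(x111, ab11 - x111, x101, ab10 - x101,
        x011, ab01 - x011, x001, ab00 - x001)
}

# Null cell counts by explicitly re-shuffling rows; the slow reference
# implementation of the same null, kept as an independent cross-check.
null_cells_shuffle <- function(a, b, c, B) {
  n <- length(a)
  t(vapply(seq_len(B), function(i) {
    triplet_cells(a[sample.int(n)], b[sample.int(n)], c[sample.int(n)])[1, ]
  }, numeric(8)))
}

#' Permutation p-value for a triplet's O-information
#'
#' Tests whether a triplet's observed O-information is more negative (more
#' synergistic) than expected when its three columns are independently
#' row-shuffled, destroying all dependence while preserving each margin. The
#' one-sided p-value is `(1 + #\{Omega_null <= Omega_obs\}) / (B + 1)`; the +1
#' smoothing keeps the test valid at finite B. A two-sided p-value (against
#' `|Omega|`) is reported alongside.
#'
#' @param data Data frame of 0/1 columns.
#' @param triplet Three column labels.
#' @param permutations Number of null draws B (default 1000, minimum 99).
#' @param seed Integer seed. The RNG stream is derived from `seed` and the
#'   sorted triplet labels, so results do not depend on the order in which
#'   triplets are tested.
#' @param engine `"counts"` (default; draws null contingency tables directly,
#'   O(1) per permutation) or `"shuffle"` (explicit row permutation; the slow
#'   reference implementation of the identical null).
#' @return A list: `omega` (observed, bits), `p_value` (one-sided, synergy),
#'   `p_two_sided`, `null_mean`, `null_sd`, `degenerate` (flag).
#' @export
permutation_pvalue <- function(data, triplet, permutations = 1000L, seed = 1L,
                               engine = c("counts", "shuffle")) {
  engine <- match.arg(engine)
  check_binary_data(data)
  check_labels_present(data, triplet)
  if (length(triplet) != 3L || anyDuplicated(triplet)) {
    abort("`triplet` must be three distinct labels.")
  }
  if (permutations < 99L) abort("`permutations` must be at least 99.")
  a <- data[[triplet[1]]]; b <- data[[triplet[2]]]; c <- data[[triplet[3]]]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L || length(unique(c)) < 2L) {
    warn(paste0("triplet (", paste(triplet, collapse = ", "),
                ") contains a constant column; test is degenerate."))
    return(list(omega = 0, p_value = 1, p_two_sided = 1,
                null_mean = 0, null_sd = 0, degenerate = TRUE))
  }
  obs <- omega_from_cells(triplet_cells(a, b, c))
  withr_seed(label_hash(triplet, base_seed = seed))
  cells <- switch(engine,
                  counts = null_cells_counts(a, b, c, permutations),
                  shuffle = null_cells_shuffle(a, b, c, permutations))
  null_omega <- omega_from_cells(cells)
  list(
    omega = obs,
    p_value = (1 + sum(null_omega <= obs)) / (permutations + 1),
    p_two_sided = (1 + sum(abs(null_omega) >= abs(obs))) / (permutations + 1),
    null_mean = mean(null_omega),
    null_sd = stats::sd(null_omega),
    degenerate = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment: sort p-values ascending,
#' take `q_i = min_{j >= i} p_j * m / j`, clip at 1, and restore the input
#' order. Delegates to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Scan a binary data table for synergistic triplets
#'
#' The full pipeline: [triangle_filter()] keeps triples with low dyadic MI
#' (the ones a pairwise network cannot see), each candidate is scored with
#' plug-in O-information and a one-sided permutation p-value
#' ([permutation_pvalue()]), and [bh_adjust()] controls the false discovery
#' rate over the candidate set. A triplet is flagged significant when its
#' q-value is at most `fdr_q`. Because filtering and testing use the same
#' data, the FDR guarantee over the post-selection candidate set is
#' approximate.
#'
#' @param data Data frame of 0/1 columns (at least three).
#' @param mi_threshold Dyadic MI filter threshold in bits (default 0.05).
#' @param permutations Null draws per candidate (default 1000).
#' @param fdr_q FDR level for the significance flag (default 0.15).
#' @param alpha Optional raw adjusted-p cutoff; when supplied, an extra column
#'   `significant_alpha` flags `q_value <= alpha` (e.g. 0.05).
#' @param seed Integer seed.
#' @param engine Permutation engine, see [permutation_pvalue()].
#' @return A tibble of class `synergy_scan`, one row per candidate triplet:
#'   `var_a`, `var_b`, `var_c`, `mi_ab`, `mi_ac`, `mi_bc`,
#'   `o_information_bits`, `p_value`, `q_value`, `significant` (and
#'   `significant_alpha` when `alpha` is given), sorted by `q_value` then
#'   O-information ascending.
#' @export
scan_synergy <- function(data, mi_threshold = 0.05, permutations = 1000L,
                         fdr_q = 0.15, alpha = NULL, seed = 1L,
                         engine = c("counts", "shuffle")) {
  engine <- match.arg(engine)
  if (fdr_q <= 0 || fdr_q >= 1) abort("`fdr_q` must lie in (0, 1).")
  cand <- triangle_filter(data, mi_threshold)
  if (!nrow(cand)) {
    out <- tibble::tibble(var_a = character(), var_b = character(),
                          var_c = character(), mi_ab = numeric(),
                          mi_ac = numeric(), mi_bc = numeric(),
                          o_information_bits = numeric(), p_value = numeric(),
                          q_value = numeric(), significant = logical())
    class(out) <- c("synergy_scan", class(out))
    return(out)
  }
  tests <- purrr::pmap(list(cand$var_a, cand$var_b, cand$var_c),
                       function(a, b, c) {
                         permutation_pvalue(data, c(a, b, c),
                                            permutations = permutations,
                                            seed = seed, engine = engine)
                       })
  out <- cand
  out$o_information_bits <- vapply(tests, `[[`, numeric(1), "omega")
  out$p_value <- vapply(tests, `[[`, numeric(1), "p_value")
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value <= fdr_q
  if (!is.null(alpha)) out$significant_alpha <- out$q_value <= alpha
  out <- dplyr::arrange(out, .data$q_value, .data$o_information_bits)
  attr(out, "config") <- list(mi_threshold = mi_threshold,
                              permutations = permutations,
                              fdr_q = fdr_q, alpha = alpha, seed = seed,
                              n_columns = ncol(data), n_rows = nrow(data))
  class(out) <- c("synergy_scan", class(out))
  out
}

#' Conditional probability profile of a target sign
#'
#' Reports `P(target = 1)` unconditionally and conditioned on every
#' configuration of one or two given variables. In a synergistic triplet the
#' single-variable conditionals stay close to the marginal while the
#' two-variable conditionals move far from it. Empty conditioning cells are
#' reported as `NA` with `n = 0`, never as zero.
#'
#' @param data Data frame of 0/1 columns.
#' @param target Target column label.
#' @param given One or two conditioning column labels.
#' @return A tibble with one row per conditioning configuration (plus the
#'   unconditional row, where the `given` columns are `NA`): the configuration,
#'   `n` (cell size) and `p_target`.
#' @export
conditional_profile <- function(data, target, given) {
  check_binary_data(data)
  check_labels_present(data, c(target, given))
  if (length(given) < 1L || length(given) > 2L) {
    abort("`given` must name one or two variables.")
  }
  if (target %in% given) abort("`target` must differ from `given`.")
  grid <- expand.grid(rep(list(0:1), length(given)))
  names(grid) <- given
  rows <- purrr::pmap(grid, function(...) {
    cfg <- c(...)
    sel <- rep(TRUE, nrow(data))
    for (g in given) sel <- sel & data[[g]] == cfg[[g]]
    tibble::tibble(n = sum(sel),
                   p_target = if (sum(sel) > 0) mean(data[[target]][sel]) else NA_real_)
  })
  out <- dplyr::bind_cols(tibble::as_tibble(grid), dplyr::bind_rows(rows))
  uncond <- tibble::as_tibble(setNames(as.list(rep(NA_integer_, length(given))), given))
  uncond$n <- nrow(data)
  uncond$p_target <- mean(data[[target]])
  out <- dplyr::bind_rows(uncond, out)
  attr(out, "target") <- target
  out
}
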