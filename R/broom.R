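#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Bayesian network into its edge list
#'
#' @param x A [bayes_net()].
#' @param ... Unused.
#' @return A tibble with columns `parent` and `child`, one row per edge.
#' @export
tidy.bayes_net <- function(x, ...) {
  rows <- purrr::map2(names(x$cpts), x$cpts, function(nm, ct) {
    if (length(ct$parents)) tibble::tibble(parent = ct$parents, child = nm)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- tibble::tibble(parent = character(), child = character())
  out
}

#' One-line summary of a Bayesian network
#'
#' @param x A [bayes_net()].
#' @param ... Unused.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `n_roots`, `max_parents`.
#' @export
glance.bayes_net <- function(x, ...) {
  np <- vapply(x$cpts, function(ct) length(ct$parents), integer(1))
  tibble::tibble(n_nodes = length(x$nodes), n_edges = sum(np),
                 n_roots = sum(np == 0L), max_parents = max(np))
}

#' Tidy a joint probability table
#'
#' @param x A [joint_table()].
#' @param ... Unused.
#' @return A tibble with one 0/1 column per variable plus `prob`.
#' @export
tidy.joint_table <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$states))
  out$prob <- x$prob
  out
}

#' Tidy a pairwise MI matrix into long form
#'
#' @param x An `mi_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `var_a`, `var_b`, `mi_bits`, one row per
#'   unordered pair.
#' @export
tidy.mi_matrix <- function(x, ...) {
  m <- unclass(x)
  labs <- rownames(m)
  pairs <- utils::combn(labs, 2L)
  tibble::tibble(var_a = pairs[1, ], var_b = pairs[2, ],
                 mi_bits = m[cbind(pairs[1, ], pairs[2, ])])
}

#' One-line summary of a synergy scan
#'
#' @param x A `synergy_scan` from [scan_synergy()].
#' @param ... Unused.
#' @return A one-row tibble: `n_candidates`, `n_significant`, `min_q`,
#'   `min_omega_bits` plus the scan configuration.
#' @export
glance.synergy_scan <- function(x, ...) {
  cfg <- attr(x, "config") %||% list()
  tibble::tibble(
    n_candidates = nrow(x),
    n_significant = sum(x$significant),
    min_q = if (nrow(x)) min(x$q_value) else NA_real_,
    min_omega_bits = if (nrow(x)) min(x$o_information_bits) else NA_real_,
    mi_threshold = cfg$mi_threshold %||% NA_real_,
    permutations = cfg$permutations %||% NA_integer_,
    fdr_q = cfg$fdr_q %||% NA_real_
  )
}
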