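#' Conditional probability table for a binary node
#'
#' A CPT maps every combination of its parents' binary states to the
#' probability that the node takes state 1. Rows are ordered by the parent
#' bitstring read with the first parent as the most significant bit, i.e.
#' `"00", "01", "10", "11"` for two parents. A root node has no parents and a
#' single row: its prior.
#'
#' @param parents Character vector of parent node labels (may be empty).
#' @param prob1 Numeric vector of length `2^length(parents)`, the probability
#'   of state 1 for each parent-state combination, in bitstring order.
#' @return An object of class `cpt`.
#' @examples
#' cpt(character(), 0.3)                 # root prior P(X = 1) = 0.3
#' cpt(c("A", "B"), c(0, 1, 1, 0))       # XOR of A and B
#' @export
cpt <- function(parents, prob1) {
  parents <- as.character(parents)
  prob1 <- as.numeric(prob1)
  structure(list(parents = parents, prob1 = prob1), class = "cpt")
}

#' @export
print.cpt <- function(x, ...) {
  k <- length(x$parents)
  if (k == 0L) {
    cat("<cpt> root prior P(X=1) =", format(x$prob1), "\n")
  } else {
    cat("<cpt> parents:", paste(x$parents, collapse = ", "), "\n")
    print(setNames(x$prob1, bitstrings(k)))
  }
  invisible(x)
}

#' Binary Bayesian network
#'
#' A directed acyclic graph over binary variables, each carrying a
#' [cpt()]. The network is the generative model: ancestral sampling draws one
#' exogenous uniform noise per node and sets the node to 1 when the noise
#' falls strictly below the CPT probability for its parents' realised states.
#'
#' @param cpts Named list of [cpt()] objects, one per node; names are the node
#'   labels.
#' @return An object of class `bayes_net`.
#' @seealso [validate_network()], [joint_distribution()], [sample_network()]
#' @examples
#' net <- bayes_net(list(
#'   A = cpt(character(), 0.5),
#'   B = cpt(character(), 0.5),
#'   Y = cpt(c("A", "B"), c(0, 1, 1, 0))
#' ))
#' marginals(joint_distribution(net))
#' @export
bayes_net <- function(cpts) {
  if (is.null(names(cpts)) || any(names(cpts) == "")) {
    abort("`cpts` must be a fully named list (names are node labels).")
  }
  structure(list(nodes = names(cpts), cpts = cpts), class = "bayes_net")
}

#' @export
print.bayes_net <- function(x, ...) {
  edges <- tidy(x)
  cat("<bayes_net> ", length(x$nodes), " nodes, ", nrow(edges), " edges\n",
      sep = "")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a Bayesian network
#'
#' Checks structural and numerical invariants: unique non-empty labels, every
#' parent exists, each CPT has exactly `2^n_parents` probabilities all in
#' \[0, 1\], and the parent relation is acyclic. Violations are returned, not
#' raised, so a network can be audited in one pass.
#'
#' @param net A [bayes_net()].
#' @return Character vector of violation descriptions; empty if the network is
#'   well formed.
#' @export
validate_network <- function(net) {
  violations <- character()
  nodes <- net$nodes
  if (any(!nzchar(nodes))) violations <- c(violations, "empty node label")
  if (anyDuplicated(nodes)) {
    violations <- c(violations,
                    paste0("duplicate node label: ",
                           paste(unique(nodes[duplicated(nodes)]), collapse = ", ")))
  }
  for (nm in nodes) {
    ct <- net$cpts[[nm]]
    if (is.null(ct)) {
      violations <- c(violations, paste0("node ", nm, " has no CPT"))
      next
    }
    unknown <- setdiff(ct$parents, nodes)
    if (length(unknown)) {
      violations <- c(violations,
                      paste0("node ", nm, " has unknown parent(s): ",
                             paste(unknown, collapse = ", ")))
    }
    want <- 2^length(ct$parents)
    if (length(ct$prob1) != want) {
      violations <- c(violations,
                      paste0("node ", nm, " CPT has ", length(ct$prob1),
                             " rows, expected ", want))
    }
    bad <- !is.finite(ct$prob1) | ct$prob1 < 0 | ct$prob1 > 1
    if (any(bad)) {
      violations <- c(violations,
                      paste0("node ", nm, " CPT probability out of [0, 1] in row(s) ",
                             paste(bitstrings(length(ct$parents))[bad], collapse = ", ")))
    }
  }
  cyc <- find_cycle(net)
  if (!is.null(cyc)) {
    violations <- c(violations,
                    paste0("cycle involving {", paste(cyc, collapse = ","), "}"))
  }
  violations
}

# returns the node set of one cycle, or NULL if acyclic (Kahn's algorithm)
find_cycle <- function(net) {
  nodes <- net$nodes
  parents <- lapply(net$cpts, function(ct) intersect(ct$parents, nodes))
  names(parents) <- nodes
  remaining <- nodes
  repeat {
    free <- remaining[vapply(remaining, function(n)
      length(intersect(parents[[n]], remaining)) == 0L, logical(1))]
    if (!length(free)) break
    remaining <- setdiff(remaining, free)
  }
  if (length(remaining)) sort(remaining) else NULL
}

#' Topological order of a network's nodes
#'
#' Every node appears after all of its parents; among simultaneously available
#' nodes, ties are broken lexicographically by label so the order is fully
#' reproducible.
#'
#' @param net A [bayes_net()].
#' @return Character vector of node labels in topological order.
#' @export
topological_order <- function(net) {
  cyc <- find_cycle(net)
  if (!is.null(cyc)) {
    abort(paste0("network contains a cycle involving {",
                 paste(cyc, collapse = ","), "}"))
  }
  nodes <- net$nodes
  parents <- lapply(net$cpts, function(ct) ct$parents)
  names(parents) <- nodes
  placed <- character()
  remaining <- nodes
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(n)
      all(parents[[n]] %in% placed), logical(1))]
    nxt <- sort(free)[1L]
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  placed
}

#' Exact joint distribution of a binary network
#'
#' Enumerates all `2^K` joint states and multiplies the CPT factors, giving
#' the exact joint probability table. Enumeration is capped at 20 nodes
#' (about a million states); larger networks should be analysed by sampling.
#'
#' @param net A [bayes_net()].
#' @return An object of class `joint_table` with fields `variables` (labels in
#'   topological order), `states` (a `2^K x K` 0/1 matrix) and `prob`.
#' @export
joint_distribution <- function(net) {
  v <- validate_network(net)
  if (length(v)) abort(paste0("invalid network: ", paste(v, collapse = "; ")))
  ord <- topological_order(net)
  k <- length(ord)
  if (k > 20L) {
    abort(paste0("exact enumeration over ", k, " nodes (", 2^k,
                 " states) refused; use sample_network() instead."))
  }
  states <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  colnames(states) <- ord
  prob <- rep(1, nrow(states))
  for (nm in ord) {
    ct <- net$cpts[[nm]]
    row <- if (length(ct$parents)) {
      bit_index(states[, ct$parents, drop = FALSE])
    } else rep(1L, nrow(states))
    p1 <- ct$prob1[row]
    prob <- prob * ifelse(states[, nm] == 1L, p1, 1 - p1)
  }
  joint_table(ord, states, prob)
}

#' Construct a joint probability table
#'
#' @param variables Character vector of variable labels.
#' @param states A `2^K x K` matrix of 0/1 states (columns in `variables`
#'   order).
#' @param prob Probability of each state; must be non-negative and sum to 1
#'   within `1e-9`.
#' @return A `joint_table`.
#' @export
joint_table <- function(variables, states, prob) {
  states <- as.matrix(states)
  if (nrow(states) != 2^length(variables) || ncol(states) != length(variables)) {
    abort("`states` must be a 2^K x K matrix over the K variables.")
  }
  if (any(prob < 0)) abort("joint probabilities must be non-negative.")
  if (abs(sum(prob) - 1) > 1e-9) {
    abort("joint probabilities must sum to 1 (within 1e-9).")
  }
  colnames(states) <- variables
  structure(list(variables = variables, states = states, prob = as.numeric(prob)),
            class = "joint_table")
}

#' @export
print.joint_table <- function(x, ...) {
  cat("<joint_table> over", length(x$variables), "variables:",
      paste(x$variables, collapse = ", "), "\n")
  print(utils::head(tidy(x), 8L))
  invisible(x)
}

#' Marginal probabilities of state 1
#'
#' @param joint A [joint_table()].
#' @return Named numeric vector: for each variable, the probability it equals
#'   1 under the joint distribution.
#' @export
marginals <- function(joint) {
  stopifnot(inherits(joint, "joint_table"))
  colSums(joint$states * joint$prob)
}

#' Sample realizations from a network
#'
#' Ancestral sampling in topological order. Each node draws a single uniform
#' exogenous noise; the node is 1 exactly when its noise is strictly below the
#' CPT probability given its parents' realised states. Noises are recorded so
#' that counterfactual (hard) interventions can replay the same individual
#' under altered conditions (see [do_intervention()]).
#'
#' @param net A [bayes_net()].
#' @param n Number of realizations (at least 1).
#' @param seed Integer seed; required, so every draw is reproducible.
#' @return A tibble with one row per realization and one 0/1 column per node
#'   (topological order), of class `bn_sample`. The matching exogenous noises
#'   are stored in `attr(x, "noises")`.
#' @export
sample_network <- function(net, n, seed) {
  v <- validate_network(net)
  if (length(v)) abort(paste0("invalid network: ", paste(v, collapse = "; ")))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort("`n` must be a single count >= 1.")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  n <- as.integer(n)
  ord <- topological_order(net)
  withr_seed(seed)
  noises <- matrix(stats::runif(n * length(ord)), nrow = n,
                   dimnames = list(NULL, ord))
  states <- matrix(0L, nrow = n, ncol = length(ord),
                   dimnames = list(NULL, ord))
  for (nm in ord) {
    ct <- net$cpts[[nm]]
    p1 <- if (length(ct$parents)) {
      ct$prob1[bit_index(states[, ct$parents, drop = FALSE])]
    } else rep(ct$prob1, n)
    states[, nm] <- as.integer(noises[, nm] < p1)
  }
  out <- tibble::as_tibble(as.data.frame(states))
  attr(out, "noises") <- noises
  class(out) <- c("bn_sample", class(out))
  out
}

withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Extract one realization (states plus noises) from a sample
#'
#' @param sample A `bn_sample` returned by [sample_network()].
#' @param i Row index.
#' @return A `bn_realization`: list with named integer `states` and named
#'   numeric `noises`.
#' @export
realization <- function(sample, i = 1L) {
  noises <- attr(sample, "noises")
  if (is.null(noises)) abort("`sample` carries no recorded noises.")
  new_realization(
    states = setNames(as.integer(sample[i, , drop = TRUE]), names(sample)),
    noises = noises[i, ]
  )
}

#' Construct a realization from explicit states and noises
#'
#' Useful for case studies where a specific patient profile is wanted; the
#' pair must satisfy the reconstruction rule (state 1 iff noise < CPT
#' probability given the parents' states), which [check_realization()]
#' verifies against a network.
#'
#' @param states Named integer vector of 0/1 node states.
#' @param noises Named numeric vector of exogenous uniforms in `[0, 1)`.
#' @return A `bn_realization`.
#' @export
new_realization <- function(states, noises) {
  structure(list(states = states, noises = noises), class = "bn_realization")
}

#' @export
print.bn_realization <- function(x, ...) {
  on <- names(x$states)[x$states == 1L]
  cat("<bn_realization> active:",
      if (length(on)) paste(on, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Check a realization against the reconstruction rule
#'
#' @param net A [bayes_net()].
#' @param r A `bn_realization`.
#' @return `TRUE` invisibly; aborts naming the first inconsistent node.
#' @export
check_realization <- function(net, r) {
  ord <- topological_order(net)
  for (nm in ord) {
    ct <- net$cpts[[nm]]
    p1 <- if (length(ct$parents)) {
      ct$prob1[bit_index(matrix(r$states[ct$parents], nrow = 1))]
    } else ct$prob1
    want <- as.integer(r$noises[[nm]] < p1)
    if (want != r$states[[nm]]) {
      abort(paste0("realization inconsistent at node ", nm,
                   ": state ", r$states[[nm]], " but noise ",
                   format(r$noises[[nm]]), " vs CPT probability ", format(p1)))
    }
  }
  invisible(TRUE)
}

# children/descendant helpers used by interventions
descendants <- function(net, node) {
  ord <- topological_order(net)
  desc <- character()
  for (nm in ord) {
    ct <- net$cpts[[nm]]
    if (any(ct$parents %in% c(node, desc))) desc <- c(desc, nm)
  }
  desc
}
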