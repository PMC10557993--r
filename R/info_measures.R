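#' Discrete information measures in bits
#'
#' All measures accept either a [joint_table()] (exact computation) or a data
#' frame of 0/1 columns (plug-in, i.e. maximum-likelihood, estimation from
#' empirical frequencies). Results carry the estimator and the variable
#' labels as attributes; the value itself is a plain number of bits.
#'
#' @name info_measures
NULL

info_quantity <- function(value, estimator, variables) {
  structure(value, estimator = estimator, variables = variables,
            class = c("info_quantity", "numeric"))
}

#' @export
print.info_quantity <- function(x, ...) {
  cat(format(unclass(x)), "bits (", attr(x, "estimator"), ") over ",
      paste(attr(x, "variables"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# probability vector of the joint state distribution of `vars`,
# from either a joint_table (exact) or a data frame (plug-in)
state_probs <- function(x, vars) {
  if (inherits(x, "joint_table")) {
    missing <- setdiff(vars, x$variables)
    if (length(missing)) {
      abort(paste0("unknown variable label(s): ", paste(missing, collapse = ", ")))
    }
    idx <- bit_index(x$states[, vars, drop = FALSE])
    as.numeric(rowsum(x$prob, idx))
  } else {
    check_binary_data(x)
    check_labels_present(x, vars)
    idx <- bit_index(x[vars])
    tabulate(idx, nbins = 2^length(vars)) / nrow(x)
  }
}

estimator_of <- function(x) {
  if (inherits(x, "joint_table")) "exact" else "plugin"
}

#' Shannon entropy
#'
#' Joint entropy of a set of binary variables, in bits; `0 * log(0)` is taken
#' as 0. With data input an optional Miller-Madow small-sample bias correction
#' (adds `(K_observed - 1) / (2 n ln 2)`) is available; it is off by default
#' because downstream significance uses a permutation null rather than bias
#' correction.
#'
#' @param x A [joint_table()] or a data frame of 0/1 columns.
#' @param variables Character vector of variable labels.
#' @param correction `"none"` (default) or `"miller-madow"` (data input only).
#' @return An `info_quantity` (bits).
#' @examples
#' d <- data.frame(x = c(0, 1, 0, 1))
#' entropy(d, "x")   # 1 bit
#' @export
entropy <- function(x, variables, correction = c("none", "miller-madow")) {
  correction <- match.arg(correction)
  p <- state_probs(x, variables)
  h <- entropy_bits(p)
  if (correction == "miller-madow") {
    if (inherits(x, "joint_table")) {
      abort("Miller-Madow correction applies to data input only.")
    }
    h <- h + (sum(p > 0) - 1) / (2 * nrow(x) * log(2))
  }
  info_quantity(h, estimator_of(x), variables)
}

#' Mutual information between two sets of variables
#'
#' `MI(A; B) = H(A) + H(B) - H(A, B)` in bits; symmetric in its arguments and
#' non-negative for exact input (plug-in values are also non-negative by
#' construction of the maximum-likelihood estimator).
#'
#' @param x A [joint_table()] or a data frame of 0/1 columns.
#' @param set_a,set_b Disjoint, non-empty label sets.
#' @return An `info_quantity` (bits).
#' @export
mutual_information <- function(x, set_a, set_b) {
  if (!length(set_a) || !length(set_b)) {
    abort("`set_a` and `set_b` must be non-empty.")
  }
  if (length(intersect(set_a, set_b))) {
    abort("`set_a` and `set_b` must be disjoint.")
  }
  mi <- unclass(entropy(x, set_a)) + unclass(entropy(x, set_b)) -
    unclass(entropy(x, c(set_a, set_b)))
  info_quantity(mi, estimator_of(x), c(set_a, set_b))
}

#' Total correlation
#'
#' `TC = sum_i H(X_i) - H(X)`: the total redundancy among the variables.
#'
#' @inheritParams mutual_information
#' @param variables At least two labels.
#' @return An `info_quantity` (bits).
#' @export
total_correlation <- function(x, variables) {
  if (length(variables) < 2L) abort("`variables` must name at least 2 variables.")
  hs <- vapply(variables, function(v) unclass(entropy(x, v)), numeric(1))
  info_quantity(sum(hs) - unclass(entropy(x, variables)),
                estimator_of(x), variables)
}

#' Dual total correlation
#'
#' `DTC = (1 - n) H(X) + sum_i H(X_{-i})`, the shared information binding the
#' system together.
#'
#' @inheritParams total_correlation
#' @return An `info_quantity` (bits).
#' @export
dual_total_correlation <- function(x, variables) {
  if (length(variables) < 2L) abort("`variables` must name at least 2 variables.")
  n <- length(variables)
  h_all <- unclass(entropy(x, variables))
  h_drop <- vapply(seq_len(n), function(i)
    unclass(entropy(x, variables[-i])), numeric(1))
  info_quantity((1 - n) * h_all + sum(h_drop), estimator_of(x), variables)
}

#' O-information
#'
#' `Omega = TC - DTC = (n - 2) H(X) + sum_i [H(X_i) - H(X_{-i})]`. Negative
#' values flag synergy-dominated interdependence (the canonical case being an
#' XOR gate, Omega = -1 bit), positive values redundancy-dominated
#' interdependence (three copies of one bit give +1).
#'
#' @inheritParams total_correlation
#' @param variables At least three labels.
#' @return An `info_quantity` (bits).
#' @examples
#' net <- bayes_net(list(
#'   A = cpt(character(), 0.5), B = cpt(character(), 0.5),
#'   Y = cpt(c("A", "B"), c(0, 1, 1, 0))
#' ))
#' o_information(joint_distribution(net), c("A", "B", "Y"))  # -1 bit
#' @export
o_information <- function(x, variables) {
  if (length(variables) < 3L) abort("`variables` must name at least 3 variables.")
  n <- length(variables)
  h_all <- unclass(entropy(x, variables))
  h_one <- vapply(variables, function(v) unclass(entropy(x, v)), numeric(1))
  h_drop <- vapply(seq_len(n), function(i)
    unclass(entropy(x, variables[-i])), numeric(1))
  info_quantity((n - 2) * h_all + sum(h_one - h_drop),
                estimator_of(x), variables)
}

#' Whole-minus-sum synergy of two parents about a target
#'
#' `WMS = MI({P1, P2}; T) - MI(P1; T) - MI(P2; T)`: positive when the parents
#' jointly carry more information about the target than the sum of their
#' individual contributions. This is the objective maximised when designing
#' synergistic conditional probability tables (see
#' [optimize_synergistic_cpt()]).
#'
#' @inheritParams mutual_information
#' @param parents Two distinct labels.
#' @param target A third distinct label.
#' @return An `info_quantity` (bits).
#' @export
wms_synergy <- function(x, parents, target) {
  labs <- c(parents, target)
  if (length(parents) != 2L || length(target) != 1L || anyDuplicated(labs)) {
    abort("`parents` must be two labels and `target` a third, all distinct.")
  }
  w <- unclass(mutual_information(x, parents, target)) -
    unclass(mutual_information(x, parents[1], target)) -
    unclass(mutual_information(x, parents[2], target))
  info_quantity(w, estimator_of(x), labs)
}

#' Pairwise mutual information matrix
#'
#' Plug-in MI, in bits, for every pair of columns of a binary data table; this
#' is the quantity a pairwise association network is built from. The diagonal
#' is reported as 0 by convention.
#'
#' @param data Data frame of 0/1 columns (at least two).
#' @return A symmetric numeric matrix of class `mi_matrix` with the column
#'   labels as dimnames.
#' @export
mi_matrix <- function(data) {
  check_binary_data(data)
  m <- ncol(data)
  if (m < 2L) abort("`data` must have at least 2 columns.")
  labs <- names(data)
  # single-column entropies once, pair entropies from 4-cell tables
  cols <- as.matrix(data)
  n <- nrow(cols)
  p1 <- colMeans(cols)
  h1 <- vapply(p1, function(p) entropy_bits(c(p, 1 - p)), numeric(1))
  out <- matrix(0, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m - 1L)) {
    xi <- cols[, i]
    for (j in (i + 1L):m) {
      idx <- xi * 2L + cols[, j] + 1L
      pj <- tabulate(idx, nbins = 4L) / n
      mi <- h1[i] + h1[j] - entropy_bits(pj)
      out[i, j] <- out[j, i] <- mi
    }
  }
  structure(out, class = c("mi_matrix", class(out)))
}

#' Write a pairwise MI matrix as TSV
#'
#' Tab-separated, labels as the first row and column, values in bits to six
#' decimals.
#'
#' @param x An `mi_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mi_matrix <- function(x, path) {
  m <- round(unclass(x), 6L)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Connected components of the thresholded pairwise-MI graph
#'
#' Builds the undirected graph whose edges are variable pairs with MI at or
#' above `threshold`, and returns its connected components — the structure a
#' pairwise-only analysis would report.
#'
#' @param x An `mi_matrix` (or plain symmetric matrix with dimnames).
#' @param threshold Edge threshold in bits.
#' @return A list of character vectors, one per component, each sorted;
#'   components sorted by their first label.
#' @export
mi_graph_components <- function(x, threshold) {
  m <- unclass(x)
  adj <- (m >= threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  out <- split(names(comp$membership), comp$membership)
  out <- lapply(out, sort)
  names(out) <- NULL
  out[order(vapply(out, `[`, character(1), 1L))]
}
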