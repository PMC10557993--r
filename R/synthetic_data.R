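#' Generate a dataset from a Bayesian network
#'
#' Draws `n` realizations by ancestral sampling and returns them as a binary
#' data table, columns in topological order.
#'
#' @param net A [bayes_net()].
#' @param n Number of rows (at least 1).
#' @param seed Integer seed.
#' @return A tibble of 0/1 columns.
#' @export
generate_reference_dataset <- function(net, n, seed) {
  out <- sample_network(net, n, seed)
  attr(out, "noises") <- NULL
  class(out) <- setdiff(class(out), "bn_sample")
  out
}

#' Configuration for survey-style generators
#'
#' Defaults emulate the shape of a geriatric screening survey: 587 subjects,
#' 37 binary signs and 14 binarized disease indicators with skewed background
#' prevalences.
#'
#' @param n_subjects Number of rows (default 587).
#' @param n_signs Number of sign columns (default 37).
#' @param n_diseases Number of disease columns (default 14).
#' @param n_planted_triplets Number of planted synergistic (XOR) triplets
#'   (default 3). Each consumes three sign columns: two inputs and one output.
#' @param n_planted_pairs Number of planted noisy-copy pairs (default 3); each
#'   consumes two sign columns.
#' @param flip_noise Probability of flipping a mechanism's output (default
#'   0.05); controls detectability of planted structure.
#' @param prevalence_range Interval background prevalences are drawn from
#'   (default `c(0.05, 0.4)`, skewed like real sign prevalences). Planted
#'   triplet inputs are drawn from `c(0.4, 0.6)` instead: a noisy XOR only
#'   remains pairwise-invisible when its inputs are close to balanced, and the
#'   pipeline's own triangle filter would otherwise discard the planted
#'   structure before testing it.
#' @param seed Integer seed.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(n_subjects = 587L, n_signs = 37L, n_diseases = 14L,
                          n_planted_triplets = 3L, n_planted_pairs = 3L,
                          flip_noise = 0.05,
                          prevalence_range = c(0.05, 0.4), seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_signs = as.integer(n_signs),
              n_diseases = as.integer(n_diseases),
              n_planted_triplets = as.integer(n_planted_triplets),
              n_planted_pairs = as.integer(n_planted_pairs),
              flip_noise = flip_noise,
              prevalence_range = prevalence_range, seed = as.integer(seed))
  if (cfg$n_subjects < 1L) abort("`n_subjects` must be >= 1.")
  if (3L * cfg$n_planted_triplets + 2L * cfg$n_planted_pairs > cfg$n_signs) {
    abort("planted mechanisms need more sign columns than `n_signs` provides.")
  }
  if (cfg$flip_noise < 0 || cfg$flip_noise >= 0.5) {
    abort("`flip_noise` must lie in [0, 0.5).")
  }
  if (any(cfg$prevalence_range <= 0) || any(cfg$prevalence_range >= 1) ||
      diff(cfg$prevalence_range) < 0) {
    abort("`prevalence_range` must be an increasing interval within (0, 1).")
  }
  structure(cfg, class = "survey_config")
}

flip <- function(x, eps, n) {
  f <- stats::runif(n) < eps
  as.integer(xor(x == 1L, f))
}

#' Generate a survey table with planted ground truth
#'
#' Emulates a cross-sectional binary survey of signs and diseases:
#'
#' * background signs are independent Bernoulli draws with prevalences from
#'   `prevalence_range`;
#' * each planted triplet sets its output sign to the XOR of its two input
#'   signs, flipped with probability `flip_noise` — a purely synergistic
#'   mechanism with (near-)zero pairwise association;
#' * each planted pair sets its second sign to a noisy copy of the first;
#' * each disease column is the OR of 1-3 randomly chosen sign columns,
#'   flipped with probability `flip_noise`.
#'
#' Everything planted is recorded in a ground-truth manifest for recovery
#' benchmarking.
#'
#' @param cfg A [survey_config()].
#' @return A list of class `survey_sim`: `data` (tibble of 0/1 columns,
#'   signs `sign_01`... then diseases `dis_01`...) and `manifest` (list with
#'   `planted_triplets`, `planted_pairs`, `disease_parents`, `prevalences`,
#'   `flip_noise`, `seed`).
#' @export
generate_survey <- function(cfg = survey_config()) {
  stopifnot(inherits(cfg, "survey_config"))
  withr_seed(cfg$seed)
  n <- cfg$n_subjects
  sign_labels <- sprintf("sign_%02d", seq_len(cfg$n_signs))
  dis_labels <- if (cfg$n_diseases > 0)
    sprintf("dis_%02d", seq_len(cfg$n_diseases)) else character()

  data <- matrix(0L, n, cfg$n_signs + cfg$n_diseases,
                 dimnames = list(NULL, c(sign_labels, dis_labels)))
  prevalences <- setNames(numeric(cfg$n_signs), sign_labels)

  used <- 0L
  triplets <- list()
  for (k in seq_len(cfg$n_planted_triplets)) {
    labs <- sign_labels[used + 1:3]
    used <- used + 3L
    p_in <- stats::runif(2, 0.4, 0.6)  # balanced inputs keep the XOR pairwise-invisible
    a <- as.integer(stats::runif(n) < p_in[1])
    b <- as.integer(stats::runif(n) < p_in[2])
    y <- flip(as.integer(xor(a == 1L, b == 1L)), cfg$flip_noise, n)
    data[, labs] <- cbind(a, b, y)
    prevalences[labs] <- c(p_in, NA)
    triplets[[k]] <- list(inputs = labs[1:2], output = labs[3],
                          mechanism = "xor", flip_noise = cfg$flip_noise)
  }
  pairs <- list()
  for (k in seq_len(cfg$n_planted_pairs)) {
    labs <- sign_labels[used + 1:2]
    used <- used + 2L
    p <- stats::runif(1, cfg$prevalence_range[1], cfg$prevalence_range[2])
    a <- as.integer(stats::runif(n) < p)
    b <- flip(a, cfg$flip_noise, n)
    data[, labs] <- cbind(a, b)
    prevalences[labs] <- c(p, NA)
    pairs[[k]] <- list(source = labs[1], copy = labs[2],
                       flip_noise = cfg$flip_noise)
  }
  for (lab in sign_labels[seq_len(cfg$n_signs) > used]) {
    p <- stats::runif(1, cfg$prevalence_range[1], cfg$prevalence_range[2])
    data[, lab] <- as.integer(stats::runif(n) < p)
    prevalences[lab] <- p
  }
  disease_parents <- list()
  for (lab in dis_labels) {
    k <- sample(1:3, 1L)
    par <- sort(sample(sign_labels, k))
    val <- as.integer(rowSums(data[, par, drop = FALSE]) > 0)
    data[, lab] <- flip(val, cfg$flip_noise, n)
    disease_parents[[lab]] <- par
  }

  manifest <- list(
    planted_triplets = triplets,
    planted_pairs = pairs,
    disease_parents = disease_parents,
    prevalences = prevalences,
    flip_noise = cfg$flip_noise,
    seed = cfg$seed
  )
  structure(list(data = tibble::as_tibble(as.data.frame(data)),
                 manifest = manifest),
            class = "survey_sim")
}

#' Generate a matched null survey
#'
#' Same column layout and marginal-prevalence scheme as [generate_survey()]'s
#' background, but every column is mutually independent: no planted triplets,
#' pairs or disease mechanisms. The type-I-error harness for the scan.
#'
#' @param cfg A [survey_config()] (the planted counts are ignored).
#' @return A list of class `survey_sim` with independent columns; the manifest
#'   records the prevalences and has empty mechanism lists.
#' @export
generate_null_survey <- function(cfg = survey_config()) {
  stopifnot(inherits(cfg, "survey_config"))
  withr_seed(cfg$seed)
  n <- cfg$n_subjects
  labels <- c(sprintf("sign_%02d", seq_len(cfg$n_signs)),
              if (cfg$n_diseases > 0) sprintf("dis_%02d", seq_len(cfg$n_diseases)))
  prevalences <- setNames(
    stats::runif(length(labels), cfg$prevalence_range[1], cfg$prevalence_range[2]),
    labels)
  data <- vapply(labels, function(lab)
    as.integer(stats::runif(n) < prevalences[[lab]]), integer(n))
  manifest <- list(planted_triplets = list(), planted_pairs = list(),
                   disease_parents = list(), prevalences = prevalences,
                   flip_noise = 0, seed = cfg$seed)
  structure(list(data = tibble::as_tibble(as.data.frame(data)),
                 manifest = manifest),
            class = "survey_sim")
}

#' Verify a ground-truth manifest against its data table
#'
#' Asserts that every label a manifest mentions exists in the data header.
#'
#' @param sim A `survey_sim` (or a list with `data` and `manifest`).
#' @return `TRUE` invisibly; aborts naming any missing label.
#' @export
verify_manifest <- function(sim) {
  labs <- names(sim$data)
  mentioned <- c(
    unlist(lapply(sim$manifest$planted_triplets, function(t) c(t$inputs, t$output))),
    unlist(lapply(sim$manifest$planted_pairs, function(p) c(p$source, p$copy))),
    names(sim$manifest$disease_parents),
    unlist(sim$manifest$disease_parents),
    names(sim$manifest$prevalences)
  )
  missing <- setdiff(mentioned, labs)
  if (length(missing)) {
    abort(paste0("manifest mentions label(s) absent from the data: ",
                 paste(unique(missing), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Recovery of planted triplets by a scan
#'
#' Convenience scorer: how many of a manifest's planted triplets appear as
#' significant rows of a [scan_synergy()] result.
#'
#' @param scan A `synergy_scan` tibble.
#' @param manifest A ground-truth manifest from [generate_survey()].
#' @return A list: `n_planted`, `n_recovered`, `recovered` (logical per
#'   planted triplet), `false_positives` (significant rows not planted).
#' @export
score_recovery <- function(scan, manifest) {
  planted <- vapply(manifest$planted_triplets, function(t)
    paste(sort(c(t$inputs, t$output)), collapse = "|"), character(1))
  sig <- scan[scan$significant, , drop = FALSE]
  sig_keys <- paste(sig$var_a, sig$var_b, sig$var_c, sep = "|")
  recovered <- planted %in% sig_keys
  list(n_planted = length(planted),
       n_recovered = sum(recovered),
       recovered = recovered,
       false_positives = sum(!sig_keys %in% planted))
}
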