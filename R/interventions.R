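#' Soft ("nudge") intervention on a root node
#'
#' Moves probability mass in the marginal distribution of a root node —
#' `delta > 0` moves mass toward state 1 — while every conditional probability
#' table is left untouched. This models a population-level intervention that
#' shifts the prevalence of a sign without altering any causal mechanism.
#' Only root nodes can be nudged: a non-root's marginal is determined by its
#' parents' distribution and its CPT, so it is not a free parameter of the
#' model.
#'
#' @param net A [bayes_net()].
#' @param node Label of a root node.
#' @param delta Signed probability mass to move toward state 1.
#' @return A new [bayes_net()] identical to `net` except the root's prior.
#' @examples
#' net <- bayes_net(list(S = cpt(character(), 0.3)))
#' nudge(net, "S", 0.1)$cpts$S$prob1   # 0.4
#' @export
nudge <- function(net, node, delta) {
  if (!node %in% net$nodes) abort(paste0("unknown node: ", node))
  ct <- net$cpts[[node]]
  if (length(ct$parents)) {
    abort(paste0("node ", node, " is not a root: its marginal is fixed by its ",
                 "parents and CPT, so it cannot be nudged directly."))
  }
  new_prior <- ct$prob1 + delta
  if (new_prior < 0 || new_prior > 1) {
    abort(paste0("nudge of ", delta, " moves the prior of ", node, " to ",
                 format(new_prior), ", outside [0, 1]."))
  }
  net$cpts[[node]] <- cpt(character(), new_prior)
  net
}

#' Population-level effect of a nudge
#'
#' Applies [nudge()] and propagates it exactly (via [joint_distribution()]),
#' reporting for every node the baseline marginal, the post-intervention
#' marginal, and the change in log-odds `logit(post) - logit(baseline)`
#' (natural-log units). Nodes that are not descendants of the nudged node are
#' unaffected. Marginals of exactly 0 or 1 produce infinite log-odds; these
#' rows are flagged rather than nudged away from the boundary.
#'
#' @inheritParams nudge
#' @return A tibble of class `effect_report` with columns `node`, `baseline`,
#'   `post`, `delta_log_odds`, `boundary` (flag for infinite log-odds).
#' @export
population_effect <- function(net, node, delta) {
  base <- marginals(joint_distribution(net))
  post <- marginals(joint_distribution(nudge(net, node, delta)))
  ord <- names(base)
  dlo <- logit(post[ord]) - logit(base[ord])
  dlo[abs(post[ord] - base[ord]) == 0] <- 0  # exact no-change, incl. boundaries
  out <- tibble::tibble(
    node = ord,
    baseline = as.numeric(base[ord]),
    post = as.numeric(post[ord]),
    delta_log_odds = as.numeric(dlo),
    boundary = !is.finite(as.numeric(dlo))
  )
  attr(out, "intervention") <- list(node = node, delta = delta)
  class(out) <- c("effect_report", class(out))
  out
}

#' Hard (do) intervention on one realization
#'
#' Clamps one or more nodes of an individual realization to fixed states and
#' recomputes every downstream node in topological order, reusing the
#' realization's recorded exogenous noises. This is the individual-level
#' counterfactual: the same patient, identical in every exogenous respect,
#' under the intervention. Nodes that are not descendants of any clamped node
#' are bit-identical to the input, and applying the same clamps twice is
#' idempotent.
#'
#' @param net A [bayes_net()].
#' @param r A `bn_realization` consistent with `net` (see
#'   [check_realization()]).
#' @param clamps Named vector mapping node labels to 0/1 states.
#' @return The counterfactual `bn_realization` (noises unchanged).
#' @examples
#' net <- build_reference_network("figure1b")
#' s <- sample_network(net, 1, seed = 7)
#' do_intervention(net, realization(s, 1), c(S2 = 0))
#' @export
do_intervention <- function(net, r, clamps) {
  if (!length(clamps)) abort("`clamps` must name at least one node.")
  unknown <- setdiff(names(clamps), net$nodes)
  if (length(unknown)) {
    abort(paste0("unknown node(s) in clamps: ", paste(unknown, collapse = ", ")))
  }
  if (!all(clamps %in% c(0, 1))) abort("clamp states must be 0 or 1.")
  ord <- topological_order(net)
  states <- r$states
  for (nm in ord) {
    if (nm %in% names(clamps)) {
      states[[nm]] <- as.integer(clamps[[nm]])
    } else {
      ct <- net$cpts[[nm]]
      p1 <- if (length(ct$parents)) {
        ct$prob1[bit_index(matrix(states[ct$parents], nrow = 1))]
      } else ct$prob1
      states[[nm]] <- as.integer(r$noises[[nm]] < p1)
    }
  }
  new_realization(states, r$noises)
}
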