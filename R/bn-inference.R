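#' Exact posterior distribution of a target node
#'
#' Computes `P(target | evidence)` by full enumeration: the joint
#' probability is summed over every configuration of the unobserved
#' variables for each target state, then normalized. Exact enumeration is
#' deliberate: the production networks here are Markov-blanket subnetworks
#' of at most a few dozen nodes, and per-report prediction observes all
#' non-target variables, reducing the sum to one term per target state.
#'
#' @param b a `discrete_bn`.
#' @param target node name (must not appear in the evidence).
#' @param evidence named list mapping observed variables to states (labels
#'   or indices); may be empty or partial.
#' @return Named probability vector over the target's states (sums to 1).
#' @export
posterior <- function(b, target, evidence = list()) {
  nodes <- b$dag$nodes
  if (!target %in% nodes) stop("unknown target node: ", target)
  if (target %in% names(evidence))
    stop("target must not appear in the evidence")
  bad <- setdiff(names(evidence), nodes)
  if (length(bad))
    stop("evidence names unknown variable(s): ", paste(bad, collapse = ", "))

  free <- c(target, setdiff(nodes, c(target, names(evidence))))
  grid <- as.matrix(expand.grid(lapply(b$cards[free], seq_len),
                                KEEP.OUT.ATTRS = FALSE))
  A <- matrix(0L, nrow(grid), length(nodes),
              dimnames = list(NULL, nodes))
  A[, free] <- grid
  for (v in names(evidence))
    A[, v] <- .state_index(b, v, evidence[[v]])

  logp <- rep(0, nrow(A))
  for (v in nodes) logp <- logp + log(.cpt_lookup(b, v, A))
  mx <- max(logp)
  if (!is.finite(mx))
    stop("evidence has probability zero under the model ",
         "(impossible evidence, not numerical underflow)")
  w <- exp(logp - mx)
  p <- vapply(seq_len(b$cards[[target]]),
              function(t) sum(w[A[, target] == t]), numeric(1))
  p <- p / sum(p)
  names(p) <- b$levels[[target]]
  p
}

# remap the columns of a case matrix onto the network's state indexing,
# erroring on missing variables or unknown state labels
.project_matrix <- function(b, m, exclude = character()) {
  needed <- setdiff(b$dag$nodes, exclude)
  missing <- setdiff(needed, names(m$cards))
  if (length(missing))
    stop("case matrix lacks network variable(s): ",
         paste(missing, collapse = ", "))
  A <- matrix(0L, nrow(m$data), length(b$dag$nodes),
              dimnames = list(NULL, b$dag$nodes))
  for (v in needed) {
    map <- match(m$levels[[v]], b$levels[[v]])
    if (anyNA(map))
      stop("state labels of '", v, "' differ between data and network")
    A[, v] <- map[m$data[, v]]
  }
  A
}

#' Per-report posterior probability of the target-positive state
#'
#' Scores every report of a case matrix with `P(target = positive |
#' all other network variables)`. Since all non-target network variables
#' are observed, the posterior reduces to the product of the target's own
#' CPT entry and its children's CPT entries, renormalized over the target
#' states; variables outside the network (e.g. AEs pruned away by the
#' Markov-blanket reduction) are ignored by design.
#'
#' @param b a `discrete_bn`.
#' @param m a [case_matrix()] providing every network variable except
#'   possibly the target; extra variables are projected away.
#' @param target node name.
#' @param positive target state treated as "positive" (defaults to
#'   `"true"` when present, otherwise the last state).
#' @param impossible how to score a report whose evidence has probability
#'   zero under every target state (possible when maximum-likelihood CPTs
#'   contain zero cells): `"error"` (default) or `"prior"`, which falls
#'   back to the model's marginal for the target, as estimated on the
#'   training data.
#' @return Numeric vector of probabilities, one per report.
#' @export
predict_scores <- function(b, m, target, positive = NULL,
                           impossible = c("error", "prior")) {
  impossible <- match.arg(impossible)
  nodes <- b$dag$nodes
  if (!target %in% nodes) stop("unknown target node: ", target)
  if (is.null(positive))
    positive <- if ("true" %in% b$levels[[target]]) "true" else
      b$levels[[target]][b$cards[[target]]]
  pos_idx <- .state_index(b, target, positive)
  A <- .project_matrix(b, m, exclude = target)
  fam_nodes <- c(target, dag_children(b$dag, target))

  r <- b$cards[[target]]
  logp <- matrix(0, nrow(A), r)
  for (t in seq_len(r)) {
    A[, target] <- t
    for (v in fam_nodes)
      logp[, t] <- logp[, t] + log(.cpt_lookup(b, v, A))
  }
  mx <- apply(logp, 1, max)
  bad <- !is.finite(mx)
  if (any(bad)) {
    if (impossible == "error")
      stop("evidence has probability zero under the model for ", sum(bad),
           " report(s) (impossible evidence, not numerical underflow)")
    mx[bad] <- 0
  }
  w <- exp(logp - mx)
  out <- w[, pos_idx] / rowSums(w)
  if (any(bad))
    out[bad] <- unname(posterior(b, target)[pos_idx])
  out
}

#' Posttest probability table of the target over its parent configurations
#'
#' One row per configuration of the target's parents, carrying
#' `P(target = positive | parents)` read from the target's CPT: the parents
#' d-separate the target from its non-descendant ancestors, so no other
#' evidence enters.
#'
#' @inheritParams predict_scores
#' @return Data frame with one (factor) column per parent plus
#'   `probability`, covering the full configuration product exactly once.
#' @export
posttest_probability_table <- function(b, target, positive = NULL) {
  cpt <- b$cpts[[target]]
  if (is.null(cpt)) stop("unknown target node: ", target)
  if (length(cpt$parents) == 0L)
    stop("target '", target, "' has no parents; ",
         "use posterior() for its prior instead")
  if (is.null(positive))
    positive <- if ("true" %in% b$levels[[target]]) "true" else
      b$levels[[target]][b$cards[[target]]]
  pos_idx <- .state_index(b, target, positive)
  grid <- expand.grid(b$levels[cpt$parents], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = TRUE)
  pm <- matrix(cpt$prob, nrow = b$cards[[target]])
  grid$probability <- pm[pos_idx, ]
  grid
}
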