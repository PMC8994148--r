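# counts of (parent configuration, child state); rows index configurations
.family_counts <- function(X, cards, node, parents) {
  cfg <- .col_config(X, parents, cards)
  q <- as.integer(prod(cards[parents]))
  r <- cards[[node]]
  idx <- cfg + q * (X[, node] - 1L)
  matrix(tabulate(idx, q * r), nrow = q, ncol = r)
}

.counts_loglik <- function(counts) {
  n_cfg <- rowSums(counts)
  pos <- counts > 0  # 0 * log(0/n) := 0
  sum(counts[pos] * log(counts[pos] / n_cfg[row(counts)[pos]]))
}

#' BIC family score of one node given a parent set
#'
#' Natural-log BIC with the penalty subtracted, so higher is better:
#' the maximized multinomial log-likelihood
#' `sum over configs/states n(state, config) * ln(n(state, config) /
#' n(config))` minus `(ln N / 2) * (r - 1) * q`, where `r` is the node
#' cardinality, `q` the product of parent cardinalities, and `N` the number
#' of reports. Zero counts contribute zero likelihood (`0 ln 0 := 0`);
#' unsupported parent configurations still pay full penalty. The total score
#' of a DAG decomposes as the sum of its family scores.
#'
#' @param node variable name.
#' @param parents character vector of parent variable names (may be empty).
#' @param m a [case_matrix()].
#' @return The family score (a negative number in practice).
#' @export
family_score <- function(node, parents, m) {
  vars <- names(m$cards)
  if (!node %in% vars) stop("unknown node: ", node)
  if (node %in% parents) stop("node '", node, "' listed in its own parents")
  if (!all(parents %in% vars))
    stop("unknown parent(s): ",
         paste(setdiff(parents, vars), collapse = ", "))
  counts <- .family_counts(m$data, m$cards, node, parents)
  n <- nrow(m$data)
  .counts_loglik(counts) -
    log(n) / 2 * (m$cards[[node]] - 1) * prod(m$cards[parents])
}

#' Score a DAG on a case matrix
#'
#' @param g a [dag()] whose nodes are variables of `m`.
#' @param m a [case_matrix()].
#' @return An object of class `scored_bn`: list with `dag`, `score` (total
#'   BIC) and `family_scores` (named vector; the total is their sum).
#' @export
score_dag <- function(g, m) {
  fs <- vapply(g$nodes, function(v) family_score(v, dag_parents(g, v), m),
               numeric(1))
  structure(list(dag = g, score = sum(fs), family_scores = fs),
            class = "scored_bn")
}

#' @export
print.scored_bn <- function(x, ...) {
  cat("scored_bn: BIC =", format(x$score), "over", length(x$dag$nodes),
      "nodes,", sum(x$dag$amat), "arcs\n")
  invisible(x)
}

#' Arc strength as BIC gain or loss on removal
#'
#' For each arc `from -> to`, the score change `(score without the arc) -
#' (score with the arc)`. Only the child's family term is recomputed
#' (decomposability). Strongly supported arcs have large negative values:
#' removing them loses score.
#'
#' @param s a [score_dag()] result.
#' @param m the [case_matrix()] the structure was scored on.
#' @return Data frame `from`, `to`, `strength`, sorted by increasing
#'   strength (strongest arcs first).
#' @export
arc_strength <- function(s, m) {
  g <- s$dag
  a <- arcs(g)
  if (nrow(a) == 0L)
    return(data.frame(from = character(), to = character(),
                      strength = numeric(), stringsAsFactors = FALSE))
  strength <- vapply(seq_len(nrow(a)), function(i) {
    pa <- setdiff(dag_parents(g, a$to[i]), a$from[i])
    family_score(a$to[i], pa, m) - s$family_scores[[a$to[i]]]
  }, numeric(1))
  out <- data.frame(from = a$from, to = a$to, strength = strength,
                    stringsAsFactors = FALSE)
  out[order(out$strength), , drop = FALSE]
}
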