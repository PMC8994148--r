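#' Fit conditional probability tables by maximum likelihood
#'
#' On a fixed DAG, each node's CPT row for a parent configuration is the
#' empirical frequency `n(state, config) / n(config)` in the data. Parent
#' configurations with no support in the data are filled by the fallback
#' policy (default: a uniform distribution over the node's states) and
#' counted in the fit report. An optional add-k smoothing mode
#' (`smooth > 0`) is available but off by default, keeping pure MLE for
#' supported rows.
#'
#' @param g a [dag()] whose nodes are variables of `m`.
#' @param m a [case_matrix()].
#' @param fallback policy for unsupported parent configurations:
#'   `"uniform"` or `"error"`.
#' @param smooth pseudo-count added to every cell (0 = pure MLE).
#' @return An object of class `discrete_bn`: list with `dag`, `cpts` (per
#'   node: `parents` and `prob`, an array whose first dimension indexes the
#'   child states), `levels`, `cards`, and a `fit_report` attribute (data
#'   frame `node`, `n_configs`, `n_unsupported`).
#' @export
fit_mle <- function(g, m, fallback = c("uniform", "error"), smooth = 0) {
  fallback <- match.arg(fallback)
  absent <- setdiff(g$nodes, names(m$cards))
  if (length(absent))
    stop("variable(s) in the DAG absent from the case matrix: ",
         paste(absent, collapse = ", "))
  cpts <- list()
  report <- list()
  for (v in g$nodes) {
    pa <- dag_parents(g, v)
    counts <- .family_counts(m$data, m$cards, v, pa) + smooth  # q x r
    n_cfg <- rowSums(counts)
    unsupported <- n_cfg == 0
    if (any(unsupported)) {
      if (fallback == "error")
        stop("unsupported parent configuration(s) for node '", v, "'")
      counts[unsupported, ] <- 1
      n_cfg[unsupported] <- m$cards[[v]]
    }
    prob <- t(counts / n_cfg)  # r x q
    dims <- c(m$cards[[v]], m$cards[pa])
    dn <- c(list(m$levels[[v]]), m$levels[pa])
    names(dn) <- c(v, pa)
    cpts[[v]] <- list(parents = pa,
                      prob = array(prob, dim = dims, dimnames = dn))
    report[[v]] <- data.frame(node = v, n_configs = length(n_cfg),
                              n_unsupported = sum(unsupported),
                              stringsAsFactors = FALSE)
  }
  structure(
    list(dag = g, cpts = cpts, levels = m$levels[g$nodes],
         cards = m$cards[g$nodes]),
    class = "discrete_bn",
    fit_report = do.call(rbind, report)
  )
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("discrete_bn:", length(x$dag$nodes), "nodes,", sum(x$dag$amat),
      "arcs\n")
  invisible(x)
}

#' Construct a discrete Bayesian network from explicit CPTs
#'
#' @param g a [dag()].
#' @param cpts named list (one per node) of lists with `parents` and `prob`
#'   (array, first dimension = child states, named dimnames).
#' @return A `discrete_bn`.
#' @export
discrete_bn <- function(g, cpts) {
  stopifnot(setequal(names(cpts), g$nodes))
  levels <- lapply(g$nodes, function(v) dimnames(cpts[[v]]$prob)[[1]])
  names(levels) <- g$nodes
  cards <- vapply(levels, length, integer(1))
  for (v in g$nodes) {
    cpt <- cpts[[v]]
    if (!setequal(cpt$parents, dag_parents(g, v)))
      stop("CPT parents of '", v, "' do not match the DAG")
    dims <- c(cards[[v]], cards[cpt$parents])
    if (!identical(as.integer(dim(cpt$prob) %||% length(cpt$prob)),
                   as.integer(dims)))
      stop("CPT dimensions of '", v, "' do not match the parent cardinalities")
    p <- matrix(cpt$prob, nrow = cards[[v]])
    if (any(p < 0) || any(abs(colSums(p) - 1) > 1e-9))
      stop("CPT of '", v, "' has a column not summing to 1")
  }
  structure(list(dag = g, cpts = cpts[g$nodes], levels = levels,
                 cards = cards),
            class = "discrete_bn")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# convert a named assignment (state labels or indices) to a 1 x V index row
.assignment_to_idx <- function(b, assignment) {
  nodes <- b$dag$nodes
  if (!all(nodes %in% names(assignment)))
    stop("assignment must cover all nodes; missing: ",
         paste(setdiff(nodes, names(assignment)), collapse = ", "))
  idx <- vapply(nodes, function(v) .state_index(b, v, assignment[[v]]),
                integer(1))
  matrix(idx, nrow = 1, dimnames = list(NULL, nodes))
}

.state_index <- function(b, v, state) {
  if (is.numeric(state)) {
    i <- as.integer(state)
  } else {
    i <- match(as.character(state), b$levels[[v]])
  }
  if (is.na(i) || i < 1L || i > b$cards[[v]])
    stop("invalid state for variable '", v, "': ", state)
  i
}

# vectorized CPT lookup: A is an integer index matrix with named columns
.cpt_lookup <- function(b, v, A) {
  cpt <- b$cpts[[v]]
  lin <- A[, v]
  mult <- b$cards[[v]]
  for (p in cpt$parents) {
    lin <- lin + (A[, p] - 1L) * mult
    mult <- mult * b$cards[[p]]
  }
  as.vector(cpt$prob)[lin]
}

#' Joint probability of a full assignment
#'
#' The product of the CPT entries `P(x_i | pa(x_i))` over all nodes,
#' accumulated in log space.
#'
#' @param b a `discrete_bn`.
#' @param assignment named list or vector giving a state (label or index)
#'   for every node.
#' @return A probability.
#' @export
joint_probability <- function(b, assignment) {
  A <- .assignment_to_idx(b, assignment)
  logp <- 0
  for (v in b$dag$nodes) logp <- logp + log(.cpt_lookup(b, v, A))
  exp(logp)
}
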