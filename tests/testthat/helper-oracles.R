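# Independent oracles used across the suite. These deliberately take
# different computational routes from the package internals.

# full joint table by native array subscripting (the package uses hand-rolled
# linear indexing instead)
brute_joint <- function(b) {
  A <- expand.grid(lapply(b$cards, seq_len), KEEP.OUT.ATTRS = FALSE)
  p <- rep(1, nrow(A))
  for (v in b$dag$nodes) {
    cpt <- b$cpts[[v]]
    sub <- as.matrix(A[, c(v, cpt$parents), drop = FALSE])
    p <- p * cpt$prob[sub]
  }
  A$prob <- p
  A
}

# exact posterior by filtering the full joint table
brute_posterior <- function(b, target, evidence = list()) {
  J <- brute_joint(b)
  keep <- rep(TRUE, nrow(J))
  for (v in names(evidence)) {
    idx <- if (is.numeric(evidence[[v]])) evidence[[v]] else
      match(as.character(evidence[[v]]), b$levels[[v]])
    keep <- keep & J[[v]] == idx
  }
  p <- vapply(seq_len(b$cards[[target]]),
              function(t) sum(J$prob[keep & J[[target]] == t]), numeric(1))
  stats::setNames(p / sum(p), b$levels[[target]])
}

# d-separation via the moralized ancestral graph
d_separated <- function(g, x, y, z) {
  amat <- g$amat
  nodes <- g$nodes
  anc <- unique(c(x, y, z))
  repeat {
    pa <- nodes[rowSums(amat[, anc, drop = FALSE]) > 0]
    new <- union(anc, pa)
    if (length(new) == length(anc)) break
    anc <- new
  }
  a <- amat[anc, anc, drop = FALSE]
  und <- (a + t(a)) > 0
  for (j in seq_len(ncol(a))) {
    pa <- which(a[, j] == 1L)
    und[pa, pa] <- TRUE
  }
  diag(und) <- FALSE
  drop <- colnames(a) %in% z
  und[drop, ] <- FALSE
  und[, drop] <- FALSE
  # breadth-first reachability from x
  reach <- colnames(a) %in% x & !drop
  repeat {
    new <- reach | (colSums(und[reach, , drop = FALSE]) > 0)
    if (all(new == reach)) break
    reach <- new
  }
  !any(reach & colnames(a) %in% y)
}

# Mann-Whitney concordance with ties counted one half
mann_whitney_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# all acyclic 0/1 adjacency matrices over `nodes` (tiny node sets only),
# acyclicity judged by igraph
enumerate_dags <- function(nodes) {
  V <- length(nodes)
  pairs <- which(diag(V) == 0, arr.ind = TRUE)
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1)) {
    amat <- matrix(0L, V, V, dimnames = list(nodes, nodes))
    on <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0)
    amat[pairs[on, , drop = FALSE]] <- 1L
    ig <- igraph::graph_from_adjacency_matrix(amat, mode = "directed")
    if (igraph::is_dag(ig)) out[[length(out) + 1L]] <- amat
  }
  out
}

# best BIC score over an enumerated DAG list, with per-family memoization
best_enumerated_score <- function(amats, m) {
  nodes <- names(m$cards)
  memo <- new.env(parent = emptyenv())
  fam <- function(v, pa) {
    key <- paste(v, paste(sort(pa), collapse = "|"), sep = ":")
    if (is.null(memo[[key]]))
      memo[[key]] <- family_score(v, pa, m)
    memo[[key]]
  }
  best <- -Inf
  for (a in amats) {
    sc <- sum(vapply(seq_along(nodes), function(j)
      fam(nodes[j], nodes[a[, j] == 1L]), numeric(1)))
    if (sc > best) best <- sc
  }
  best
}

# a quick random case matrix with independent binary columns
random_binary_matrix <- function(n, vars, outcome = vars[1],
                                 p = rep(0.3, length(vars))) {
  data <- vapply(seq_along(vars), function(j)
    1L + (stats::runif(n) < p[j]), integer(n))
  colnames(data) <- vars
  levels <- stats::setNames(rep(list(c("false", "true")), length(vars)),
                            vars)
  case_matrix(data, levels, outcome)
}
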