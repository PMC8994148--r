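#' Directed acyclic graph over named variables
#'
#' Lightweight DAG container used for structure learning: a node set and an
#' adjacency matrix (`amat[i, j] == 1L` means an arc `i -> j`). Every
#' mutating operation re-checks acyclicity.
#'
#' @param nodes character vector of unique node names.
#' @param arcs optional two-column matrix or data frame of arcs
#'   (`from`, `to`).
#' @return An object of class `bn_dag` with elements `nodes` and `amat`.
#' @export
dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicated node names")
  amat <- matrix(0L, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  g <- structure(list(nodes = nodes, amat = amat), class = "bn_dag")
  if (!is.null(arcs) && NROW(arcs) > 0) {
    arcs <- as.matrix(arcs)
    for (i in seq_len(nrow(arcs))) g <- add_arc(g, arcs[i, 1], arcs[i, 2])
  }
  g
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("bn_dag:", length(x$nodes), "nodes,", sum(x$amat), "arcs\n")
  a <- arcs(x)
  if (nrow(a)) {
    cat(paste0("  ", a$from, " -> ", a$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Arc list of a DAG
#'
#' @param g a [dag()].
#' @return Data frame with columns `from` and `to`, ordered lexicographically.
#' @export
arcs <- function(g) {
  idx <- which(g$amat == 1L, arr.ind = TRUE)
  out <- data.frame(from = g$nodes[idx[, 1]], to = g$nodes[idx[, 2]],
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

.check_arc_nodes <- function(g, from, to) {
  if (!from %in% g$nodes) stop("unknown node: ", from)
  if (!to %in% g$nodes) stop("unknown node: ", to)
  if (from == to) stop("self-loop on node: ", from)
}

#' Add, drop or reverse an arc
#'
#' @param g a [dag()].
#' @param from,to arc endpoints.
#' @return The modified `bn_dag`; adding or reversing an arc that would
#'   create a directed cycle is an error.
#' @export
add_arc <- function(g, from, to) {
  .check_arc_nodes(g, from, to)
  if (g$amat[from, to] == 1L) stop("duplicate arc ", from, " -> ", to)
  g$amat[from, to] <- 1L
  if (!is_acyclic(g)) stop("arc ", from, " -> ", to, " creates a cycle")
  g
}

#' @rdname add_arc
#' @export
drop_arc <- function(g, from, to) {
  .check_arc_nodes(g, from, to)
  if (g$amat[from, to] != 1L) stop("no arc ", from, " -> ", to)
  g$amat[from, to] <- 0L
  g
}

#' @rdname add_arc
#' @export
reverse_arc <- function(g, from, to) {
  g <- drop_arc(g, from, to)
  add_arc(g, to, from)
}

#' Parents / children of a node
#'
#' @param g a [dag()].
#' @param node node name.
#' @return Character vector of node names.
#' @export
dag_parents <- function(g, node) {
  if (!node %in% g$nodes) stop("unknown node: ", node)
  g$nodes[g$amat[, node] == 1L]
}

#' @rdname dag_parents
#' @export
dag_children <- function(g, node) {
  if (!node %in% g$nodes) stop("unknown node: ", node)
  g$nodes[g$amat[node, ] == 1L]
}

#' Test a (candidate) graph for acyclicity
#'
#' Kahn's algorithm on the adjacency matrix: repeatedly remove nodes with no
#' incoming arc; the graph is acyclic iff all nodes can be removed. Runs in
#' `O(V + E)` node/arc visits.
#'
#' @param g a `bn_dag`, or a square 0/1 adjacency matrix.
#' @return `TRUE` iff the directed graph has no cycle.
#' @export
is_acyclic <- function(g) {
  amat <- if (inherits(g, "bn_dag")) g$amat else g
  n <- nrow(amat)
  if (n == 0L) return(TRUE)
  indeg <- colSums(amat)
  queue <- which(indeg == 0L)
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    ch <- which(amat[v, ] == 1L)
    indeg[ch] <- indeg[ch] - 1L
    queue <- c(queue, ch[indeg[ch] == 0L])
  }
  removed == n
}

#' Topological order of a DAG
#'
#' @param g a [dag()].
#' @return Character vector of node names, parents before children.
#' @export
topo_sort <- function(g) {
  amat <- g$amat
  n <- nrow(amat)
  indeg <- colSums(amat)
  order <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail)) {
    v <- min(avail)  # deterministic: smallest index first
    avail <- setdiff(avail, v)
    order <- c(order, v)
    ch <- which(amat[v, ] == 1L)
    indeg[ch] <- indeg[ch] - 1L
    avail <- c(avail, ch[indeg[ch] == 0L])
  }
  if (length(order) != n) stop("graph contains a cycle")
  g$nodes[order]
}

#' Prior-knowledge arc constraints
#'
#' @param blacklist,whitelist two-column matrices or data frames of arcs
#'   (`from`, `to`). Whitelist arcs are forced into, and never removed from,
#'   a learned structure; blacklist arcs are never added. The two sets must
#'   be disjoint and the whitelist alone must be acyclic.
#' @param nodes optional node universe used to validate endpoints.
#' @return An object of class `arc_constraints`.
#' @export
arc_constraints <- function(blacklist = NULL, whitelist = NULL,
                            nodes = NULL) {
  norm <- function(x) {
    if (is.null(x) || NROW(x) == 0)
      return(data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE))
    x <- as.data.frame(as.matrix(x), stringsAsFactors = FALSE)
    names(x) <- c("from", "to")
    unique(x)
  }
  blacklist <- norm(blacklist)
  whitelist <- norm(whitelist)
  key <- function(x) paste(x$from, x$to, sep = "\r")
  if (length(intersect(key(blacklist), key(whitelist))))
    stop("blacklist and whitelist overlap")
  if (!is.null(nodes)) {
    bad <- setdiff(c(blacklist$from, blacklist$to,
                     whitelist$from, whitelist$to), nodes)
    if (length(bad)) stop("constraint arc references unknown node(s): ",
                          paste(unique(bad), collapse = ", "))
  }
  if (nrow(whitelist)) {
    wnodes <- unique(c(whitelist$from, whitelist$to))
    if (!is_acyclic(dag(wnodes, whitelist)$amat))
      stop("whitelist arcs form a cycle")
  }
  structure(list(blacklist = blacklist, whitelist = whitelist),
            class = "arc_constraints")
}

#' Default prior-knowledge constraints for the GBS analysis
#'
#' Encodes the analysis' prior knowledge: no variable may point into `age`
#' or `gender` (they are not consequences of symptoms), and both `age` and
#' `gender` must point to the outcome.
#'
#' @param nodes node universe (variable names of the case matrix).
#' @param outcome outcome node name.
#' @return An [arc_constraints()] object.
#' @export
gbs_constraints <- function(nodes, outcome) {
  stopifnot(all(c("age", "gender", outcome) %in% nodes))
  others <- setdiff(nodes, c("age", "gender"))
  blacklist <- rbind(
    data.frame(from = setdiff(nodes, "age"), to = "age",
               stringsAsFactors = FALSE),
    data.frame(from = setdiff(nodes, "gender"), to = "gender",
               stringsAsFactors = FALSE)
  )
  blacklist <- blacklist[blacklist$from != blacklist$to, ]
  whitelist <- data.frame(from = c("age", "gender"),
                          to = outcome, stringsAsFactors = FALSE)
  key <- function(x) paste(x$from, x$to, sep = "\r")
  blacklist <- blacklist[!key(blacklist) %in% key(whitelist), ]
  arc_constraints(blacklist, whitelist, nodes = nodes)
}

#' Markov blanket of a node
#'
#' The parents, children, and children's other parents (spouses) of the
#' target; the blanket renders the target conditionally independent of every
#' other variable. A node may hold several roles at once (for example a
#' parent that also co-parents a child); `members` is the plain set union,
#' target excluded.
#'
#' @param g a [dag()].
#' @param target node name.
#' @return List with `parents`, `children`, `spouses` and `members`
#'   (character vectors, sorted).
#' @export
markov_blanket <- function(g, target) {
  if (!target %in% g$nodes) stop("unknown target node: ", target)
  parents <- dag_parents(g, target)
  children <- dag_children(g, target)
  spouses <- setdiff(unique(unlist(lapply(children, dag_parents, g = g))),
                     target)
  list(parents = sort(parents), children = sort(children),
       spouses = sort(spouses),
       members = sort(setdiff(unique(c(parents, children, spouses)),
                              target)))
}

#' Extract the Markov-blanket subnetwork of a target node
#'
#' Induced subgraph on the target plus its Markov-blanket members: those
#' nodes, and every arc of `g` with both endpoints retained. This is the
#' "ultimate network" reduction: all other variables are conditionally
#' independent of the target given the blanket and are pruned.
#'
#' @param g a [dag()].
#' @param target node name.
#' @return A `bn_dag` on `1 + length(members)` nodes.
#' @export
extract_mb_subnetwork <- function(g, target) {
  mb <- markov_blanket(g, target)
  keep <- c(target, mb$members)
  keep <- g$nodes[g$nodes %in% keep]  # preserve original node order
  sub <- dag(keep)
  sub$amat <- g$amat[keep, keep, drop = FALSE]
  sub
}
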