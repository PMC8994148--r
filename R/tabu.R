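#' Constrained tabu search over DAG structures
#'
#' Score-based local search maximizing the decomposable BIC score of
#' [family_score()] under add / delete / reverse arc moves, with
#' prior-knowledge constraints: whitelist arcs are present from the start
#' and are never deleted or reversed; blacklist arcs are never added. The
#' search keeps a tabu list of recently visited structures (by canonical arc
#' hash) and, once a local optimum is reached, is allowed a bounded number of
#' non-improving escape moves before stopping; the best structure ever
#' visited is returned.
#'
#' The search is fully deterministic: ties among equal-score moves are broken
#' by move type (delete, then add, then reverse) and then lexicographically
#' by arc, so repeated runs on the same data give identical structures.
#'
#' @param m a [case_matrix()].
#' @param constraints an [arc_constraints()] object.
#' @param nodes variables to include (default: all variables of `m`).
#' @param tabu length of the tabu list (visited structures barred from
#'   revisiting).
#' @param max_iter iteration cap.
#' @param max_escape maximum consecutive moves without improving the best
#'   score before the search stops.
#' @param max_parents cap on the parent-set size of any node.
#' @return A `scored_bn` (see [score_dag()]) for the best structure found.
#' @export
tabu_search <- function(m, constraints = arc_constraints(),
                        nodes = names(m$cards), tabu = 10L,
                        max_iter = 10000L, max_escape = 10L,
                        max_parents = Inf) {
  X <- m$data[, nodes, drop = FALSE]
  cards <- m$cards[nodes]
  V <- length(nodes)
  n <- nrow(X)
  eps <- 1e-10

  to_idx <- function(d) cbind(match(d$from, nodes), match(d$to, nodes))
  bl <- wl <- matrix(FALSE, V, V)
  if (nrow(constraints$blacklist)) {
    ii <- to_idx(constraints$blacklist)
    if (anyNA(ii)) stop("blacklist references nodes outside the search set")
    bl[ii] <- TRUE
  }
  if (nrow(constraints$whitelist)) {
    ii <- to_idx(constraints$whitelist)
    if (anyNA(ii)) stop("whitelist references nodes outside the search set")
    wl[ii] <- TRUE
  }
  if (any(wl & bl)) stop("inconsistent constraints: arc both white- and blacklisted")

  amat <- matrix(0L, V, V)
  amat[wl] <- 1L
  if (!is_acyclic(amat)) stop("whitelist arcs form a cycle")

  fam <- function(j, pa) {
    counts <- .family_counts(X, cards, j, pa)
    .counts_loglik(counts) - log(n) / 2 * (cards[[j]] - 1) * prod(cards[pa])
  }
  fs <- vapply(seq_len(V), function(j) fam(j, which(amat[, j] == 1L)),
               numeric(1))

  dadd <- ddel <- matrix(NA_real_, V, V)
  refresh <- function(j) {
    pa <- which(amat[, j] == 1L)
    for (p in seq_len(V)) {
      dadd[p, j] <<- NA_real_
      ddel[p, j] <<- NA_real_
      if (p == j) next
      if (amat[p, j] == 1L) {
        if (!wl[p, j]) ddel[p, j] <<- fam(j, setdiff(pa, p)) - fs[[j]]
      } else if (!bl[p, j] && length(pa) < max_parents) {
        dadd[p, j] <<- fam(j, c(pa, p)) - fs[[j]]
      }
    }
  }
  for (j in seq_len(V)) refresh(j)

  closure <- function(a) {
    r <- a > 0
    repeat {
      r2 <- r | ((r %*% a) > 0)
      if (identical(r2, r)) return(r)
      r <- r2
    }
  }
  hash <- function(a) paste(which(a == 1L), collapse = ",")

  best_amat <- amat
  best_score <- sum(fs)
  tabu_list <- hash(amat)
  stagnation <- 0L

  for (iter in seq_len(max_iter)) {
    reach <- closure(amat)
    # deletions
    del_idx <- which(amat == 1L & !wl, arr.ind = TRUE)
    # additions: p -> j admissible iff no path j ~> p
    add_ok <- !is.na(dadd) & !t(reach)
    add_idx <- which(add_ok, arr.ind = TRUE)
    # reversals: i -> j with j -> i admissible
    rev_idx <- del_idx[!is.na(dadd[cbind(del_idx[, 2], del_idx[, 1])]) &
                         !bl[cbind(del_idx[, 2], del_idx[, 1])], ,
                       drop = FALSE]
    if (nrow(rev_idx)) {
      ok <- vapply(seq_len(nrow(rev_idx)), function(k) {
        i <- rev_idx[k, 1]; j <- rev_idx[k, 2]
        a2 <- amat; a2[i, j] <- 0L
        !closure(a2)[i, j]
      }, logical(1))
      rev_idx <- rev_idx[ok, , drop = FALSE]
    }

    mv_type <- c(rep(1L, nrow(del_idx)), rep(2L, nrow(add_idx)),
                 rep(3L, nrow(rev_idx)))
    mv_from <- c(del_idx[, 1], add_idx[, 1], rev_idx[, 1])
    mv_to <- c(del_idx[, 2], add_idx[, 2], rev_idx[, 2])
    mv_delta <- c(ddel[del_idx], dadd[add_idx],
                  if (nrow(rev_idx)) ddel[rev_idx] +
                    dadd[cbind(rev_idx[, 2], rev_idx[, 1])] else numeric(0))
    if (!length(mv_type)) break

    ord <- order(-mv_delta, mv_type, mv_from, mv_to)
    chosen <- 0L
    for (k in ord) {
      a2 <- amat
      i <- mv_from[k]; j <- mv_to[k]
      if (mv_type[k] == 1L) a2[i, j] <- 0L
      else if (mv_type[k] == 2L) a2[i, j] <- 1L
      else { a2[i, j] <- 0L; a2[j, i] <- 1L }
      if (!hash(a2) %in% tabu_list) { chosen <- k; amat <- a2; break }
    }
    if (chosen == 0L) break

    i <- mv_from[chosen]; j <- mv_to[chosen]
    fs[[j]] <- fam(j, which(amat[, j] == 1L))
    refresh(j)
    if (mv_type[chosen] == 3L) {
      fs[[i]] <- fam(i, which(amat[, i] == 1L))
      refresh(i)
    } else {
      # parent sets of i unchanged, but adds into i may hit the parent cap
      if (is.finite(max_parents)) refresh(i)
    }
    tabu_list <- c(hash(amat), tabu_list)
    if (length(tabu_list) > tabu) tabu_list <- tabu_list[seq_len(tabu)]

    score <- sum(fs)
    if (score > best_score + eps) {
      best_score <- score
      best_amat <- amat
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
      if (stagnation >= max_escape) break
    }
  }

  g <- dag(nodes)
  g$amat[] <- best_amat
  score_dag(g, m)
}
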