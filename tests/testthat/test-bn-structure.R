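test_that("acyclicity detection agrees with igraph on constructed and random graphs", {
  expect_true(is_acyclic(dag(character(0))))
  expect_true(is_acyclic(dag(c("a", "b"), cbind("a", "b"))))
  amat <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  amat["a", "b"] <- 1L; amat["b", "a"] <- 1L
  expect_false(is_acyclic(amat))
  # 50-node DAG built along a topological order, then one back-arc
  withr::with_seed(31, {
    nodes <- paste0("n", 1:50)
    amat <- matrix(0L, 50, 50, dimnames = list(nodes, nodes))
    for (j in 2:50) {
      pa <- sample(seq_len(j - 1), min(3, j - 1))
      amat[pa, j] <- 1L
    }
    expect_true(is_acyclic(amat))
    amat[50, 1] <- 1L
    expect_false(is_acyclic(amat))
    # random digraphs vs igraph
    for (i in 1:50) {
      a <- matrix(rbinom(64, 1, 0.2), 8, 8)
      diag(a) <- 0L
      ig <- igraph::graph_from_adjacency_matrix(a, mode = "directed")
      expect_equal(is_acyclic(a), igraph::is_dag(ig))
    }
  })
})

test_that("arc mutations preserve DAG invariants", {
  g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_error(add_arc(g, "c", "a"), "cycle")
  expect_error(add_arc(g, "a", "b"), "duplicate")
  expect_error(add_arc(g, "a", "a"), "self-loop")
  expect_equal(topo_sort(g), c("a", "b", "c"))
  g2 <- reverse_arc(g, "b", "c")
  expect_equal(dag_parents(g2, "b"), c("a", "c"))
})

test_that("family score has the stated closed form and decomposes", {
  # parentless binary node with 30/100 positives
  data <- cbind(x = rep(c(2L, 1L), c(30, 70)),
                y = rep(c(1L, 2L), 50))
  m <- case_matrix(data, list(x = c("false", "true"),
                              y = c("false", "true")), "x")
  expect_equal(family_score("x", character(), m),
               30 * log(0.3) + 70 * log(0.7) - log(100) / 2)
  expect_error(family_score("x", "x", m), "own parents")

  # an independent parent can only lower the BIC score
  withr::with_seed(21, {
    m2 <- random_binary_matrix(10000, c("x", "z"), "x", p = c(0.3, 0.5))
    expect_lt(family_score("x", "z", m2),
              family_score("x", character(), m2))
  })

  # decomposability: total score equals monolithic fitted log-likelihood
  # minus the summed penalties, on a 4-node fixture
  b <- random_network(4, cards = 2, max_parents = 2, seed = 8)
  m4 <- sample_cohort(b, 500, seed = 9)
  s <- score_dag(b$dag, m4)
  expect_equal(s$score, sum(s$family_scores), tolerance = 1e-9)
  fit <- fit_mle(b$dag, m4)
  ll_mono <- sum(log(apply(m4$data, 1, function(row)
    joint_probability(fit, as.list(row)))))
  pen <- sum(vapply(b$dag$nodes, function(v) {
    q <- prod(m4$cards[dag_parents(b$dag, v)])
    log(nrow(m4$data)) / 2 * (m4$cards[[v]] - 1) * q
  }, numeric(1)))
  expect_equal(s$score, ll_mono - pen, tolerance = 1e-9)
})

test_that("family score is invariant to row order and state relabelling", {
  b <- random_network(4, cards = 2, max_parents = 2, seed = 15)
  m <- sample_cohort(b, 400, seed = 16)
  sc <- family_score("v2", dag_parents(b$dag, "v2"), m)
  perm <- withr::with_seed(1, sample(nrow(m$data)))
  m_shuf <- cm_subset(m, perm)
  expect_equal(family_score("v2", dag_parents(b$dag, "v2"), m_shuf), sc)
  # relabel: swap the two states of every variable
  data2 <- 3L - m$data
  lv2 <- lapply(m$levels, rev)
  m_flip <- case_matrix(data2, lv2, m$outcome)
  expect_equal(family_score("v2", dag_parents(b$dag, "v2"), m_flip), sc)
})

test_that("tabu search respects constraints and prunes spurious arcs", {
  withr::with_seed(33, {
    m <- random_binary_matrix(10000, c("a", "b"), "a", p = c(0.4, 0.6))
    s <- tabu_search(m)
    expect_equal(sum(s$dag$amat), 0L)
    # forced whitelist arc on independent data
    cons <- arc_constraints(whitelist = cbind("b", "a"))
    s2 <- tabu_search(m, cons)
    expect_equal(dag_parents(s2$dag, "a"), "b")
  })
  expect_error(arc_constraints(blacklist = cbind("a", "b"),
                               whitelist = cbind("a", "b")), "overlap")
  expect_error(arc_constraints(whitelist = rbind(c("a", "b"),
                                                 c("b", "a"))), "cycle")
})

test_that("tabu search attains the exhaustive optimum on a strong 4-node chain", {
  # chain v1 -> v2 -> v3 -> v4 with near-deterministic CPTs
  g <- dag(paste0("v", 1:4),
           cbind(paste0("v", 1:3), paste0("v", 2:4)))
  bin <- c("false", "true")
  cpt_root <- array(c(0.5, 0.5), 2, dimnames = list(v1 = bin))
  edge <- function(child, parent) {
    dn <- stats::setNames(list(bin, bin), c(child, parent))
    list(parents = parent,
         prob = array(c(0.9, 0.1, 0.1, 0.9), c(2, 2), dimnames = dn))
  }
  b <- discrete_bn(g, list(v1 = list(parents = character(),
                                     prob = cpt_root),
                           v2 = edge("v2", "v1"), v3 = edge("v3", "v2"),
                           v4 = edge("v4", "v3")))
  m <- sample_cohort(b, 20000, seed = 77)
  s <- tabu_search(m)
  best <- best_enumerated_score(enumerate_dags(paste0("v", 1:4)), m)
  expect_equal(s$score, best, tolerance = 1e-9)
  # the learned skeleton is the chain
  und <- s$dag$amat + t(s$dag$amat)
  expect_equal(sum(und), 6L)
  expect_true(all(und[cbind(1:3, 2:4)] == 1L))
})

test_that("markov blanket roles follow the parent/child/spouse definition", {
  b <- gbs_fixture_network()
  mb <- markov_blanket(b$dag, "gbs")
  expect_equal(mb$parents, c("age", "erythema", "gender"))
  expect_equal(mb$children, c("asthenia", "hypesthesia",
                              "muscular_weakness", "paresthesia"))
  expect_true(all(c("chills", "dizziness", "myalgia", "nausea",
                    "pain_in_extremity") %in% mb$spouses))
  # age, paresthesia and hypesthesia double as spouses
  expect_true(all(c("age", "paresthesia", "hypesthesia") %in% mb$spouses))
  expect_length(mb$members, 12L)
  expect_false("gbs" %in% mb$members)

  g1 <- dag(c("solo", "x", "y"), cbind("x", "y"))
  mb1 <- markov_blanket(g1, "solo")
  expect_equal(mb1$members, character(0))
  expect_error(markov_blanket(g1, "nope"), "unknown")
})

test_that("the blanket d-separates the target from every non-member", {
  withr::with_seed(55, {
    for (i in 1:100) {
      b <- random_network(8, max_parents = 3,
                          seed = sample.int(1e6, 1))
      target <- sample(b$dag$nodes, 1)
      mb <- markov_blanket(b$dag, target)
      outside <- setdiff(b$dag$nodes, c(target, mb$members))
      for (u in outside)
        expect_true(d_separated(b$dag, target, u, mb$members))
    }
  })
})

test_that("MB subnetwork extraction keeps exactly the blanket and its arcs", {
  b <- gbs_fixture_network()
  # embed the 13-node truth among 40 isolated decoy nodes
  g53 <- dag(c(b$dag$nodes, sprintf("decoy_%02d", 1:40)))
  g53$amat[b$dag$nodes, b$dag$nodes] <- b$dag$amat
  sub <- extract_mb_subnetwork(g53, "gbs")
  expect_length(sub$nodes, 13L)
  expect_equal(sum(sub$amat), sum(b$dag$amat))
  # single-node case
  lone <- extract_mb_subnetwork(dag(c("t", "u")), "t")
  expect_equal(lone$nodes, "t")
  # closure: the blanket inside the subnetwork equals the original blanket
  withr::with_seed(91, {
    for (i in 1:25) {
      bb <- random_network(9, max_parents = 3, seed = sample.int(1e6, 1))
      tg <- sample(bb$dag$nodes, 1)
      mb <- markov_blanket(bb$dag, tg)
      sub <- extract_mb_subnetwork(bb$dag, tg)
      expect_equal(markov_blanket(sub, tg)$members, mb$members)
    }
  })
})

test_that("arc strength equals the decomposable removal delta", {
  b <- gbs_fixture_network()
  m <- sample_cohort(b, 5000, seed = 13)
  s <- score_dag(b$dag, m)
  st <- arc_strength(s, m)
  expect_setequal(paste(st$from, st$to), paste(arcs(b$dag)$from,
                                               arcs(b$dag)$to))
  # strong dependency arc: removal loses score
  expect_lt(st$strength[st$from == "gbs" & st$to == "paresthesia"], 0)
  # brute-force full-rescoring oracle
  for (i in seq_len(nrow(st))) {
    g2 <- drop_arc(b$dag, st$from[i], st$to[i])
    expect_equal(st$strength[i], score_dag(g2, m)$score - s$score,
                 tolerance = 1e-9)
  }
})
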