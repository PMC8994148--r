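#' Random discrete Bayesian network generator
#'
#' Draws a DAG from a random topological order with a bounded number of
#' parents per node, then fills every CPT column with a draw from a
#' symmetric Dirichlet distribution (via normalized gamma variates). Large
#' concentration values give near-uniform rows; small values give
#' near-deterministic ones.
#'
#' @param n_nodes number of nodes (named `v1`, `v2`, ...).
#' @param cards state counts: scalar or vector of length `n_nodes` (all
#'   `>= 2`).
#' @param max_parents upper bound on parent-set sizes; must be below
#'   `n_nodes`.
#' @param concentration Dirichlet concentration parameter for CPT rows.
#' @param seed integer seed; the network is a deterministic function of it.
#' @return A `discrete_bn`.
#' @export
random_network <- function(n_nodes, cards = 2L, max_parents = 2L,
                           concentration = 1, seed = NULL) {
  if (max_parents >= n_nodes)
    stop("max_parents must be smaller than the node count")
  cards <- rep_len(as.integer(cards), n_nodes)
  stopifnot(all(cards >= 2L))
  nodes <- paste0("v", seq_len(n_nodes))
  names(cards) <- nodes
  build <- function() {
    ord <- sample(nodes)
    g <- dag(nodes)
    for (p in seq_along(ord)[-1]) {
      npa <- sample.int(min(max_parents, p - 1L) + 1L, 1L) - 1L
      if (npa > 0) {
        pas <- sample(ord[seq_len(p - 1L)], npa)
        for (pa in pas) g <- add_arc(g, pa, ord[p])
      }
    }
    cpts <- lapply(nodes, function(v) {
      pa <- dag_parents(g, v)
      r <- cards[[v]]
      q <- prod(cards[pa])
      pm <- matrix(stats::rgamma(r * q, shape = concentration), nrow = r)
      pm <- sweep(pm, 2, colSums(pm), "/")
      dn <- c(list(.default_states(r)), lapply(cards[pa], .default_states))
      names(dn) <- c(v, pa)
      list(parents = pa,
           prob = array(pm, dim = c(r, cards[pa]), dimnames = dn))
    })
    names(cpts) <- nodes
    discrete_bn(g, cpts)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

.default_states <- function(r) {
  if (r == 2L) c("false", "true") else paste0("s", seq_len(r))
}

#' Sample a cohort from a network by ancestral sampling
#'
#' Nodes are sampled in topological order, each from its CPT row given the
#' already-sampled parent states; fully vectorized over reports.
#'
#' @param b a `discrete_bn`.
#' @param n number of reports.
#' @param seed optional integer seed.
#' @param outcome variable to mark as the outcome of the returned matrix
#'   (defaults to the network's `outcome` attribute, else the first node).
#' @return A [case_matrix()] with `n` rows.
#' @export
sample_cohort <- function(b, n, seed = NULL, outcome = NULL) {
  stopifnot(n >= 1)
  outcome <- outcome %||% attr(b, "outcome") %||% b$dag$nodes[[1]]
  nodes <- b$dag$nodes
  draw <- function() {
    X <- matrix(1L, n, length(nodes), dimnames = list(NULL, nodes))
    for (v in topo_sort(b$dag)) {
      cpt <- b$cpts[[v]]
      r <- b$cards[[v]]
      cfg <- .col_config(X, cpt$parents, b$cards)
      cum <- apply(matrix(cpt$prob, nrow = r), 2, cumsum)  # r x q
      u <- stats::runif(n)
      st <- rep(1L, n)
      for (s in seq_len(r - 1L)) st <- st + (u > cum[s, cfg])
      X[, v] <- st
    }
    case_matrix(X, b$levels, outcome = outcome)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Published-network fixture for the GBS analysis
#'
#' A 13-node ground-truth network reproducing the qualitative structure of
#' the established GBS Markov-blanket model: the outcome `gbs` with parents
#' `age` (4 groups), `gender` and `erythema`; children `asthenia`,
#' `hypesthesia`, `muscular_weakness` and `paresthesia`; and spouse AEs
#' `chills`, `dizziness`, `myalgia`, `nausea` and `pain_in_extremity`, each
#' co-parenting at least one child. `age` doubles as a spouse through
#' `paresthesia` and `hypesthesia`; `paresthesia` and `hypesthesia` are
#' themselves spouses through the downstream sensory symptoms.
#'
#' The CPTs encode the published qualitative behaviour: the GBS risk rises
#' then falls over the four age groups (peak at 50-64), men carry roughly
#' 2.4 times the female risk, erythema strongly lowers the risk (so the
#' maximal posttest row is male, 50-64, no erythema), and the exact marginal
#' outcome prevalence is calibrated by enumeration to 1.26%. AE baseline
#' prevalences sit in the published 0-140 per-mille range. Which spouse
#' feeds which child is not dictated by the published structure; the default
#' assignment is a documented assumption and is configurable.
#'
#' @param spouse_map named character vector mapping each spouse AE to the
#'   child it co-parents.
#' @param gbs_prevalence target marginal outcome prevalence.
#' @return A `discrete_bn` with an `outcome` attribute (`"gbs"`) and a
#'   `term_map` attribute mapping node names to display AE terms.
#' @export
gbs_fixture_network <- function(spouse_map = c(
                                  chills = "asthenia",
                                  dizziness = "paresthesia",
                                  myalgia = "muscular_weakness",
                                  nausea = "asthenia",
                                  pain_in_extremity = "hypesthesia"),
                                gbs_prevalence = 0.0126) {
  children <- c("asthenia", "hypesthesia", "muscular_weakness",
                "paresthesia")
  spouses <- names(spouse_map)
  stopifnot(all(spouse_map %in% children),
            setequal(spouses, c("chills", "dizziness", "myalgia", "nausea",
                                "pain_in_extremity")))
  nodes <- c("gbs", "age", "gender", "erythema", children, spouses)

  # marginals used for calibration (near the published totals)
  p_age <- c(0.1674, 0.3211, 0.2207, 0.2908)
  p_male <- 0.3010
  p_ery <- 0.0897
  spouse_marg <- c(chills = 0.0685, dizziness = 0.0635, myalgia = 0.0495,
                   nausea = 0.0627, pain_in_extremity = 0.0868)
  # non-outcome baseline rates for the child AEs (per published non-GBS
  # columns) and their risk multipliers when GBS is present
  child_base_rate <- c(asthenia = 0.0416, hypesthesia = 0.0280,
                       muscular_weakness = 0.0150, paresthesia = 0.0338)
  child_gbs_mult <- c(asthenia = 7, hypesthesia = 10,
                      muscular_weakness = 12, paresthesia = 10)
  # age is a spouse for the sensory symptoms, with a rise-then-fall profile
  age_profile <- c(0.5, 1.0, 1.5, 0.9)
  chain_mult <- list(
    hypesthesia = c(paresthesia = 6),
    muscular_weakness = c(paresthesia = 3, hypesthesia = 4)
  )
  spouse_mult <- 2
  # co-parent effects are amplified when GBS is present ("coaction"): these
  # interactions are what make the collider orientations at the child nodes
  # statistically identifiable, mirroring the spouse roles of the published
  # network
  spouse_synergy <- 4
  chain_synergy <- 3
  age_synergy <- c(0.6, 1.0, 1.4, 1.0)
  clamp <- function(p) pmin(pmax(p, 1e-6), 0.95)

  g <- dag(nodes, rbind(
    cbind(c("age", "gender", "erythema"), "gbs"),
    cbind("gbs", children),
    cbind("age", c("paresthesia", "hypesthesia")),
    cbind("paresthesia", c("hypesthesia", "muscular_weakness")),
    cbind("hypesthesia", "muscular_weakness"),
    cbind(spouses, unname(spouse_map))
  ))

  bin <- c("false", "true")
  levels <- c(list(gbs = bin, age = age_group_labels(),
                   gender = c("female", "male"), erythema = bin),
              stats::setNames(rep(list(bin), length(c(children, spouses))),
                              c(children, spouses)))
  cards <- vapply(levels, length, integer(1))

  root_cpt <- function(v, p_true) {
    prob <- array(c(1 - p_true, p_true), dim = 2,
                  dimnames = stats::setNames(list(levels[[v]]), v))
    list(parents = character(), prob = prob)
  }
  cpts <- list(
    age = list(parents = character(),
               prob = array(p_age, dim = 4,
                            dimnames = list(age = age_group_labels()))),
    gender = list(parents = character(),
                  prob = array(c(1 - p_male, p_male), dim = 2,
                               dimnames = list(gender = c("female",
                                                          "male")))),
    erythema = root_cpt("erythema", p_ery)
  )
  for (s in spouses) cpts[[s]] <- root_cpt(s, spouse_marg[[s]])

  # outcome CPT: multiplicative in an age profile, a gender ratio and a
  # strong protective erythema factor; scaled so the enumerated marginal
  # equals the target prevalence exactly
  a_mult <- c(0.34, 0.865, 1.48, 1.16)
  m_mult <- c(1, 2.39)
  e_mult <- c(1, 0.03)
  marg1 <- sum(p_age * a_mult) * sum(c(1 - p_male, p_male) * m_mult) *
    sum(c(1 - p_ery, p_ery) * e_mult)
  s0 <- gbs_prevalence / marg1
  grid <- expand.grid(a = 1:4, g = 1:2, e = 1:2)
  p_true <- s0 * a_mult[grid$a] * m_mult[grid$g] * e_mult[grid$e]
  stopifnot(all(p_true < 1))
  dn <- list(gbs = bin, age = age_group_labels(),
             gender = c("female", "male"), erythema = bin)
  cpts$gbs <- list(
    parents = c("age", "gender", "erythema"),
    prob = array(rbind(1 - p_true, p_true), dim = c(2, 4, 2, 2),
                 dimnames = dn)
  )

  # child CPTs: risk = base * gbs multiplier * co-parent multipliers,
  # with the base back-computed from the target non-outcome rate and the
  # co-parent marginals
  mean_mult <- function(mult, marg) sum(mult * marg)
  par_marg <- list(
    age = p_age,
    paresthesia = c(1 - 0.0376, 0.0376),
    hypesthesia = c(1 - 0.0313, 0.0313)
  )
  for (ch in children) {
    pa <- dag_parents(g, ch)
    co <- setdiff(pa, "gbs")
    mults <- lapply(co, function(p) {
      if (p == "age") age_profile
      else if (p %in% names(chain_mult[[ch]]))
        c(1, chain_mult[[ch]][[p]])
      else c(1, spouse_mult)
    })
    names(mults) <- co
    denom <- prod(vapply(co, function(p) {
      marg <- if (p == "age") par_marg$age
      else if (p %in% names(par_marg)) par_marg[[p]]
      else c(1 - spouse_marg[[p]], spouse_marg[[p]])
      mean_mult(mults[[p]], marg)
    }, numeric(1)))
    base <- child_base_rate[[ch]] / denom
    gmult <- c(1, child_gbs_mult[[ch]])
    inter <- lapply(co, function(p) {
      if (p == "age") age_synergy
      else if (p %in% names(chain_mult[[ch]])) c(1, chain_synergy)
      else c(1, spouse_synergy)
    })
    names(inter) <- co
    cfg <- expand.grid(lapply(cards[pa], seq_len))
    risk <- base * gmult[cfg[["gbs"]]]
    for (p in co) {
      risk <- risk * mults[[p]][cfg[[p]]] *
        ifelse(cfg[["gbs"]] == 2L, inter[[p]][cfg[[p]]], 1)
    }
    risk <- clamp(risk)
    dn <- c(list(levels[[ch]]), levels[pa])
    names(dn) <- c(ch, pa)
    cpts[[ch]] <- list(
      parents = pa,
      prob = array(rbind(1 - risk, risk), dim = c(2, cards[pa]),
                   dimnames = dn)
    )
  }

  b <- discrete_bn(g, cpts)
  attr(b, "outcome") <- "gbs"
  attr(b, "term_map") <- c(
    gbs = "GBS", erythema = "Erythema", asthenia = "Asthenia",
    hypesthesia = "Hypesthesia", muscular_weakness = "Muscular weakness",
    paresthesia = "Paresthesia", chills = "Chills",
    dizziness = "Dizziness", myalgia = "Myalgia", nausea = "Nausea",
    pain_in_extremity = "Pain in extremity"
  )
  b
}

#' Emulate a raw, messy report table from a network
#'
#' Renders a sampled cohort as raw surveillance-style reports: the discrete
#' age group becomes a real age drawn uniformly within the group's interval,
#' binary AE nodes become preferred-term strings, and the configured
#' fractions of invalid rows (missing age, age below half a year, unknown
#' gender) are injected, along with independent low-prevalence decoy AE
#' columns that a correct Markov-blanket reduction should prune.
#'
#' @param b a `discrete_bn` containing nodes `age`, `gender` and binary AE
#'   nodes (e.g. [gbs_fixture_network()]).
#' @param n number of reports.
#' @param seed integer seed.
#' @param mess list with fractions `missing_age`, `under_age`,
#'   `unknown_gender` (each in `[0, 1]`, applied to disjoint report
#'   subsets) and `decoy_terms` (count of decoy AE columns); optional
#'   `decoy_prevalence` vector overrides the default grid of low
#'   prevalences (0.2-1.6%).
#' @param age_upper upper bound (years) used to render ages in the open-ended
#'   oldest group.
#' @return A [report_table()] carrying a `term_map` attribute.
#' @export
emulate_raw_reports <- function(b, n, seed = NULL,
                                mess = list(missing_age = 0.01,
                                            under_age = 0.005,
                                            unknown_gender = 0.01,
                                            decoy_terms = 0L),
                                age_upper = 90) {
  fr <- c(mess$missing_age %||% 0, mess$under_age %||% 0,
          mess$unknown_gender %||% 0)
  if (any(fr < 0 | fr > 1)) stop("mess fractions must lie in [0, 1]")
  if (sum(fr) > 1) stop("mess fractions must sum to at most 1")
  k_decoy <- as.integer(mess$decoy_terms %||% 0L)
  term_map <- attr(b, "term_map")

  build <- function() {
    m <- sample_cohort(b, n)
    X <- m$data
    breaks <- c(0.5, 18, 50, 65, age_upper)
    age <- stats::runif(n, breaks[X[, "age"]], breaks[X[, "age"] + 1L])
    gender <- c("female", "male")[X[, "gender"]]

    ae_nodes <- setdiff(colnames(X), c("age", "gender"))
    terms <- vapply(ae_nodes, function(v)
      term_map[[v]] %||% gsub("_", " ", v), character(1))
    present <- X[, ae_nodes, drop = FALSE] == 2L
    if (k_decoy > 0) {
      prev <- mess$decoy_prevalence %||%
        seq(0.002, 0.016, length.out = k_decoy)
      prev <- rep_len(prev, k_decoy)
      decoys <- vapply(seq_len(k_decoy), function(j)
        stats::runif(n) < prev[j], logical(n))
      if (n == 1L) decoys <- matrix(decoys, nrow = 1L)
      colnames(decoys) <- sprintf("decoy ae %02d", seq_len(k_decoy))
      present <- cbind(present, decoys)
      terms <- c(terms, colnames(decoys))
    }
    ae_terms <- apply(present, 1, function(row) terms[row],
                      simplify = FALSE)

    # disjoint invalid-row subsets
    n_bad <- round(fr * n)
    bad <- sample.int(n, sum(n_bad))
    miss <- bad[seq_len(n_bad[1])]
    under <- bad[seq_len(n_bad[2]) + n_bad[1]]
    unk <- bad[seq_len(n_bad[3]) + n_bad[1] + n_bad[2]]
    age[miss] <- NA_real_
    age[under] <- stats::runif(length(under), 0, 0.4999)
    gender[unk] <- "unknown"

    t <- report_table(report_id = sprintf("R%07d", seq_len(n)),
                      age = age, gender = gender, ae_terms = ae_terms)
    attr(t, "term_map") <- term_map
    t
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Write a report table to delimited text
#'
#' @param t a [report_table()].
#' @param path file path.
#' @param sep field separator; `term_sep` separates AE terms within the
#'   `ae_terms` column.
#' @export
write_reports <- function(t, path, sep = ",", term_sep = ";") {
  out <- data.frame(report_id = t$report_id, age = t$age,
                    gender = t$gender,
                    ae_terms = vapply(t$ae_terms, paste,
                                      character(1), collapse = term_sep),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}
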