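---
title: "Methods: Bayesian-network risk prediction for post-vaccination GBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian-network risk prediction for post-vaccination GBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsbn)
```

## The problem and the model

Guillain-Barré syndrome (GBS) is a rare acute paralytic neuropathy that is
occasionally reported after influenza vaccination. Passive surveillance
systems such as VAERS collect, per report, the vaccinee's age and gender
and the set of adverse-event (AE) preferred terms experienced. The goal of
this package is a risk model over such reports: which AEs carry information
about GBS, and what is the probability of GBS for a vaccinee with a given
symptom profile?

The model is a discrete Bayesian network $B(G, \Theta)$: a directed acyclic
graph $G = (V, E)$ over the outcome, the demographic variables, and binary
AE indicators, together with one conditional probability table (CPT) per
node. The joint distribution factorizes as
$P(X_1, \dots, X_n) = \prod_i P(X_i \mid \mathrm{Pa}(X_i))$.
The Markov blanket (MB) of the outcome — its parents, children, and the
children's other parents ("spouses") — renders the outcome conditionally
independent of every other variable, so after structure learning the
network is reduced to the blanket subnetwork and all other AEs are pruned.

The workflow has two steps, mirroring standard practice for score-based
network classifiers:

1. **Structure.** Learned once on the full development cohort by tabu
   search maximizing the BIC score, under prior-knowledge constraints:
   no arc may point into `age` or `gender`, and `age` and `gender` are
   whitelisted as parents of the outcome. The MB subnetwork of the outcome
   is then extracted as the final model, and each arc's strength is
   measured as the BIC change its removal would cause.
2. **Parameters.** For evaluation, CPTs are refit by maximum likelihood on
   each set of training folds during repeated stratified 5-fold
   cross-validation; per-report outcome probabilities on the validation
   fold are computed by exact inference, thresholded at the fold's Youden
   optimum, and summarized as AUC / sensitivity / specificity / accuracy
   with approximate-normal 95% confidence intervals.

## Data preparation choices

* **Exclusions.** Reports with missing age, age below 0.5 years, or
  unknown gender are removed. When a report fails both an age rule and the
  gender rule it is logged once, under the age rule (the precedence affects
  only the log, never the retained set).
* **Age bins.** Ages are discretized into four groups with half-open
  intervals $[0.5, 18)$, $[18, 50)$, $[50, 65)$, $[65, \infty)$. Published
  integer labels ("0.5-17", "18-49", ...) leave fractional ages between the
  labels unspecified; the half-open convention makes the four bins an exact
  partition of $[0.5, \infty)$, with an age like 17.6 falling in the lower
  bin.
* **Term matching.** AE terms are matched exactly after trimming,
  case-folding and collapsing non-alphanumeric runs to underscores. No
  MedDRA hierarchy logic is attempted.
* **Vocabulary.** AEs are ranked by report-level prevalence and the top
  $K$ (default 50 in the published analysis; the synthetic workflow uses
  $K = 25$, see below) enter the model; prevalence ties break
  lexicographically so runs are reproducible. The outcome term is excluded
  from the ranking.

## Screening conventions

Each AE is tested against the outcome with the *uncorrected* Pearson
chi-square statistic on the 2×2 table, at the fixed threshold
$\alpha = .001$ (a Bonferroni-style 0.05/50) applied as a strict
inequality $p < .001$. The uncorrected statistic is deliberate: it
reproduces the published borderline values (a p-value that rounds to .001
is *not* significant, which is what keeps the published count at 33
significant US terms). Per-mille prevalences are carried at full precision
and rounded only for presentation; published rounded values are inverted
with `reconstruct_count()`, which is exact whenever
$0.005\,N/1000 < 0.5$ — true for all four cohort group sizes. The
published `"<0.01"` per-mille sentinel can only mean a zero count at these
group sizes (a single case would already print as ≥ 0.08‰) and is mapped
to 0. Terms with zero cases everywhere are flagged untestable and never
counted on either side of a significance tally.

## Scoring and search

The BIC score is decomposable: for a node with cardinality $r$, parent
configuration count $q$, and $N$ reports,
$$\mathrm{BIC}(X, \mathrm{Pa}) = \sum_{j,k} n_{jk}
\ln\frac{n_{jk}}{n_j} - \frac{\ln N}{2}(r - 1)\,q,$$
with $0 \ln 0 := 0$; higher is better, and unsupported parent
configurations contribute zero likelihood but full penalty. Arc strength is
the total-score change on removing one arc, which by decomposability only
involves the child's family term.

Tabu search walks the space of DAGs under add / delete / reverse moves,
keeping a tabu list of the last 10 visited structures (by canonical arc
hash) and allowing up to 10 consecutive non-improving escape moves after a
local optimum before stopping; the best structure ever visited is returned.
Whitelist arcs are placed in the initial graph and are never deletion or
reversal candidates; blacklist arcs are never added. Ties between
equal-score moves break deterministically (delete before add before
reverse, then lexicographic arc order), so results are reproducible without
any randomness in the search itself. The algorithm's control parameters
(tabu length 10, escape budget 10, iteration cap 10,000) are package
defaults; the published analysis names the algorithm but no parameters.

## Inference

Inference is exact enumeration. For posterior queries the joint is summed
over all configurations of the unobserved variables; for per-report
prediction every non-outcome variable is observed, so the posterior
reduces to the outcome's own CPT entry times its children's CPT entries,
renormalized over the outcome states — two table lookups per report,
vectorized across the cohort. Probabilities accumulate in log space.
Variables outside the blanket are projected away silently: the pruned AEs
are ignored by design. The "posttest probability" table is the outcome's
CPT laid out over its parent configurations; the parents d-separate the
outcome from its remaining ancestors, so no other evidence enters.

Two degenerate situations have explicit policies:

* **Unsupported CPT rows** (parent configurations absent from training
  data) are filled uniformly and flagged in the fit report. Pure MLE is
  kept for supported rows; add-$k$ smoothing exists behind an argument but
  is off by default. How the original analysis handled such rows on
  validation folds is not stated anywhere; the uniform fallback is this
  package's choice, isolated behind a policy switch.
* **Impossible evidence** — a validation report whose symptom profile has
  fitted probability zero under *both* outcome states, possible because
  supported MLE rows may contain exact zeros — raises an error in
  `posterior()`; during cross-validation and external validation such
  reports are scored at the training-fold outcome marginal
  (`impossible = "prior"`). At the cohort sizes used here this affects at
  most a handful of reports per fold.

## Evaluation protocol

Folds are stratified on the outcome. The published protocol does not say
whether its folds were stratified, but at a 1.26% outcome prevalence
unstratified 5-fold splits risk validation folds without a single case, so
stratification is the default here. The classification threshold is chosen
on the validation fold itself by maximizing the Youden index
($J = \mathrm{sens} + \mathrm{spec} - 1$), exactly as the source protocol
states; this is mildly optimistic, and an honest train-fold-threshold mode
is available (`threshold_on = "train"`). Classification is strict
(`score > threshold`). ROC curves place candidate thresholds at midpoints
between distinct scores with $\pm\infty$ sentinels, so the (0,0) and (1,1)
corners are always present; AUC is the trapezoidal area and equals the
Mann-Whitney concordance with ties counted one half. Youden ties break
toward the smaller threshold (favouring sensitivity), with a $10^{-9}$
float guard — true $J$ differences are multiples of $1/P$ or $1/N$ and sit
far above it. Summary confidence intervals are
$\bar{x} \pm 1.96\, s/\sqrt{K}$ over the $K$ retained folds. For external
validation the threshold is re-chosen by Youden on the external cohort by
default (the original choice is not documented); a transferred fixed
threshold is supported.

## The synthetic generator and the published-network fixture

No raw surveillance extract ships with the package; a generator stands in.
`gbs_fixture_network()` encodes a 13-node ground truth with the published
blanket: parents `age`, `gender`, `erythema`; children `asthenia`,
`hypesthesia`, `muscular_weakness`, `paresthesia`; spouses `chills`,
`dizziness`, `myalgia`, `nausea`, `pain_in_extremity`. `age` doubles as a
spouse through the sensory symptoms, `paresthesia` and `hypesthesia`
through the downstream ones. Which spouse feeds which child is not fully
determined by the published description; the default assignment
(chills→asthenia, dizziness→paresthesia, myalgia→muscular weakness,
nausea→asthenia, pain in extremity→hypesthesia) is an explicit assumption
and is configurable.

CPT magnitudes are artifact constants chosen once to match the published
margins: the outcome CPT is multiplicative in a rise-then-fall age profile
(peak at 50-64), a male/female risk ratio of 2.39, and a strong protective
erythema factor (0.03), rescaled by enumeration so the marginal outcome
prevalence is exactly 1.26%; AE baselines sit at the published per-mille
prevalences (≈15-140‰). Child CPTs multiply a baseline risk by an
outcome factor and co-parent factors, **plus outcome-by-co-parent
interaction ("synergy") factors**. The interactions matter: with purely
multiplicative risks, collider co-parents are conditionally independent
given the child, the spouse v-structures carry no statistical signature,
and no score-based learner could orient them — the blanket would be
genuinely unidentifiable. The synergy terms give the "coaction" of the
spouses with the outcome a real footprint, making the ground truth
recoverable from data.

One orientation is knowingly *not* recoverable at these magnitudes:
erythema as a *parent* of the outcome. With age and gender already
whitelisted as parents, promoting erythema to a third parent multiplies
the outcome CPT by another factor of two (8 extra parameters, ≈45 nats of
BIC penalty at $n = 80{,}000$) while the reverse orientation costs one
parameter, and the collider signal that would separate the two lives in
the roughly *three* expected reports carrying both erythema and GBS. BIC
therefore learns erythema as a child. The blanket membership is unaffected
(a child is still a member), as is prediction; only the layout of the
posttest table changes, which is why the qualitative posttest checks in
the test suite are run on the MLE fit of the known fixture structure.

`emulate_raw_reports()` renders sampled cohorts as raw report tables:
ages drawn uniformly within their group's interval (the open-ended oldest
group is capped at 90 years for rendering), configurable fractions of
missing-age / under-age / unknown-gender rows (defaults 1% / 0.5% / 1%),
and independent low-prevalence decoy AE columns (0.2-1.6%) that a correct
blanket reduction must prune. All generators are deterministic functions
of their seed.

What the generator does **not** emulate: reporting biases and stimulated
reporting, overlapping or near-synonymous preferred terms, year-to-year
formulation changes, and any AE co-occurrence structure beyond the blanket
(decoys are fully independent). Passing tests therefore demonstrate that
the pipeline recovers a known ground truth of realistic size, prevalence
and effect pattern — not that it would reproduce the published performance
numbers on the real cohorts, which are not redistributable and whose
headline AUCs are out of scope here.

## Problem sizes used by the shipped analyses

The analysis scripts and the acceptance checks run at a development-cohort
size of $n = 80{,}000$ with a vocabulary of $K = 25$ AEs (the 10 true ones
plus 15 decoys) — the ground truth has 10 informative AEs, so a 25-term
vocabulary exercises ranking, screening and pruning without padding the
search space with more decoys than the fixture can make meaningful. The
external cohort is drawn at $n = 12{,}495$, matching the published
external cohort's size. Cross-validation in the scripts uses 5 repeats of
5 folds (the full 100-repeat protocol is a single argument away and scales
linearly). Blanket-recovery rates are estimated over 20 seeds in the test
suite and 5 seeds in the acceptance script.

## Known limitations

* Arc directions inside the blanket are reported as learned, but several
  are only identifiable through the interaction structure; on data without
  such interactions the same score may support reversed chains
  (score-equivalence), as the erythema case illustrates.
* Exact enumeration limits posterior queries with many *unobserved*
  variables (per-report prediction is unaffected); a junction-tree engine
  is out of scope for blanket-sized networks.
* The validation-fold Youden threshold reproduces the published protocol
  and inherits its optimism; use `threshold_on = "train"` for honest
  threshold selection.
* No disproportionality statistics (PRR, ROR, EBGM), no Bayesian parameter
  estimation, no missing-data EM: the cleaned case matrix is complete by
  construction.
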