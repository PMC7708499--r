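---
title: "Multiplex sociability analysis of scan-sampling data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex sociability analysis of scan-sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmux)
```

## The problem

Captive chimpanzee groups are observed by instantaneous scan sampling: every
two minutes within a 20-minute session, an observer records each
individual's behaviour, its interaction partner, the set of group mates
within an arm's reach, its mapped position in the enclosure and its height
level on the climbing structures. From such logs, `panmux` quantifies
*sociability* along four mutually exclusive interaction types of increasing
intimacy:

* **stationary vicinity** — beyond arm's reach but within 5 m, at most one
  height level apart, without interacting (low-level);
* **affiliative behaviour** — directed social play, socio-sexual and other
  affiliative acts, excluding allogrooming (medium-level);
* **allogrooming** — cleaning/manipulating a partner's hair or body,
  unidirectional or mutual (high-level);
* **passive close proximity** — within an arm's reach without further
  interaction (high-level).

Rather than analysing one interaction type (or their sum), the four types
are kept as separate layers of a *multiplex network* per social group: the
same seven nodes in every layer, one directed weighted adjacency matrix per
interaction type. The package then asks three questions: how similar the
layers are (edge overlap, spectral distances), whether fewer layers would
carry the same information (structural reducibility), and whether the
individuals' early-life biography predicts the dyadic rates (mixed models).

## From scans to indices

For an ordered dyad (sender A, receiver B), each index is

\[
\mathrm{index}_{A \to B} \;=\;
\frac{\#\,\text{scans credited to the interaction type}}
     {\#\,\text{scans where A and B had access to each other}} .
\]

The denominator counts scans where both individuals had access to the
outdoor enclosure — including scans where one was indoors and invisible to
the observer — but not scans where one was separated for veterinary or
management reasons. Exclusivity is enforced per dyad and scan: a grooming
scan can never also be a close-proximity or stationary-vicinity scan for
that dyad, while either individual may simultaneously be in close proximity
to *other* group members. Stationary vicinity is derived from geometry
(positions within 5 m, height-level difference at most 1, arm's-reach and
interaction scans subtracted); scans without mapped positions contribute to
the denominator but never to the stationary-vicinity count. Asymmetric
arm's-reach annotations are resolved by the union of the two individuals'
sets, since observers record the pair once and direction is an artifact.

Because the four index distributions live on different scales, network
weights divide each index by the largest value observed for that layer in
*either* group (`normalize_weighted()`), so every layer spans (0, 1] with
the layer-maximum dyad at exactly 1. This removes between-layer scaling
effects from all multiplex measures; the mixed models use the raw
proportions.

## Multiplex measures

All spectral computations symmetrize a directed layer as \((A + A^T)/2\):
the Laplacian-spectrum machinery below requires a symmetric operator, and
direction is retained where it matters scientifically (densities, strengths,
the dyadic models). Logarithms are base 2.

**Von Neumann entropy.** For a layer with symmetrized Laplacian \(L\),
rescale the eigenvalues to a unit-sum spectrum
\(\tilde\lambda_i = \lambda_i / \sum_j \lambda_j\) and take
\(h = -\sum_i \tilde\lambda_i \log_2 \tilde\lambda_i\). Closed forms used as
test oracles: a single-edge graph has \(h = 0\); the complete graph \(K_n\)
has \(h = \log_2(n-1)\). The entropy is invariant under multiplying all
weights by a constant, which is why aggregating layers by summation or by
averaging yields identical reducibility curves.

**Quantum Jensen–Shannon distance.** With \(\rho = L/\mathrm{tr}\,L\),

\[
D(A,B) = \sqrt{\,h\!\left(\tfrac{\rho_A+\rho_B}{2}\right)
              - \tfrac{1}{2}\left(h(\rho_A)+h(\rho_B)\right)} \in [0,1],
\]

a semimetric that is 0 for structurally identical layers. Negative values
from floating-point round-off are clipped at 0; eigenvalues below
\(-10^{-10}\) raise an error.

**Structural reducibility.** The pairwise JSD matrix is clustered
hierarchically (Ward linkage, `stats::hclust(method = "ward.D2")`); the
merge sequence is replayed by aggregating the merged layers' matrices by
summation. After each of the \(L-1\) steps the *relative entropy*
\(q = 1 - \overline{h}(\text{current layers}) / h(\text{full aggregate})\)
measures how distinguishable the remaining layers are from the aggregate;
the optimal representation is the layer count maximizing \(q\), with a
parsimony tie-break (the smallest count within \(10^{-9}\) of the maximum,
so a stack of identical layers reduces to one). A 4-layer multiplex always
reaches full aggregation after exactly three merges.

**Centrality and versatility.** Within a layer, importance is the leading
eigenvector of the symmetrized matrix, rescaled to max 1 — appropriate for
small, dense, weighted networks where degree-based measures saturate.
Across layers, *eigenvector versatility* takes the leading eigenvector of
the \(NL \times NL\) supra-adjacency matrix: symmetrized layers on the
diagonal blocks and a uniform categorical coupling \(\omega\) (default 1)
linking every node's layer replicas; per-node scores sum the \(L\) replica
entries and rescale to max 1. The coupling is exposed because no canonical
value exists; with all layers identical, any \(\omega > 0\) reproduces the
single-layer ranking (a test invariant). `rank_report()` assembles six
"rings" (four layers, aggregate, multiplex) with dense ranks and orders
them by Spearman correlation with the versatility ring.

**Edge overlap.** The pairwise overlap of two layers is Jaccard similarity
on directed edge presence; the global overlap is the fraction of edges
present in all layers among those present in any. The Jaccard convention is
a documented choice: verbal descriptions of "fractions of shared edges"
admit several normalizations, and published values for this population
cannot be recomputed without the raw matrices, so interlayer similarities
are treated as orderings, not target numbers.

## The dyadic mixed models

Each of the five responses (four indices plus their sum, the *aggregated*
variable) is modelled over the \(2 \times 7 \times 6 = 84\) ordered
within-group dyads:

```
response ~ origin_combo + phc_combo + sex_combo + (1 | group / sender)
```

The three fixed factors code the sender's and receiver's early-life
attributes as 4-level sender→receiver categories — origin (wild-caught vs
captive-born), predominant housing condition during infancy (with vs
without conspecifics for more than 2.5 of the first five years), and sex —
with reference levels `captive->captive`, `with->with`, `F->F`. Group and
sender-within-group are random intercepts.

Model comparison follows standard mixed-model practice: the full-vs-null
comparison is a likelihood-ratio test on maximum-likelihood fits; marginal
Type III F tests with Satterthwaite degrees of freedom are computed on the
REML refit (`lmerTest`); post hoc Tukey contrasts (`multcomp::glht`) are
adjusted by Holm–Bonferroni within each factor's contrast family (the
family is per factor, not global — the conventional reading of factor-wise
post hoc testing). Generalized VIFs, reported as
\(\mathrm{GVIF}^{1/(2\,df)}\) squared for comparability with conventional
thresholds, check the fixed design for collinearity. Responses stay on the
proportion scale: conclusions are equivariant under the alternative
percent scaling, and no transformation is applied. Singular random-effect
fits — common with only two groups — are flagged, never silently
simplified; a constant response yields a flagged degenerate result rather
than an error.

## The synthetic generator

No raw scan data is published for this population, so `synth_config()` /
`simulate_scans()` generate datasets with the statistical structure the
analysis assumes, and every downstream claim is tested against that known
truth. The generative model per scan:

1. Every present individual draws at most one outgoing directed behaviour
   (affiliative or grooming towards one partner) from a per-sender
   categorical whose per-dyad marginals equal the configured probabilities
   exactly. The scan-record format — one row per individual with a single
   behaviour/partner field — cannot encode two simultaneous outgoing acts,
   so full dyadic independence is restricted to "at most one outgoing act
   per sender per scan"; cross-direction class collisions (A affiliates
   towards B while B grooms A, which would violate per-dyad exclusivity)
   are resolved by a fair coin. Both deviations perturb the marginals by
   \(O(p^2) \approx 4\times10^{-4}\) relative, far below sampling error at
   the scales used.
2. Dyads without a realized directed behaviour draw one of {none,
   stationary vicinity, passive close proximity}; conditional probabilities
   are inflated by \(1/((1-p_a)(1-p_b))\) so unconditional marginals equal
   the configured rates.
3. Geometry realizes the sampled states exactly. Individuals sit on
   enclosure sites more than 5 m apart; stationary-vicinity components are
   laid out on a 1.6 m cell grid (8 × 8 cells per site, heights 0–4) by a
   forward-checking backtracking solver: vicinity pairs sit within 2 cells
   and one height level, and non-interacting pairs in the same component
   are pushed 4+ cells or 2+ height levels apart, so the counting rules
   recover the sampled states without false positives. Per-dyad
   independence occasionally samples configurations with no geometric
   realization (e.g. one individual in stationary vicinity to many mutually
   distant partners); such scans are repaired by deterministically demoting
   the most constrained vicinity edge to "none", the demotion is written
   back into the latent state table (so the latent and record routes stay
   exactly consistent), and the count is reported in
   `attr(records, "n_demoted")`. Repairs occur at a rate of roughly
   \(10^{-5}\) per dyad-scan under the default rates.

Defaults: two groups of seven with the attribute composition of the study
population; 30 sessions of ten 2-minute scans (the stated 20-minute session
at 2-minute intervals, first scan at minute 2); session-level absence
probability 0.05 (individuals occasionally lack enclosure access, which the
index denominator must absorb); per-scan, per-dyad base rates of 0.08
(stationary vicinity), 0.04 (passive close proximity), 0.015 (affiliative,
per direction) and 0.025 (grooming, per direction). The rates are
order-of-magnitude choices for sanctuary-housed adults — spatial
association roughly twice as common as contact proximity, directed
affiliative acts rarest — and are fully configurable; no published per-dyad
rates exist for this population. Indoor (access-but-invisible) scans are
supported (`p_indoor`) but default to 0: unobservable interactions bias
indices downward in a way real studies cannot correct either, and the
recovery analyses isolate pure sampling error. Planted effects are
multiplicative on the rates per sender→receiver category and layer.

What the generator deliberately does **not** emulate: temporal
autocorrelation within sessions, movement trajectories, dominance or
agonistic states, partner preference beyond the biography categories, and
observer error. Passing tests therefore demonstrate that the *pipeline*
recovers what the sampling design can deliver — not that real chimpanzee
data satisfies the independence assumptions.

All randomness flows from one configured seed (roster: seed; state
sampling: seed + 1; geometry: seed + 2), so every artifact is reproducible
bit for bit.

## Validation studies and problem sizes

Four simulation studies substitute for the unpublished raw data (run by
`analysis/05_validation.R` and recomputed by `scripts/acceptance.R`; sizes
chosen to give the binomial checks sharp expectations):

* **Recovery** — 50 replicates of one 7-individual group observed for 500
  sessions (5000 access scans per dyad, absence disabled): the proportion
  of dyad-layer index estimates within 3 binomial SE of the planted
  probability must be at least 99%.
* **Detection** — 20 replicates, two groups, 50 sessions, grooming
  multiplied by 3 within with→with dyads: the grooming model must beat its
  null at \(\alpha = 0.05\) with all non-reference housing-category
  coefficients negative in at least 90% of replicates.
* **Type-I calibration** — 200 replicates, 8 sessions, no effects: the
  full-vs-null rejection rate must sit within 3 binomial SE of 0.05.
* **Aggregation information loss** — 50 replicates with a 2× grooming
  effect and 12 sessions per group: a moderate-power regime chosen by a
  back-of-envelope power calculation (effect ≈ 0.025 on the proportion
  scale against a binomial SE of ≈ 0.02 at 100 scans) so that the dilution
  of a single-layer signal by the other layers' noise is visible: the
  aggregated-response model must show lower power and a larger median
  likelihood-ratio p than the grooming-specific model, mirroring the
  information-loss argument for keeping layers separate.

The model-based studies compute indices through the latent tally route,
which is proven value-identical to the full record route by the test suite;
the recovery study runs the full record route, geometry included.

## Numerical choices and degenerate inputs

* Zero access denominator: index 0 with a warning naming the dyad.
* All-zero layer: entropy and JSD raise errors (flagged to the caller);
  eigenvector centrality returns zeros with a warning; edge overlap of two
  empty layers is defined as 0 with a warning.
* Eigen-decompositions use `eigen(symmetric = TRUE)`; JSD values are
  clipped at 0 before the square root; entropy terms use
  \(0 \log 0 := 0\).
* Ward merges are deterministic; `hclust` resolves ties by pair index.
* Dense ranks share tied ranks; rank correlations between rings use
  Spearman.
* Factor levels absent from a dyad table are dropped with a warning before
  fitting (rank-deficient designs otherwise abort inside the solver).

## Known limitations

* Two social groups give the group-level random effect very little to
  estimate; singular fits are the norm and are reported as flags, matching
  the scale of the original design rather than idealized asymptotics.
* Published interlayer similarity and model statistics for this population
  depend on raw data that was never deposited; the package reproduces the
  printed combinatorial quantities exactly and treats the data-bound
  values as qualitative orderings only.
* The Jaccard edge-overlap convention and the uniform categorical coupling
  \(\omega\) are documented choices among several defensible ones; both are
  parameters of the relevant functions.
* Group sizes above nine are not supported by the placement engine's site
  grid (the study population has seven per group).
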