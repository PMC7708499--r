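# panmux

Multiplex social network analysis of chimpanzee scan-sampling data.

Sanctuary-housed chimpanzees are observed by two-minute instantaneous scan
sampling: behaviour, interaction partner, arm's-reach neighbours, mapped
position and climbing height for every individual, every two minutes, in
20-minute sessions. `panmux` turns such logs into a *sociability* analysis
for researchers and captive-care managers:

1. **Dyadic interaction indices.** Four mutually exclusive interaction
   types — stationary vicinity (within 5 m, beyond arm's reach, at most one
   height level apart, not interacting), affiliative behaviour, allogrooming
   and passive close proximity — counted per ordered dyad and divided by the
   number of scans the two individuals had access to each other:
   `index(A→B) = #credited scans / #mutual-access scans`.
2. **Directed weighted 4-layer multiplex networks** per social group
   (weights normalized by the per-layer maximum across groups), with layer
   and multiplex densities, node strength, eigenvector centrality, and
   eigenvector versatility from the supra-adjacency matrix.
3. **Interlayer structure**: Jaccard edge overlap, Von Neumann graph entropy
   `h = −Σ λ̃ᵢ log₂ λ̃ᵢ` of the trace-rescaled Laplacian spectrum, the
   quantum Jensen–Shannon distance
   `D = sqrt(h((ρ_A+ρ_B)/2) − (h(ρ_A)+h(ρ_B))/2)`, and structural
   reducibility: Ward clustering of the distance matrix with the relative
   entropy `q = 1 − mean(h)/h(aggregate)` tracked across merge steps.
4. **Dyadic biography-effect models**: five linear mixed models
   (`index ~ origin_combo + phc_combo + sex_combo + (1 | group/sender)`)
   testing whether sender→receiver combinations of origin (wild-caught vs
   captive-born), infant housing condition and sex predict each interaction
   index and their sum — likelihood-ratio full-vs-null comparison, Type III
   Satterthwaite F tests, Holm-adjusted Tukey contrasts, generalized VIFs.
5. **A synthetic scan generator** with planted dyad-level effects and exact
   geometric realization, so every stage is testable against known ground
   truth (no raw observation data is published for this population).

## Worked example

```r
library(panmux)

# simulate a scan-sampling study with a planted grooming effect
cfg <- synth_config(
  n_sessions = 50,
  effect_multipliers = list(list(factor = "phc_infant", combo = "with->with",
                                 layer = "grooming", value = 3)),
  seed = 11)
roster <- make_roster(cfg)
records <- simulate_scans(dyad_state_probs(roster, cfg))

# dyadic indices and the 4-layer multiplex of one group
idx <- normalize_weighted(compute_indices(records, roster))
net <- build_multiplex(idx, "GroupA", weight = "weighted")
print(net)
#> multiplex network: 7 nodes, 4 layers
#>   layers: stationary_vicinity, affiliative, grooming, passive_close_proximity
#>   multiplex density: 1

# interlayer similarity and structural reducibility
reducibility(net)
#> structural reducibility: 3 merge steps
#>   step 1: passive_close_proximity+stationary_vicinity (height 0.0451)
#>   step 2: affiliative+passive_close_proximity+stationary_vicinity (height 0.0805)
#>   step 3: affiliative+passive_close_proximity+stationary_vicinity+grooming (height 0.0978)
#> relative entropy by layer count:
#>      4      3      2      1
#> 0.0040 0.0047 0.0047 0.0000
#> optimal number of layers: 3

# biography-effect model on the grooming index
fit <- fit_models(build_dyad_table(roster, idx), "grooming")
print(fit)
#> dyadic biography-effect model: response = grooming
#>   full vs null: chisq = 147.483, df = 9, p = 2.928e-27
#>   Type III (Satterthwaite) F tests:
#>              Sum Sq Mean Sq NumDF DenDF  F value Pr(>F)
#> origin_combo 0.0002  0.0001     3    74   0.6257 0.6007
#> phc_combo    0.0292  0.0097     3    74 113.8767 0.0000
#> sex_combo    0.0004  0.0001     3    74   1.4994 0.2218
#>   note: singular random-effect fit
```

The planted housing-condition effect is the only factor detected
(F = 113.9), and the Holm-adjusted Tukey contrasts
(`posthoc_contrasts(fit, "phc_combo")`) recover its direction: every
non-`with->with` category grooms less (estimates ≈ −0.052, adjusted
p < 1e-15), i.e. grooming concentrates in dyads where both partners grew
up with conspecifics — exactly the planted ×3 rate. The `chisq` is the
full-vs-null likelihood-ratio statistic; the singular-fit note reflects
that two social groups give the group-level random intercept almost nothing
to estimate (it is reported, never silently dropped). In the reducibility
output, merge heights are Ward linkage distances on the quantum
Jensen–Shannon matrix; here the two spatial-proximity layers merge first.

## Analysis workflow

The `analysis/` scripts run the pipeline end to end, writing all tables
under `results/`:

| script | stage |
| --- | --- |
| `01_simulate.R` | generate the demonstration scan dataset (planted biography effects) |
| `02_indices.R` | read scans, compute and normalize the dyadic indices |
| `03_networks.R` | densities, overlap, JSD, reducibility, centrality/versatility |
| `04_models.R` | the five mixed models, contrasts and VIFs |
| `05_validation.R` | recovery / detection / type-I / information-loss studies |
| `06_report.R` | one-shot `run_pipeline()` bundle + figures |

`run_pipeline()` accepts a YAML configuration (`read_pipeline_config()`)
and also ingests externally recorded data (`scans` + `biographies` CSV
paths in the canonical dialect documented in `?read_scans`).

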