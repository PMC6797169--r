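# formamentis

Forma mentis networks quantify how a population *feels* about a set of
concepts, not just how it connects them. The package builds these networks
from two standard psycholinguistic survey tasks — continuous free
association (each participant produces up to three responses per cue word)
and 1–5 Likert valence ratings — and provides the statistics needed to read
emotional structure off the resulting graph: per-word valence attributes,
neighborhood "valence auras", and emotional-homophily tests against
degree- and attribute-preserving null models. It is aimed at cognitive
network scientists and psycholinguists analysing their own survey data, and
it ships a fully seeded synthetic survey generator so every stage of the
pipeline can be validated against known ground truth.

## The method

1. **Cleaning.** Tokens are lowercased and passed through a user-supplied
   normalization map; each participant's first three response slots (in
   presentation order) are blanked as warm-up; forms with more than 25%
   blank cells are discarded, independently per task.
2. **Valence lexicon.** Ratings are pooled per word *i* (a blank rating
   counts as the neutral score 3). Each word is tested against the pooled
   ratings of all other words with a two-group Kruskal–Wallis test; at
   significance level α = 0.1, a word with lower median than the rest is
   labelled *negative*, higher median *positive*, otherwise *neutral*.
   Pooled-score asymmetry is summarised by Pearson's skewness
   3(mean − median)/σ.
3. **Network.** An undirected edge {c, r} joins every cue–response pair;
   its weight is the number of *distinct participants* producing the
   association in either orientation. A support filter (weight ≥ 2) is
   optional.
4. **Auras.** A word's aura is the valence composition of its immediate
   neighborhood: a negative aura means more negative than positive
   neighbors (ties are neutral).
5. **Homophily.** Valence attributes are scored −1/0/+1 and mixing is
   measured by Kendall's τ-b: across edge endpoints (assortativity) and
   between each word's score and its neighbors' mean score (clustering).
   Observed τ values are compared with 50 realisations of a configuration
   model that fixes each node's degree and attribute while rewiring links
   by degree-preserving double-edge swaps.

## Worked example

```r
library(formamentis)

sim <- simulate_survey(survey_config(n_participants = 100, h = 0.8, seed = 7))
fit <- forma_mentis(sim$associations, sim$ratings)
summary(fit)
#> Nodes 90, edges 2641 (filter level 1)
#> Valence: 30 positive, 30 neutral, 30 negative
#> Rejected forms: 0 association, 0 rating
#> Pooled rating skewness -0.013
#> Mixing: edge-endpoint tau 0.2102, node-neighborhood tau 0.8217

configuration_null_ensemble(fit$graph, "edge", n_realisations = 50, seed = 7)
#> Configuration-model null (edge tau, 50 realisations, seed 7)
#>   observed tau 0.2102 (p = 3.28e-66)
#>   null mean tau -0.0078, mean null p 0.489
#>   observed at percentile 100.0 of the null ensemble

aura_table(fit$graph, c("pos001", "neg001"))
#>     word frac_positive frac_neutral frac_negative     aura degree
#> 1 pos001     0.4754098    0.2459016     0.2786885 positive     61
#> 2 neg001     0.2000000    0.2727273     0.5272727 negative     55
```

The simulated survey plants 30 positive, 30 neutral and 30 negative words
and generates responses with homophily strength `h = 0.8` (80% of responses
are drawn from the cue's own valence pool). The fitted lexicon recovers all
90 planted labels; the observed edge-endpoint τ = 0.21 sits above every one
of the 50 null τ values (percentile 100), i.e. the planted homophily is
detected far beyond what degree and attribute counts alone explain, while
the null ensemble itself stays centered near zero (−0.008). Planted
positive words end up with predominantly positive neighborhoods (aura
fractions above), and lexicon means correlate with the simulated external
norms at τ = 0.68 over the 90 shared words (`cross_validate`).

Real survey data enter through `read_association_forms()`,
`read_rating_forms()` and `read_norms()` (tab/comma-delimited text; see the
function documentation for the expected columns), and
`run_pipeline(config)` — or the `inst/cli/fmn.R` script — runs the whole
analysis end to end, writing lexicon CSV, GraphML networks, aura tables and
homophily JSON plus a manifest that makes the run bit-reproducible.

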