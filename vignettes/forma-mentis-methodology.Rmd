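---
title: "Forma mentis networks: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forma mentis networks: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formamentis)
```

## The model

A forma mentis network represents a population's stance toward a set of
concepts by combining two layers of survey evidence. The *structural*
layer is a free-association graph: participants see cue words and write up
to three associative responses each, and every cue–response pair becomes
an undirected edge between lexical nodes. The *affective* layer is a
valence attribute on each node — positive, neutral or negative — estimated
from 1–5 Likert ratings pooled across participants. The combination lets
one ask questions neither layer supports alone: is a concept that people
rate as neutral nevertheless embedded in a cloud of negative associates?
Do people link words of like valence more often than chance?

Three modelling assumptions are worth making explicit. First, edges are
treated as undirected: the elicitation is directional (cue to response),
but the analyses concern neighborhoods and symmetric mixing, so the
orientation is deliberately discarded. Second, edge weight counts
*distinct participants*, not mentions — a single participant repeating an
association contributes once, so weight is population support, not
frequency. Third, a blank rating is read as deliberate neutrality (score
3) rather than missing data; this follows the survey instructions, where
respondents were told blanks and 3 both express neutrality.

## Valence classification

Pooled score distributions from Likert tasks are skewed and discrete, so
the per-word location test is nonparametric: word *i*'s ratings are
compared with the union of all other words' ratings by a two-group
Kruskal–Wallis test (tie-corrected H, df = 1). At level α = 0.1 (the
package default), a significantly lower median yields *negative*, higher
*positive*, otherwise *neutral*. Three numerical choices:

* **No multiplicity correction by default.** The decision rule is applied
  per word at α = 0.1; `build_lexicon(..., correct = "BH")` enables a
  Benjamini–Hochberg variant for users who prefer a controlled false
  discovery rate across the vocabulary.
* **Exact p-values for small words.** When the smaller group has fewer
  than 5 ratings, the χ² approximation is poor; the test switches to exact
  enumeration of all label assignments whenever at most 10^5 assignments
  exist. Against-the-rest comparisons have an enormous second group, so
  beyond that cap the χ² approximation is used — the cap is a feasibility
  bound, and the H statistic itself is always exact.
* **Shared global ranking.** For word *i* the combined sample (word plus
  rest) is always the full pooled vector, so all against-the-rest tests
  share one ranking; `build_lexicon()` exploits this and is exactly equal
  to calling `classify_word_valence()` word by word (a property the test
  suite asserts).

Pearson's skewness 3(mean − median)/σ uses the population (divide-by-n)
standard deviation; the formula's σ is not otherwise pinned down, so the
choice is exposed (`sd_type = "sample"`) and documented. The coefficient
is reported signed; users should note that a positive value indicates
mean above median even when the distribution's long tail is on the left
of its mode.

## Auras and their tie rule

The aura of a word summarises its immediate neighborhood's valence. Two
labelling rules coexist in the literature-standard description: a
three-class majority over {positive, neutral, negative}, and a two-class
comparison of positive versus negative neighbor counts. The package
defaults to the **two-class polarity rule** — negative aura iff strictly
more negative than positive neighbors, positive iff the reverse, neutral
on ties — because it matches the explicit definitions of positive and
negative auras (a concept "associated with more negative concepts than
positive ones"); the strict three-class majority is available as
`rule = "majority"`. Neighbor fractions are unweighted (each neighbor
counts once) by default, since auras describe the composition of the
neighborhood, not the strength of individual links; `weighted = TRUE`
switches to edge-weight counting.

## Homophily statistics and the null model

Attributes are scored −m/0/+m (m = 1 by default; the statistics are
rank-based, so any m > 0 gives identical values — asserted as a test
property). Two Kendall τ-b statistics are computed:

* **Edge-endpoint τ** pairs the scores of every edge's two endpoints.
  Undirected edges have no canonical orientation, so each edge contributes
  *both* orientations (symmetrization), making the statistic exactly
  invariant to how the edge list happens to be stored; a seeded
  single-orientation mode exists for sensitivity analysis.
* **Node-neighborhood τ** pairs each node's own score with the unweighted
  mean score of its neighbors, the graph-level analogue of the aura
  definition.

The Kendall implementation is tie-corrected τ-b with two exact
computation routes (a contingency-table scan for few-valued data, blocked
pair counting otherwise — both asserted equal to an independent O(n²)
oracle), a normal-approximation p-value with the classical tie-corrected
variance, and full-enumeration exact p for n ≤ 8.

Observed mixing must be compared with what degree heterogeneity and
attribute counts alone produce. The null model fixes both: each
realisation rewires the simple graph by degree-preserving double-edge
swaps (10 × |E| swap trials per realisation; swaps creating self-loops or
multi-edges are rejected) while node attributes never move. The ensemble
reports the null mean τ, the mean of per-realisation p-values, and the
observed τ's percentile among the null τ values. Only the percentile is
recommended for inference: the per-realisation p-values test each null
network against *its own* randomness, not the observed value against the
ensemble, and their mean is reported purely for completeness.

## The synthetic generator

Because raw survey forms of this kind are typically collected anonymously
and not redistributable, the package treats a seeded generator as a
first-class module. It emulates the study design: each participant sees 50
cues (10 fixed across participants, 40 drawn at random), produces 3
responses per cue, and rates the full vocabulary on the 1–5 scale. The
vocabulary is partitioned into planted positive/neutral/negative pools
(default 30/30/30); responses follow a mixture — with probability *h* from
the cue's own pool, otherwise uniform over the vocabulary — so *h* is a
direct dial on emotional homophily; ratings are drawn per pool from
skewed distributions (positive pool (0, 0, .1, .4, .5), neutral
(.05, .2, .5, .2, .05), negative (.5, .4, .1, 0, 0)) and blanked with
probability 0.05, a realistic light missingness for a supervised lab
task. Default `n_participants = 100` is the scale at which the package's
recovery and calibration properties are asserted; `h = 0.5` is the
neutral midpoint of the dial. One simplification: simulated participants
rate the whole vocabulary, whereas real respondents rate only cues and
their own responses — strictly denser rating data, which matters only for
per-word rater counts.

What the generator does *not* emulate: real lexical statistics (token
frequencies, morphology, spelling variation), topic structure among cues,
participant heterogeneity in response style, and any correlation between
a participant's associations and their ratings. Passing recovery tests on
synthetic data therefore demonstrates the estimators' correctness and
calibration under the declared design, not robustness to the messiness of
real survey text — that is what the normalization map and rejection rules
are for, and they are tested separately on constructed fixtures.

```{r example}
sim <- simulate_survey(survey_config(n_participants = 30, h = 0.8, seed = 1))
fit <- forma_mentis(sim$associations, sim$ratings)
summary(fit)
```

## Cleaning order and degenerate inputs

The cleaning rules are applied in a fixed order: lowercase/normalize,
then warm-up removal (the first three response slots per form, in
presentation order — the recorded row order of cues), then blank-fraction
rejection. The order matters: warm-up-blanked cells count toward the 25%
rule, the conservative reading. Rejection uses a strict inequality
(exactly 25% blanks is kept), and the two tasks are filtered
independently — a participant rejected in one task keeps contributing to
the other, with the overlap logged. Degenerate inputs are signalled, not
silently absorbed: zero-cell forms, constant vectors in τ (undefined),
all-tied Kruskal–Wallis samples (H = 0, p = 1), single-edge graphs (too
constrained to rewire), empty post-filter networks (allowed, flagged).

## Problem sizes and reproducibility

The test suite validates the statistics against independent oracles
(pair counting for τ, hand-computed mid-ranks for H, full enumerations
for exact p-values) and asserts the end-to-end properties at 100
participants, 90-word vocabulary, 20 seeds and 50-realisation null
ensembles — sizes chosen so the full suite completes in a few minutes
while keeping every Monte-Carlo margin wide. All stochastic steps take
explicit integer seeds and are bit-reproducible; `run_pipeline()` writes
a manifest (config hash + seed) sufficient to reproduce a run exactly.

## Known limitations

* The valence classifier's power depends on rater counts per word;
  idiosyncratic associates rated by few participants default to neutral,
  which deflates homophily estimates on sparse data.
* Against-the-rest testing reuses the pooled distribution for every word,
  so the tests are not independent across words; the optional BH switch
  controls FDR only approximately under this dependence.
* The configuration null counts swap *trials*, not accepted swaps; at
  10 × |E| trials the acceptance rate is high for the sparse-to-moderate
  graphs this method targets, and degree sequences and attribute counts
  are preserved exactly regardless.
* Auras and mixing statistics ignore edge weights by default; populations
  whose agreement structure matters should use the weighted variants and
  compare.
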