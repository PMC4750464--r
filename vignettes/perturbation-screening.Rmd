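---
title: "In-silico perturbation screening of probabilistic Boolean signalling models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico perturbation screening of probabilistic Boolean signalling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolscreen)
library(dplyr)
```

## The model and its semantics

`boolscreen` simulates logical (Boolean) models of signal transduction and
screens them systematically for influential components. A model is a set of
*components*, each holding a binary state. *Internal* components (signalling
proteins, second messengers) update by a regulatory truth table over their
regulators. *External* components (ligands, matrix contacts, stress signals)
have no regulatory function; their activity level `p` (a percentage) is
realised during simulation as an independent Bernoulli(`p`/100) draw at every
step, which emulates a ligand concentration: the higher the level, the more
often the receptor sees the ligand.

Simulation is synchronous: at step `t + 1` every internal component reads the
global state at step `t`. A simulation runs `steps = 800` iterations and
reports, per component, the **activity level (AL)**: 100 times the fraction
of active states over the trailing `window = 300` iterations, averaged over
`replicates = 30` repeat simulations. The leading 500 steps act as burn-in;
by then the trajectory has settled into its long-run behaviour, and the AL is
a semi-continuous (0–100) readout of a discrete model. With these defaults a
pass-through node downstream of an external at level `p` has expected AL `p`,
which is the calibration the whole pipeline relies on.

Two numerical conventions are worth stating. First, the trailing window is
exactly the final `window` states of the `steps`-step trajectory (the state
after step `steps - window + 1` through the state after step `steps`).
Second, initial internal states are Bernoulli(0.5) unless an explicit start
state is supplied; with a 500-step burn-in the start has no detectable
influence on the windowed AL, and an unbiased start avoids favouring either
attractor in bistable circuits.

## Environments

An *environmental condition* assigns each external component a range of
activity levels, emulating an extracellular milieu. `builtin_conditions()`
provides five: death, growth, motility, quiescence and an unconstrained
random environment, over the nine stimuli of the large signal-transduction
model this methodology was developed for (ECM, EGF, the calcium pump, four
GPCR ligands, IL1/TNF, stress). A screen samples `n_combinations = 100`
concrete environments per condition, each stimulus drawn uniformly on its
range. Uniform is a choice, not a given: the source methodology says only
that combinations are "randomly selected", and the uniform distribution is
the maximum-entropy default on a bounded interval. Conditions can be
overridden from YAML/JSON, including an alias table for reconciling ligand
labels with model component ids.

## Random numbers: counter-based substreams

All stochastic draws (environment sampling, initial states, per-step
external states) come from a counter-based generator: a splitmix64 hash of
the tuple (seed, environment combination, replicate, component, step). This
has two consequences the screen depends on:

1. **Common random numbers.** The wild type and every perturbation of a
   screen see bit-identical environments and external input streams, so any
   difference is attributable to the clamp, and the identity intervention
   (an empty perturbation) reproduces the wild type bit-exactly.
2. **Local interventions.** Because each (replicate, component) pair owns
   its substream, clamping a component consumes no other component's draws.
   Components not downstream of the clamp in the interaction graph follow
   bit-identical trajectories — a property the test-suite asserts exactly,
   and a useful sanity check that perturbation effects propagate only
   through regulatory edges.

The scheme is deterministic given the seed, independent of R's session RNG,
and reproducible across platforms.

## Perturbations and scoring

A perturbation clamps components at 0 (knockout / loss of function) or 1
(overexpression / gain of function) for the entire run, including step 0.
`single_perturbation_screen()` runs the wild type plus every internal
component clamped in one direction; `combinatorial_perturbation()` runs a
joint clamp such as `perturbation(PI3K = 0, IP3R1 = 1)`.

Scoring compares, per component, the wild-type and perturbed distributions
of per-combination replicate-mean ALs with a two-sample, two-sided
Kolmogorov–Smirnov test. The **difference value (DV)** is the KS statistic
when `p < 0.05`, otherwise 0; the clamped component itself is forced to 0
since interest lies in its effect on the rest of the network. The KS sample
unit is the environment combination (not the individual replicate): the
Fligner–Killeen check (`replicate_homogeneity()`) verifies that replicates
of the same combination are homogeneous, so combinations are the independent
draws and pooling replicates first avoids pseudo-replication. Exact KS
p-values are used when both groups have at most 25 combinations, the
asymptotic distribution otherwise. No multiple-testing correction is applied
by default, matching the raw-threshold convention of this screen design; a
Benjamini–Hochberg option exists (`p_adjust = "BH"`).

The **influence score (IS)** of a perturbation is the sum of its DVs over
all components; the top `ceiling(0.10 * M)` components (ties broken
lexicographically — the rounding and tie rules are our choice, stated here
because the source convention does not specify them) are *most influential*
and components with IS exactly 0 are *least influential*. `most_affected()`
ranks the components a given perturbation moves (threshold 1.0 = complete
separation of the AL distributions), `fold_differences()` classifies each
(perturbation, component) pair into exactly one of: a numeric fold
(perturbed/WT mean AL), complete inactivation (perturbed mean 0, WT
positive), complete activation from zero, no change (both 0), or NSA ("no
significant alteration", DV = 0). Where a pair is both degenerate (both
means 0) and non-significant, the degenerate label wins: a fold of 0/0 is
not an alteration that a DV could make "non-significant".
`cross_condition_overlap()` and `upstream_regulators()` support the
downstream set-algebra and feedback analyses.

When counting a perturbation's "affected" components across several
conditions, the default is DV = 1 in *at least one* condition (a pooled-mode
alternative is a one-liner on the DV tables); the any-condition reading is
the one consistent with combining per-condition screens.

## The expression stage

To compare model predictions against expression data, log2 intensities are
standardised per array into Z-scores, and per gene the **Z-ratio** is the
difference of group-mean Z-scores scaled by the standard deviation of those
differences across genes; calls are made at ±1.50. Two conventions are
explicit arguments: the SD used for Z-scores defaults to the sample (n−1)
convention with a population option, and the Z-ratio denominator is taken
over *all* genes. When treated and control are identical the denominator is
0 and the Z-ratio is defined as identically 0. Note the statistic is
self-standardising: under a pure-noise null roughly a tenth of genes will
still exceed ±1.5 in any single comparison, so calls acquire meaning through
effect size, replication across comparisons (`concordance(mode = "all")`),
or both. `concordance()` cross-tabulates model fold changes (≥2-fold by
default) with the calls through a component-to-gene map, counting a
component concordant if any mapped gene agrees in at least one replicate
comparison (strict all-replicate mode available).

## Synthetic data: what it emulates, what it does not

`random_boolean_network()` generates Kauffman-style random networks (uniform
regulator choice, independent Bernoulli truth-table outputs with a bias
knob) with designated stochastic external inputs. `motif_fixtures()`
provides hand-built circuits with exhaustively understood behaviour —
pass-through, a monotone AND-cascade, a negative-feedback oscillator, an
incoherent feed-forward loop, and a mutual-antagonism pair in which knocking
out one branch de-represses the other (echoing the mutually inhibitory
relationship between a kinase and a calcium-channel branch that motivates
combinatorial targeting). `synthetic_expression()` plants ±`effect_size`
log2 shifts in a fraction of genes over Gaussian noise.

These generators make every pipeline stage testable without downloads, and
that is all they claim. Random networks do not have the in-degree
distribution, redundancy or feedback structure of a curated signalling
map; the expression generator has no array-level artefacts, probe effects
or correlation structure. Green tests on synthetic data therefore validate
the *machinery* (simulator semantics, scoring identities, calibration), not
the biology of any particular network.

## Sizes used by the shipped checks

The package's own test-suite and the bundled acceptance script run on
reduced problem sizes chosen so the full suite completes in a few minutes on
one core while still giving each statistical check adequate resolution:
screens use 12–20 environment combinations with 3–5 replicates and 100–400
steps on 5–34-node models; the false-positive calibration uses 100–200
WT-vs-WT repeats at 20 combinations per group (where the exact null
distribution of the KS statistic is computable via `stats::psmirnov`, so the
empirical rate is compared with the test's exact size rather than a nominal
0.05 the discrete statistic cannot attain); the expression stage uses 1,000
genes and 4 arrays per group. Full-scale screening (800 steps, 300-step
window, 100 combinations, 30 replicates) is the package default for real
models.

The checks that reproduce published numbers for the 137-component
signal-transduction model need that model's SBML-qual file, which is journal
supplementary material and is not redistributed here; the corresponding
tests state this explicitly when the file is absent and run in full when it
is placed at `inst/extdata/signal_transduction_137.sbml`.

## Known limitations

* Synchronous updating only; asynchronous or continuous-time semantics are
  out of scope, and synchronous updates can sustain oscillations (the
  negative-feedback fixture) that an asynchronous scheme would damp.
* Boolean (two-level) models only; multi-valued logical models are rejected
  at load.
* The mean AL over a screen is computed as the mean over environment
  combinations of replicate means. With equal replicate counts this equals
  the grand mean; variance differs, which matters only if downstream code
  treats the per-combination means as i.i.d. draws (as the KS stage does,
  deliberately).
* Clamps are all-or-nothing; dose-like partial clamps are not provided.

## A worked example

```{r example, eval = FALSE}
fx <- motif_fixtures()
cond <- environment_condition("e", list(E = c(35, 85)))
cfg <- sim_config(steps = 800, window = 300, replicates = 30, seed = 1)

screen <- single_perturbation_screen(fx$and_cascade, cond, "inactivate",
                                     n_combinations = 100, config = cfg)
dvm <- screen_difference_values(screen)
ranking <- influence_scores(dvm)
tidy(ranking)
autoplot(dvm)
most_affected(dvm, "H")
fold_differences(screen$wild_type, screen$perturbed[["H:0"]],
                 dvm = dplyr::filter(dvm, perturbation == "H"))
```
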