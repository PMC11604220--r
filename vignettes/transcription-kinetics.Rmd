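---
title: "Modeling the RNA polymerase II transcription cycle with txkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the RNA polymerase II transcription cycle with txkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txkinetics)
```

# The model

`txkinetics` simulates steady-state RNAPII occupancy along a discretized
model gene.  Space is coarse-grained into 120 bp compartments: an
optional UAS (enhancer), a promoter, `N` transcript bins (default 10,
i.e. a 1.2 kb coding region, the median transcribed length in budding
yeast), and a terminator.  Every step of the transcription cycle is a
Poisson process, so the whole gene is a continuous-time Markov chain
(CTMC); at most one polymerase may occupy a compartment (hard-core
exclusion, as in the TASEP family of lattice models).

Two recruitment architectures are modeled.  **STM** genes (bound by
sequence-specific transcription factors plus coactivators) recruit
RNAPII to the UAS at `k1` (/s), lose it at `k-1`, and transfer it to an
empty promoter at `k2`, with reversal at `k-2` possible only before
TFIIH arrival and only into an empty UAS.  **TFO** genes (transcription
factor only) have no UAS compartment and recruit directly to the
promoter at `k3`.  In both classes the promoter-bound polymerase is in a
pre-TFIIH sub-state from which it dissociates at `k-3`; TFIIH
recruitment (`k4`) is the committed step, after which dissociation and
reversal are disabled and the polymerase awaits initiation (`k5`, gated
on transcript bin 1 being empty).  Elongation is a hop chain: a
polymerase advances one compartment at `k6 / 120` per second (with `k6`
in bp/s internally; user-facing configuration takes bp/min, the unit in
which elongation rates are usually quoted), blocked when the successor
compartment is occupied.  The final hop enters the terminator, which
empties at `k7`; each terminator release is one completed mRNA.

## Exclusion semantics

A move whose target compartment is occupied has **zero propensity** — it
is absent from the transition set rather than fired and rejected.  This
keeps the process Markov with the stated rates.  The same rule applies
uniformly: a second polymerase cannot be recruited to an occupied UAS or
promoter, initiation requires bin 1 empty (initiation physically
relocates the polymerase from the promoter into bin 1), and the last
transcript bin cannot hand off into an occupied terminator.

## Rate presets

Published values ship as presets (`default_rates()`): `k1 = 0.002`/s and
`k-1 = 0.003`/s from single-molecule measurements of UAS association;
`k3 = 0.002`/s (set equal to `k1` for lack of an independent
measurement); `k5 = 0.1`/s from TFIIH residency; `k6 = 1000` bp/min;
`k7 = 0.0325`/s, a ~30 s terminator pause at the lower bound of the
published 56±20 s / 70±41 s termination times — the value that best fits
cleavage-based occupancy.  The remaining rates (`k2`, `k-2`, `k-3`,
`k4`) have no published values and are the free parameters of the fit;
their functional ranges (`functional_ranges()`) bound the grid search,
and `default_rates()` places them at the range midpoints when a single
concrete rate set is needed.  `chip_forced_rates()` packages the rate
overrides that *can* reproduce a transcript-dominated (ChIP-like)
profile: no promoter dissociation, effectively instantaneous TFIIH
recruitment (realized as a large finite `k4`, default 10/s, since the
chain needs a finite rate), doubled initiation, and `k7 = 0.14`/s.

# The stochastic engine

`simulate_population()` runs the direct Gillespie method per gene:
cumulative propensity plus two uniforms per event.  State spaces are
tiny (at most 14 compartments), so dependency-graph variants would buy
nothing.  The compiled core mirrors the transition structure defined
once in R by `list_transitions()`; the package keeps a pure-R reference
engine built directly on `list_transitions()`/`apply_event()` and the
test suite checks compiled engine, reference engine, and the exact
oracle against each other, so the three routes cannot drift apart
silently.

Design choices that matter:

* **Occupancy is a time-weighted average** over the measurement window
  (default the final 60 s of a 1000 s run), not a set of snapshots: for
  a piecewise-constant indicator this is the unbiased estimator of mean
  occupancy.  Promoter occupancy counts both pre- and post-TFIIH
  sub-states.
* **Initial condition is an empty gene.**  At the preset rates all
  relaxation times are far below the 940 s burn-in, so the window
  samples the stationary law.  (For deliberately degenerate parameter
  choices this need not hold — see *Numerical choices* below.)
* **Per-gene RNG streams** are derived from `(master seed, gene index)`
  (splitmix64 seeding a xoshiro256++ generator), so population results
  are independent of execution order and a single gene can be
  re-simulated bit-identically (`simulate_gene(i)` equals gene `i` of
  the population run).
* **Event tallies** are recorded both over the full run and within the
  measurement window; the windowed initiation/termination counts give
  flux estimates comparable against `k7 x` terminator occupancy without
  burn-in bias.

## The exact oracle

`ctmc_stationary_occupancy()` enumerates the reachable state space by
breadth-first search over `list_transitions()` (3 promoter sub-states x
2 flags per other compartment; 6144 states for the default TFO gene,
12,288 for STM), builds the sparse generator, and solves the stationary
linear system (one balance equation replaced by the normalization
constraint).  A Tarjan strong-components check rejects chains with more
than one closed communicating class, where the stationary law is not
unique; architectures beyond a configurable state cap are refused with
the required cap named.  Compartment occupancy is the summed stationary
probability of the states occupying that compartment, and
`stationary_fluxes()` exposes the initiation/termination fluxes whose
equality is a stationarity identity.  The oracle is what the test suite
trusts: simulated means must sit within three standard errors of it.

# The minimal model

`minimal_occupancy()` strips the recruitment machinery: a polymerase is
always available at the promoter (instantaneous refill), escapes into
bin 1 at `1/promoter_dwell` when bin 1 is empty, elongates, and pauses
at the terminator for `termination_dwell` on average.  It asks whether
published dwell times alone predict promoter/terminator enrichment.

Because the physical promoter flag is trivially always set under
instantaneous refill, the reported promoter occupancy is the occupancy
attributable to productively cycling polymerase: escape flux times dwell
(Little's law).  With escape rate `1/dwell` gated on bin 1, this equals
`P(bin 1 empty) = 1 - occ(bin_1)` exactly — near 1 when the gene flows
freely, and small when elongation or termination congests the entrance.
This accounting is what makes the dwell-time sweep informative: a
promoter pinned at occupancy 1 could never fall below the transcript,
yet short dwell times with slow elongation must produce exactly that
ChIP-like inversion.

`sweep_minimal()` crosses dwell times (default 5–20 s), elongation rates
(1000–3000 bp/min) and termination pauses (5–70 s) and flags, per
combination, whether promoter and terminator occupancy exceed the mean
transcript-bin occupancy (per-bin *mean*, not maximum — the natural
region summary given that empirical transcript signal is averaged over
the region).  With the stochastic engine a flag is set only when the
difference exceeds twice its standard error; the exact engine compares
directly.  The expected orderings are phase-dependent, and the package
states them in the standard exclusion-process terms: with entry rate
`a = 1/dwell`, exit rate `b = 1/termination_dwell` and hop rate
`p = elongation/120` per second, the entry-limited (low-density) phase
requires `a < p/2` and `a < b`; there promoter occupancy exceeds the
transcript mean whenever the dwell exceeds the per-bin elongation time,
and a 70 s terminator pause dominates every transcript bin whenever the
promoter is not itself the entry bottleneck.  Long pauses drive the gene
into the exit-limited phase where transcript bins fill and the promoter
(by flux accounting) empties — which is why the sweep grid's exact
composition matters and why the package asserts orderings, not counts,
over its default grid.

# Ensemble fitting

`grid_search()` fits the free rates to an empirical per-region vector
(UAS, promoter, transcript, 3'UTR for STM; promoter, transcript, 3'UTR
for TFO — the TFO model has no UAS compartment, and by default the
empirical UAS bin is simply not part of the TFO fit).  Every point of
the Cartesian grid over the functional ranges is simulated, regions are
aggregated (single compartments copied, transcript bins averaged,
terminator mapped to the 3'UTR region), and agreement is scored with
cosine similarity — scale-invariant, so dimensionless occupancies
compare directly against CPM-normalized cleavage (CPMn).  All models
scoring at least the threshold (default 0.995) form the ensemble; when
no model reaches the threshold — the situation met when fitting
transcript-dominated ChIP-like shapes — the top-N models are returned
with an explicit fallback flag instead.  Predictions are converted to
empirical units by L2 scaling (`l2_scale()`), which preserves cosine
similarity, and the ensemble-average prediction is the mean of the
members' scaled vectors.

All grid points share one simulation seed (common random numbers), so
score differences between neighboring points reflect the rates, not
Monte-Carlo noise, and the whole search is reproducible from the master
seed.  Grid resolution is configurable (default 10 points per free
rate; the acceptance runs use 5): ensemble *size* depends on resolution
and is therefore never asserted — containment of the generating
parameters and score properties are.

## Perturbations

A `perturbation_scenario()` replaces specific rates with absolute values
or ranges; presets cover TFIIB depletion (20/60 min), TFIIH-kinase
inhibition, and the Gcn4 positioning-domain and null mutants, each with
the alternative rate-combination models that fit those experiments.
`apply_perturbation()` re-simulates each ensemble member under the
scenario (range-valued replacements are sub-gridded within the member,
default 3 points, and the envelope reported) and reports region-wise
changes **in empirical units using the member's baseline conversion
factor**: the scale factor that matches the baseline prediction to the
fitted data is held fixed for the perturbed prediction.  Rescaling the
perturbed prediction independently would erase absolute decreases —
exactly the signal a global perturbation produces — leaving only shape
changes.  `score_perturbation_fit()` compares modeled and observed
change vectors by cosine similarity, where sign disagreements are
penalized; the comparison metric for change vectors is a package choice,
made explicit here because region-wise agreement of signed changes is
what the perturbation analyses assert.

# Genomic signal

The supporting computations reproduce the conventions used for
region-binned cleavage data:

* **Coordinates** are 1-based closed intervals internally (the native
  convention of R/GRanges); BED and bedGraph files are converted at the
  I/O boundary by rtracklayer.  Gene regions are defined by inclusive
  offsets with the TSS/TES at offset 0: UAS `-500..-151` and promoter
  `-150..+25` around the TSS (the promoter therefore spans 176 bases —
  offset arithmetic here is ambiguous by ±1, so the package fixes and
  tests this convention), transcript `+26` from the TSS to `-76` from
  the TES, terminator `-75..+150` around the TES; minus-strand genes are
  exact mirror images.  Genes whose transcript would be empty after the
  promoter/terminator encroachment (span < 102 bp) are excluded with a
  recorded reason.
* **CPM normalization** scales per-base counts by `1e6 / total`;
  **background subtraction** (e.g. soluble-MNase control) is element-wise
  on identically shaped, identically united tracks and retains negative
  values, since depletion relative to the accessibility control is
  meaningful.
* **Metagene profiles** use three segments (1 kb upstream, the
  length-normalized transcript, 1 kb downstream) of 100 bins each;
  replicates are averaged per base first, then bins within a gene, then
  across genes — the order matters for unequal gene lengths and is fixed
  to match how replicate-averaged profiles are usually built.
  **Metasite profiles** average oriented ±250 bp windows at base
  resolution, excluding sites whose window would cross a contig edge,
  then smooth.
* **Smoothing** is a sliding window (width 10, step 5) whose windows are
  truncated at the right boundary and reported at their truncated-window
  centers; edge policy and output coordinates are package conventions,
  stated because they are not standardized anywhere.
* **Expression filtering** keeps genes with replicate-mean nascent
  counts ≥ 50 (inclusive).  **Relative region enrichment** divides a
  factor's length-normalized region signal by a reference's (typically
  total RNAPII) per gene and replicate; the z-score for a difference of
  ratios divides by the root of the summed squared replicate standard
  errors with a two-sided normal p-value — a deliberate, documented
  construction, since the dispersion formula behind such panels is
  rarely printed.

# Synthetic data

`synth_region_vectors()` generates fitting targets with known ground
truth: occupancy simulated under known rates, aggregated, noised per
replicate, and converted to a pseudo-CPMn magnitude with a single
truth-derived L2 factor (so the relative noise structure survives the
unit change).  The default noise model is multiplicative gaussian on
region values with three replicates and 5% relative SD — matching the
form in which empirical data enter the fit (region-level replicate
means); a Poisson-counts mode exists for count-level end-to-end tests.
`synth_genome_fixture()` builds a single-contig genome whose genes have
exactly specified per-base region means and whose sites carry a
specified oriented profile, giving bit-exact expectations for
`region_signal()`, `metagene()` and `metasite()`.

What the generators do **not** emulate: sequence preference of the
nuclease, nucleosome structure, fragment-level read sampling, mappability
or copy-number artifacts.  Passing tests therefore demonstrate that the
computations are correct on clean signal, not that the pipeline is
robust to every artifact of real sequencing data.

# Numerical choices

* Stationary solves use sparse LU on the generator transpose with one
  equation replaced by normalization; solutions are validated
  (non-negativity, unit mass to 1e-10) and tiny negative round-off is
  clipped and renormalized.
* The degenerate two-state check (`k4 = 0`, `k3 = k-3`) has a 250 s
  relaxation time, so its simulation check measures over `[2940, 3000]` s
  of a 3000 s run, where the window genuinely samples the stationary
  value being compared against; the standard conditions (1000 s, final
  60 s) are kept everywhere the preset rates apply, where relaxation is
  fast.
* Zero vectors make cosine similarity undefined and raise errors rather
  than returning 0; region values must be finite and non-negative.
* A chain with zero total propensity simply fast-forwards its clock to
  the end of the run (an absorbing state is a valid trajectory, not an
  error).
* Monte-Carlo comparisons in the test suite use 3-standard-error bands;
  sweep flags use a 2-SE rule so that ties are not resolved by noise.

## Problem sizes

The package defaults to the study conditions (100,000 genes, 1000 s,
final 60 s).  The test suite and acceptance script scale Monte-Carlo
sizes to what a laptop-class single core solves in minutes — 10,000
genes for engine/oracle comparisons and fits, 5 grid points per free
rate (625 simulations for the four-parameter STM recovery), reduced
two-bin architectures where the oracle is the reference — sizes at which
the 3-SE criteria are already stringent (standard errors of a few 1e-4).

# Limitations

The model has no nucleosomes, no promoter-proximal pausing or
backtracking, no explicit CTD phosphorylation states, and one polymerase
per 120 bp compartment by construction.  Rates are per-class aggregates:
fitting uses class-average region vectors, not per-gene data.  The
UAS-to-promoter transfer is a single exponential step standing in for an
ordered assembly pathway, and recruitment to an occupied UAS is blocked
(exclusion is assumed uniform) although the data neither confirm nor
exclude stacking of polymerases at enhancers.  Ensemble sizes depend on
grid resolution and are not meaningful in absolute terms.  Finally, the
mapping from occupancy to cleavage frequency is taken to be linear
(the L2 unit conversion); saturation or accessibility effects in the
underlying assay are outside the model.
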