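---
title: "Demography-aware ARG sampling and introgression mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demography-aware ARG sampling and introgression mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Given unphased genome sequences from a handful of modern and archaic
hominins (or any small set of closely related populations), we want to know
*where along the genome* a sampled lineage descends from a migrant that
crossed between populations — for example, segments of the Neanderthal
genome that trace back to early modern humans, or Denisovan segments from an
unsampled ("super-archaic") hominin. The confounder is incomplete lineage
sorting: deep coalescence within a structured population history produces
locally unusual genealogies without any gene flow. Summary statistics
struggle to separate the two, so `argthreader` takes the model-based route:
it samples full ancestral recombination graphs (ARGs) — the sequence of
local coalescent trees along the genome, linked by recombination — under a
user-specified demographic model in which migration is an explicit,
low-prior event, and reads introgressed tracts directly off the sampled
genealogies.

## The model

**Discrete-time structured coalescent.** Time is discretized on a fixed grid
of `K` coalescence times (the default hominin grid has 20 points from 0 to
15 Mya, denser near the present). Population divergences and migration
events live at *half time-points*, the arithmetic midpoints of adjacent grid
times; user-supplied event times are snapped to the nearest half time-point
(ties toward the younger, a documented deterministic rule). With the default
grid this places the usable migration times at 50, 150, 250 and 350 kya.
The population model is a tree with a "continuing parent" convention
(a child merges into its parent, which continues above the merge), with
piecewise-constant diploid sizes per population and per epoch. Times are
entered in years and converted to generations with a generation time of 29
years by default.

**Migration bands.** A band `source -> dest` at time `t` with prior rate
`p_M` means: a lineage traced backwards that sits in `dest` at `t` follows
the migrant path into `source` with prior probability `p_M` (default 0.01
— migration is a priori rare, which is what makes posterior calls
conservative). The sequence of populations a branch occupies through time,
including any band crossing, is its *population path*.

**Threading HMM.** The sampler is a Gibbs chain over ARGs. One move removes
a haploid lineage from every local tree ("unthreading") and re-samples its
coalescence points with a hidden Markov model along the genome whose states
are `(branch, time, population path)` triples: which branch of the fixed
tree the new lineage coalesces onto, at which grid time, via which
population path. Coalescence requires the new branch and its target to
occupy the same (non-ghost) population at the coalescence time. Transitions
between adjacent columns factorize as "no recombination" (probability
`exp(-r * w * b)` for recombination rate `r`, column width `w` bp, and new
branch length `b` generations) versus a recombination placed uniformly on
the new branch followed by a re-coalescence walk up the discrete grid:
within each interval the walk coalesces onto one of the `m` co-located
branches with the discretized rate `m / (2N)`, and at each half time-point
it multiplies in the band factors — `p_M` for states whose path crosses a
band there, `1 - p_M` for states that pass without crossing. Rows of the
transition matrix sum to one by construction, and the marginal probability
that the new branch is migrant under uniform emissions equals the band
prior (verified against exhaustive enumeration in the tests). Emissions are
two-state (ancestral/derived) pruning likelihoods with per-column mutation
rates; the root carries the ancestral allele. Forward filtering uses
per-column scaling (checked against a log-space recursion), and stochastic
backward sampling draws the threading exactly from its posterior.

Two bands can share a half time-point for the same recipient (the hominin
model places `Hum->Nea` and `Sup->Nea` at the same `t_mig`). Band choices
are then weighted sequentially in model order — cross the first band with
`p_1`; otherwise cross the second with `p_2`; otherwise stay with
`(1-p_1)(1-p_2)` — which keeps rows exactly stochastic and agrees with
independent weighting to second order in the (small) rates.

**At most one migration per location.** By default at most one branch of
any local tree may cross a band. Several lineages can still be introgressed
at one position when they descend from a shared migrant ancestor (they
coalesce below the band and only the ancestral branch crosses) — this is
exactly the configuration behind homozygous tracts. The constraint also
means an unsampled *ghost* population never hosts more than the single
migrant lineage, so ghost sizes are irrelevant to inference and
within-ghost coalescence is excluded from the state space.

**Phase integration.** Diploid genomes may be unphased: phase is randomized
up front (driven by the run seed, so runs are reproducible) and, after each
lineage of an individual is rethreaded, a Gibbs step re-draws the
assignment of the two alleles to the individual's two lineages at each
heterozygous column, proportional to the local tree likelihood.

**Schedule.** The chain runs `n_iter` iterations (one iteration = rethread
every haploid lineage once), discards `burnin`, and keeps every `thin`-th
ARG afterwards; the published schedule (2000 / 500 / 20) retains 75
samples. Migration is disabled for the first `start_mig` iterations
(default 100) so the chain settles into a sound tree structure before
exploring migrant configurations. Site compression (default 10 bp per
invariant column; variant sites keep their own single-bp column with the
column's mutation rate scaled by the bases it represents) keeps the state
sequence short.

## Calling and dating introgression

A retained ARG encodes introgression directly: a lineage is migrant at a
column when its ancestral branch at the band's half time-point follows the
band. Posterior tracks report, per (band, individual, column), the fraction
of retained ARGs with exactly one (`p_het`), both (`p_hom`) or at least one
(`p_any = p_het + p_hom`) of the individual's lineages migrant. Regions are
maximal runs with `p_any >= 0.5` (the threshold is inclusive); a region is
`hom` when columns with `p_hom >= p_het` hold the base-pair majority
(het/hom switching below threshold affects a negligible fraction of sites,
so the majority rule is a convention, documented here). Adjacent calls are
not merged across sub-threshold columns (a `merge_bp` knob exists,
defaulting to 0). An individual's coverage is half its heterozygous plus
its homozygous called fraction; haploid samples (the outgroup) are excluded
from individual-level calling.

Because older migrations drift to higher frequency among recipients, the
joint-zygosity spectrum of called regions dates the migration: regions are
flattened across recipient individuals, labeled per individual (hom / het /
absent by base-pair majority of overlap) and the bp-weighted category
fractions compared — with bootstrap confidence intervals over regions —
against caller-ascertained spectra simulated under candidate migration
times. A candidate time is accepted when its intervals overlap the
observed intervals in every category; no likelihood over spectra is
defined, so none is invented.

## The simulator and what it does (not) emulate

`simulate_dataset()` drives msprime: the structured coalescent with
recombination under the model's divergence/size history, pulse admixture at
the stated times and proportions, ancient sampling ages honored exactly
(inference later snaps them to the grid, as with real data), and binary
mutations. Ground truth is defined per haploid lineage: an interval is
migrant for a band exactly when the lineage's ancestor just above the pulse
time sits in the source population, extracted from census nodes placed at
the pulse. The deep-introgression preset mirrors the published design — a
2 Mb window with 5 unphased diploids (two Africans, the two Neanderthals
sampled at 115 and 52 ky, a Denisovan at 72 ky) plus a haploid outgroup,
pulses `Hum->Nea` 8%, `Sup->Den` 4%, `Sup->Afr` 0.5% — and `degrade()`
adds randomized phase and BED-style missing-data masks. The recent preset
adds a European population (split 100 kya, size 2,100, exponential growth
at 0.002/generation from 42 kya to 37,236 today) with a 2% `Nea->Hum`
pulse at 50 kya and an optional 5% `Hum->Nea` pulse at 250 kya.

Parameter values that the published model leaves unspecified were fixed
once as package defaults: the African size is 23,700 and the deep ancestral
size 18,500; the archaic branches use a simplified three-epoch
stand-in (Neanderthal 1,200 / 2,700 / 3,400; Denisovan 1,500 / 2,500 /
5,000; shared Neanderthal–Denisovan ancestor 3,800), chosen to mimic
declining archaic populations at realistic magnitudes. The super-archaic
size (13,000) matters only for simulation. Fixtures use a constant
recombination rate of 5e-9/bp/generation and a mutation rate averaging
1.45e-8/generation/site; both accept maps.

What simulations do not emulate: real mutation-rate maps estimated from
primate divergence, empirical recombination maps, sequencing-error and
depth/quality masking patterns, or reference biases. Passing the simulated
checks therefore demonstrates correctness of the machinery and calibration
under the model, not performance on any particular real dataset.

## Numerical choices and degenerate inputs

* Per-column scaling of the forward table (not log-space matrices); the two
  agree to 1e-8 on small instances in the tests.
* Coalescence probabilities are clamped below 1 - 1e-12 before taking
  survival logs; the topmost grid time forces coalescence onto the root
  continuation, so the walk is always proper.
* A coalescence exactly at the top grid time can create a zero-length root
  segment; this is tolerated only there.
* Sample ages snap to the nearest grid time (52/72/115 ky all map to the
  100 kya point of the default grid).
* Recombinations of the new branch are placed within local-tree spans; at
  recombinations of the fixed ARG the attachment carries over
  deterministically when the mapped state survives, and is re-drawn from
  the coalescent prior otherwise. This is an approximation to the exact
  boundary conditional; the exact-enumeration checks run on single-tree
  instances where no approximation is involved.
* Node ids are renumbered canonically after every edit (leaves sorted by
  name, internal nodes by time then smallest descendant), and every
  branch's path id is reduced to the smallest table row matching its
  population history, so serialized ARGs are byte-identical for a given
  seed.
* All-missing columns emit likelihood 1; sites with more than two observed
  alleles are dropped at load time with a counter.

## Design choices where the design was open

* **Sweep unit.** Only leaf-haplotype rethreading is implemented; internal
  branch or whole-interval moves would improve mixing on large samples but
  are not needed at the sample sizes targeted here.
* **Tie-breaking.** Snapping ties go to the younger half time-point; bands
  are crossed only by branches spanning the half time-point strictly.
* **Region zygosity by bp-majority** (see above).
* **Truth definition** for simulated tracts is the ancestor's population
  just above the pulse — matching the basewise scoring, which requires the
  correct migration type in the correct individual.
* **False-positive denominators** exclude masked (unscorable) base pairs.

## Problem sizes used by the checks

The bundled tests and the acceptance script replicate the simulation study
at desk scale: 20 kb windows, one African diploid plus the two Neanderthals,
the Denisovan and the outgroup (9 haploid lineages; 11 for the recent
preset), chains of ~30 iterations with migration enabled after 5, and 1–3
replicates per condition, chosen so the full suite runs on one CPU in
minutes. Power replicates are screened deterministically for windows whose
truth contains at least one tract of the focal band (basewise power is a
per-truth-bp quantity, so conditioning on the presence of truth does not
bias it). At these sizes a window often carries a single migrant tract
whose detectability depends on whether the migrant ancestor coalesced with
a sampled donor lineage before the donor/recipient populations merge — the
same mechanism that limits power at full scale — so per-replicate
estimates are lumpy and the tests quote multi-standard-error tolerances.

## Known limitations

* Pure-R tree editing keeps windows in the tens-of-kb range pleasant;
  multi-megabyte windows are feasible but slow (the forward/backward core
  is compiled, the rest is not).
* The at-most-one-migration default excludes stacked migration histories
  (e.g. super-archaic material relayed through a second pulse at one
  location).
* The boundary treatment at fixed-ARG recombinations is approximate (see
  above).
* Dating by CI overlap is conservative: with few ascertained regions the
  intervals are wide and several candidate times may be accepted.
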