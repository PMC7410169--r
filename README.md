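# argthreader

Demography-aware sampling of ancestral recombination graphs (ARGs) and
mapping of introgressed DNA.

`argthreader` is for population geneticists who have a small number of
genome sequences from closely related populations — the motivating case is
modern humans, Neanderthals and Denisovans — and want posterior
probabilities, along the genome, that a sampled lineage descends from a
migrant that crossed between populations. That includes gene flow from
populations with no sequenced representative (a "ghost" such as a
super-archaic hominin), and ancient events whose tracts are short and badly
confounded with incomplete lineage sorting.

## The method

The sampler is a Gibbs chain over ARGs conditional on a user-defined
demographic model: a population tree with piecewise-constant diploid sizes
N(t), a discrete grid of coalescence times t_1 < … < t_K, and
*migration bands* — instantaneous gene-flow opportunities `source → dest`
placed at half time-points, each with a prior rate p_M (default 0.01) per
lineage. One move removes a haploid lineage from every local tree
("unthreading") and re-samples its coalescence points with an HMM along the
genome whose states are triples

    (branch, coalescence time, population path)

where the population path records which populations the new branch
occupies through time, including any band crossing. Transitions combine
no-recombination persistence `exp(-r·w·b)` with a discretized
re-coalescence walk (rate m/2N per interval, band factors p_M vs 1−p_M at
half time-points); emissions are two-state pruning likelihoods with
per-column mutation rates; forward filtering + stochastic backward sampling
draw the threading exactly from its posterior. Unphased diploids are
handled by integrating over phase during the sweep.

Sampled ARGs encode introgression directly: a lineage is migrant wherever
its ancestral branch follows a band. Averaging over the retained ARGs gives
per-column posteriors (`p_het`, `p_hom`, `p_any = p_het + p_hom` per
diploid), thresholded at p ≥ 0.5 into region calls; an individual's
coverage is `½·het + hom`. The joint-zygosity frequency spectrum of called
regions, compared with caller-ascertained simulated spectra under candidate
migration times, brackets the date of the gene flow.

The package also ships the matching coalescent simulator (msprime-backed,
with per-lineage ground-truth migrant tracts extracted from census nodes at
the pulse time) and basewise power / false-positive / ROC / length /
dating evaluation utilities.

## Worked example

Simulate a 20 kb window under the bundled hominin model (one African
diploid, two Neanderthals sampled at 115 and 52 ky, a Denisovan at 72 ky, a
haploid outgroup; pulses Hum→Nea 8%, Sup→Den 4%, Sup→Afr 0.5% at 250 kya),
randomize phase, and scan it:

```r
library(argthreader)

model <- hominin_deep_model(n_afr = 1, t_mig = 250e3)
sim   <- simulate_dataset(model, 20e3, deep_admixture(250e3), seed = 19)
sim   <- degrade(sim, phase_randomize = TRUE, seed = 20)
data  <- as_arg_data(sim, compress = 10)
data
#> <arg_data> 9 lineages, 2293 compressed columns over 20,000 bp ( 213 variant )

scan <- introgression_scan(data, model, n_iter = 30, burnin = 10, thin = 2,
                           start_mig = 5, seed = 1)
scan$calls
#> # A tibble: 5 × 7
#>   start   end band       individual zygosity mean_posterior    bp
#>   <dbl> <dbl> <chr>      <chr>      <chr>             <dbl> <dbl>
#> 1  3513  3719 Afr_to_Nea NeaA       het               0.5     206
#> 2  4694  7928 Afr_to_Nea NeaA       het               0.830  3234
#> 3  8074 20000 Afr_to_Nea NeaA       het               0.740 11926
#> 4  4694  7586 Afr_to_Nea NeaV       het               0.783  2892
#> 5  7878  7918 Afr_to_Nea NeaV       het               0.575    40
```

The sampler recovers the simulated event: the calls are human→Neanderthal
(`Afr_to_Nea`), heterozygous, concentrated in the Neanderthal individuals,
with mean posteriors the fraction of retained ARGs in which a lineage of
that individual follows the band. Scoring against the simulator's truth
tracts:

```r
rates <- basewise_rates(scan$calls, sim$truth, 20e3,
                        individuals = c("Afr1", "NeaA", "NeaV", "Den1"),
                        bands = model$bands$band)
rates$overall[, c("band", "truth_bp", "tp_rate", "fp_rate")]
#> # A tibble: 5 × 4
#>   band       truth_bp tp_rate fp_rate
#>   <chr>         <int>   <dbl>   <dbl>
#> 1 Afr_to_Den        0  NA      0
#> 2 Afr_to_Nea    20000   0.768  0.0489
#> 3 Sup_to_Afr        0  NA      0
#> 4 Sup_to_Den    20000   0      0
#> 5 Sup_to_Nea        0  NA      0
```

76.8% of the truly introgressed human→Neanderthal base pairs are recovered
in this window; the missed Sup→Den tract illustrates the genuinely lower
power for ghost-source events when the super-archaic divergence is recent.
`plot_posterior_track(scan$tracks[["Afr_to_Nea.NeaA"]])`, `tidy()` /
`glance()` on the chain, and `write_outputs()` (BED / bedGraph / TSV / ARG
text) cover inspection and export; `inst/scripts/argthreader-sampler.R` is
a command-line front end with the usual flags (`--compress`, `--n-iters`,
`--burnin`, `--sample-step`, `--start-mig`, `--mig-prior`, `--unphased`,
`--seed`).

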