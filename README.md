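# cnvmix

Joint calling of copy-number variants (CNVs) across multiple sequenced
samples, from two signals at once: per-segment read depth and
mate-pair insert-size aberrations.

Most read-depth CNV callers analyse one genome at a time. When a cohort is
sequenced — especially at low coverage — the recurrent deletions and
duplications shared across individuals are best genotyped jointly: the
cross-sample distribution of depth at a locus separates real copy-number
states from noise, and mate pairs spanning a deletion add an independent
signal (their apparent insert is stretched by the deleted length).
`cnvmix` is for cohort studies of diploid genomes: population panels,
trios, case/control collections.

## The model

The genome is tiled into segments of length *L* (default 150 bp). For
sample *j* at a segment, the read count *f<sub>j</sub>* and the split of
its *n<sub>j</sub>* spanning mate pairs into library-like
(*n<sub>j1</sub>*) and stretched (*n<sub>j2</sub>*) inserts are modelled
by a mixture over digitized copy-number states *i* = 0..*m*
(0 = homozygous deletion, 1 = heterozygous deletion, 2 = diploid,
≥3 = duplication):

> p(f_j, n_j1, n_j2) = Σ_i α_i · Pois(f_j; θ_i λ) · C(n_j1+n_j2, n_j1) β_i^n_j1 (1−β_i)^n_j2

with θ_0 = ε (small), θ_i = i/2 for i ≥ 1, λ the diploid rate, α the
cross-sample state proportions and β_i the probability of a library-like
insert in state *i*. Parameters are estimated per segment by MAP
expectation-maximization (Dirichlet prior on α, Beta priors on β,
uniform prior on λ); each sample's copy number is the MAP state of the
posterior, filtered at posterior 0.5, and adjacent same-state segments
merge into CNV calls reported at ≥ 1 kb. Insert membership is itself
inferred, from a robustly fitted clone-library insert model and a
deletion-shifted alternative. See the methods vignette
(`vignettes/cnvmix-methods.Rmd`) for the full account.

## Worked example

Simulate a 10-sample cohort over 150 kb with 20 implanted CNV regions at
10× coverage, call, and score against the ground truth:

```r
library(cnvmix)
sim <- simulate_cnv_dataset(sim_config(k = 10, genome_length = 1.5e5,
                                       cnv_count = 20, seed = 42))
fit <- cnvmix(sim$obs)
fit
#> Multi-sample CNV mixture fit (MAP-EM)
#>   samples: 10   segments: 1000   max copy number: 5
#>   EM: 200 iteration(s), not converged (final max relative change 4.25e-06)
#>   non-diploid segment calls: 427 of 10000 cells
#>   merged CNV calls (>= 1000 bp): 21

head(fit$calls, 4)
#>   sample contig  start    end size state       class posterior
#> 1    s01   sim1  12300  13800 1500     1    deletion 1.0000000
#> 2    s01   sim1  50700  51750 1050     1    deletion 0.9999967
#> 3    s01   sim1  76050  78150 2100     1    deletion 1.0000000
#> 4    s01   sim1 145050 146100 1050     5 duplication 0.8995270
```

Each row is one merged call: sample `s01` carries, e.g., a heterozygous
deletion (copy number 1) of 1.5 kb at position 12,300–13,800 with
posterior ≈ 1. Scoring every sample-segment cell against the simulated
truth:

```r
cnv_confusion(fit, sim$truth)$stats
#>   state  precision    recall   f_score
#> 1     0 1.00000000 1.0000000 1.0000000
#> 2     1 0.99690402 0.9907692 0.9938272
#> 3     2 0.99937324 0.9977057 0.9985388
#> 4     3 0.08333333 0.2500000 0.1250000
#> 5     4 0.40000000 0.6666667 0.5000000
#> 6     5 1.00000000 1.0000000 1.0000000

overall_accuracy(fit, sim$truth, sim$obs$segmentation)
#> [1] 0.9968
```

Deletions are recovered essentially perfectly (rows for states 0–1);
duplication states share no insert-size signal and overlap in depth, so
they confuse each other more (rows 3–5) — the known hard case. Overall,
99.7% of nucleotide states are correct.

Real data enters through `extract_observations()` (coordinate-sorted,
indexed BAMs, one per sample, MAPQ ≥ 25) or through plain TSV count and
insert tables; a command-line wrapper with `simulate` / `call` /
`evaluate` / `cluster` subcommands is installed at
`system.file("cli", "cnvmix", package = "cnvmix")`.

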