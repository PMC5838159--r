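---
title: "Joint CNV calling across samples: model, inference and evaluation"
author: "cnvmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint CNV calling across samples: model, inference and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmix)
```

## The problem

Copy-number variants (CNVs) — genomic intervals present in different copy
counts in different individuals — leave two footprints in paired-end
sequencing data mapped to a reference genome. A deleted region loses read
depth in proportion to the missing copies, and mate pairs whose unsequenced
insert straddles the deletion map further apart than the sequencing
library's insert size. A duplicated region gains read depth while its mate
pairs keep library-like inserts. Most depth-based callers analyse one
sample at a time; `cnvmix` genotypes many samples jointly, so that the
recurrent variants shared across individuals — the ones most relevant for
population and disease studies — borrow strength across the cohort, and so
that depth noise common to a locus is absorbed by the locus's own
cross-sample model.

## The model

The reference genome is tiled into $T$ segments of fixed length $L$
(default 150 bp). For sample $j \in 1..k$ at a given segment we observe

* $f_j$ — the number of reads whose alignment start falls in the segment;
* $o_{j1}, \dots, o_{jn_j}$ — the insert sizes of the $n_j$ mate pairs
  whose insert region covers the whole segment while both reads flank it.

Each sample carries a latent digitized copy number
$i \in \{0, 1, \dots, m\}$ (0 = homozygous deletion, 1 = heterozygous
deletion, 2 = diploid, $\ge 3$ = duplication; default $m = 5$). Per state:

* **Read depth.** $f_j \mid i \sim \text{Poisson}(\theta_i \lambda)$ with
  $\theta_0 = \varepsilon$ (a small leakage rate, default 0.01, absorbing
  mismapped reads inside homozygous deletions) and $\theta_i = i/2$ for
  $i \ge 1$, so $\lambda$ is the diploid segment rate.
* **Insert aberration.** Each spanning pair is either library-like
  ($z_{jr} = 1$) or stretched ($z_{jr} = 0$); with
  $n_{j1} = \sum_r z_{jr}$ and $n_{j2} = n_j - n_{j1}$,
  $n_{j1} \mid i \sim \text{Binomial}(n_j, \beta_i)$, where $\beta_i$ is
  the probability of a library-like insert in state $i$. Idealized values
  are $\beta_0 = 0$ (both copies deleted: every spanning pair crosses the
  deletion), $\beta_1 = 1/2$, $\beta_{\ge 2} = 1$.

With $\alpha_i$ the proportion of samples in state $i$ at this segment,
the per-sample likelihood is the mixture

$$p(f_j, n_{j1}, n_{j2}) = \sum_{i=0}^{m} \alpha_i\,
  e^{-\theta_i\lambda} \frac{(\theta_i\lambda)^{f_j}}{f_j!}
  \binom{n_{j1}+n_{j2}}{n_{j1}} \beta_i^{n_{j1}} (1-\beta_i)^{n_{j2}}.$$

Priors make the estimation MAP rather than ML: a Dirichlet prior on
$\alpha$ with pseudo-counts $\gamma = (2, 2, 100, 2, 2, 2)$ — the large
diploid pseudo-count encodes that most segments in most samples are
diploid — independent Beta$(\nu_{i1}, \nu_{i2})$ priors on each $\beta_i$
($(1, 9)$ for state 0, $(5, 5)$ for state 1, $(9, 1)$ for states
$\ge 2$), and a uniform prior on $\lambda$ over $(0, 10^6)$. The printed
prior guidance is qualitative (orderings such as
$\nu_{i1} \gg \nu_{i2}$); the concrete values above are this package's
defaults and are exposed through `cnv_priors()`.

## Classifying insert sizes

$n_{j1}$ is not observed: each spanning insert must be scored against the
clone-library distribution. `fit_insert_library()` estimates the library
location and spread robustly (median and $1.4826 \times$ MAD of the
central 99% of the genome-wide insert sizes), because the genome-wide pool
always contains a minority of CNV-stretched inserts. The aberrant
component is the library density shifted by $\delta$ — physically, the
deleted length, which is unknown — so $\delta$ is estimated per segment as
the mean excess of inserts beyond $\mu + 3\sigma$, floored at $4\sigma$;
when a segment has no such outliers, a uniform right-tail density over
$[\mu + 3\sigma, \mu + 3\sigma + 100\,\text{kb}]$ stands in. The
membership weight of insert $o$ is
$w = \pi g_{\text{lib}}(o) / \{\pi g_{\text{lib}}(o) +
(1-\pi) g_{\text{shift}}(o)\}$, clamped to $[10^{-12}, 1-10^{-12}]$.
During EM the library prior $\pi$ is tied to the current fit per sample,
$\pi_j = \sum_i r_{ji} \beta_i$ (and 0.5 before the first E-step), so the
insert classification and the state posterior inform each other, as the
hierarchical model implies. Expected counts
$E[n_{j1}] = \sum_r w_{jr}$ replace the latent counts in the Binomial
term, with the binomial coefficient generalized through the gamma
function for non-integer arguments.

## MAP-EM

Each segment is fitted independently across its $k$ samples (the model
couples samples within a segment, not segments within a genome):

* **E-step** — state responsibilities
  $r_{ji} \propto \alpha_i \cdot \text{Pois}(f_j; \theta_i\lambda)
  \cdot \text{Binom}(E[n_{j1}], E[n_{j2}]; \beta_i)$, normalized per
  sample in log space; insert weights refreshed at the current $\pi_j$.
* **M-step** — closed-form MAP updates:
  $\alpha_i = (\sum_j r_{ji} + \gamma_i - 1) / (k + \gamma_s - (m+1))$
  with negative numerators clamped to $10^{-8}$ and renormalized (at
  small $k$ the $\gamma_i - 1$ terms can otherwise drive a proportion
  negative); $\beta_i = (\sum_j r_{ji} E[n_{j1}] + \nu_{i1} - 1) /
  (\sum_j r_{ji} n_j + \nu_{i1} + \nu_{i2} - 2)$, clamped into
  $[10^{-6}, 1 - 10^{-6}]$ so every log stays finite;
  $\lambda = \sum_j f_j / \sum_j \sum_i r_{ji}\theta_i$, truncated to the
  prior support.
* **Initialization** — $\lambda_0 = 2c(L+\ell)/\ell$ from coverage $c$ and
  read length $\ell$: reads starting anywhere in a window of length
  $L + \ell$ overlap the segment, on each of two haplotypes (5×, 100 bp
  reads, 100 bp segments give 20). $\alpha$ starts at
  $(0.02, 0.02, 0.90, 0.02, 0.02, 0.02)$ and $\beta$ at its idealized
  values. When coverage is unknown, the median per-segment mean count
  stands in for $\lambda_0$.
* **Convergence** — iterate until the relative change of the MAP
  objective (log-likelihood plus log-prior) falls below `tol` ($10^{-6}$)
  or 200 iterations. The EM is deterministic given its inputs.

`run_em()` is the readable per-segment reference implementation.
`cnvmix()` runs a vectorized engine that iterates all segments
simultaneously in matrix arithmetic and freezes segments as they
converge, so late iterations touch only the few segments still moving;
the test suite asserts numerical agreement between the two paths. With
`lambda_mode = "global"` the genome-wide initial rate is held fixed in
every segment instead of being re-estimated — a guard for very small
cohorts, where a segment whose samples are mostly non-diploid can
otherwise re-interpret its rate (per-segment re-estimation remains the
default because it is what the per-segment model implies).

## Calling and reporting

Per sample and segment the call is the MAP state of the posterior; a
non-diploid MAP call whose posterior is below 0.5 is filtered out (the
call reverts to diploid). Ties prefer the state closest to diploid, then
the smaller copy number — a conservative tie-break. Maximal runs of
adjacent segments with the identical sample, contig and copy number merge
into one CNV call; merging requires the same digitized copy number, not
merely the same deletion/duplication class, because the digitized copy
number is the model's output of record. Calls shorter than 1 kb are
dropped at reporting time only — per-segment evaluation uses the
unfiltered segment calls. The final partial segment of a contig is
retained with its true length, with the Poisson rate scaled
proportionally.

BAM ingestion counts a read in the segment containing its alignment start
(so counts partition the alignments and the Poisson independence
assumption is not corrupted by double counting), excludes duplicate,
secondary and supplementary alignments, and filters mapping quality below
25. A spanning pair contributes its outer-distance insert to every
segment its insert region fully covers. `--count-mode`-style overlap
counting was considered and rejected: with 100–150 bp segments and 100 bp
reads, overlap assignment would count most reads twice.

## The synthetic-data generator

`simulate_cnv_dataset()` emulates the package's study conditions at
summary level — per-segment counts and insert sizes, not reads — since
that is exactly the statistical structure the model consumes. Defaults
describe the 10× design the evaluation replays: 40 samples, a 3 Mb genome
in 150 bp segments ($T = 20{,}000$), 100 bp reads at 10× coverage
($\lambda_{\text{true}} = 50$), a Normal(500, 50) clone library, and 10
expected spanning pairs per segment. 300 CNV regions cycle through the
twelve lengths 250 bp–5 kb (about 24% of the genome inside CNV regions),
placed uniformly at random with at least one segment length between
regions, typed loss/gain/mixed with probabilities 0.80/0.15/0.05.
Per-sample copies are drawn per region: loss 2/1/0 with 0.8/0.15/0.05;
gain 2/3/4/5 with 0.85/0.08/0.06/0.01; mixed 0–4 with
0.04/0.16/0.67/0.11/0.02. Shifted inserts are displaced by the region
length — the physically correct value for a deletion — and homozygous
deletions still emit spanning pairs (they originate in the flanking
sequence), all of them shifted. Truth is digitized at segment level: a
segment takes a region's copy number when the region covers at least half
of it (the gap rule guarantees no segment straddles two regions).

What the generator does **not** emulate: GC and mappability bias,
overdispersed depth noise, alignment artefacts, reference errors, or
breakpoint micro-homology. Passing the evaluation below therefore shows
the inference machinery recovers the generative model at realistic rates
and sizes; it does not bound performance on real alignments, where the
read-level noise is harder.

## Evaluation conventions

`cnv_confusion()` scores every (sample, segment) cell once into a
predicted-by-real state matrix; precision is row-wise and recall
column-wise, with a pooled "duplication" aggregate over states $\ge 3$.
`overall_accuracy()` is nucleotide-weighted: correctly-stated nucleotides
over total nucleotides. `accuracy_by_allele_frequency()` groups CNV
regions by type and by allele frequency — the number of samples carrying
a non-diploid copy — in bins 0–5, 6–10, 11–15, 16–25.
`cluster_samples()` applies average-linkage agglomerative clustering with
Manhattan distance to the samples-by-regions copy-number matrix (the
distance/linkage pair is this package's choice — Manhattan is robust to a
few outlying regions — and both are arguments).

```{r example}
sim <- simulate_cnv_dataset(sim_config(k = 10, genome_length = 1.5e5,
                                       cnv_count = 20, seed = 42))
fit <- cnvmix(sim$obs)
fit
cnv_confusion(fit, sim$truth)$stats
overall_accuracy(fit, sim$truth, sim$obs$segmentation)
```

## Numerical choices and degenerate inputs

All inference runs in log space; linear-scale densities exist for
interactive use and testing. $\beta$ is clamped to
$[10^{-6}, 1-10^{-6}]$ before iterating (the idealized initialization
contains exact 0s and 1s). A sample-segment cell whose mixture components
all vanish receives uniform responsibilities with a warning. The library
spread is floored at 1 bp. Empty insert lists give a Binomial term of 1
(depth-only calling degrades gracefully). A cohort of one sample
triggers a warning: the cross-sample proportions $\alpha$ then carry
prior information only.

## Known limitations

Per-segment independence means no explicit segmentation prior: long CNVs
are recovered by merging per-segment calls, without an HMM's smoothing.
Copy numbers above $m = 5$ fold into state $m$. The caller assumes a
diploid baseline (no sex chromosomes/haploid support). Duplication states
3–5 overlap heavily in depth at low coverage and carry no insert-size
signal, so their mutual confusion is intrinsically higher than for
deletions — visible in the evaluation tables as lower duplication
precision/recall.

## Problem sizes used by the shipped checks

The test suite and the acceptance script replay the simulation design at
40 samples × 20,000 segments (one run each), run the EM property suites
on 50 small seeded datasets (k = 8) plus 20 recovery replicates at
k = 100, and exercise BAM ingestion on a hand-built SAM fixture. These
sizes were chosen to exercise every code path at full cohort scale while
keeping a complete check run in the minutes range on one CPU.
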