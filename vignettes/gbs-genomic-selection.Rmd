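---
title: "Low-coverage GBS versus SNP arrays for genomic selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-coverage GBS versus SNP arrays for genomic selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbselect)
```

## The question the package answers

Genotyping-by-sequencing (GBS) trades genotype quality for flexibility: the
mean genome-wide read depth *x* per individual can be dialled down so that a
fixed sequencing budget covers more individuals. For genomic selection in
outbred livestock this poses a concrete design question: given a total
budget of, say, 10 000x per genotyped locus, is estimated-breeding-value
(EBV) accuracy and response to selection maximised by deep sequencing of few
animals or shallow sequencing of many? `gbselect` simulates the whole chain
needed to answer that question - base-population haplotypes, a
two-generation pedigree, a polygenic trait, GBS or SNP-array genotype
observation, SNP-BLUP prediction, and selection-response evaluation - in a
reproducible, tested pipeline.

## The simulation chain

### Base haplotypes

`sim_haplotype_panel()` produces the base population: a matrix of 0/1
haplotypes over biallelic segregating sites with a genetic map (by default
1 cM per Mbp, uniform site placement). Two population-genetic features
matter downstream and are the generator's contract:

* an allele-frequency spectrum skewed toward rare variants (the neutral
  expectation that the number of sites carrying the derived allele *i*
  times is proportional to 1/*i*), and
* linkage disequilibrium (LD) that decays with genetic distance.

The generator is a discrete forward Wright-Fisher simulation initialised at
mutation-drift equilibrium: derived-allele counts are drawn from the 1/*i*
spectrum with sites independent, and the population is then propagated
through the most recent `max_generations` generations of a piecewise-linear
effective-size history (`ne_schedule()`; the default declines from 43 500 at
100 000 years ago to 100 today, with one year per generation as the assumed
generation interval, a value the history's source does not pin down).
Infinite-sites mutation injects singletons at a rate recalibrated each
generation so the segregating-site count stays stationary at the target;
recombination is Poisson along the map. Deep history is thus summarised
analytically by the initial spectrum, while the explicit forward phase
builds LD and recent drift - the properties the prediction analyses consume.

Two rescalings keep the reduced-size simulation honest. The census at each
generation is `Ne(t)/scale`, floored so the terminal generation can supply
the requested panel; and the per-meiosis crossover rate is adjusted per
generation so the population-scaled recombination rate `4 Ne r` matches the
unscaled history even where the floor binds. The practical consequence is
that short-range LD has the magnitude the true recent `Ne` implies, not the
one the inflated census would give.

The forward phase is deliberately short (default 100 generations). The
spectrum is stationary from generation zero, so the phase's only job is LD:
tightly linked pairs approach their drift-recombination equilibrium on a
timescale of a few times `1/(2c)` generations, and 100 generations builds
the strong local LD that drives marker-QTL tagging while leaving long-range
LD at its noise floor. Pairwise r^2 between adjacent sites exceeds r^2
between sites more than 50 cM apart by roughly an order of magnitude in the
shipped preset; the exact equilibrium level of very-tight-pair LD is not
reached, which is one reason absolute accuracies at desk scale sit below
full-scale values (orderings, the quantity of interest, are preserved).

Genuine coalescent output can replace the internal generator:
`read_ms_panel()` ingests ms/MaCS-style text (one replicate block per
chromosome), drops monomorphic columns with a warning, and produces the same
panel container, so full-scale runs can import externally simulated
haplotypes. `write_panel()`/`read_panel()` checkpoint panels as plain text.

### Pedigree and gene-dropping

`make_generation1()` founds a cohort by drawing each chromosome's two
haplotypes uniformly with replacement from the panel (the base population is
a pool, not a census, so replacement is the natural reading). Sexes
alternate deterministically by default so any cohort size yields a
predictable parent supply; Bernoulli sexes are available. The generation-1
cohort *is* the training set: it is the only phenotyped set, and its size is
the training-set size of a scenario.

`make_generation2()` samples sires and dams uniformly from the cohort, mates
each sire to a fixed number of dams, and builds each progeny from one
recombinant gamete per parent. The crossover model is the plain
no-interference reading of a 1%-per-cM map: per chromosome, the crossover
count is Poisson(length in Morgans) and positions are uniform
(`sim_crossovers()` exposes the sampler). Mendelian consistency of every
progeny allele is asserted in the test suite, not assumed.

One structural note: a cohort with alternating sexes of size *n* holds *n*/2
females, so the classic 25-sire x 20-dam design needs a cohort of at least
1000. The mating design is therefore configurable, and the scaled-down
preset uses 5 sires x 10 dams (50 dams), which every preset cohort size
from 100 up can supply. `sample_prediction_set()` draws the generation-2
candidates with every dam equally represented, failing loudly (or, on
request, allocating as equally as possible) when the count does not divide.

### Trait

`sample_trait_architecture()` assigns QTL as an equal-per-chromosome random
sample of segregating sites - 300 per chromosome (9000 total) at full scale,
60 per chromosome (300) in the preset - with allele-substitution effects
drawn from Normal(0, 1/sqrt(n_QTL)). Markers are sampled *excluding* QTL by
default; whether the original design allowed overlap is unstated, and
exclusion is the cleaner default (a flag allows overlap).

True breeding values are the effect-weighted true dosages.
`simulate_phenotypes()` then fixes the heritability as a property of the
realized data: the genetic variance is the cohort variance of TBV, the
residual variance is `sigma_g2 (1 - h2) / h2` (three times the genetic
variance at the default h^2 = 0.25), and phenotypes are TBV plus normal
noise. Scaling noise to the *realized* rather than expected genetic
variance makes every replicate's realized heritability match the target up
to sampling error, which is what "a trait with h^2 = 0.25" should mean in a
simulation; the alternative (an analytic 2-sum-pq-a^2 target) would let
realized h^2 drift with the QTL draw.

### Genotype observation

SNP arrays are modelled as error-free truth at the marker set
(`genotype_array()`). GBS (`genotype_gbs()`) observes each marker of each
individual through an independent Poisson(*x*) read count and applies the
discrete, error-free calling rule:

* no reads: the genotype is missing and is *mean-filled* with twice the
  base-population frequency of the allele coded 1 (frequencies are treated
  as known, taken from the base panel);
* a covered homozygote is always called correctly;
* a covered heterozygote is called heterozygous only if both alleles were
  seen - probability `1 - 2/2^n` - and each homozygote otherwise
  (`1/2^n` each), since all *n* reads carry the same allele with that
  probability.

The rule is additively unbiased: conditional on coverage, the expected
called dosage of a heterozygote is exactly 1, which is why shallow GBS
still supports unbiased *population-level* effect estimation even though
most heterozygotes are called wrongly at 1x. Calls are hard 0/1/2 values
(or the 2p fill), never genotype probabilities; depth is independent across
loci and individuals. Real GBS violates both (cut-site dropout, depth
autocorrelation, sequencing error), so passing tests here say nothing about
those failure modes - they are deliberately outside the model.

### Prediction

`fit_ridge()` implements SNP-BLUP with *known* variance components: with
dosages centered at twice the base frequency, marker effects solve
`(Z'Z + lambda I) beta = Z'(y - mean(y))` with
`lambda = sigma_e2 / sigma_beta2`. With the variances treated as known this
posterior mean is exact - no MCMC is involved, and a sampler would only add
noise around the same estimand. When markers outnumber individuals the
mathematically identical dual solve `beta = Z'(ZZ' + lambda I)^{-1}` yc is
used; primal/dual agreement to 1e-8 is part of the test suite. The marker
effect variance comes from the standard equivalence
`sigma_beta2 = sigma_g2 / sum_j 2 p_j q_j` (`derive_sigma_beta2()`), with
`sigma_g2 / m` available as an alternative convention; base-panel
frequencies are used for both centering and the 2pq sum, matching the
"frequencies known" assumption of the mean fill. EBV are
marker-effect-weighted centered dosages (`predict_ebv()`); centering shifts
all EBV by a constant and so touches neither accuracy nor bias.

### Evaluation

Accuracy is the Pearson correlation of TBV with EBV in the prediction set;
bias is the slope of TBV regressed on EBV (1 is unbiased; below 1 means
over-dispersed, "overestimated" EBV). Response to selection uses the
breeders' equation `R = i * accuracy` in genetic-standard-deviation units,
with the selection intensity `i = phi(z)/p` of infinite-population
truncation selection on the selected proportion `p` (the whole prediction
set is the candidate pool). A finite-candidate order-statistic correction
(Blom's approximation to the mean of the top *k* of *n* normal order
statistics, accurate to ~0.005 against Monte Carlo) is available via
`selection_intensity(p, n_candidates = )`; it matters at small candidate
counts and is essentially indistinguishable from the infinite form by
n = 50 000.

## The scenario engine

`scenario_spec()` + `run_scenario()` orchestrate the four designs: A1 (same
depth in training and prediction, including the array sentinel), A2 (all
depth combinations), A3 (a fixed total coverage spread over an expanding
training set, with array or matched-GBS prediction genotyping), and A4 (the
budget spread over an expanding prediction set, response computed for an
array-trained and a matched-GBS-trained model). Budget conservation is
exact by construction: per-individual depth is `total_x / n`.

Within a replicate, the panel, trait architecture, and marker samples are
drawn once and shared by all cells; each distinct cohort size gets its own
gene-dropped pedigree. Every random stream derives deterministically from
the master seed via order-independent counter-style mixing, so a scenario
table is byte-identical across reruns and across cell orderings, and cells
are *paired* within replicates - directional comparisons (array versus 10x,
budget corners) are made on shared worlds, which removes between-world noise
from the contrasts. Panels are additionally memoised across calls that
share a seed and configuration, purely as a compute saving.

## The scaled-down preset

Desk-scale defaults (`desk_config()`) shrink the study conditions while
preserving the regime that drives its findings:

| quantity | full scale | preset |
|---|---|---|
| chromosomes | 30 x 100 cM / 1e8 bp | 5 x 20 cM / 2e7 bp |
| base haplotypes | 1000 | 400 |
| segregating sites | ~1.7M | 10 000 (2000/chrom) |
| QTL | 9000 | 300 |
| marker densities | 3000-300 000 | 300-3000 |
| mating design | 25 sires x 20 dams | 5 sires x 10 dams |
| training sets | 500-50 000 | 100-1000 |
| prediction set | 500 | 100 |
| budget totals | 1000x-10 000x | 400x |
| replicates | 10 | 10 |

The choices preserve (i) heritability and per-individual depth values,
which are scale-free; (ii) dense-marker redundancy over QTL (10 markers per
QTL at the densest preset setting versus ~33 at full scale), the feature
that lets low-coverage data recover accuracy through locally correlated
markers; and (iii) the budget-corner contrast (4x over 100 individuals
versus 0.4x over 1000 at 400x total). Absolute accuracies are lower than
full-scale values (smaller training sets, shorter genome, partial LD
build-up), so the test suite asserts *orderings and contrasts* - accuracy
monotone in depth, 10x within 0.02 of the array baseline, budget corners,
response-to-selection corners, bias inflation at very low depth - rather
than absolute levels. The directional acceptance run takes a few minutes on
one core with the preset sizes above. `study_config()` expresses the
full-scale conditions for completeness; running them is cluster-scale work
and is best done with an imported coalescent panel.

## Numerical and design notes

* **Seeds.** All user-facing samplers take an explicit seed and restore the
  caller's RNG state; `NULL` consumes the global stream.
* **Degenerate inputs.** Constant TBV (heritability undefined), constant
  EBV (bias undefined), monomorphic panels, infeasible mating designs, and
  indivisible prediction-set allocations all fail with descriptive errors
  rather than producing numbers.
* **Centering convention.** Dosages are centered at `2p` from the base
  panel (column means are the fallback for plain matrices). The intercept
  absorbs the residual offset; accuracy and bias are invariant to it.
* **Ties and ordering.** Imported ms positions are de-duplicated by a
  minimal jitter to keep within-chromosome positions strictly increasing;
  site subsampling always preserves map order.
* **Infinite-sites convention.** Sites are biallelic; recurrent mutation at
  a segregating site never occurs; sites lost or fixed during the forward
  phase are pruned (they carry no information and cannot re-segregate).

## Known limitations

The model inherits the study's idealisations: no sequencing error, no
imputation or error correction, no cut-site dropout or depth correlation
along the genome, dominance-free trait architecture, two non-overlapping
generations, and selection evaluated for a single round via the breeders'
equation. The internal genome generator trades coalescent exactness for
speed and testability; where sequence-level realism matters, import ms
output. Conclusions about real GBS data should rest on the orderings this
package reproduces, not on its absolute accuracy values.
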