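---
title: "Linkage disequilibrium decay analysis: models, estimators and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage disequilibrium decay analysis: models, estimators and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lddecay)
```

## The problem

Linkage disequilibrium (LD) — the non-random association of alleles at
different loci — decays with the physical distance separating markers, at a
rate shaped by recombination, effective population size and breed history.
Characterising that decay in a dense SNP panel tells a breeder or a GWAS
designer how far a marker's information reaches, and hence how many markers
and how many phenotyped animals a genomic analysis needs. `lddecay`
implements the complete locus-level workflow for diploid, biallelic panels
genotyped across several labelled populations: quality control, two-locus
haplotype-frequency estimation from unphased genotypes, the D / D′ / r²
family of statistics, and distance-resolved summaries, together with a
synthetic-data generator rich enough to validate every stage without access
to proprietary genotypes.

## Quality control cascade

`apply_qc()` runs three stages in a fixed order on the panel pooled across
populations, and charges each removed locus to exactly the first stage that
rejects it, so the stage counts always partition the input:

1. **Non-autosomal loci** (chromosomes outside `1..29` by default, i.e.
   X, Y and MT under the bovine labelling) are dropped.
2. **Hardy–Weinberg equilibrium**: a locus is dropped when the exact test
   p-value falls below `hwe_p_min` (default `1e-7`).
3. **Call rate or minor allele frequency**: loci with call rate below 90%
   or pooled MAF below 0.05 are dropped as one merged stage, mirroring how
   such counts are conventionally reported together.

All inequalities are strict; boundary values (MAF exactly 0.05, call rate
exactly 90%) are retained. Pooling across populations is the conventional
across-breed protocol, but note the caveat: population structure induces a
Wahlund heterozygote deficit, so the pooled HWE stage preferentially removes
strongly differentiated loci. The per-population analyses
(`maf_histogram()`, `monomorphic_loci()`, `monomorphic_overlap()`) are
computed within populations on the retained panel, which is also why pooled
filtering leaves some loci fixed *within* individual populations — the
overlap of those within-population monomorphic sets is itself a relatedness
signal between populations.

The HWE test is the conditional exact test: given the observed allele
counts, every attainable heterozygote count receives its probability under
random union of gametes, and the two-sided p-value is the total mass of
configurations no more probable than the observed one (no mid-p).
Probabilities are computed with the numerically stable ratio recurrence
between adjacent heterozygote counts; a relative slack of `1e-12` in the
tail-inclusion comparison keeps exact probability ties (which occur by
allele-label symmetry) classified consistently under floating-point
round-off.

## Haplotype frequencies by EM

With unphased genotypes, the 3×3 table of dosage pairs is the sufficient
statistic for the four gamete frequencies $(p_{AB}, p_{Ab}, p_{aB},
p_{ab})$. Every cell determines its two gametes except the double
heterozygote, which is a mixture of the coupling ($AB/ab$) and repulsion
($Ab/aB$) phases. `em_haplotype_freqs()` maximises the multinomial
likelihood by EM: the E-step splits the double-heterozygote count in
proportion to $p_{AB}p_{ab}$ versus $p_{Ab}p_{aB}$, and the M-step renormalises
gamete counts. Two properties are guaranteed and tested: the allele-frequency
marginals are preserved exactly at every iteration, and the log-likelihood
never decreases.

Numerical choices:

* **Multi-start.** The likelihood can stall at the linkage-equilibrium
  point when the starting value is symmetric, so three deterministic starts
  are run — LE, and D offset to half its positive and negative bounds — and
  the highest final log-likelihood wins; ties within `1e-8` log units break
  toward the smaller |D|. This is deterministic and needs no randomness.
* **Convergence** is declared when the largest absolute frequency change in
  one iteration falls below `1e-10`, with a cap of 1000 iterations (the cap
  is reported via a `converged` flag rather than an error).
* **Degenerate tables.** If either locus is monomorphic in the table the
  frequencies are fully determined (marginal products) and are returned with
  `monomorphic = TRUE`; pair-level functions translate that flag into a
  `monomorphic_pair` condition because D′ and r² are undefined there.

## LD statistics

From fitted frequencies with marginals $p_A, p_B$:

$$D = p_{AB}p_{ab} - p_{Ab}p_{aB} = p_{AB} - p_A p_B$$

$$D' = D / D_{\max}, \qquad
D_{\max} = \begin{cases}
\min(p_A(1-p_B),\,(1-p_A)p_B) & D > 0 \\
\min(p_A p_B,\,(1-p_A)(1-p_B)) & D < 0
\end{cases}$$

$$r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}$$

D′ is defined as 0 at D = 0 (the branch of $D_{\max}$ is otherwise
unspecified there). The sign of D depends on which allele is counted at each
locus; r², |D′| and the corrected r² are orientation-invariant, and the
package's allele orientation (first-observed in PED sample order) is
documented as arbitrary.

Finite samples inflate r²: at linkage equilibrium its expectation is
approximately $1/n$ with $n$ the number of sampled alleles (twice the
pairwise-complete individuals). `correct_r2()` removes this null
expectation, $(r^2 - 1/n)/(1 - 1/n)$, flooring at 0 by default since a
negative squared correlation is uninterpretable (`floor_at_zero = FALSE`
restores the raw formula). The pair-specific $n$ is the default; a panel-wide
$n$ is available via `use_panel_n` since with missing data the two
conventions differ.

## Decay summaries

`pairwise_syntenic_ld()` estimates LD for every within-chromosome pair up to
a 1 Mb ceiling (tunable). Aggregations:

* `bin_by_distance()` — the four conventional classes 1–50 kb, 50–100 kb,
  100–500 kb, 0.5–1 Mb. Intervals are `(lo, hi]` with the first bin closed
  at 1 bp, so a pair at exactly 50 kb belongs to the lower class and no pair
  is counted twice. The SD is the population SD (divisor *n*), matching
  descriptive "mean ± SD" reporting.
* `point_distance_summary()` — mean LD "at" 1, 10 and 100 kb, implemented
  as a ±10% relative window around each nominal distance (floored at the
  1 bp minimum). The window is a reporting convention, not an estimate, and
  is tunable.
* `per_chromosome_summary()` — all syntenic pairs within the ceiling,
  grouped by chromosome; `adjacent_snp_summary()` restricts to
  consecutive-position pairs, which is a distinct (and much sparser)
  summary, so both are provided.
* `decay_curve()` — log-spaced bins for plotting; `autoplot()` methods
  render each summary with ggplot2.

Every scan reports skipped pairs by reason (monomorphic, insufficient data)
so that bin counts, out-of-range pairs and skips always reconcile exactly
with the pairs enumerated.

## The synthetic generator

`simulate_panel()` emulates the features of a multi-breed SNP-chip study
that the analysis is sensitive to, at desk scale. Haplotypes come from a
latent stationary AR(1) Gaussian process along each chromosome with
inter-locus correlation $\exp(-d/\lambda)$, thresholded at each locus's
allele-frequency quantile (a Gaussian copula); diploids are random unions of
two independent haplotypes, so HWE holds except where violations are
planted. This construction was chosen over a coalescent simulator because it
gives direct, tunable control of the distance–correlation map — exactly the
property the decay analysis measures — with no external dependency. What it
does **not** reproduce: coalescent variance in local tree depth, selection,
demography, or SNP-chip ascertainment bias. Passing tests therefore
demonstrate correctness of the estimators and bookkeeping, not realism of
any particular breed's decay curve.

Defaults mirror a five-breed, twelve-animals-per-breed design with a 100 kb
decay length scale, an allele-frequency spectrum of uniform [0.05, 0.5] plus
a 20% low-MAF component (exercising the MAF filter), and 1% missingness.
The package's standard validation problem size is 2,000 loci on 20 Mb
chromosomes — large enough that all four distance classes are populated by
hundreds of pairs, small enough to run in seconds.

Planted features are disjoint and recorded in a truth record: all-het
HWE-violating loci (the exact-test p of an all-heterozygote column is
1.8e-10 at 36 individuals and 4.9e-14 at 48, so panels of ≥36 individuals
make the planted loci detectable at the 1e-7 screen), single-copy MAF
violations, forced low-call-rate loci, X-chromosome loci, and
within-population fixed loci with designed cross-population overlaps.

`simulate_two_locus_wf()` is an independent theory check: a two-locus
Wright–Fisher population of $N_e$ diploids evolved by multinomial
resampling with recombination fraction $c$, sampled at the end exactly as
the pipeline samples real data (EM on the genotypes of $n$ diploids). At
drift–recombination equilibrium the mean raw r² over replicates follows
Sved's approximation $1/(1+4N_ec)$ plus the $1/n$ sampling term; the
package's acceptance suite verifies the simulated mean brackets 0.5 at
$4N_ec = 1$.

## Concordance scoring

For re-genotyped (or imputed-versus-true) sample pairs,
`concordance_from_panels()` cross-tabulates called against true dosage
classes over loci where both calls are present. The observed agreement
$P_o$ is the diagonal mass; the chance agreement
$P_c = \sum_i n_{i.}n_{.i}/n^2$ is what identical marginal class
frequencies would produce by coincidence; the quality score combines them in
the Cohen-kappa form $Q = (P_o - P_c)/(1 - P_c)$ — the canonical
combination of exactly these two quantities, equal to 1 only at perfect
concordance and 0 at chance level.

## File formats and orientation

PLINK text PED/MAP is the interchange format; population labels come from a
separate two-column file because PED family IDs are unreliable. PED carries
no allele metadata, so the reader fixes orientation by first observation:
the dosage counts the partner of the first allele code seen in sample
order. One consequence is worth knowing: a panel whose first non-missing
call at some locus is homozygous for the counted allele cannot be written
and re-read bit-identically — it returns relabelled ($d \to 2-d$, codes
swapped), which changes no magnitude statistic. `canonical_orientation()`
converts any panel to the reader's fixed-point form, for which the round
trip is exact; panels read from PED are already canonical.

## Known limitations

* HWE is tested on the pooled panel; with strong structure the Wahlund
  effect makes this stage conservative toward differentiated loci.
* The EM estimator assumes random union of gametes within the analysed
  sample; within-population analyses satisfy this by construction in the
  generator, but inbred or admixed real samples violate it.
* With 12 diploids per population, pair-level r² is noisy and the $1/n$
  correction matters; corrected values are the default statistic.
* The generator's Gaussian-copula LD is an idealisation; acceptance
  tolerances reflect estimator behaviour under that model, not under real
  bovine demography.
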