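---
title: "Methods: homozygosity, relatedness and introgression in inbred-line panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homozygosity, relatedness and introgression in inbred-line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(inbredpanel)
```

This vignette is the package's account of its models and of the design
choices made where the methodology was genuinely open. Every number quoted
here is either a model constant or something the test suite and
`scripts/acceptance.R` themselves compute.

## The setting

A panel of near-isogenic lines is created from a wild population by
repeated single full-sibling-pair (brother–sister) matings: each
generation imposes a strong bottleneck, and after G generations the
expected autozygous genome fraction follows Wright's recurrence

F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4,  F_0 = F_{-1} = 0,

so F_9 = 0.859375 (`wright_f(9)`). Residual heterozygosity survives in
patches, the sex-determining region of heterogametic (XY male) genomes
must stay heterozygous, and occasional accidental outcrosses reset parts
of a line's pedigree. The package characterises such panels from genotypes
alone and ships a simulator that reproduces this generative process with
exact, segment-level founder-ancestry truth.

## The homozygosity HMM

**Model.** For each line, heterozygous SNP calls are counted in
non-overlapping 10-kb windows. Window counts are modelled as a hidden
Markov chain over K states with independent Poisson emissions,
`x_t | s_t = k ~ Poisson(lambda_k)`. Two states separate homozygous
tracts from residual heterozygosity; four states give the graded view
used to refine the sex region. Counts are deliberately *not* normalised
by the number of genotyped sites per window — the block caller operates
on raw counts, matching how such callers are usually trained on
uniform-coverage panels; an exposure offset
(`use_exposure = TRUE`) is available when site density varies strongly.

**Joint training, separate decoding.** All per-line, per-chromosome
sequences share one parameter set (one EM fit across the panel), because
the emission regimes — error-floor counts in autozygous tracts, diversity
-scale counts elsewhere — are panel-level properties, not line-level ones.
Decoding is per line: Viterbi for block calls, forward–backward
(`posterior_decode()`) when per-window uncertainty is wanted. Chromosomes
restart from the initial distribution: windows are not physically adjacent
across chromosome boundaries.

**Numerics.** Scaled (normalised) forward–backward recursions are used
everywhere; sequences of equal length are batched into matrix operations,
so an 80-line × 2,400-window panel fits in well under a second per EM
iteration. Initialisation is deterministic: rates start at the 25th and
97.5th percentiles of the pooled counts (K = 2) or K quantiles evenly
spaced between those probabilities (duplicated starts are spread
multiplicatively, which handles near-constant counts); transitions start
sticky at 0.99 self-probability; the initial distribution starts uniform.
EM stops when the total log-likelihood improves by less than `tol = 1e-6`
or after `max_iter = 500` iterations; the trace is retained and tested for
monotonicity. Rates are floored at `1e-3` to avoid `log(0)` on all-zero
data (which additionally warns). States are relabelled by ascending rate
before return, so results are invariant to initialisation permutations and
state 0 always means "most homozygous". Viterbi ties break toward the
lower state index; the test suite checks decoded paths attain the
exhaustive-enumeration optimum rather than matching one arbitrary
tie-resolution.

**Blocks and fractions.** `states_to_blocks()` run-length encodes paths
into BED-exportable blocks; `homozygous_fraction()` is the state-0 span
over the total span, excluding the sex chromosome by default in panel
summaries, since sampled males are obligately heterozygous there.

## Sex-region refinement

Two per-window tracks over the sex chromosome are combined in
`het_proportion_track()`: the fraction of lines with strictly more than 5
heterozygous SNPs per window (the count-based estimate; the threshold and
its strictness are parameters), and an HMM-weighted estimate in which each
line contributes the min–max normalised emission rate of its decoded
4-state label, `w_k = (lambda_k - lambda_0)/(lambda_{K-1} - lambda_0)`.
The published description of this weighting says only that more
heterozygous states contribute more weight; min–max normalisation is this
package's concrete choice and is recorded as such. The refined region is
the longest contiguous run of windows with weighted value at least
`min_level` (default 0.8) spanning at least `min_span` (default 300 kb),
reported 1-based inclusive. Both knobs are exposed because the original
cutoffs defining the half-megabase region were not published.

## Population-genetic statistics

* **F_ST** uses Hudson's estimator per site, aggregated per 10-kb window
  as a ratio of averages (sums of numerators over sums of denominators),
  which is robust when per-site information is weak and sample sizes are
  small and unequal. The named estimator and the aggregation are design
  choices — the source analyses specify neither — and
  `method = "mean_of_ratios"` exposes the alternative. Windows under
  `min_snps = 50` usable SNPs are reported missing, with `log10(n_snps)`
  carried for diagnostics.
* **Nucleotide diversity** sums the unbiased per-site heterozygosity
  `2 p q n/(n-1)` over a 500-kb window and divides by the full window
  span. VCF-only input has no accessibility mask, so unsequenced positions
  silently count as monomorphic — a documented downward-bias limitation
  shared by all VCF-based windowed-pi implementations.
* **LD decay**: squared Pearson correlation of unphased genotype dosages
  (composite LD — appropriate since inbred lines are nearly homozygous and
  phase is unknown) for all pairs within 10 kb after MAF filtering at
  0.10, binned into 100-bp distance bins.
* **Inbreeding coefficient**: the method-of-moments
  `F = (O_hom - E_hom)/(L - E_hom)` against supplied reference
  frequencies. The simulator records its true founder frequencies so the
  estimator can be tested against the Wright expectation without
  estimation noise in the reference.
* **Heritability**: `eta² = SS_between/SS_total` from one-way ANOVA across
  line labels, exactly and without small-sample (omega²) correction,
  matching the effect-size-as-H² convention for clonal panels. Its
  permutation bias, (k-1)/(N-1) under no effect, is part of the test
  suite.

## Introgression

Sites are polarized against a caller-supplied ancestral-allele table
(sites with no usable call, or whose ancestral base matches neither
allele, are dropped and tallied). Patterson's
`D = sum(ABBA - BABA)/sum(ABBA + BABA)` on derived-allele frequencies and
the window-level admixture proportion f_d (Martin et al. 2015, with the
donor `P_D` chosen site-by-site as whichever of P2/P3 has the higher
derived frequency) are computed in 500-kb sliding windows. The step
defaults to a half-window (250 kb) — the convention of the tooling this
follows; the publication said only "sliding". f_d is reported only where
window D > 0, its validity domain; for genome-wide means the
`negative_d` switch either zeroes those windows (default, so the mean
reads as a genome fraction) or drops them. Single inbred genomes used as
"populations" simply produce frequencies in {0, 0.5, 1}.

Two properties worth keeping in mind when reading f_d values: it is exact
(f_d = 1) when P2 and P3 have identical *frequencies*, but with finite
samples the `pmax` in its denominator is inflated by sampling noise, so
even complete replacement measures below 1, and admixture fractions are
recovered with a known downward bias. This drove two defaults of the
admixed-population generator (below): 30 diploids per population and a
clearly diverged donor, chosen once so that the designed f = 0.3 signal is
not swamped by estimator bias, and kept fixed thereafter.

## Relatedness

IBS between two samples is the mean over co-genotyped sites of
`(2 - |dosage difference|)/2`; clustering is average linkage on 1 − IBS
(no linkage was published; average linkage is the conservative default for
similarity matrices with block structure) with samples pre-sorted
lexicographically so tie resolution is reproducible. Sibling-pair
adjacency is the fraction of recorded pairs occupying adjacent leaves.

`pairwise_sharing_fraction()` calls a 10-kb window "shared" when the
cross-line mean IBS reaches `identity_floor = 0.99` (tolerant of residual
heterozygosity and genotype error). Two denominators are offered, and the
choice matters. Sibling lines are expected to fix the *same* founder
haplotype at 1/4 of loci — a probability that is exactly 1/4 regardless of
generation, because any single lineage drawn from a line is uniform over
the founder pair's four haplotypes. Measuring it therefore requires
conditioning on windows where both lines *are* fixed
(`denominator = "co_fixed"`, the default: each line's within-window
heterozygous-site fraction must not exceed `1 - identity_floor`).
Dividing instead by all co-genotyped windows (`denominator = "all"`)
multiplies the estimate by roughly the squared fixation probability
(about 0.74 at G = 9), yielding ~0.19 — a statement about incomplete
inbreeding, not about sibling relatedness. The package defaults to the
conditional estimate because it is the quantity the 25% pedigree
expectation refers to; the unconditional variant remains available.

## What the simulator emulates — and what it does not

`simulate_panel()` reproduces: a wild founder population with per-site
diversity calibrated to `target_pi = 0.0037` (sites placed uniformly,
derived-allele frequencies from the neutral 1/i SFS, haplotypes drawn
site-independently at those frequencies); 24 chromosomes of 1 Mb at
3 cM/Mb — a desk-scale genome in which each chromosome recombines rarely,
like a miniature of a ~25-cM chromosome; families of sibling lines
initiated from the same founder pair; G generations of single
full-sib-pair matings with Poisson (interference-free) recombination and
exact ancestry tracking; a forced-heterozygous sex segment on chr1
(default 100 kb on the 1-Mb desk chromosome), imposed on the sampled
male's ancestry; accidental outcrosses to an unrelated line at a
configurable mid-pedigree generation; and uniform genotype errors
(default 1e-3, hom-to-het and het-to-hom), which set the HMM's
homozygous-state rate floor.

It does *not* emulate: linkage disequilibrium *within* the founder
population beyond what family structure induces (haplotypes are drawn
site-independently, i.e. founder LD is absent — LD in simulated panels
arises from the pedigree); mutation or selection during inbreeding;
mortality/extinction dynamics of lines; recombination-rate heterogeneity
along chromosomes (per-chromosome rates are configurable but default
uniform); structural variation and the permanent heterozygosity it causes;
and sequence divergence of the Y segment (the sex region is an ancestry
constraint, not divergent sequence). Consequently, passing tests show the
*estimators* behave correctly under the pedigree model; they do not
certify behaviour under real-data artefacts such as callable-site
variation, inversions or reference bias.

The admixed-population generator is frequency-based rather than
genealogical: an ancestral SFS drifts through Balding–Nichols transitions
to P1/P2 (close), P3 (diverged donor) and an outgroup fixed for the
ancestral allele; a fraction f of P2's genome, in 250-kb blocks, takes
P3's frequencies. This is deliberately minimal — enough to verify D/f_d
algebra, ranking (AUC) and calibrated recovery, not a demographic model.

## Problem sizes and reproducibility

All randomness flows from explicit seeds; panels are reproducible
bit-for-bit given (seed, config). The test suite and acceptance script use
desk-scale runs chosen as the package's standard validation sizes: 100
sibling-line pairs for the sharing check, an 80-line panel for the
homozygosity census, 500 replicate pedigrees for the recurrence check,
1,000 random chains against the exhaustive-path oracle (enumeration capped
at 2^12 paths for K = 2 and 4^8 for K = 4), and 20 seeded panels for the
sex-region refinement. The pipeline (`run_pipeline()`) writes per-stage
manifests with parameters, seed and output checksums, and re-running a
stage with unchanged inputs reproduces byte-identical outputs.

## Known limitations

* Windowed pi uses the full window span as denominator (no accessibility
  mask), biasing it downward where callable fraction is low.
* The HMM assumes conditionally independent Poisson counts; overdispersion
  (e.g. mapping artefacts) would be absorbed by state switching rather
  than modelled.
* f_d under-measures admixture with small per-population samples, as
  discussed above.
* `read_vcf()` keeps genotypes in memory as an integer matrix — ample for
  panel-scale data (tens of millions of genotypes), but not a streaming
  design for biobank-scale VCFs.
* Multiallelic records are dropped, not split; that is the intended
  behaviour for statistics defined on biallelic SNPs, but means densely
  polymorphic sites are invisible.
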