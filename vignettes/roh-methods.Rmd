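---
title: "Methods: ROH detection, inbreeding and selection-signature statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, inbreeding and selection-signature statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscape)
```

rohscape analyses runs of homozygosity (ROH) — contiguous stretches of
homozygous genotypes inherited identical-by-descent from a common ancestor —
in diploid SNP-array data, the setting typical of livestock breeding
populations genotyped on ~50K chips. This vignette documents the models and
procedures, the parameters that matter, the behaviour of the synthetic-data
generator the test suite is built on, and the numerical and design choices
made where the methods literature leaves latitude.

## The genotype substrate

All analyses consume a `geno_matrix`: an individuals × markers matrix of
codes 0 (homozygous for allele1), 1 (heterozygous), 2 (homozygous for
allele2), `NA` (missing), together with a marker map (chromosome, 1-based bp
position, allele labels) and sample metadata (population, sex). Storage is
orientation-free: codes count copies of allele2 in map order, never of the
minor or derived allele, so allele-frequency bookkeeping cannot silently
change when frequencies drift; minor/derived orientation is resolved where it
matters (`allele_freq()`, `linear_assoc()`). Coordinates are 1-based
inclusive everywhere; the BED 0-based half-open convention is translated
exactly at the file boundary and nowhere else.

## Quality control

`apply_qc()` applies the standard chip filters in a fixed, reported order:
non-autosomal/unmapped markers; marker call rate (default ≥ 0.90);
individual call rate (≥ 0.90, recomputed on the markers that survived the
previous step); exact Hardy–Weinberg test (remove p < 1e-6); optional minor
allele frequency. The order is fixed because the filters interact — an
individual's call rate depends on which markers are still present — and
reporting removals per step makes counts reproducible.

The Hardy–Weinberg test is the exact conditional test: given the observed
allele counts, the probability of every possible heterozygote count is
enumerated and the p-value is the sum over counts no more probable than the
observed one (no mid-p adjustment). Exactness matters at chip scale, where
hundreds of thousands of tests meet small expected counts; it is also
directly verifiable by brute-force enumeration, which the test suite does.
Two HWE modes are provided: per-population (default when population labels
are present; a marker is removed if it fails in *any* population, since
pooling diverged lines manufactures spurious heterozygote deficits) and
pooled.

By default no MAF filter is applied: pruning low-MAF markers deletes exactly
the homozygous stretches the ROH caller needs. Diversity analyses
conventionally re-run QC with `maf_min = 0.01`.

## ROH detection

`detect_roh()` implements scanning-window detection per individual and
chromosome:

1. a window of `window_snps` consecutive markers (default 50) slides one
   marker at a time; a window *qualifies* if it contains at most
   `window_max_het` heterozygous (default 1) and `window_max_missing`
   missing (default 5) calls — the tolerance that absorbs occasional
   genotyping errors and no-calls;
2. a marker is *ROH-eligible* if at least `window_hit_fraction` (default
   0.05) of the windows containing it qualify;
3. maximal runs of consecutive eligible markers become candidates;
4. candidates are split wherever adjacent markers are more than `max_gap_bp`
   apart (default 1 Mb), so a segment never bridges an assay desert;
5. candidates shorter than `min_length_bp` (default 1 Mb), with fewer than
   `min_snp_count` markers, or sparser than `min_density_bp_per_snp`
   (default one SNP per 100 kb) are discarded.

Segment bounds are the first/last member marker positions and
`length_bp = end − start + 1`. Chromosomes with fewer markers than the
window are scanned with a single truncated window rather than skipped.

Step 2 is the one semantic that window-based callers leave genuinely open —
how window verdicts become per-marker calls. The scanning-tool convention of
5% is adopted and exposed as a parameter, and the whole five-step pipeline is
regression-tested against an independent exhaustive implementation on
hundreds of random fixtures.

### The minimum-SNP threshold

Short homozygous runs arise by chance (identity by state). `min_snp_count()`
sets the threshold

$$l = \frac{\ln\big(\alpha / (n_s\, n_i)\big)}{\ln(1 - \bar h)}$$

where $\alpha$ is the tolerated number of false-positive ROH genome-wide
across all individuals (conventionally 0.05), $n_s$ the markers per
individual, $n_i$ the number of individuals, and $\bar h$ the observed
proportion of heterozygous calls over all genotypes. The result is rounded
*up*: ceiling is the conservative direction for false-positive control, and
fractional marker counts are meaningless. At chip scale (45,424 SNPs, 2,096
individuals, $\bar h = 0.27$) the threshold is 68 consecutive SNPs.

### Dating segments

Recombination whittles autozygous segments at ~1% per Mb per meiosis, so the
expected segment length reaching back $g$ generations is $100/(2g)$ cM.
With the pig-genome convention 1 cM ≈ 1 Mb, `generations_from_length()`
inverts this: a 10 Mb segment points to a common ancestor roughly five
generations back; a 1 Mb segment to fifty.

### Length classes

Segments are classified into left-closed classes [1, 5), [5, 10) and
[10, ∞) Mb. Short segments reflect ancient inbreeding, long ones recent
close inbreeding; the left-closed rule is arbitrary but documented, so a
segment of exactly 5,000,000 bp is "5–10 Mb".

## Inbreeding coefficients

`f_roh()` computes $F_{ROH} = L_{ROH} / L_{auto}$ per individual — summed
segment length over the SNP-covered autosomal span — in total and within
each length class; the class values decompose the total exactly. The default
$L_{auto}$ is 2.45 Gb, the span of the 18 pig autosomes; users of other
genomes supply their own.

`f_hom()` computes the excess-homozygosity (method-of-moments) coefficient
$F = (O_{hom} - E_{hom}) / (N_{nm} - E_{hom})$, where for each individual
$N_{nm}$ is its non-missing marker count, $O_{hom}$ its observed homozygous
count, and $E_{hom}$ sums $1 - 2p(1-p)\cdot 2n/(2n-1)$ over those markers
($p$ = sample allele frequency with the focal individual included, $n$ =
non-missing samples at the marker). The $2n/(2n-1)$ factor is the standard
small-sample correction; monomorphic markers contribute 1 (they carry no
information about heterozygosity). $F_{ROH}$ and $F_{HOM}$ differ in kind:
$F_{HOM}$ cannot distinguish identity by descent from identity by state, so
$F_{ROH}$ typically exceeds it in inbred populations.

Group contrasts (sex, line) use the Wilcoxon rank-sum test: inbreeding
coefficients are bounded, skewed quantities, so a distribution-free test is
the safe default, and the test used is named in the output.
`correlate_inbreeding()` reports pairwise-complete Pearson correlations with
t-transform p-values.

## ROH landscape

`roh_occurrence()` computes, per marker, the fraction of all individuals
whose ROH cover it — the landscape statistic. `call_hotspots()` reports
maximal runs of consecutive markers at or above the threshold (default 0.80,
inclusive; a flag switches to strictly-greater). A single sub-threshold
marker breaks a run: bridging rules would manufacture contiguity the data do
not show. Single-marker regions are reported rather than suppressed, since
region size is in the output and filtering is the user's call.
`call_coldspots()` intersects populations: a coldspot is a maximal run of
markers with occurrence exactly zero in *every* supplied track — regions
apparently intolerant of homozygosity.

`flank_regions()` grows points or regions by 50 kb on each side (the
candidate-gene window conventional for chip data, where strong LD extends
~100 kb), clips at bp 1 and the chromosome end, and merges overlaps.
`overlap_intervals()` reports all query/subject pairs sharing ≥ 1 bp, with
an optional subject-length pre-filter (default 1 Mb) that mirrors the usual
practice of discarding over-long, imprecisely mapped QTL annotations.

## Diversity and differentiation

Windowed statistics use non-overlapping 500 kb tiles anchored at bp 1 —
the windowing behaviour of the standard VCF tools (step = size); the step is
a parameter for users who want overlapping windows.

*Nucleotide diversity.* Per site with allele counts $(c_1, c_2)$ over $n$
non-missing chromosomes, $\pi = c_1 c_2 / \binom{n}{2}$; the window value is
the per-site sum divided by the window span in bp. Windows without SNPs get
π = 0 under the monomorphic assumption, with `n_snps = 0` marking them.

*Tajima's D* compares the pairwise-diversity and segregating-sites
estimators of the population mutation rate with the classical
normalisation; negative values indicate an excess of rare variants (sweeps,
expansion). With missing data the constants need a single $n$ per window:
the minimum non-missing chromosome count among the window's segregating
sites is used — the conservative choice, since the constants are computed
for the worst-covered site — while per-site diversity still uses each
site's own counts. Windows with no segregating sites or $n < 4$ return
`NA`.

*FST.* Per-site Weir–Cockerham (1984) variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals) are computed from sample sizes, allele frequencies and observed
heterozygote proportions. Window and genome-wide estimates are the ratio of
sums $\sum a / \sum(a+b+c)$ — the weighted estimator, which does not blow up
on low-information sites — with the unweighted mean of window values
reported alongside. Components are validated site-by-site in the tests
against an independent nested-ANOVA computation from raw sums of squares.

*Effective population size.* `ne_ld()` bins same-chromosome marker pairs by
physical distance and converts each bin's mean squared dosage correlation
into an estimate of $N_e$ at time $t = 1/(2c)$ generations ago, where $c$ is
the bin midpoint in Morgans at 1 Mb = 1 cM:
$$N_e = \frac{1}{4f(c)}\left(\frac{1}{E[r^2_{adj}]} - \alpha\right),$$
with $f(c) = c$, $r^2_{adj} = r^2 - 1/n$ correcting the sampling inflation of
unphased-genotype $r^2$, and $\alpha = 2.2$ the mutation-adjusted constant.
All four conventions ($f$, $t$, the adjustment, $\alpha$) are explicit
arguments because published analyses vary in them silently; the defaults are
recorded in the output. Bins where $r^2_{adj} \le 0$ or where the estimate
would be non-positive return `NA` rather than a nonsense value.

## Allele frequencies and association

`allele_freq()` reports per-population allele2 frequencies and, given an
ancestral-allele designation (obtained externally, e.g. from outgroup
species), derived-allele frequencies. `linear_assoc()` fits the single-SNP
additive model

$$y = \mu + \beta\,\mathrm{code} + \gamma_{age}\,\mathrm{age} +
\mathrm{batch} + e$$

by ordinary least squares, with the genotype coded 0/1/2 copies of a
user-designated allele, complete-case handling, and an explicit error naming
the collinear column when the design is rank-deficient. Batch is
dummy-encoded by default — the statistically correct treatment of a
categorical covariate — with a `numeric_covariates` switch reproducing the
numeric-coding behaviour of the common association tool for comparability.
No multiple-testing correction is applied: the intended use is a handful of
candidate SNPs, not a scan.

## The synthetic-data generator

`simulate_genotypes()` emulates the study design the package targets: two
diverged selection lines on a 50K-class chip. Defaults: 2 populations,
18 autosomes of 136 Mb (2.45 Gb total), 2,500 markers per chromosome
(~45k total, ~54 kb mean spacing), Balding–Nichols divergence at F = 0.093
(the moderate differentiation typical of separated commercial lines).
Ancestral frequencies are uniform on [0.05, 0.95]; population frequencies
are Beta-distributed around them with variance set by F — chosen precisely
because F is then a known quantity the Weir–Cockerham estimator must
recover; genotypes are Hardy–Weinberg within populations. Everything is
deterministic given the seed (Mersenne–Twister, recorded in the truth
object).

`plant_autozygosity()` writes ground-truth autozygous tracts: each planted
tract overwrites an individual's calls with one sampled haplotype (zero
heterozygotes by construction), then genotyping noise is applied genome-wide
— hom→het flips at `err_rate` (default 0.002; the error mode the caller's
one-het window allowance exists to absorb) and missingness at `miss_rate`
(default 0.01). The default plan places per individual one tract of 1.5, 3,
7.5 and 15 Mb — one per length class plus one near the caller's resolution
limit; tracts can instead be planted at a fixed locus with a population
frequency, which is how hotspot ground truth is created.
`simulate_phenotypes()` adds an additive effect at a focal marker with age
and batch covariates and Gaussian noise; ages are uniform integers on
[140, 200] and batches round-robin.

What the generator deliberately does *not* emulate: linkage disequilibrium
beyond what tract-planting induces (so LD-decay-based Ne is checked against
closed-form fixtures, not recovery simulations), chip-realistic clustered
marker spacing (positions are uniform; density edge-cases get dedicated
sparse fixtures), unequal chromosome lengths, ascertainment bias, and
batch/plate artefacts. Passing tests therefore demonstrate correctness of
the algorithms under a clean, known model — not robustness to every artefact
of real chip data.

## Verification strategy and problem sizes

Every statistic with any algebraic depth is tested against an independent
implementation built by a different route: exact HWE against direct
enumeration; π against exhaustive pairwise allele comparison; Tajima's D
against a second transcription of the formulas; Weir–Cockerham components
against a raw sums-of-squares nested ANOVA; OLS against the closed form
$(X^\top X)^{-1}X^\top y$; the ROH caller against a plain-loop exhaustive
scan on 500 random fixtures; interval overlap against a quadratic all-pairs
scan. End-to-end checks run at deliberately scaled sizes — 500 individuals,
5 chromosomes × 1,000 markers at the same 54 kb spacing as the full design —
which keep the whole suite under a minute while preserving the marker
density that drives detection behaviour.

## Boundary accuracy and known limitations

Two boundary effects of window-based ROH calling deserve explicit statement.

First, segments *over-extend* into flanking markers that are homozygous by
chance: an IBS-homozygous marker adjacent to a true autozygous tract is
indistinguishable, locally, from the tract itself, and the window verdicts
extend eligibility ~2–3 markers on average into such flanks. Planted-tract
bounds are therefore recovered exactly only when the flanks are
heterozygous; the test suite measures boundary accuracy as *under-coverage*
(a tract counts as recovered when one called segment covers all its member
markers except at most one at each end) and checks exact bounds on
het-flanked fixtures.

Second, under genotyping error, segments can *under-cover* a tract end by
two markers: when an error-flipped heterozygote sits within a window-length
of the tract end and the first flanking marker is also heterozygous, the
boundary-spanning windows hold two heterozygotes and the terminal markers
fall below the hit fraction. At the default error rate (0.002) this affects
roughly 7% of tracts; with error-free genotypes the under-coverage
essentially vanishes. This is a property of the window semantics shared
with the tools the caller models, not of this implementation (which matches
the exhaustive oracle exactly); analyses that need exact tract ends should
treat window-based boundaries as ±2 markers.

Other limitations: the caller is frequentist and windowed, not model-based
(no HMM and no LD model, so it cannot distinguish autozygosity from
homozygous IBS runs in low-recombination regions); F_HOM is frequency-model
bound (its expectation term assumes the sample frequencies); the Ne formula
inherits the strong assumptions of LD-based estimation and its output should
be read as order-of-magnitude; and coldspots are defined on the marker grid,
so assay deserts and true coldspots are distinguishable only through the
reported SNP counts.
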