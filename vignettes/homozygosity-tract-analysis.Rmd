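---
title: "Homozygosity-tract case-control analysis with tohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity-tract case-control analysis with tohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tohscan)
```

## The model

Long runs of homozygous genotype calls — tracts of homozygosity (TOH), the
population-genetics literature's runs of homozygosity (ROH) — arise when an
individual inherits the same haplotype from both parents. If a particular
haplotype carries a low-penetrance disease allele, the *region* where many
subjects' tracts overlap can behave as a carrier variant: present or absent
per subject, testable in a case-control design with far fewer tests than a
SNP-by-SNP scan. `tohscan` implements that idea end to end:

1. **TOH scan** — per subject and chromosome, maximal runs in which every
   non-missing call is homozygous.
2. **cTOH calling** — consensus regions where at least `min_carriers = 10`
   subjects share `min_shared_snps = 100` consecutive homozygous calls.
   A cTOH is defined by *positional* co-homozygosity only; carriers may be
   homozygous for different alleles.
3. **aTOH grouping** — within a cTOH, carrier segments are compared
   pairwise; two segments match allelically when at least 0.95 of their
   jointly non-missing, jointly homozygous sites carry identical genotypes.
   Matching segments are pooled into allelic subgroups, and only subgroups
   present in at least 5 cases and 5 controls are carried into association
   testing.
4. **Association** — per region, logistic regression of case status on the
   binary carrier indicator, adjusted for age category (ordinal 1–5), sex,
   and smoking (never/former/current as two dummies). The region p-value
   is the Wald test of the carrier coefficient; regions with p < 0.01 are
   declared significant, with BH-FDR and Storey q-values reported across
   the screen as an exploratory guide. Effect modification is assessed by
   adding carrier×smoking (2 terms) and carrier×age interaction columns.
5. **Expression integration** — significant regions are extended 250 kb on
   each side, overlapping genes are mapped, each mapped gene is screened
   by logistic regression of tumor status on its z-scored log2 expression
   (Bonferroni over the mapped panel, significance at adjusted p < 0.01),
   smoking-stratified per-gene odds ratios are computed, and the
   significant genes are bi-clustered.

## Quality control

Before scanning, samples require a 95% genotype call rate, and SNPs are
excluded for minor allele frequency below 5% (so MAF exactly 0.05
survives), Hardy–Weinberg departure at exact-test p < 0.01, or missingness
of 5% or more (so exactly 5% is removed). Samples are filtered first and
SNP statistics computed on the survivors. The HWE exact test conditions on
the observed allele counts and sums the probabilities of all heterozygote
counts no more probable than the observed one; monomorphic sites return
p = 1. HWE is tested in cases and controls combined: the analysis unit
downstream is the tract rather than the single SNP, and a single combined
threshold mirrors how one threshold is usually reported.

A consequence worth knowing about: a *true* shared homozygous tract is
itself a Hardy–Weinberg departure (excess homozygosity), so when several
percent of a cohort carry the same haplotype, a noticeable fraction of the
tract's SNPs fail the HWE filter. Tracts comfortably longer than the
100-SNP consensus floor survive this attrition; tracts near the floor may
not. The synthetic defaults below keep planted carrier fractions in the
1–5% per-group range seen in region-level carrier tables, with spans of
141–180 SNPs, precisely for this reason.

## Scanner semantics

`scan_params()` exposes the knobs a ROH module would have:
`min_snps = 100` homozygous calls (the consensus rule requires 100 shared
calls, and array-scale catalogs put the first quartile of tract sizes near
108 SNPs, so 100 is the natural detection floor); `max_het_in_run = 0`
(strict homozygosity, configurable for sensitivity analyses);
`max_missing_fraction_in_run = 0.02` of the spanned SNPs (missing calls do
not count toward `min_snps`). Runs begin and end on homozygous calls.

When the missing-fraction cap binds, maximality is resolved greedily: from
the leftmost usable homozygous call the run is extended to the furthest
homozygous end that keeps the spanned missing fraction within the cap,
emitted if it holds at least `min_snps` homozygous calls, and the scan
resumes after it. This keeps each subject's runs disjoint and the output
deterministic (no ties are possible). The test suite re-derives the same
definition by exhaustive window enumeration and checks equality on
hundreds of random fixtures.

Tract length in bp is `position(last SNP) − position(first SNP) + 1`.
Internally SNPs are indexed 1-based within chromosome; exports use 1-based
inclusive coordinates for PLINK-style tables and 0-based half-open for
BED.

## Region and group calling

Carrier counts per SNP come from stabbing the catalog's segments; cTOH
regions are maximal runs of at least 100 consecutive SNPs with at least 10
covering subjects, so the SNP immediately before and after every region
fails the constraint. A subject is a region carrier when one of its tracts
overlaps the region by at least 100 SNPs — the only sharing threshold the
method states, reused to resolve partial overlaps.

Allelic matching compares two carriers over the intersection of the region
span with both segments. Grouping uses single-linkage connected components
of the match graph (the segment-pool approach familiar from PLINK's
allelic matching); clique-style pooling could be substituted by replacing
one function, but connected components is the default because it is the
least surprising reading of "matching groups". Groups are ordered by their
smallest member id so output is reproducible.

## Association details

Logistic models are fitted by iteratively reweighted least squares (the
standard `glm` machinery) to a relative deviance tolerance of 1e-13, which
makes single-binary-predictor fits agree with the 2×2 closed forms
(`log(ad/bc)`, `sqrt(1/a+1/b+1/c+1/d)`) to about 1e-6. Confidence
intervals are Wald on the log scale with z = 1.959964. Complete or
quasi-separation is flagged (diverging coefficient with pinned fitted
probabilities) and reported as an odds-ratio sentinel of 0 or Inf rather
than being papered over with penalized fits — stratified expression tables
conventionally print exactly those sentinels.

The interaction model adds three columns (carrier×former,
carrier×current, carrier×age). Its joint p-value is reported two ways: the
likelihood-ratio chi-square (headline) and the analysis-of-deviance F
statistic, which some reports quote for this test even though the
dispersion of a binomial model is fixed; at fixed df the two are monotone
transforms of the same deviance drop and rank datasets identically.
Stratum-specific odds ratios are evaluated from the interaction fit at the
reference age category (1). If a smoking level has no carriers, its
interaction column is aliased; the column is dropped, the test df reduced,
and the stratum's odds ratio reported as `NA` with a flag.

Storey q-values are `pi0 × BH(p)`. pi0 is estimated from tail counts
`#(p > λ)/(m(1−λ))` over λ = 0.05, …, 0.90, smoothed with a cubic spline
and read off at λ = 0.90; with fewer than 100 p-values a bootstrap λ
selection is used, and below 10 p-values pi0 falls back to 1, where
q-values reduce exactly to BH-FDR. pi0 is clamped to (0, 1].

## Expression integration choices

The per-gene predictor is z-scored log2 expression, so odds ratios are per
SD and comparable across genes; whether a published stratified table used
continuous or dichotomized expression is usually not recoverable, and the
per-SD convention plus explicit separation sentinels reproduces the
qualitative 0/∞ behaviour such tables print. "Univariate logistic
regression" and "chi-squared test" are reconciled as a logistic fit with a
Wald chi-square p-value. The ever-smoker stratum pools former and current
smokers; expression is standardized within stratum. Clustering uses
1 − Pearson correlation distance with average linkage on standardized
rows (the classic expression-clustering convention); leaf order is the
deterministic `hclust` order with ties broken by input index. Constant
rows are an error naming the offending gene. RMA normalization is out of
scope: the package consumes an already-normalized log2 matrix.

## The synthetic cohort

`sim_config()` defaults describe the study conditions the package is
exercised under: 788 cases / 830 controls; age in 5 ordered categories
with population mean ≈ 1.63 (probabilities 0.60/0.25/0.09/0.04/0.02); sex
967 male / 651 female; smoking never/former/current = 156/703/759; 4
chromosomes × 5,000 SNPs at ~6 kb exponential spacing (a 141-SNP tract
then spans ≈ 850 kb, matching array-scale tract-length catalogs); MAF
uniform on (0.05, 0.5); no-call rate 0.005 (a typical modern array rate —
no per-call rate is stated for the original data). Background genotypes
are independent draws under Hardy–Weinberg at each SNP's MAF.

Planted tracts force carriers homozygous for a fixed haplotype across the
span — the exact observable the scanner detects — rather than simulating
inbreeding. Defaults plant a risk tract (carrier frequencies 5%/1.7%,
crude OR ≈ 3.0), a protective tract (1.7%/5%, OR ≈ 0.33), and one span
carrying two distinct haplotypes (3%/1% and 1%/3%) that splits into two
allelic subgroups with opposite effects. Two sampling modes are available:
retrospective (default; case/control counts fixed, carriers drawn at the
per-group frequencies, covariates tilted in cases by their log-odds
effects) and prospective (case labels drawn from the logistic model, used
for calibration work). Covariate effect defaults (age +0.25 per category,
female −0.2, former smoker +1.0, current +1.5 log-odds) are generic
lung-cancer-like values, not estimates of any published table.

What the generator deliberately does *not* emulate: linkage
disequilibrium between background SNPs (independence makes false-tract
rates analytically checkable — with per-SNP homozygosity ≈ 0.62, a
spurious 100-SNP run has probability ≈ 0.62^100 per start), population
structure and relatedness, chip intensity artifacts, and informative
missingness. Passing tests therefore demonstrate correctness of the
machinery and calibration of the inference under clean conditions, not
robustness to confounding by ancestry — on real data the
ancestry-matching and PCA steps that precede this pipeline remain
essential.

The expression generator emulates a 107-sample tumor/normal design
(58/49, never/former/current ≈ 20/26/28 among patients) with unit-SD
Gaussian noise on a log2 scale and planted mean shifts (in SD units) in
tumor samples, optionally restricted to a smoking stratum.

For the recovery benchmark (50 seeds of a 1,618 × 20,000 cohort with two
120-SNP planted tracts), the no-call rate is set to 0.001: at 0.005,
about 2% of carriers draw three or more missing calls inside a 120-SNP
tract and roughly a third of those arrangements admit no window with 100
homozygous calls under the 2% missing cap, which would make "exact carrier
recovery" fail for reasons unrelated to scanner correctness. The choice is
an analysis-driven fixture decision, recorded here; all other tests use
the defaults.

## Problem sizes used by the test suite

Unit tests run on cohorts of tens to hundreds of subjects and hundreds to
thousands of SNPs. The deeper checks use: 200 random scanner fixtures up
to 2,000 SNPs against the enumeration oracle; exhaustive HWE verification
for all genotype configurations with up to 30 subjects plus 300 random
larger ones; 500 random 2×2 tables for the closed-form logistic check;
2,000 null cohorts and 1,000 coverage cohorts at n = 1,618 for Wald
calibration; 200 + 200 seeds at n = 1,618 for interaction power and null
calibration; 50 seeds of the 1,618 × 20k recovery benchmark; and 20 seeds
of the 153-gene, 58-vs-49 expression screen. The full suite completes in
under ten minutes on a single core.

## Known limitations

* The scanner's greedy resolution of the missing-fraction cap is one of
  several defensible maximality conventions; a different convention can
  produce different boundaries when missing calls cluster inside a run.
* Single-linkage allelic grouping can chain two dissimilar haplotypes
  through an intermediate segment; with the 0.95 threshold this is rare
  but not impossible.
* Separated fits report sentinels rather than penalized estimates; if
  finite estimates under separation are needed, a Firth-type fit would
  have to be added.
* The q-value pi0 estimator is unstable for screens of only a handful of
  regions; the BH column is the dependable multiplicity summary there.
* Association assumes unrelated, ancestry-matched subjects; no genomic
  control or mixed-model correction is applied.
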