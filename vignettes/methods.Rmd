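---
title: "Models and methods behind margindiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind margindiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

margindiff tests whether quantitative traits of inbred plant genotypes are
more differentiated among biogeographical groups than genetic drift predicts.
This vignette records the models, the parameter choices, and the numerical
decisions, so a reader can judge exactly what a passing test suite does and
does not demonstrate.

## The data model

The package assumes a panel of predominantly selfing, effectively homozygous
lines — each genotype contributes a single allele per site, so dosages are
coded 0/1 ("haploid reduction") and heterozygous VCF calls are treated as
missing with a warning. Positions are 0-based half-open internally and
1-based only at the VCF boundary. Each genotype carries a latitude (degrees),
a genome-wide relict-ancestry fraction in [0, 1], and a per-10-kb-window
binary relict/outlier-haplotype status.

Phenotypes come from a blocked greenhouse design: three treatments (control,
intraspecific competition, water stress), each grown on one table in each of
two compartments, four blocks per table, one replicate per genotype per
block — 8 replicates per genotype and treatment, 1704 pots for 71 genotypes.

## Phenotype processing

* **Fecundity** is fruits × mean fruit length (mm), a proxy for total seed
  output; **seed mass** (mg/seed) is sample weight over seed count (10–30
  seeds per sample; deviations warn).
* **Outlier removal** uses the Hampel rule within genotype × treatment:
  keep x iff |x − median| ≤ k·MAD with k = 3 and the *raw* MAD (no 1.4826
  normal-consistency factor — the rule is defined on raw median absolute
  deviations). Groups with fewer than 3 values pass through; a zero MAD keeps
  only values at the median, with a warning. Two properties of this rule are
  worth knowing. First, it is not idempotent: re-filtering a filtered group
  can flag further borderline values, because removal shrinks the recomputed
  MAD. Second, at 8 replicates it flags roughly 7–9% of *clean* continuous
  draws per variable, purely from MAD sampling noise; removals on clean data
  are therefore a property of the rule at this group size, not evidence of
  bad records. Gross errors (several-fold inflated counts) are still caught
  at a much higher rate, which is what the rule is for.
* **Stress responses** are genotype-mean differences, stress − control, in
  fecundity units. The signed difference is the default (declines are
  negative) because downstream effect-sign analyses need direction; a
  magnitude-only mode exists and every output records which convention was
  used. Fecundity and its stress responses are arithmetically coupled
  (response = difference of means), so their strong correlation is expected,
  not a discovery.
* **Block adjustment**: rather than fitting nested mixed models, plant values
  are centred on their block-mean deviation within treatment before
  averaging. Group-level inference is carried by label-shuffling null tests
  (100 shuffles by default, group sizes fixed) with add-one-corrected
  two-sided empirical p-values, (r + 1)/(n + 1), so p never reaches zero at
  finite replicates.
* **Classification**: south < 45°, north > 55°, otherwise center; a latitude
  exactly at a threshold goes to the center, with a warning. The genetic
  cluster is relict iff the relict-ancestry fraction exceeds 0.5. The scheme
  has five groups; "Center relict" is rejected unless explicitly permitted.

## Differentiation machinery

* **F_ST** is the Weir–Cockerham variance-components estimator in its haploid
  form: per SNP, among-group component a = (MSB − MSW)/n_c and within
  component c = MSW from the one-way ANOVA of allele indicators, θ = a/(a+c).
  Small negative per-SNP values are legitimate estimator output and are kept;
  genome-wide summaries use the ratio of sums Σa/Σ(a+c), never the mean of
  per-SNP ratios (the one deliberate exception is F_STQ below, whose field
  definition is the arithmetic mean over a top set). SNPs monomorphic across
  the analysed groups, or left without within-group replication by
  missingness, are undefined and excluded.
* **MAF filtering** keeps SNPs with minor-allele frequency strictly above the
  threshold (default 5%); **LD pruning** is a deterministic greedy scan
  (drop the later SNP of any pair with r² ≥ 0.1 within a 50-kb window,
  advancing 50 SNPs), which refuses unsorted input rather than sorting
  silently.
* **Q_ST** is σ²B/(σ²B + σ²W) from genotype means by method-of-moments with
  the unbalanced-design correction. For a selfing species, genotype means
  carry total genotypic variance, so the selfing denominator (no factor 2) is
  the default; the outcrossing form σ²B/(σ²B + 2σ²W) is a mode switch.
  Negative moment estimates truncate to zero and are flagged. The
  **Q_ST-in-F_ST test** resamples genotypes within groups (for Q_ST) and
  draws single SNPs from the genomic F_ST distribution, reporting the
  add-one-corrected probability that a neutral draw is at least as large.
* **Coancestry** Θ is estimated from standardized allele sharing at
  non-coding SNPs genotyped in at least 95% of lines, then eigenvalue-clipped
  to the nearest positive semi-definite matrix; group-level entries average
  distinct pairs within and across groups.

## The S statistic

The multivariate drift test replaces a full Bayesian animal-model MCMC with a
method-of-moments + parametric Monte-Carlo construction having the same
neutral-model semantics. Under drift, the matrix of group means M (groups ×
2 traits) is matrix-normal around the ancestral mean with row covariance 2Θ
and column covariance G, the pooled within-group genetic covariance. The
ancestral mean is the coancestry-weighted GLS mean of the group means;
divergence is the Mahalanobis quadratic form D = tr((2Θ)⁻¹ (M − 1aᵀ) G⁻¹
(M − 1aᵀ)ᵀ). S is the fraction of Monte-Carlo neutral draws (default 1000)
with smaller D than observed. Because observed and simulated means pass
through the identical estimation pipeline, S is uniform under the neutral
model by construction — its mean over drift replicates is 0.5 without any
tuning — and it approaches 1 under directional displacement and 0 when group
means coincide. The exact divergence metric inside the published Bayesian
version of this test is not fully specified; the Mahalanobis choice is this
package's, validated against the three limiting values (0.5 / 1 / 0).
Singular G or Θ are ridge-regularised with a logged message.

## Polygenic effects and scans

Total SNP effects combine sparse-model components as E = α + β·δ (small
polygenic effect, large sparse effect, inclusion probability; δ outside
[0, 1] is an error). Top sets take ceil(fraction/2 × n) SNPs per signed tail
— for a 1% total fraction on 474,708 SNPs that is 2 × 2374 = 4748 — ranked on
signed E (not |E|) with deterministic (chrom, pos) tie-breaking; in the
degenerate all-tied case the positive tail fills first and the negative tail
takes the next coordinate-ordered candidates, with a warning, so the tails
stay disjoint. (Reported SNP counts for such effect tables can disagree
between sections of a source dataset's documentation; the 4748 figure
corresponds to 474,708 SNPs.)

F_STQ is the arithmetic mean of per-SNP F_ST over a trait's top set — the
definitional choice, although the ratio-of-sums variant is statistically
preferable and available via a flag. Significance of F_STQ/F_ST uses a Welch
(unequal-variance) two-sample t test between the top and non-coding per-SNP
F_ST samples; per-SNP F_ST is heavy-tailed, making pooled-variance t unsafe.
Group-pair contrasts bootstrap the top set once per replicate and apply the
same resampled SNPs to every pair, preserving the dependence induced by the
shared sets.

The enrichment bootstrap follows the three-category design: per permutation
(50 by default), 1000 SNPs each from the positive tail, the negative tail,
and the non-coding background — without replacement when the category is
large enough, with replacement (warned) otherwise. SNPs map to 10-kb windows
by floor(pos/10000), half-open. Proportions average over genotypes first,
then groups, then permutations. Enrichment is reported as a difference in
percentage points (null at 0) by default, with a ratio mode (null at 1); the
difference form is the operative definition, the ratio form matches how such
results are often displayed. One caveat the tests quantify: the SEM over
permutations understates the full null spread, because the top set — and
hence the windows it occupies — is fixed across permutations; at desk scale
the per-fixture null enrichment scatters by a few percentage points even
though its SEM is tiny. Null calibration is therefore asserted on means over
replicate fixtures, not on single SEM bands.

## The synthetic generator

The generator exists so every stage is testable without external data. It
emulates: two ancestral lineages diverged under a Balding–Nichols model
(beta-distributed lineage frequencies around a uniform ancestral frequency;
the divergence parameter maps directly onto the F_ST the estimator targets);
inbred admixture mosaics over 10-kb windows with genome-wide relict fractions
high (0.75–0.98) in relict-cluster genotypes and low (0.02–0.25) in
cosmopolitans; a causal architecture (2% of SNPs by default) whose fecundity
and seed-mass effects are drawn with genetic correlation `tradeoff_rho`
(default −0.6, the competition–colonization trade-off); and the full blocked
design with residual noise calibrated so method-of-moments H² hits its
targets (defaults 0.40–0.63 across traits, lowest for fecundity under
competition, highest for seed mass). Stress treatments subtract a
genotype-specific penalty positively correlated with control fecundity, so
the non-independence of fecundity and stress response present in real panels
is reproduced rather than hidden.

Two switchable signals define the selection conditions. With
`selection_signal`, causal-SNP lineage frequencies are drawn directionally
(relicts enriched for seed-mass-increasing alleles), producing elevated F_ST
at causal SNPs and directional group divergence. With `enrichment_signal`,
windows holding positive-seed-mass causal SNPs are pushed toward relict
status in relict genotypes and away from it in cosmopolitans (and conversely
for negative-effect windows). The push operates on the log-odds of the
window's relict-ancestry probability (shift 2 × `enrichment_boost`): an
earlier additive formulation could raise a cosmopolitan genotype's
relict-ancestry probability above one half at negative-effect windows, which
cancelled the very allele-frequency divergence the scan is meant to detect;
the odds-scale shift enriches or depletes haplotype status without letting
the minority ancestry take over. A consequence worth noting: introgression
of negative-effect relict haplotypes into cosmopolitans *reduces*
differentiation at those SNPs, so the planted F_STQ signal is carried mainly
by the positive tail — which is also the biologically coherent pattern.

Defaults are the study conditions: 71 genotypes split 24/23/24 across south,
center and north with 7 and 11 relicts at the margins (group sizes
23/17/7/13/11), divergence_fst = 0.3 (a deep intraspecific lineage split;
the true relict/cosmopolitan divergence depth is not published as an F_ST, so
this is a package choice made once), and zero attrition/outlier/neighbor-loss
rates so the default design yields exactly 1704 records; study-like loss
rates are config knobs exercised in the tests. Determinism is strict: one
global seed, fixed per-stage child seeds, so identical configs are
bit-identical, and the ancestry mosaic is re-derivable independently of the
genotype matrix.

What the generator does **not** emulate: linkage disequilibrium decay and
recombination maps (window ancestry and SNP draws are independent given the
mosaic), demography-explicit coalescence, flowering-time biology,
seed-dispersal mechanics, and real measurement-error structure. Passing
tests therefore demonstrate that the estimators recover the generating
model's structure at study scale — not that real data meet these
assumptions.

## Numerical choices and problem sizes

Ridge regularisation for Cholesky factors starts at 1e-10 × mean diagonal
and escalates by decades, logging when used. Eigenvalue clipping adds a
1e-8 relative ridge. Empirical p-values all use the add-one correction.
The test suite runs the S-statistic calibration at 200 drift replicates ×
1000 draws, Q_ST recovery over 100 simulated studies (300 SNPs each), null
F_STQ over 20 fixtures of 2000 SNPs, null enrichment over 10 such fixtures,
and exhaustive F_ST oracle comparisons on instances up to 10 genotypes × 10
SNPs; these sizes make the whole suite run in about a minute on one core
while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

Q_ST from 5 groups is intrinsically noisy (4 among-group degrees of
freedom); the Q_ST-in-F_ST bootstrap is a ranking diagnostic, not an exact
test. Estimates from phenotype-derived genotype means are mildly attenuated
relative to generating truth because residual noise inflates the
within-group component (about −0.01 at the default 8 replicates). The
haploid Weir–Cockerham reduction drops the heterozygosity component, which is
correct for fully inbred lines only. The coancestry scale (allele sharing
relative to total-sample frequencies) centres Θ near zero, so
between-group entries can be negative; only the positive semi-definite
projection enters the drift model.
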