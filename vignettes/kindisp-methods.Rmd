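---
title: "Methods: pedigree-based natal dispersal from noninvasive SNP genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-based natal dispersal from noninvasive SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindisp)
```

`kindisp` estimates individual natal dispersal distances — the distance
between an offspring's home-range center and its mother's — from biallelic
SNP genotypes typed on replicated, noninvasively collected samples. This
vignette describes the statistical models, the defaults and why they were
chosen, the design decisions that were genuinely open, and what the
package's validation does and does not demonstrate.

## Data model

Genotypes are coded as B-allele counts (0, 1, 2), with `NA` for missing
calls ("no calls") and `-1` for invalidated calls (ambiguous assay
clusters). Missing and invalid are deliberately distinct states: invalid
calls are excluded from every statistic but counted in the call-rate
denominator. A marker panel assigns each locus a class — autosomal, X, Y or
mitochondrial — and a population A-allele frequency. Haploid calls (Y,
mtDNA, and X in males) are stored as the matching homozygote. Only
autosomal loci enter relatedness and parentage likelihoods; X and Y drive
sex calling, and the mitochondrial pattern gives a matrilineal haplotype
used as a post-hoc consistency check, never as likelihood evidence.

## Genotype quality control

**Replicate consolidation.** Samples of one individual are consolidated per
locus by majority vote over valid calls; ties become missing. A replicate
group whose mean pairwise autosomal mismatch exceeds 20% is flagged as
probable contamination and dropped entirely — a deliberately coarse
threshold, since genuine replicate disagreement under per-allele error
rates around 10^-4^ is orders of magnitude rarer.

**Error and dropout rates.** Both rates are estimated from replicate
disagreements at diploid loci, restricted to comparisons involving at
least one heterozygote (homozygote-homozygote concordance carries almost
no information about either error process). With biallelic SNPs, every
discordance involving a heterozygote is a heterozygote-versus-homozygote
pattern, so a strict split into "miscall" and "dropout" numerators is not
identifiable from the data alone. The package therefore reports

* `error_rate` = discordant heterozygote comparisons / heterozygote
  comparisons — the per-genotype convention in which three discordances
  among 7,825 heterozygote genotype comparisons give 0.00038; and
* `dropout_rate` = heterozygote-versus-homozygote discordances /
  (2 x heterozygote comparisons) — the heterozygote-based convention of
  Broquet & Petit, with two alleles at risk per heterozygote.

Note the estimand of `error_rate` is a *per-comparison discordance*
probability: under a per-allele miscall rate epsilon it converges to
roughly 4&nbsp;epsilon (either of two calls, either of two alleles), not to
epsilon itself. The property tests check the estimator against its
closed-form expectation under the generating model rather than against the
raw per-allele rate.

**Sex calling.** A sample is male if every Y locus yields a valid call and
no X locus is heterozygous (males are hemizygous on X, so an X
heterozygote contradicts Y presence); female if all Y loci are missing,
with at least one X heterozygote confirming. Partial or invalidated Y
signal gives `undetermined` — a value, not an error — because noninvasive
data must tolerate unresolvable samples. Unanimity across Y loci is
required deliberately: with two Y markers, demanding both keeps the
false-male rate at the square of the per-locus contamination rate.

**Probability of identity.** PID = prod~l~ (p~l~^4^ + 4p~l~^2^q~l~^2^ +
q~l~^4^), the HWE probability that two random individuals share a full
multilocus genotype. The naive HWE form is used (no sibling correction):
its role here is to certify that replicate-group identity matching is
safe, and at 87 loci with mean minor allele frequency 0.37 the bound is
already astronomically small. `pid_identity()` is exact and closed-form;
tests verify it against brute-force enumeration of genotype pairs.

## Lynch–Ritland relatedness

For reference individual *x* with alleles (a, b) and partner *y* with
(c, d), the single-locus regression estimator is

$$\hat r_x = \frac{p_a(S_{bc}+S_{bd}) + p_b(S_{ac}+S_{ad}) - 4p_ap_b}
{(1+S_{ab})(p_a+p_b) - 4p_ap_b},$$

with S the allele-identity indicator. Loci are combined as the ratio of
summed numerators to summed denominators, each scaled by $1/(2p_ap_b)$ —
the Lynch–Ritland inverse-variance weights — and the reported value is the
arithmetic mean of the two reciprocal estimates, the recommended
symmetrization. Loci with a missing call in either member, or monomorphic
in the frequency vector, are excluded from both sums.

Allele frequencies are estimated from all consolidated individuals, with
no small-sample correction and without excluding the pair being evaluated —
matching the default behavior of the estimator's standard software
implementations. This leaves a small negative bias in the population mean r
(each individual's alleles inflate the reference frequencies slightly),
visible as mean r just below zero in large samples; the calibration tests
bound it.

Pedigree relationship categories (PO, FS, HS, GG, MT) are derived from
parent tables with closest-category priority, so a pair that is both
parent–offspring and mate is classified PO. No outlier filtering is applied
to high-r pairs: unusually related mates or inbred grandparent pairs are
real features of wild pedigrees, not artifacts.

## Parentage

**Likelihood.** For each focal individual the package scores three
hypothesis families per locus, always *conditionally on the observed
parental genotypes*: parental true genotypes are weighted by their
posterior given the observation (HWE prior if the observation is missing),
the offspring's true genotype follows Mendelian transmission, and the
observation model is a symmetric per-allele miscall of probability epsilon
(default 1.538 x 10^-4^, an empirically determined panel typing error).
An unobserved co-parent transmits an allele drawn from the population
frequencies; under the no-parent hypothesis the offspring genotype is pure
HWE. The conditional form makes parent-pair, single-parent and no-parent
hypotheses directly comparable, and a zero-epsilon opposite-homozygote
exclusion correctly yields a log-likelihood of -Inf.

**Prior and posterior.** Each sex's parent slot is spread uniformly over
`N_max` candidates; the unsampled mass is proportional to `N_max` minus the
number sampled of that sex. Posteriors are normalized per focal individual
over all enumerated hypotheses. Retention uses *per-parent marginal
posteriors* — the summed posterior of every hypothesis naming that parent,
whatever the co-parent — at threshold 0.95. Joint parent-pair posteriors
would penalize a securely identified mother whenever the father's evidence
is marginal; the marginal convention retains the mother as a dyad in that
case, which is how parentage programs conventionally report.

**Assembly and directionality.** Retained parent edges are inserted
greedily in decreasing likelihood-ratio order (posterior as tiebreak),
rejecting any edge that would create a cycle, a second same-sex parent, or
a sex-role violation. The ordering matters: a parent–offspring likelihood
is symmetric in direction, so reversed configurations (a mother assigned
her own daughter as "mother") can carry posteriors near 1 of their own, and
only their weaker likelihood support separates them from the truth.
`reconstruct_pedigree()` iterates the whole procedure, excluding each
individual's current pedigree descendants from its candidate parents on the
next pass — a deterministic approximation to a joint pedigree-space search,
which this package deliberately does not perform (a full MCMC over
pedigrees would obscure what each stage contributes and is unnecessary at
this panel's resolution). Pure dyads are oriented only when the reverse
direction is structurally impossible in the assembled pedigree; otherwise
they remain unoriented and are excluded from dispersal distances, a
conservative choice that trades a few records for directional certainty.

**Known limitation.** In densely sampled multigeneration pedigrees without
any age information, an individual's own children remain strong reversed
candidates, and the greedy resolution can misdirect a small number of edges
where the v-structure likelihood contrast is weak; a chance zero-exclusion
unrelated pair can likewise clear the posterior threshold. The package's
exact-reconstruction validation therefore uses two-generation populations,
where direction is identifiable from triads alone; three-generation
behavior is exercised by the end-to-end pipeline tests, which check high
(not perfect) edge precision.

## Spatial statistics

Home-range centers are coordinate-wise medians of an individual's fecal
sites — the median center, chosen for its insensitivity to occasional
excursions; a single site is used as is. Distances are planar Euclidean
(meters scaled to km), appropriate for projected national-grid coordinates.

The Mantel test correlates the upper triangles of the distance and
relatedness matrices and builds its null by jointly permuting rows and
columns of one matrix; p = (1 + extreme permutations) / (n_perm + 1), with
999 permutations by default. The default alternative is one-sided in the
direction of the observed sign, the convention of the classical randtest
implementations; two-sided and fixed-direction alternatives are available,
and an exact mode enumerates all n! relabelings for small matrices (used by
the tests to pin the p-value definition). Sex-stratified isolation by
distance runs on the putative parents: all pairs, female–female and
male–male as Mantel tests, opposite-sex pairs as a Pearson correlation only
(the pair set is an asymmetric rectangle, so no joint permutation applies).
Individuals introducing missing relatedness entries are dropped listwise
per stratum.

## Dispersal

Pre-dispersal cubs are flagged by three criteria: a full sibling exists;
the siblings are co-located (mutual distance at most `delta_sib_km`); and
both lie within `delta_mother_km` (default 1 km) of the mother's center.
The sibling co-location scale is not separately identifiable from field
data, so it defaults to the same 1 km as the mother criterion — the only
distance scale the filter has — and both are configurable. The filter is
monotone in `delta_mother_km` by construction. Natal distances are computed
for every non-cub offspring with an oriented mother link; zero distances
are retained, since short-distance settlement is part of the dispersal
distribution, not a failure of it. Summaries report n, median, mean,
SE = SD/sqrt(n) (sample SD, n-1 denominator) and maximum per offspring sex.
Sex difference is tested with a two-sided Wilcoxon rank-sum test
(first-sample W convention; exact for small untied samples, normal
approximation with continuity and tie correction otherwise) — two-sided
because the scientific claim is a difference, not a prespecified direction.

## The simulator

`simulate_population()` generates truth-known data with the statistical
structure the analysis assumes: non-overlapping generations; founders
unrelated and uniform over a 214 km x 214 km study square; each mother
drawing one mate per generation uniformly from that generation's males
(full-sib litters, paternal half-sibs through polygamy); offspring sexes
independent at 50:50; autosomal founders in HWE at minor allele frequencies
drawn from a scaled Beta with mean 0.37; Mendelian transmission with
X-hemizygous males, father-to-son Y, and matrilineal mtDNA; per-allele
miscall (default 3.8 x 10^-4^), one-allele heterozygote dropout (default
10^-4^, chosen so total replicate discordance stays at the order of the
panel's observed error rate) and call invalidation (default 0.36%); 1-19
fecal samples per genotyped individual with a long-tailed default
distribution (mean about 2.2) and isotropic Gaussian site scatter (default
8.8 km per axis, set so the mean within-individual site spread is around
15 km); and a genotyped fraction defaulting to 433/810.

Dispersal displacements take an exponential magnitude (half-normal
available) with sex-specific means defaulting to 12.9 km (females) and
33.8 km (males), and an isotropic direction. At the study boundary the
direction is redrawn, keeping the drawn magnitude, until the endpoint falls
inside the square (clamping only in the rare case no direction fits). This
choice preserves the kernel's magnitude distribution exactly, so realized
mother-offspring distances follow the configured kernel — the property the
parameter-recovery validation needs; truncating endpoints to the boundary
would bias realized distances downward. Final-generation litters of two or
more are marked as still-accompanying cubs with probability 0.11 (the
order of cub prevalence among recovered mother-offspring pairs in field
data) and placed at the mother's center.

What the simulator does not emulate: overlapping generations and age
structure, mortality, landscape heterogeneity or resistance, sex-biased
sampling effort, spatially clustered sampling gaps, and linkage between
loci. Passing validation on this simulator therefore demonstrates the
statistical machinery under the analysis's own assumptions — it does not
demonstrate robustness to the ways real field data violate them.

## Validation scale and numerical choices

The test suite and acceptance checks were sized to be decisive yet quick:
estimator calibration uses 2,000 pairs at 87 loci (Monte-Carlo SE of a mean
r around 0.002, far inside the +/-0.02-0.03 bands); exact pedigree
reconstruction uses a two-generation, fully sampled population of about
120 individuals with candidate pools set to the sampled counts plus the
founder generation's unsampled parents; triad orientation uses 500
simulated trios; dispersal recovery uses 40 replicate populations sized to
roughly 60 recovered offspring each; Mantel calibration uses 200 null runs
at n = 30 with 99 permutations. Posterior arithmetic is done in log space
with a log-sum-exp reduction; candidate parents enter the triad enumeration
when their single-parent likelihood ratio is positive (capped at 15 per
sex), while all candidates contribute to the posterior normalization
through the dyad hypotheses. Monomorphic loci are skipped wherever a
frequency-weighted quantity would be undefined.
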