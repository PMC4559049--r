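# kindisp

Pedigree-based natal dispersal estimation from noninvasively collected SNP
genotypes.

## The problem

Individual natal dispersal — how far an animal settles from its birthplace —
is central to population management but hard to measure in elusive,
wide-ranging species. A practical route is genetic: collect feces across a
large study area (citizen volunteers make the sampling resolution feasible),
genotype each sample on a small SNP panel designed for relatedness
inference, reconstruct a pedigree from the genotypes, and measure the
Euclidean distance between each offspring's home-range center and its
mother's. Because a parent–offspring genotype pair is directionally
symmetric, triads (offspring plus both parents) are what make the direction
of the relationship — and hence "natal" distance — identifiable without any
observational or age data.

`kindisp` implements that entire analysis for biallelic SNP panels typed
from replicated noninvasive samples, together with a truth-known spatial
pedigree simulator so that every stage can be validated against known
parentage and dispersal kernels:

* **Genotype QC** — replicate consolidation by majority vote with
  contamination flagging; genotyping error and allelic dropout estimated
  from replicate disagreements at heterozygous loci; sex calling from
  Y-chromosome presence validated by X-chromosome heterozygosity;
  mitochondrial haplotype assignment from diagnostic markers; call rate,
  allele frequencies and the multilocus probability of identity
  PID = ∏ₗ (pₗ⁴ + 4pₗ²qₗ² + qₗ⁴).
* **Relatedness** — the locus-weighted Lynch–Ritland regression estimator
  r̂ₓ(l) = [p_a(S_bc+S_bd) + p_b(S_ac+S_ad) − 4p_ap_b] /
  [(1+S_ab)(p_a+p_b) − 4p_ap_b], combined across loci with inverse-variance
  weights and symmetrized over the two reference choices.
* **Parentage** — per-offspring likelihoods of parent-pair, single-parent
  and no-sampled-parent hypotheses under a per-allele genotyping-error
  model, Mendelian transmission and HWE priors; posteriors with
  unsampled-parent mass set by candidate pool sizes (N_f_max, N_m_max);
  marginal-posterior filtering at 0.95; greedy likelihood-ordered assembly
  into acyclic, sex-consistent pedigrees; triad-based dyad orientation.
* **Spatial statistics** — median centers of fecal sites (coordinate-wise
  median, robust to excursions), planar distances in km, Mantel permutation
  tests of isolation by distance stratified by sex, Pearson correlation for
  the asymmetric opposite-sex stratum.
* **Dispersal** — the three-criterion cub filter (full sibling, co-located,
  within 1 km of the mother), mother–offspring distances, sex-stratified
  summaries (n, median, mean, SE = SD/√n, max) and a two-sided Wilcoxon
  rank-sum test for sex-biased dispersal.

## Worked example

Simulate a three-generation population under a 96-SNP panel (87 autosomal
loci at mean MAF 0.37), 80% of individuals genotyped from 1–19 fecal
samples each, sex-specific exponential dispersal kernels (female mean
12.9 km, male 33.8 km), then run the full pipeline:

```r
library(kindisp)

cfg <- sim_config(n_founders_f = 40, n_founders_m = 32, n_generations = 3,
                  mean_offspring_per_mother = 2.2, prop_sampled = 0.8,
                  seed = 42)
sim <- simulate_population(cfg)
res <- run_dispersal_pipeline(sim, n_perm = 999)
```

The run prints (abridged):

```
<truth_population> 347 individuals (202 F / 145 M), 3 generations, 277 sampled, 16 cubs
error rate: 0.0026 | call rate: 0.9962 | PID: 1.73e-34
<relatedness_matrix> 277 individuals, 38226 pairs; mean r = -0.0036 (SD 0.1333)
<parentage_result> 277 candidate assignments, 199 retained at posterior >= 0.95 (132 triads, 67 dyads)
  stratum n_ind n_pairs mantel_r mantel_p pearson_r
1     all   114    6441   -0.068    0.001    -0.068
2      FF    76    2850   -0.100    0.001    -0.100
3      MM    38     703    0.016    0.355     0.016
4      FM   114    2888       NA       NA    -0.058
  group   n median_km mean_km se_km max_km
1   all 152      21.1    29.5  2.20  157.7
2     F  88      18.1    20.8  1.43   58.9
3     M  64      29.3    41.6  4.44  157.7
rank-sum W = 1770 , p = 9.56e-05
```

Reading the output: the replicate-based error rate (~2.6e-3) reflects the
configured miscall, dropout and invalidation rates acting on both members
of each comparison; the panel's probability of identity (1.7e-34) shows two
individuals essentially cannot share a genotype by chance. Isolation by
distance is significant among female putative parents (Mantel r = −0.10,
p = 0.001) but not among males — the classic signature of female philopatry
with male-biased dispersal at a sampling scale that captures female but not
all male movements. The dispersal table shows males settling roughly twice
as far as females (medians 29 vs 18 km; distances include home-range-center
noise), and the rank-sum test confirms the sex difference.

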