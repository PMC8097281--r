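---
title: "Mixed-ploidy selection scans and the de novo / standing variation decision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-ploidy selection scans and the de novo / standing variation decision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

After a whole-genome duplication, an autotetraploid lineage must rapidly
readjust core cellular machinery — most acutely meiosis, where four
homologous chromosomes must be sorted instead of two. A central question is
where the adaptive alleles come from: were they already segregating in the
diploid source populations (standing variation), or did they arise de novo
after the ploidy split? `mixscan` implements an allele-frequency based
analysis chain that addresses this question in mixed diploid/autotetraploid
resequencing panels, where unreliable phasing in polyploids rules out most
haplotype-based machinery. Everything downstream of variant calling and
annotation works from population allele frequencies and genotype dosages,
which are well defined at any ploidy.

## The statistics

**Per-SNP differentiation.** Hudson's single-variant FST estimator in the
ratio-of-estimates form
\[
F_{ST} = \frac{(p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1} - \frac{p_2(1-p_2)}{n_2-1}}
              {p_1(1-p_2) + p_2(1-p_1)},
\]
with $n$ the post-filter called chromosome count at the site, not the
nominal sample size. Negative estimates are retained. Outliers are sites
exceeding the empirical 99% quantile of FST over synonymous SNPs genomewide
(type-7 interpolation), the more conservative choice relative to
nonsynonymous quantiles.

**Functional prioritization (FineMAV, modified).** Each missense site gets
\[
\mathrm{score} = f_{\max}\cdot \mathrm{DAP}^{3.5}\cdot S,
\qquad \mathrm{DAP} = \frac{\max_\ell f_\ell}{\sum_\ell f_\ell},
\]
where $f_\ell$ are the derived-allele frequencies in the six lineages
(five diploid + one tetraploid; purity is always assessed range-wide) and
$S$ is either the Grantham distance of the amino-acid pair or the rescaled
SIFT score $1 - \mathrm{raw}$ (so that 1 = most deleterious for both).
Candidate amino-acid substitutions (AASs) are the overlap of the FST
outliers with the top-1% outliers of *both* FineMAV variants; sites in
proteins without any SIFT database entry are judged on Grantham alone.
The diploid scan unions all ten pairwise lineage contrasts; the ploidy scan
pools all diploids against the tetraploid lineage. Enrichment of a focal
gene set among candidate genes is a two-sided Fisher exact test.

**McDonald–Kreitman with AFD divergence.** Between recently diverged
groups, fixed differences barely exist, so divergence classes (Dn, Ds) are
defined as the upper-1% outliers of the allele frequency difference
$|f_{2x} - f_{4x}|$, recomputed from the data at hand (the threshold is a
dataset property, not a constant); remaining classified sites are
polymorphisms, and variants with overall derived frequency below 0.15 are
excluded to limit the footprint of slightly deleterious segregating
variants. Then $\alpha = 1 - (D_s P_n)/(D_n P_s)$ with a Fisher exact
p-value on the 2x2 table; $\alpha$ is undefined when $D_n = 0$ or
$P_s = 0$. Divergent sites are never double-counted as polymorphic.

**Haplotype frequencies over linked candidates (HAF).** For the $n$
candidate AAS sites of one gene, $M_i$ is the per-group frequency of the
allele that is major in the combined sample. The combined panel is the full
diploid sampling plus the 40-individual tetraploid subsample, so combined
chromosome counts are diploid-dominated and the major allele at a swept
site is the ancestral one. Then HAFd $= \min_i M_i$ (ancestral,
diploid-like haplotype), HAFa $= 1 - \max_i M_i$ (derived, tetraploid-like
haplotype), HAFr $= 1 -$ HAFd $-$ HAFa (recombinants). The triple is a
point on the unit simplex by construction.

**Ploidy-aware Hamming distance.** Genotypic distance between two
individuals at one site is a binary lookup: diploid pairs differ only as
opposite homozygotes ($|\Delta d| = 2$); tetraploid pairs only when dosages
differ by at least 3; diploid–tetraploid pairs only when the diploid is
homozygous and the tetraploid carries at most one copy of the diploid's
allele. The Hamming distance sums these over a gene's candidate sites, and
the Hamming diameter of a group is the maximum pairwise distance within it.

**The three-criterion de novo verdict.** A gene's tetraploid haplotype is
called de novo only when (A) at least one candidate AAS is absent from
every diploid individual, (B) no diploid individual carries the derived
allele at every candidate site simultaneously (genotype co-occurrence
stands in for phased haplotypes), and (C) the diploid–tetraploid Hamming
distance exceeds the diploid Hamming diameter.

**Sweep ages, MNMs, conservation.** Relative sweep age is the count of
segregating tetraploid SNPs strictly between a gene's first and last
candidate AAS (candidates excluded), divided by that span; higher ratios
mean older sweeps (rank 1 = oldest, ties share the minimum rank).
Multinucleotide-mutation evidence combines a Wilcoxon rank-sum test of
consecutive candidate spacings against genomewide missense spacings
(within genes, consecutive — not all pairs) with a one-sided two-proportion
z test for transversion excess over the genomewide transversion fraction; a
gene is flagged when both reject at 0.01. Conservation of a candidate
residue is the pairwise alignment identity (PAI) of its ortholog-MSA
column — identical-residue pairs over all pairs, gap pairs counting as
non-identical — compared between tetraploid- and diploid-contrast
candidates by Wilcoxon rank-sum.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 8 | genotypes at depth <= 8 are masked (strictly greater kept) |
| `max_missing` | 0.5 | variants reaching this missing fraction in any lineage are dropped |
| `dip_target_chrom` | 32 | per-diploid-lineage subsample (16 highest-depth individuals) |
| `tet_target_chrom` | 160 | tetraploid subsample (40 individuals) |
| `fst_quantile`, `finemav_quantile` | 0.99 | outlier thresholds |
| `dap_exponent` | 3.5 | purity exponent of the FineMAV score |
| `af_min` | 0.15 | MK rare-polymorphism exclusion |
| `afd_quantile` | 0.99 | MK divergence-class threshold (override available) |
| `hamming_between` | `"median"` | cross-ploidy pair summary (`"min"` available) |

The cross-ploidy Hamming summary deserves a note. Under tetrasomic
inheritance, any realistic tetraploid panel contains individuals carrying
two or fewer copies of the swept haplotype, and such individuals have
genotypic distance 0 from an ancestral-homozygous diploid at every site.
The minimum over all cross-ploidy pairs is therefore 0 essentially always,
which would make criterion C unsatisfiable even for a textbook de novo
sweep. The median pair distance — effectively the distance between the
*typical* diploid and tetraploid haplotype combinations, which is how the
package reads the distance between the two haplotype clouds — is the
default; `"min"` is retained for the most conservative reading.

## What the synthetic generator emulates

The generator mimics a range-wide resequencing design: five diploid
lineages (14 populations) and one tetraploid lineage (11 populations),
eight individuals per population (112 diploids + 88 tetraploids; the
analysis then subsamples 16 + 40 as the scans require). Ancestral derived
frequencies follow a 1/p spectrum truncated at 1/(2N) with N = 100;
lineage frequencies are Balding–Nichols draws
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ with $F = 0.05$ per lineage — a
modest within-species drift level chosen once as realistic for recently
diverged conspecific lineages (the real lineage-specific values are not
identifiable from anything the pipeline consumes, so this is a free
parameter of the generator). Genotypes are Binomial(ploidy, f) —
tetrasomic inheritance, no disomic mode — with Poisson depth (mean 25) and
genotypes missing at rate 0.02 plus whenever depth <= 8, so the depth
filter has something to do.

Planted structure:

* **Sweeps.** Eight genes carry sweeps at haplotype frequency 0.95 in the
  swept lineage(s): four de novo (diploid frequency exactly 0), two
  standing (diploid frequency drawn in [0.02, 0.15]), two parallel
  (tetraploid + one designated diploid lineage). Candidate sites of a gene
  are drawn inside a contiguous block and genotypes at them are drawn once
  per individual — the linkage of a swept haplotype, which is what makes
  the haplotype-presence screen (criterion B) informative. Within the
  candidate span the swept lineage's other variation is cleared
  (hard-sweep hitchhiking) and a configured number of sites regain
  low-frequency variation, emulating post-sweep mutation accumulation;
  the default staggers these (8/4/2/0) so the sweep-age ranking has a
  planted ordering.
* **MNM clusters.** Two further genes carry ten candidate AASs spaced at
  most 19 bp apart with transversion probability 0.95 against a neutral
  background of 0.4, and are de novo swept over the cluster. Cluster size
  ten was fixed from a pre-test power calculation: the one-sided
  two-proportion z test at alpha = 0.01 against a 0.4 baseline rejects at
  eight or more transversions of ten, an event of probability ~0.99 at
  transversion probability 0.95.
* **Annotations and scores.** Effects are assigned at generation time
  (50% missense, 45% synonymous — half fourfold — 5% other); codon
  bookkeeping is simulated rather than derived from sequence, since the
  pipeline consumes annotations, not DNA. Planted candidates get radical
  amino-acid pairs (Grantham >= 180) and raw SIFT <= 0.05; neutral
  missense sites draw their amino-acid pair from the single-nucleotide-
  accessible exchanges of the standard genetic code, weighted by codon
  paths — what a SNP annotator can actually emit, keeping radical
  exchanges appropriately rare — and raw SIFT in [0.2, 1] —
  the anti-correlation with constraint that makes the two FineMAV variants
  agree on real candidates. One planted gene and every twentieth gene lack
  SIFT entirely, exercising the Grantham-only path.
* **Alignments.** Each planted gene gets a 17-species protein MSA;
  tetraploid-sweep candidate columns are conserved (substitution rate
  0.02), parallel (diploid) candidate columns free (0.45), background 0.2,
  with 2% gaps.
* **Polarization.** Most sites carry the ancestral state as `AA=` in the
  VCF INFO; 10% are emitted with the derived allele as REF and 10% lack
  the ancestral state, exercising the outgroup and minor-allele-fallback
  paths. Planted sites always have a usable outgroup state.

The default genome is 400 genes x 100 SNPs. At substantially smaller
sizes the ~44 planted candidate sites are no longer a vanishing fraction
of missense sites and visibly inflate the FineMAV 99% quantile — a
finite-size artifact the real genomewide scan does not have — so the
default keeps planted sites near 0.2% of the missense total.

What the generator does *not* emulate, and what passing tests therefore do
not show: linkage beyond the planted candidate blocks (no recombination
graph), realistic demography or gene flow between lineages, indels and
multiallelic sites, annotation errors, or reference-bias artifacts. The
recovery results say the machinery is correct under its stated model, not
that the thresholds are well calibrated for any particular empirical
system.

## Numerical choices and degenerate inputs

* Quantiles are type-7 (linear interpolation), documented because no
  convention is otherwise forced.
* FST is NA when both groups are monomorphic for the same allele
  (denominator 0); such sites never enter quantiles.
* FineMAV quantiles are taken over sites with non-null scores only;
  all-zero frequency vectors give a null DAP and null score.
* Tie-breaks: arg-max group of FineMAV taken at the lowest index;
  polarization at exactly 0.5 overall frequency takes ALT as derived
  (logged); sweep-age ties share the minimum rank.
* Tajima's D is computed at constant n on fourfold sites with no residual
  missingness in the group, because the 1989 constants assume fixed n;
  S = 0 gives a null D.
* Wilcoxon tests use the exact distribution below 20 total observations
  and the tie-corrected normal approximation above.
* Missing dosages contribute 0 to genotypic distances (a difference cannot
  be asserted); individuals missing more than half of a gene's candidate
  sites are excluded from that gene's Hamming analysis.
* MK alpha is reported as NA (with the Fisher p still computed) whenever
  its ratio is undefined.

## Problem sizes used by the validation suite

The test suite validates formula-level operations against independent
oracles (pair enumeration, independently coded Tajima constants,
hypergeometric identities) to 1e-9, and the pipeline against planted truth
at the default bundle size. Stochastic claims use repeated seeds: verdict
classification over 5 default-scale panels, MNM flagging over 10, sweep-age
ordering over 20 two-epoch fixtures (80 genes), and the null calibration of
the transversion test over 1000 resampled candidate sets. The neutral MK
calibration pools counts over six sweep-free panels of 2000 genes x 50
sites, sized so the sampling standard deviation of alpha (~0.05) is well
inside the +-0.15 window being checked; at single-bundle scale the
divergence counts (~200) would leave alpha's noise comparable to the window
itself. These sizes are the package's own validation design choices.

## Known limitations

* Criterion B uses genotype co-occurrence, not phased haplotypes; it can
  call a haplotype "present" in a diploid that carries the candidate
  alleles in repulsion. This is the same compromise the frequency-based
  HAF reconstruction makes, and it is conservative for the de novo call.
* The AFD-based divergence classes make alpha a relative, dataset-internal
  quantity; it is not comparable across datasets with different AFD
  thresholds.
* Sweep-age ratios are a coarse relative ordering; they ignore
  recombination-driven haplotype shortening entirely (unphasable data), and
  the package deliberately reports ranks, not ages.
* With very few candidate distances (a 2-AAS gene) the spacing test has
  essentially no power; such genes are reported but effectively cannot be
  flagged.
* Range-wide derived-allele purity structurally penalizes parallel sweeps:
  an allele shared by the tetraploid and one diploid lineage has DAP 0.5,
  capping its FineMAV score near the neutral quantile set by
  lineage-private drifted variants (which have DAP near 1 by definition).
  Detection of parallel candidates therefore leans on the FST component
  and the pairwise diploid contrasts, and individual parallel sites close
  to the FineMAV threshold can drop out of the overlap.
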