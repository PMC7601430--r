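---
title: "Weighted single-step GWAS: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssgblup)
```

## The model

`wssgblup` implements single-step genomic BLUP (ssGBLUP) and the weighted
single-step genome-wide association scan (WssGWAS) for a single-trait animal
model

$$\mathbf{y} = \mathbf{X b} + \mathbf{Z a} + \mathbf{e},
\qquad \mathbf{a} \sim N(\mathbf{0}, \mathbf{H}\sigma_a^2),
\qquad \mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma_e^2),$$

where $\mathbf{b}$ holds fixed effects (contemporary-group factors and
covariates), $\mathbf{a}$ the additive genetic effects of *all* pedigree
animals, and $\mathbf{H}$ merges pedigree and genomic relationships so that
genotyped and ungenotyped animals are evaluated jointly. The variance
components $\sigma_a^2$ and $\sigma_e^2$ are treated as known inputs
throughout, as is usual when they come from a prior pedigree-based analysis;
the package performs no REML estimation.

Only the inverse of $\mathbf{H}$ is needed:

$$\mathbf{H}^{-1} = \mathbf{A}^{-1} +
\begin{bmatrix}\mathbf{0} & \mathbf{0}\\
\mathbf{0} & (0.95\,\mathbf{G} + 0.05\,\mathbf{A}_{22})^{-1} -
\mathbf{A}_{22}^{-1}\end{bmatrix},$$

with $\mathbf{A}$ the pedigree numerator relationship matrix (tabular
method; diagonal $1+F$), $\mathbf{A}^{-1}$ from Henderson's rules with
inbreeding-adjusted Mendelian-sampling variances, $\mathbf{A}_{22}$ the
genotyped block of $\mathbf{A}$, and $\mathbf{G}$ the VanRaden genomic
matrix

$$\mathbf{G} = \frac{\mathbf{M D M'}}{2\sum_i p_i(1-p_i)},$$

where $\mathbf{M}$ is the column-centred dosage matrix, $p_i$ the observed
allele frequency and $\mathbf{D}$ a diagonal matrix of per-SNP weights
(initially $\mathbf{I}$). Because column centring places the vector of ones
in the null space of $\mathbf{G}$, the raw $\mathbf{G}$ is always singular;
the 0.95/0.05 blend with $\mathbf{A}_{22}$ (both coefficients are arguments,
not constants) restores positive definiteness and is used wherever an
inverse of the genomic matrix is required. The package deliberately does not
rescale $\mathbf{G}$ to the mean of $\mathbf{A}_{22}$ before blending; with
the simulator's observed allele frequencies the two matrices are already on
a comparable scale, and the choice is logged rather than hidden.

## The weighted iteration

One round of the scan is:

1. build $\mathbf{G}_t$ from the current weights $\mathbf{D}_t$
   ($\mathbf{D}_1 = \mathbf{I}$) and solve the mixed-model equations with
   $\mathbf{H}_t^{-1}$ for $\hat{\mathbf{b}}$ and the GEBV $\hat{\mathbf{a}}$;
2. back-solve SNP effects for the genotyped animals,
   $\hat{\mathbf{u}}_t = \frac{1}{c}\,\mathbf{D}_t \mathbf{M}'
   \mathbf{G}_{b,t}^{-1} \hat{\mathbf{a}}_t$, with
   $c = 2\sum_i p_i(1-p_i)$ and $\mathbf{G}_b$ the blended matrix. The $1/c$
   scalar makes $\mathbf{M}\hat{\mathbf{u}}$ reproduce the target vector
   when the supplied inverse is that of $\mathbf{M D M'}/c$ itself
   (`backsolve_scaling = FALSE` gives the literal unscaled back-solve, which
   changes every effect by the same constant and no variance *ratio*);
3. derive a shared weight for every window of 20 adjacent SNPs as the summed
   squared effects $\sum_{i \in w}\hat u_i^2$. By default
   (`use_dgv = TRUE`) the effects used *here* are back-solved from the
   direct genomic values $\mathrm{DGV}_i = -\sum_{j\ne i} g^{ij}
   \hat a_j / g^{ii}$ rather than from the GEBV, which strips the
   non-genomic part of the breeding value before it is squared into weights;
4. rescale the new weights so their sum (the trace of $\mathbf{D}$) is
   exactly the marker count, keeping total genetic variance constant, and
   loop. Two iterations are the default; accuracy is known to degrade with
   further rounds, so the count is an argument rather than a convergence
   rule.

After the last round the share of additive genetic variance of window $w$ is

$$\mathrm{GV}\%_w = \frac{\mathrm{var}\left(\sum_{i\in w}
\mathbf{M}_{\cdot i}\hat u_i\right)}{\sigma_a^2}\times 100,$$

the empirical variance (denominator $n-1$) taken across genotyped animals.
Windows are non-overlapping blocks of 20 SNPs in (chromosome, position)
order, restarting at every chromosome boundary, and windows reaching 1% or
more (inclusive) are selected as QTL candidates. Reported effects and window
shares at every iteration come from the GEBV back-solve; the DGV enters only
the weight update.

## Tunable parameters

| argument | default | meaning |
|---|---|---|
| `block_size` | 20 SNPs | window and weight-sharing block |
| `n_iterations` | 2 | weight-update rounds |
| `threshold` | 1 (%) | inclusive window selection bound |
| `g_coef`, `a_coef` | 0.95 / 0.05 | blend of G and A22 |
| `use_dgv` | TRUE | weight update from DGV instead of GEBV |
| `backsolve_scaling` | TRUE | include the 1/c factor in the back-solve |

Quality-control defaults (`qc_thresholds()`): SNP call rate ≥ 0.98, minor
allele frequency ≥ 0.01, Hardy–Weinberg heterozygote departure ≤ 0.15 (an
absolute difference of frequencies, not a chi-square test — the literal
reading of the editing rule it reproduces), animal missingness ≤ 0.10,
opposing-homozygote rate with a genotyped parent ≤ 0.01 (the progeny is
removed, as the data cannot tell which member of a conflicting pair is
mislabelled), and pedigree–genomic deviation bounds of 0.25 on the diagonal
and 0.5 off it (no published values exist for these two; both are
arguments). Failures are attributed to the *first* rule in the listed order,
so per-filter counts plus survivors always add up to the input size;
membership of the surviving set is order-independent because every rule is a
per-SNP (or per-animal) predicate.

## What the simulator does and does not emulate

`simulate_pedigree` / `simulate_genotypes` / `simulate_phenotypes` implement
discrete non-overlapping generations, random mating, per-locus gene dropping
from founder frequencies drawn in a configurable range, and phenotypes built
from fixed-effect levels, QTL dosage effects, a pedigree-dropped polygenic
term with inbreeding-adjusted Mendelian-sampling variance
($\sigma^2_{poly}/2\,(1-\bar F)$, $F$ from the tabular A recursion), and
Gaussian residuals. Everything is a pure function of (config, seed).

By default loci are independent — there is no within-chromosome linkage
disequilibrium — which keeps every expectation analytically checkable
(parent–offspring genomic relationship 0.5, mean diagonal of G near 1,
offspring–midparent regression equal to $h^2$). An optional blocked-LD mode
(`ld_block = k`) transmits parental haplotypes in blocks of `k` adjacent
SNPs, a deliberately crude stand-in for LD: window-based detection assumes
neighbouring markers tag the same QTL, which independent loci cannot
provide. The simulator does not attempt realistic bovine LD maps, selection,
assortative mating, or sequence-level variation, so passing tests show the
machinery is correct, not that the power estimates transfer to real cattle
data.

The one-QTL recovery study (`simulate_qtl_study`, `run_qtl_study`) fixes the
conditions used by the acceptance checks: 500 animals (100 founders plus two
generations of 200), 2,000 SNPs on 10 chromosomes, `ld_block = 20` aligned
with the window size, heritability 0.4, and a single QTL at 25% of the
additive variance placed mid-chromosome-1 at the marker with founder
frequency nearest 0.3. These sizes keep a 20-replicate study under a minute
on one core.

## Numerical choices

* Mixed-model equations are solved by sparse Cholesky factorisation
  (`Matrix`); a Jacobi-preconditioned conjugate-gradient solver is available
  and tested to agree, for systems where a factorisation would be
  impractical. The relative residual of the assembled normal equations is
  always checked and reported.
* Fixed-effect rank deficiency is handled by reference coding: the first
  factor keeps all levels (no intercept), later factors drop their first
  level. Only constraint-invariant quantities (fitted records, GEBV, DGV)
  are used downstream, and that invariance is asserted in the tests.
* Missing dosages are imputed to the column mean $2p_i$ before centring, so
  the imputed entries of M are exactly zero.
* Symmetric inverses go through a Cholesky factorisation that fails loudly
  with the eigenvalue range rather than falling back to a pseudo-inverse.
* All-zero effect vectors trigger a uniform weight fallback; an individual
  zero block is floored to a tiny positive weight so D stays positive
  definite. Weight renormalisation preserves the trace exactly (checked to
  1e-9 over every iteration of the test studies).
* Ties at the selection threshold are kept (≥, "1% or more").

## Known limitations

* The DGV-based weight update — the default, matching the method this
  package reproduces — is a leave-own-information-out genomic prediction.
  In the synthetic study, where every genotyped animal has an own phenotype
  and equal information, it is noisier than GEBV-based updating: across 100
  replicates of the one-QTL study the QTL window tops the scan in roughly
  70% of replicates under DGV updating versus about 85–90% under
  `use_dgv = FALSE`. The iteration-1 → 2 concentration property (the QTL
  window's share grows) holds in ~97% of replicates either way. Real designs
  with heterogeneous information (genotyped sires evaluated through progeny)
  are where the DGV refinement is expected to pay off; the generator does
  not emulate that structure.
* Window shares do not sum to 100%: between-window covariances are ignored
  by construction, and shrinkage keeps the genomic variance of predictions
  below $\sigma_a^2$.
* The pipeline reconstruction $\mathbf{M}\hat{\mathbf{u}} \approx$ target is
  exact only up to the blend: the raw VanRaden G is singular, so the blended
  inverse is used, leaving a discrepancy of the order of `a_coef`.
* A is built densely ($O(n^2)$ memory): fine for the tens of thousands of
  pedigree animals this package targets, not for national evaluations. APY
  and other large-scale G inverses are out of scope.
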