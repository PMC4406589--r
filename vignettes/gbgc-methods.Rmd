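---
title: "Quantifying GC-biased gene conversion from class-specific allele frequency spectra"
author: "beeGBGC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GC-biased gene conversion from class-specific allele frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeGBGC)
```

## The problem

GC-biased gene conversion (gBGC) is a recombination-associated repair bias:
when a heteroduplex formed during meiosis carries a weak/strong mismatch
(weak W = A or T, strong S = G or C), repair favours the G/C allele. At the
population scale this acts like selection of strength $B = 3 N_e b$ in a
haplodiploid species such as the honeybee ($4 N_e b$ in diploids), where $b$
is the per-meiosis transmission bias. Its footprint is a shift of
weak-to-strong (WS) derived alleles toward high population frequencies and
of strong-to-weak (SW) alleles toward low frequencies, while GC-conservative
(WW and SS) variants are untouched. This package implements the full chain
needed to measure that footprint from population resequencing data:
polarizing SNPs against an outgroup, classifying mutations, accumulating
class-specific derived allele frequency (DAF) spectra, and fitting a
constant-gBGC likelihood model that returns $B$, the AT mutational bias
$\lambda$, and nuisance parameters for demography and polarization error.
Windowed recombination-landscape statistics and gene-level
CpG/expression/methylation class comparisons round out the analyses, and a
seeded synthetic-data generator makes every stage testable against ground
truth.

## Polarization by substitution-aware weighted parsimony

For a biallelic site with ingroup alleles $X/Y$ and outgroup consensus
allele $O$, simple parsimony calls the shared allele ancestral. That ignores
the scenario in which the other allele was ancestral and the outgroup
lineage substituted it. We weigh the two scenarios:

* $O = X$: $w(\mathrm{anc}=X) = \mu(X \to Y)$ against
  $w(\mathrm{anc}=Y) = \mu(Y \to X)\,\sigma(Y \to X)$;
* $O \notin \{X, Y\}$: $w(\mathrm{anc}=X) = \mu(X \to Y)\,\sigma(X \to O)$
  against $w(\mathrm{anc}=Y) = \mu(Y \to X)\,\sigma(Y \to O)$,

where $\mu$ holds per-site ingroup mutation weights (estimated from
polymorphism counts divided by the ancestral-base opportunity) and $\sigma$
per-site outgroup substitution probabilities (ingroup-fixed differences
divided by aligned base counts). Both are single-pass moment estimates; no
iteration is performed. The probability that the chosen (larger-weight)
ancestral allele is correct is its weight over the sum, and sites are
reported unresolved when that probability falls below a threshold, when the
weights tie exactly, when the outgroup allele or its coverage is missing, or
when both weights vanish. The default acceptance threshold is 0.9; ties are
always unresolved. Flanking context for CpG/GpC flags is read from the
ingroup reference, and adjacent polymorphisms are ignored when deciding
context — a documented simplification that slightly blurs context classes in
SNP-dense regions.

## The spectrum model

A derived allele with scaled transmission advantage $B$ spends time at
population frequency $x$ in proportion to the sojourn density

$$\phi(x; B) = \frac{1 - e^{-B(1-x)}}{(1 - e^{-B})\,x(1-x)},
\qquad \phi(x; 0) = \frac{1}{x},$$

so the expected DAF spectrum in a sample of $n$ haplotypes is
$G_i(B) = \int_0^1 \binom{n}{i} x^i (1-x)^{n-i} \phi(x;B)\,dx$ for
$i = 1..n-1$, with $G_i(0) = 1/i$. WS mutations feel $+B$, SW mutations
$-B$, the pooled WW+SS class is neutral. The expected observed counts add
two nuisance layers:

* **Distortion** $r_i$ ($r_1 \equiv 1$), shared across the three classes,
  absorbing demography, population structure and sampling departures from
  the stationary spectrum (an Eyre-Walker-style nuisance
  parameterization). Because the likelihood is a product of independent
  Poisson cells, the optimal $r_i$ at fixed structural parameters has the
  closed form (column total of observed counts) / (column total of expected
  counts), so the distortion vector is profiled out analytically inside the
  objective rather than optimized numerically — an exact inner maximization
  that removes 58 parameters from the quasi-Newton search at $n = 60$.
* **Polarization error** $e_c \in [0, 0.5]$ per class: a mispolarized
  derived-$i$ WS variant is observed as a derived-$(n-i)$ SW variant and
  vice versa; the neutral class mirrors into itself.

$$E_i^{WS} = r_i\left[(1-e_{WS})\,\theta_{WS} G_i(B) +
  e_{SW}\,\theta_{SW} G_{n-i}(-B)\right]$$

and symmetrically for SW; $\theta_c$ are free per-class influx scales. The
log-likelihood is the independent-Poisson sum over classes and frequency
cells. Given the average GC content $g$ of the analyzed sequence, the AT
mutational bias is
$\lambda = (\theta_{SW}/g)\,/\,(\theta_{WS}/(1-g))$, and the equilibrium GC
content under mutation–conversion balance is
$GC^* = 1/(1 + \lambda e^{-B})$.

### Numerical choices

* Quadrature: fixed-order Gauss–Legendre with 256 nodes on $(0,1)$; the
  binomial kernel vanishes fast enough at both endpoints to regularize the
  $1/x(1-x)$ singularities for $1 \le i \le n-1$. Agreement with a dense
  trapezoid evaluation is at the $10^{-8}$ level. $|B| < 10^{-6}$ is routed
  to the analytic neutral limit, and negative $B$ uses an algebraically
  equivalent form with all exponents non-positive for stability out to
  $B = -50$.
* Optimizer: L-BFGS-B on $(B, \log\theta, \mathrm{logit}(e/0.5))$ with
  $B \in [-50, 50]$; 8 seeded random starts by default (the first start is
  deterministic: $B = 0$ with data-derived $\theta$); ties in log-likelihood
  are broken toward smaller $|B|$.
* Profile CI for $B$: the remaining parameters are re-optimized on a walk
  away from the MLE until the profile log-likelihood drops by
  $\chi^2_{1,0.95}/2$, then the crossing is located by bisection. Each
  profile point starts the inner optimization both from the neighbouring
  profile optimum and from the MLE and keeps the better, which prevents the
  warm-start path from settling on a local branch.
* Identifiability: with $e_{WS} = e_{SW} = 0.5$ the two observed classes
  become identical mixtures and $B$ is undefined; near-symmetric data
  (true $B \approx 0$) therefore yield honest, wide profile intervals.
  $B$ and $e$ are well separated away from that corner because
  misorientation mirrors the spectrum while conversion tilts it.

Binned fits (by local GC from 100 bp of flanking sequence per side, or by
the recombination rate of the enclosing window) share nothing across bins;
Ti/Tv-specific fits restrict WS/SW to one mutation type while keeping the
shared neutral class.

## Windowed statistics and gene classes

Windows are fixed and non-sliding, anchored at base 0 of each chromosome
(default 100 kb; the final partial window is kept if it spans at least half
a window). Annotation overlaps resolve by CDS > UTR > intron, and bases
outside genes are intergenic. Per window and element we report Watterson's
$\theta_w = S/(a_{n-1} L)$, pairwise diversity $\pi$, Tajima's $D$ (standard
constants), GC, CpG observed/expected (dinucleotides counted within
contiguous valid runs only, never across extraction boundaries), per-base
divergence to the outgroup consensus over masked-in sites, and the
length-weighted mean population recombination rate $\rho$ from the interval
map. Statistics for elements with fewer than 200 covered bases in a window
are reported absent, not zero. Regression of any two window statistics uses
ordinary least squares with the slope's two-sided t-test p-value, raw
(uncorrected), and class comparisons use percentile bootstrap confidence
intervals from 200 within-class resamples — both matching the conventions of
the analyses this package reproduces.

Gene-level analyses classify genes as HCpG/LCpG by coding-sequence CpG O/E
(strictly above the threshold is HCpG; 1.19 at the gene level, 1.04 for the
1 kb-window variant), tag caste-biased expression from membership lists, and
derive germline-methylation classes from methylated-CpG site tables: genes
with no mCpG are UNMET, and methylated genes split at the median of the
proportion of CpGs methylated (LMET below, HMET at or above — the
proportion metric is used because it controls for CpG availability; ties go
to HMET). Crossover rates are compared inside coding sequence and in
geometric flanks (50 kb starting 10 kb away, and 100 kb starting 50 kb away,
both sides pooled, truncated at chromosome ends, other genes' CDS excluded
by default), all gene-weighted.

## What the generator emulates — and what it does not

`simConfig()` defaults encode the study system this package was built
around: $n = 60$ haploid genomes (30 diploids), AT-biased mutation
$\lambda = 12$, gBGC acting on transitions ($B_{ti} = 6.47$) but essentially
not on transversions ($B_{tv} = 0.03$), outgroup divergence of about 3%,
per-element GC of 0.39 (CDS), 0.23 (intron), 0.31 (intergenic), high
noncoding CpG O/E (~1.7) with a bimodal gene-body CpG O/E, a mean
recombination rate of 390 $\rho$/kb, and a genome-wide SNP influx giving a
realistic per-base density. Sequences are first-order Markov chains whose
parameters are solved numerically per element type to hit the target GC and
CpG O/E (infeasible combinations are rejected with the attainable values).
Derived population frequencies are drawn from the discretized sojourn
density and sample counts from a conditioned binomial — not from a
coalescent or forward simulation. Consequences to keep in mind:

* **Sites are independent.** No linkage, no shared genealogy; sampling noise
  across windows is underdispersed relative to real data, so recovery tests
  certify the estimators and the plumbing, not robustness to linked
  selection or genealogical correlation.
* **Influx versus observed density.** The configured per-class $\theta$ is a
  mutational influx; the expected number of segregating sites scales with
  the sojourn mass of the class's $B$ (neutral classes see exactly
  $\theta \times$ eligible bases). This keeps $\lambda$ recoverable
  end-to-end; with observed-density semantics the SW:WS count ratio would
  be decoupled from $\lambda$ whenever $B \neq 0$.
* **Mispolarization is mechanistic.** Outgroup alleles evolve along a
  configurable branch with a transition-favouring kernel, so double hits and
  back-substitutions — the real cause of polarization error — are what the
  weighted-parsimony stage confronts; errors are not injected by flipping
  labels (a direct spectrum-level error injection is available through
  `simulateClassSfs()` for isolating the $e$ parameters).
* Methylation and expression classes are planted with a configurable
  association to the CpG class; mCpG sites are drawn from the actual CpG
  positions of each gene's CDS, so planted-unmethylated genes emit none.

All randomness flows through one seeded generator per call (seeds are offset
per stage so genome, map, SNPs and gene tables are independently
reproducible), and equal configurations produce byte-identical files.

## Problem sizes used in the test suite

The shipped tests run the estimator-recovery checks at roughly one tenth of
the study's SNP totals (about $3 \times 10^5$ SNPs per spectrum, twenty
seeded replicates per truth point) and the full pipeline closure on a 1 Mb
genome with about $10^5$ SNPs; these sizes give profile intervals narrow
enough to be informative while keeping the whole suite comfortably
desk-scale. Composition targets are validated on 200–300 kb genomes, where
a first-order chain's realized GC is within 0.01 and CpG O/E within 0.05 of
target.

## Known limitations

* The distortion vector is shared across classes; class-specific demography
  (e.g. reference bias differing by base composition) would be absorbed into
  $e$ and $\theta$ instead.
* Hard ancestral assignment: downstream spectra use the chosen allele, not
  probability-weighted counts; the polarization-error parameters of the fit
  are the corrective mechanism.
* A single constant $B$ per fit (per bin); within-bin heterogeneity of $B$
  biases the fitted value toward an effective average.
* CpG O/E of short elements is noisy; gene classification requires a
  configurable minimum CDS length (200 bp).
* The crossover-rate map is an input (an LD-based interval map); no
  recombination inference is performed here.

## A worked micro-example

```{r example}
set.seed(1)
th <- c(WS = 2000, SW = 2000 * 11.69 * 0.34 / 0.66, N = 4000)
sfs <- simulateClassSfs(5.71, th, c(WS = 0.15, SW = 0.02, N = 0),
                        n = 60, seed = 4)
fit <- fitM1star(sfs, nStarts = 3, seed = 2, gc = 0.34)
fit
equilibriumGC(gbgcB(fit), gbgcLambda(fit))
bFromB(gbgcB(fit), Ne = 5e5, ploidy = "haplodiploid")
```
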