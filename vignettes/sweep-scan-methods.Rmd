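---
title: "Methods: simulation model, sweep scan, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation model, sweep scan, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

`sweepscan` implements the downstream half of a whole-genome resequencing
population-genomics workflow: it starts from a multi-sample VCF and a
population map, and ends with filtered SNPs, functional annotation, a
windowed selective-sweep scan, a neighbor-joining phylogeny, a PCA,
linkage-disequilibrium (LD) decay curves, and gene-set enrichment for
candidate regions.  A genotype simulator with known ground truth makes every
stage testable.  This vignette documents the models, the parameters, and the
numerical decisions; the README shows a worked example.

## 1. The simulation model

### Balding–Nichols population frequencies

Each variant site gets an ancestral allele frequency $p \sim U(a, 1-a)$
with floor `maf_floor_ancestral` ($a = 0.05$ by default).  Population $k$
with drift coefficient $F_k$ draws its own frequency

$$p_k \sim \mathrm{Beta}\!\left(p\,\frac{1-F_k}{F_k},\; (1-p)\,\frac{1-F_k}{F_k}\right),$$

the Balding–Nichols model.  Its two properties used throughout:
$E[p_k] = p$, and the expected Hudson FST between two populations with
drift $F_1, F_2$ is approximately $(F_1+F_2)/2$, which provides an analytic
oracle for calibration tests.

### Planted sweeps

A sweep interval names a target population, a stronger drift coefficient
`F_sweep`, and a `diversity_scale` $s \in (0, 1]$.  Inside the interval the
target population's ancestral draw is rescaled to $p' = 1 - s\,(1-p)$
(pushing frequencies toward fixation of one allele, shrinking expected
heterozygosity by roughly $s$) and its Balding–Nichols draw uses `F_sweep`.
Other populations are untouched, so sweep windows show simultaneously
depressed target diversity and elevated FST — the joint signature the scan
looks for.

### Linkage by latent-uniform copying

Haplotypes are drawn site by site as $\mathbf{1}[u < p_k]$.  With
probability $\exp(-d/\texttt{ld\_block\_scale})$, where $d$ is the distance
to the previous site, the haplotype *reuses* the previous site's latent
uniform $u$ instead of drawing a fresh one.  This induces r² that decays
approximately exponentially with distance while leaving every marginal
exactly $\mathrm{Bernoulli}(p_k)$, so frequency-based expectations
(diversity, FST) are unaffected by the LD machinery.

### Mutation spectrum, genotypes, metadata

Each site is a transition (A↔G, C↔T) with probability
$\tau/(1+\tau)$, $\tau$ = `tstv_ratio` (default 2.57), otherwise a uniform
transversion.  Diploid genotypes are the sum of two haplotypes; calls are
masked at `missing_rate`.  Per-site total depth is Poisson with mean
`depth_mean` per sample, and RMS mapping / base qualities are Gaussian
around `mq_mean` / `bq_mean`, giving the filter stage realistic inputs.

Default study-scale configuration: 3 populations of 6/20/4 samples, one
1 Mb contig, ~1 SNP per 300 bp, $F$ = (0.12, 0.10, 0.18).

### Scope and limitations of the generator

The simulator is a calibration device, not a coalescent: sites are
exchangeable draws (no genealogy, no recombination map, no mutation-age
structure), LD comes from the copying kernel rather than shared ancestry,
sweeps are frequency rescalings rather than hitchhiking dynamics, and depth
/ quality metadata are independent of genotype.  Quantities it reproduces
faithfully and that tests rely on: expected FST, expected diversity,
Ts/Tv composition, monotone LD decay, and the joint sweep signature.

## 2. The sweep scan

Windows are `window_size` wide every `window_step` (40 kb / 20 kb
defaults), 0-based half-open; truncated terminal windows are dropped, and a
site belongs to a window iff $\text{pos} > \text{start}$ and
$\text{pos} \le \text{end}$.

Per site with alternate count $a$ of $n$ called alleles, diversity is the
unbiased mean pairwise difference $a(n-a)/\binom{n}{2}$; window $\theta_\pi$
is the sum over sites divided by window length in bp.  Hudson's FST uses
per-site components

$$N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad D = p_1(1-p_2) + p_2(1-p_1),$$

combined per window as the ratio of sums (windows, not sites, are the unit
of inference; ratio-of-sums avoids instability from near-zero per-site
denominators).

Sweep calling Z-standardises $\log_2(\theta_{\pi,\mathrm{ref}} /
\theta_{\pi,\mathrm{target}})$ and $\log(F_{ST} + 1 - \min F_{ST})$ (the
shift keeps the logarithm defined; it is monotone, so outlier membership is
unchanged).  A window is an outlier iff **both** scores reach their
empirical $1 - \texttt{top\_frac}$ quantile (type 7, ties inclusive);
overlapping or book-ended outlier windows merge into candidate regions,
which are then intersected with gene spans.

The intersection of the two marginal 5% tails is *not* 0.25% under the
null: both statistics respond to target-population drift, so they are
positively dependent and the joint rate is somewhat higher.  The test suite
treats $\texttt{top\_frac}^2$ as an independence approximation and checks
the observed fraction against it within sampling tolerance.

## 3. Distances, trees, PCA

The p-distance between samples $i, j$ is
$\sum_s |g_{is} - g_{js}| / (2\,m_{ij})$ over the $m_{ij}$ sites called in
both.  Trees come from neighbor joining (via ape); NJ can produce
negative branch lengths on noisy distances, which are clamped to zero with
the deficit transferred to the sibling edge so path lengths are preserved
as closely as possible (the raw minimum is kept as an attribute).  Bootstrap
supports resample variant columns; supports are percentages on internal
nodes.

PCA centres dosages by $2\hat p$ and scales by $\sqrt{\hat p(1-\hat p)}$
(allele-frequency scaling), imputes missing calls at the site mean (zero
after centring), drops monomorphic sites, and eigendecomposes the
sample-by-sample covariance.  Component signs follow a fixed convention
(largest-magnitude loading positive) so results are reproducible.

## 4. LD from unphased genotypes

The default `composite` r² is the squared Pearson correlation of dosage
vectors — phase-free and robust, but with a known null inflation of about
$1/(n-1)$ that sets a noise floor on decay curves.  The `em` method
estimates haplotype frequencies by expectation–maximisation: double
heterozygotes are the only phase-ambiguous class, and their cis fraction is
iterated to the maximum-likelihood split.  Decay curves bin pairs by
distance (`bin_width`) up to `max_distance`, subsampling at most
`max_pairs_per_bin` pairs per bin with a caller-supplied seed; the
half-decay distance is the linearly interpolated point where mean r² first
drops to half of the first bin's mean (undefined when it never does).

## 5. Enrichment

For a candidate-gene set of size $n$ in a universe of $M$ genes and a term
of size $m$, the p-value is the binomial upper tail
$P(X \ge k),\; X \sim \mathrm{Binom}(n, m/M)$, with a hypergeometric
option; adjustment is Benjamini–Hochberg.  Genes missing from the universe
are dropped with a warning.  Note the binomial tail's discreteness: with
few, small terms the realised false-positive rate at a nominal cutoff can
sit well below it.

## 6. Determinism and problem sizes

Every stochastic step takes an explicit integer seed, and all writers emit
plain text with fixed formatting, so equal configurations give
byte-identical outputs (the pipeline manifest contains no timestamps).  The
test suite exercises the package at study scale: simulations of 0.05–2 Mb,
tens of samples per population, hundreds to thousands of SNPs, 100–1000
bootstrap or Monte-Carlo replicates; the full pipeline on a 1 Mb,
30-sample dataset runs in well under a minute.

## Limitations

* The scan detects the classic hard-sweep signature (low diversity, high
  differentiation); soft or shared sweeps and background selection are out
  of scope, as are haplotype-based statistics.
* Hudson FST is the only estimator; per-window values below 0 (sampling
  noise at low divergence) are reported as-is rather than truncated.
* The EM r² assumes random mating within each population and biallelic
  sites.
* Annotation is designed around UTR-free models (CDS == exons) of the kind
  the generator emits.  On external GFF3s with UTRs, codon effects are
  computed only within CDS; there is no dedicated UTR category, so exonic
  non-CDS positions fall into the remaining intragenic classes.
* p-distance trees are distance-based; no substitution-model correction is
  applied.
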