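---
title: "The skim genotyping model: coverage, depth filtering and accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The skim genotyping model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimeval)
```

## The problem

Skim whole-genome resequencing (WGR) — anything under about 10x genome
coverage — trades read depth for sample number. Library preparation is a
fixed per-sample cost while sequencing scales linearly with coverage, so a
fixed budget buys either few deep genomes or many shallow ones. The price
of shallow sequencing is statistical: cells of the genotype matrix with too
few reads are missing, and heterozygous sites covered by few reads are
miscalled homozygous when, by chance, every read carries the same allele.
`skimeval` packages a generative model of this process, the filtering and
evaluation machinery used to audit real skim data sets, and closed forms
for design decisions.

## The generative model

Genotype truth is simulated per population class:

* **Diverse panel** — per site an alternate-allele frequency $p$ is drawn
  from a configurable MAF distribution (default uniform on $[0.05, 0.5]$),
  and genotypes follow inbreeding-adjusted Hardy–Weinberg proportions
  $\{(1-p)^2 + Fp(1-p),\; 2p(1-p)(1-F),\; p^2 + Fp(1-p)\}$. Crop panels
  are far from panmictic; the inbreeding coefficient $F$ is the single
  knob for the heterozygote deficit ($F = 1$ gives a fully homozygous
  panel).
* **Four-parent cross** — samples are grouped into families; per family
  and site, four founder gametes carry Bernoulli($p$) alleles and each
  offspring unites two distinct gametes drawn at random. Families default
  to ~19 offspring, the granularity of the doubled-haploid material this
  emulates.
* **Doubled haploid (DH)** — hom-alt with probability $p$, else hom-ref.
  Truth contains no heterozygotes, so every heterozygous *call* in a DH is
  an error signal.

Read counts are then layered on top. Depth at cell $(s, i)$ is
$\mathrm{Pois}(\lambda\, m_i)$, where $\lambda$ is the mean coverage and
$m_i$ is a per-sample multiplier drawn from a Gamma distribution with mean
1 and shape $1/\mathrm{cv}^2$ — pooled sequencing spreads realized coverage
around the mean, and the Gamma family hits any target coefficient of
variation with a single parameter (the dispersion *law* is a modelling
choice; only the realized CV is observable). Defaults follow the realized
dispersions of pooled canola runs: CV 0.27 for a diverse panel, 0.34 for
four-parent crosses, 0.17 for DHs. At heterozygous cells each read is
reference with probability $1/2$; at homozygous cells each read reports the
true allele, flipped to the paired allele with per-read error $\varepsilon$.
A configurable fraction of sites are *collapsed-paralog artifacts*: reads
from two homoeologous loci pile onto one position, so every individual's
read pool carries both alleles regardless of genotype. Artifact sites are
drawn once per run — site-level, not cell-level — because misalignment is
consistent across individuals; DH surveys report 3–7% heterozygous calls
from this mechanism but cannot separate artifacts from sampling noise, so
the fraction is left as a free parameter (default 0) rather than asserted.

Sites are simulated independently: linkage is deliberately absent, because
none of the evaluation machinery uses LD. Consequently the simulator says
nothing about haplotype-based callers or imputation, and passing tests here
do not certify behaviour on data whose errors are locally correlated
(e.g. alignment artifacts clustered in homoeologous blocks). Genome-level
depth heterogeneity (GC bias, repeat collapse) is also not modelled: depth
varies across samples but not across sites, which makes per-site missing
fractions more concentrated than in real data (see "Degenerate regimes").

## Calling, filtering, evaluating

The caller is a deliberately transparent two-allele maximum-likelihood
rule over ref/alt counts $(r, a)$: homozygotes emit the wrong allele with
probability $\varepsilon$, heterozygotes emit each with probability $1/2$;
zero depth is missing; exact ties break toward the homozygote of the
majority allele, then hom-ref. A full pileup caller's priors and BAQ
machinery are out of scope — the design questions here concern depth
arithmetic, and the simple rule makes the allele-sampling mathematics
exact: with $\varepsilon = 0$ and $k$ reads over a heterozygote,
$P(\text{called homozygous}) = 2^{1-k}$ exactly. De novo discovery uses
an evidence rule (one sample with $\ge 2$ alternate reads, or two samples
with $\ge 1$) chosen so that a single-read error in a single sample can
never create a site.

Filtering runs in a fixed order: triallelic handling → per-cell depth
masking → per-site missing data → MAF → heterozygosity. The order matters
and is a design choice: the site filters must see the depth-masked matrix,
otherwise the missing-data filter would judge sites on evidence the depth
filter is about to delete. All thresholds are inclusive on the retain side
(missing $\le$ 0.5, MAF $\ge$ 0.05, het $\le$ 0.1): the thresholds are
stated as maxima/minima, and an exactly-borderline site satisfies a
maximum. Per-group MAF uses an *any-group* rule — a site informative in
one subpopulation is worth keeping even if monomorphic elsewhere — with an
`"all"` option for the stricter reading. Presets bundle the three
parameter sets in routine use: diversity panel (MAF 0.05, missing 0.5, het
0.1, triallelics dropped), four-parent (MAF 0.01, missing 0.5), doubled
haploid (no site filters; triallelic sites set to missing rather than
dropped, keeping the matrix aligned to the full SNP list).

Evaluation against a deep reference is *matched-depth*: a skim set
filtered at minimum depth $d$ is compared to the reference masked at
$\max(d, 2)$, so both sides face comparable evidence requirements and the
reference is never judged on single-read calls. Cells partition into
match / mismatch / missing-in-skim / not-evaluable (reference itself too
shallow); accuracy of called genotypes excludes the last two from both
numerator and denominator. Cumulative accuracy tables bin sites by
per-site missing fraction with strict upper edges (<10%, … <50%) — a
reporting convention, distinct from the $\le 0.5$ retention filter.
Chromosome density is SNPs per Mbp normalized by the densest chromosome
(length correction is a choice; a raw-count switch is provided), with
half-open 1-Mbp bins.

## Design closed forms

For a quick answer before simulating: the probability a cell is callable
is $P(\mathrm{Pois}(\lambda) \ge d)$; the heterozygote under-call
probability at observed depth $k$ is $2^{1-k}$; and expected called
accuracy mixes the caller's per-depth correctness over the Poisson depth
distribution truncated at $\max(d, 1)$ (zero-depth cells are missing, not
wrong) and the population's genotype mix. The cost model is
$n\,(\$12 + \text{coverage} \times \text{Gb}/1x \times \$30)$ with 1 Gb
per 1x by default (a genome of roughly 1 Gbp; set `gb_per_1x = 4.3` for
pea-sized genomes); affordable sample counts round to the nearest whole
sample. At these defaults 100 samples cost \$4,200 at 1x and \$16,200 at
5x, and \$50,000 buys 1,190 samples at 1x or 309 at 5x.

```{r design}
design_table(coverages = c(0.5, 1, 2), depths = c(2, 4),
             het_rate = 0.1, eps = 0.01, budget = 50000)
```

## Numerical choices and degenerate regimes

* Reproducibility: every stochastic function takes a seed; identical
  inputs and seed give bit-identical output. FASTQ subsampling derives a
  per-file stream seed from the master seed and the file name, so adding
  samples never perturbs existing outputs.
* Subsampling keeps each read (pair) independently with probability
  `fraction` rather than drawing an exact count — the binomial variability
  is part of what pooled sequencing looks like, and pairs are kept
  together (the jointly-vs-independently question is unstated in routine
  protocols; jointly preserves pairing invariants).
* Zero-depth cells are missing by definition, never counted as wrong;
  sites with no called genotypes have undefined MAF (removed by the MAF
  filter when it is enabled) and undefined accuracy (flagged `NA`).
* Under a pure Poisson depth model, low coverage with relaxed depth
  filters is a degenerate regime: at $\lambda = 1$ and $d = 2$, per-site
  missing concentrates near $1 - P(\mathrm{Pois}(1) \ge 2) \approx 0.74$,
  so the 50%-missing filter removes essentially all sites. Real data
  escape this because depth also varies along the genome, letting a
  subset of sites ride above-average coverage; that between-site
  variance is outside the model, so model-based evaluations of relaxed
  filters are most informative at coverage $\ge 2$x.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to make
binomial/Poisson standard errors small relative to the quantities checked:
distributional checks at $10^5$ cells, the closed-form-vs-pipeline closure
test at $10^6$ cells per grid point over a $3 \times 3$
(coverage × heterozygosity) grid, and the end-to-end simulated study at
5,000 sites × 60 samples. All statistical assertions use 3-standard-error
bands from the analytic null, never tuned constants.
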