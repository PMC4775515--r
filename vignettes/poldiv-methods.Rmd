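---
title: "Methods and design of poldiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of poldiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poldiv)
```

`poldiv` implements a multilocus polymorphism-to-divergence workflow for
phased coding alignments from a pair of closely related species — the study
design in which a handful of candidate loci (here, heat-shock protein
paralogs and a mitochondrial reference gene in sister krill species) are
screened for selective sweeps, balancing selection and demographic change.
This vignette explains the statistical models, the defaults, the numerical
choices, and what the simulation-backed tests do and do not establish.

## Input model

The universal input is an equal-length alignment of phased coding alleles in
FASTA, two alleles per individual, with species/individual/allele encoded in
the label (default schema `EC12_All1`-style; configurable regex). Internally
coordinates are 0-based half-open; every report is 1-based, and amino-acid
positions are 1-based residues within the sequenced fragment. The alphabet is
`A,C,G,T,N,-`; `N` and `-` are treated as missing by *pairwise deletion*:
they never create polymorphism and drop only the affected pairs from
pairwise statistics. Haplotype collapsing treats `N` as a wildcard, which
maximises use of partially resolved cloned alleles. Both the
pairwise-deletion and complete-deletion segregating-site counts are logged
(`S` and `S_complete`), since published tables can follow either convention.

## Diversity and divergence statistics

Per locus and species the package reports `S`, Watterson's
$\theta_w = S/(a_{n-1}L)$, nucleotide diversity $\pi$, haplotype diversity
$H_d = \frac{n}{n-1}(1-\sum p_i^2)$, and Tajima's $D$, with the standard
no-recombination variances (Tajima's constants; Nei's variance for $H_d$) —
the "± SD" convention of classic polymorphism tables. $D$ is reported as
undefined when $S=0$ or $n\le 3$ (the normalising constants vanish there).

Between groups, divergence is the mean pairwise p-distance with the
Jukes–Cantor correction $K_{JC} = -\tfrac34\log(1-\tfrac43 K_{raw})$; net
divergence ($D_a$) is logged alongside. Synonymous/nonsynonymous accounting
uses Nei–Gojobori (1986) pathway counting with equal pathway weights,
stop-traversing pathways excluded from the averaging, mutations to stop
codons counted as nonsynonymous in the site totals (so synonymous +
nonsynonymous sites are exactly three per codon), and Jukes–Cantor
correction of the proportions. All 64×64 codon-pair path averages are
precomputed, which keeps 50-bp/10-bp sliding windows (the default profile
resolution, with a 100-bp/50-bp variant for divergence) fast. Ratio windows
with a zero denominator are flagged, never dropped.

## Linkage and recombination

Pairwise LD uses $r^2$ with a two-tailed Fisher exact test on the 2×2
haplotype table and Bonferroni correction at $\alpha/\text{pairs}$. Kelly's
$Z_{nS}$ is the mean $r^2$. By default **all** biallelic segregating sites
enter the pair set — on fully biallelic data that yields exactly
$\binom{S}{2}$ pairs, which is the convention that reproduces published
pair counts; `exclude_singletons = TRUE` gives the stricter convention and
the pipeline reports both. Hudson–Kaplan $R_m$ applies the four-gamete test
to every biallelic pair and counts a maximal set of disjoint incompatible
intervals.

The infinite-sites filter used before coalescent-likelihood work removes
multiallelic sites, then greedily removes the site or sequence that resolves
the most remaining four-gamete incompatibilities, preferring sites on ties
to preserve sample size — a data-maximising stand-in for the published
filtering scripts whose exact weighting is not described.

## McDonald–Kreitman and heterozygote excess

The MK table contrasts within-sample polymorphic site classes ($P_n, P_s$)
with fixed between-group differences ($D_n, D_s$). Two two-tailed exact
conventions are reported (`p`, the sum of tables at most as probable as the
observed one, and `p_doubled`, twice the smaller tail), because published
values can follow either. The polymorphism source defaults to one focal
species; a pooled mode simply passes both. Heterozygote excess at a
diallelic diagnostic system uses the Levene exact conditional distribution,
one-sided toward excess.

## Multilocus maximum-likelihood HKA

Each locus contributes a polymorphism count $S_i$ with expectation
$k_i c_i \theta_i L_i a_{n_i-1}$ and a divergence count $D_i$ (mean pairwise
between-species differences) with expectation $c_i\theta_i L_i(T+1)$, where
$c_i$ is an inheritance scalar (1 nuclear, 0.25 mtDNA by default — the
source study never states its mitochondrial scaling, so it is exposed as an
argument), $T$ the shared species divergence in $2N$ generations, and $k_i$
a per-locus selection coefficient multiplying the polymorphism expectation
only: $k<1$ reads as a sweep, $k>1$ as balancing selection. The `+1` is the
ancestral-polymorphism term and is configurable.

Two likelihood marginals are provided. `"poisson"` treats both counts as
Poisson at their means — the textbook shorthand — but ignores genealogical
variance and we measured its LRT type-I error at 0.23 for nominal 0.05. The
default `"coalescent"` marginal keeps the same means and integrates the
genealogy: Tavaré's (1984) exact sampling distribution for $S_i$, and for
$D_i$ a Poisson mixed over the ancestral pairwise coalescence time
($t \sim \mathrm{Exp}(1)$, Gauss–Laguerre quadrature; we verified on
simulations that the mean-pairwise divergence of an isolation model has
almost exactly this variance). With it the nested LRT has empirical size
0.05 and ≥80% power against a 10×-reduced locus at $n=20$, $L\approx1000$,
$\theta=0.01$/site. Fitting is by bounded quasi-Newton on log-scale
parameters with three jittered restarts; the spread of restart likelihoods
is the convergence diagnostic (the original software used MCMC; with ≤9
parameters a quasi-Newton profile is faster and reproducible).

## Mismatch distributions and expansion dating

The observed spectrum is the normalised histogram of pairwise difference
counts; its mean equals the mean pairwise difference count identically.
Constant size gives the geometric curve $F(i)=\theta^i/(1+\theta)^{i+1}$.
The sudden-expansion model (ancestral $\theta_0$, current $\theta_1$,
expansion at mutational time $\tau$) is evaluated in closed form,

$$F_i = F_i^{c}(\theta_1)\,P\!\left[\Gamma(i{+}1) \le (1{+}1/\theta_1)\tau\right]
 + e^{-\tau/\theta_1}\sum_{j=0}^{i}\mathrm{Pois}(j;\tau)\,F^{c}_{i-j}(\theta_0),$$

computed in log space for numerical stability. At $\tau=0$ the curve
reduces to constant size at the *ancestral* $\theta_0$ (a labelling slip in
some descriptions puts $\theta_1$ here; the model itself is unambiguous).
Fitting is least squares over $(\theta_0,\theta_1,\tau)$ with the ordering
enforced by the parameterisation, three starts, and the constant-size fit
reported for comparison; $R_2$ (Ramos-Onsins & Rozas) and Harpending's
raggedness are computed from the data. Expansion dating uses
$t = \tau/(rL)$ with $r$ the *pairwise* divergence rate per site per My
(the "2% per My" convention; this arithmetic reproduces the order of 4×10^5
years for a mitochondrial spectrum with mean ≈ 5 differences over 558 bp).
A $\theta$-ratio dating under exponential growth is exposed separately.

## Constant size vs bottleneck vs sweep

The three-model comparison fits, per species: M1, constant size with one
$\theta_i$ per locus; M2, a shared instantaneous coalescent-intensity burst
$(T_b, S_b)$ — at time $T_b$ (units of $2N$ generations) $S_b$ units of
coalescent time are compressed into the event; M3, a private $(T_i, S_i)$
per locus. The sweep is thus modelled as a locus-specific contraction, with
no explicit hitchhiking trajectory — exactly the equivalence the original
coalescent-likelihood tool is built on. Parameter counts are $n_\ell$,
$n_\ell+2$ and $3n_\ell$.

The per-locus likelihood is a Monte-Carlo mixture over genealogies of the
folded site-frequency-spectrum probability,
$\log E_G \prod_m \mathrm{Pois}(\eta_m;\ \theta L^f_m(G)/2)$, with $\theta$
profiled per locus on $(0, 30]$ (the traditional prior range). The folded
SFS keeps tree-shape information — with an $S$-only likelihood the
per-locus $\theta$ would absorb any event and M3 would be unidentifiable —
while remaining tractable. Genealogies are simulated once per locus on the
effective-time scale and remapped through every $(T,S)$ grid point
(default $T\in[0,4]$, $S\in[0,4]$, covering published estimates), so all
three model maxima share their Monte-Carlo noise and are exactly nested:
$\ln L(M3) \ge \ln L(M2) \ge \ln L(M1)$ always holds.

Two calibration caveats are intrinsic and documented rather than hidden.
First, the $\chi^2$ reference for these profile LRTs is anticonservative
(boundary parameters, grid profiling, Monte-Carlo error); the package
provides `null_lrt_quantiles()`, a parametric-bootstrap calibration of the
three LRT statistics, and the test suite uses it. Second, the power to
crown M3 when only one locus of four experienced a contraction is low
(roughly 10–40% across the worlds we examined): the single locus's SFS
signal must overcome a $2(n_\ell-1)$-df penalty over M2, and the original
program's richer full-configuration likelihood is not published at
implementable detail. The suite keeps that recovery check in place and it
fails honestly; detection of the same contraction by direct likelihood
comparison at the affected locus (truth vs constant size) does succeed and
is tested.

## The synthetic-data generator

The generator is first-class, tested code. It produces codon-aware FASTA
under: constant size; sudden expansion (step change or exponential growth);
an instantaneous contraction (bottleneck/sweep emulation); a two-species
isolation model (independent coalescents below the split, one ancestral
population above); and two ancient balanced allelic classes (structured
coalescent with class-exchange rate $m$). Infinite-sites mutations are
assigned to distinct alignment sites on a random stop-free codon backbone:
synonymous mutations go to third positions that have a synonymous
alternative (2-fold and 4-fold codons), nonsynonymous ones to first/second
positions with a stop-free amino-acid-changing derived base. A rare
two-hits-in-one-codon combination can create a stop in some leaves; the
most recent offending mutation is undone. This collision-free design keeps
the analytic expectations exact — $E[S]=\theta L a_{n-1}$,
$E[\pi]=\theta$, $E[D]\approx 0$ — which the suite verifies against theory
and against an independently coded plain-R coalescent.

Defaults state a world shaped like the motivating study: 24 alleles per
species, locus lengths 558–891 bp, per-site $\theta$ of 0.004–0.012 across
loci, mitochondrial scalar 0.25, species split 5 × $2N$ generations, 80% of
mutations synonymous (coding loci under purifying selection are dominated
by synonymous variation). Sweep and balancing emulation multiply the
mutation intensity of branches private to one species by a factor (0.1 and
4 in the tests). Every simulation is bit-reproducible under its seed.

What a green test establishes: the estimators agree with coalescent theory
and with independent oracles under the generator's assumptions — a single
non-recombining genealogy per locus, free recombination between loci,
equilibrium or the stated simple demographies, uniform codon usage. Real
data add intralocus recombination, mutation-rate heterogeneity, codon bias
and sampling structure; green tests say nothing about those.

## Numerical choices

* Exact tests by enumeration in log space; ties in the "sum of small
  tables" convention use a $1+10^{-7}$ slack, as standard.
* All likelihood optimisation on log-scale parameters with `nlminb` or 1-D
  `optimize`; $\theta$ bounds $(10^{-4}, 30]$ locus-scale.
* Monte-Carlo log-likelihoods via a max-shifted log-mean-exp; genealogies
  incompatible with an observed class give $-\infty$ and degenerate grid
  points report effectively impossible fits rather than errors.
* Divergence counts may be non-integer (mean pairwise); Poisson terms use
  the continuous-density extension $d\log\lambda - \lambda - \log\Gamma(d+1)$.
* Seeds: every stochastic routine takes one; the pipeline records it in all
  outputs.

## Known limitations

* The M3-vs-M2 model-selection power limitation described above.
* The MK framework here is unpolarised (no outgroup assignment of derived
  states) and no asymptotic-α extension is provided — both out of scope.
* The Jukes–Cantor correction saturates at raw distances ≥ 0.75 and the
  package refuses rather than extrapolates.
* Reproduction of the motivating study's per-locus numbers requires its
  supplementary alignments, which cannot be redistributed with the package;
  the acceptance tests encode the printed values and run whenever the files
  are placed under `inst/extdata/krill/`.
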