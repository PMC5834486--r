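---
title: "Modelling gene-environment interaction in case-parent triads"
author: "triadscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene-environment interaction in case-parent triads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadscan)
```

## The design and the model

A case-parent triad study genotypes an affected child together with its
mother and father. The two parental alleles that were *not* transmitted to
the child act as internal controls, so the design is robust to population
stratification: any allele-frequency difference between subpopulations is
matched within each family. `triadscan` analyses biallelic autosomal SNPs in
such families, including *dyads* — families where one parent's genotype is
missing entirely.

Within a stratum of families, the model assumes:

* **HWE / random mating for founders.** Each parent is two independent
  draws from a haplotype pool with frequencies $p_h$ over the $2^k$
  haplotypes of a window of $k$ tightly linked SNPs ($k \le 3$ by default;
  no recombination is modelled within a window).
* **Mendelian transmission.** Each parent transmits one of its two
  haplotypes with probability 1/2.
* **Multiplicative dose-response.** A child carrying haplotypes
  $(t_m, t_f)$ is affected with relative risk
  $\mathrm{RR}(t_m)\cdot\mathrm{RR}(t_f)$; two copies of a haplotype with
  relative risk $R$ confer $R \times R$ (`child_risk()`).

Because families are ascertained through the affected child, the
probability of a fully phased configuration
$(m_1, m_2, f_1, f_2, t_m, t_f)$ is tilted by the child's risk:

$$
P(\text{config}) \;=\;
p_{m_1} p_{m_2} p_{f_1} p_{f_2}\cdot \tfrac14 \cdot
\frac{R_{t_m} R_{t_f}}{\mu},
\qquad
\mu = \Big(\sum_h p_h R_h\Big)^{2}.
$$

Phase is never observed, genotypes may be missing, and a parent may be
absent. The observed-data likelihood therefore sums the configuration
probabilities over everything compatible with what was seen
(`observed_loglik()`); this is exactly the quantity an EM algorithm for
haplotype reconstruction maximizes. The sum factorizes by parent — with $M$
the 0/1 matrix of ordered parental pairs compatible with a parent's
genotypes, the "transmission kernel" is $A(t) = p_t (Mp)_t$, and a family's
likelihood is $\frac{1}{\mu}\sum_{(t_m,t_f)\in C} R_{t_m}R_{t_f} A_m(t_m)
A_f(t_f)$ with $C$ the child's compatibility matrix. A missing parent has
$A(t) = p_t$. The test suite verifies this factorization against
brute-force enumeration of the full configuration space to $10^{-10}$
log-likelihood units.

### Estimation

`fit_triads()` maximizes the observed-data log-likelihood over
$(p_h, \log \mathrm{RR}_h)$ with the reference haplotype pinned at
$\mathrm{RR} = 1$. We deliberately use a quasi-Newton optimizer (L-BFGS-B)
on softmax-transformed frequencies rather than literal EM: the objective is
identical, convergence is faster on the 2-parameter single-SNP surface that
dominates genome-wide scans, and the estimate is validated contractually —
on small instances the fit must dominate a dense grid search over
$(p, \mathrm{RR}) \in [0.05, 0.95] \times [0.1, 10]$ to $10^{-6}$.
Standard errors come from the observed information (numerical Hessian) at
the optimum; the frequency parameters are part of the Hessian, so the
uncertainty of estimating $p_h$ propagates into the RR standard errors.

Choices a user can tune via `model_options()`:

| option | default | meaning |
|---|---|---|
| `rare_haplotype_min` | 0.01 | haplotypes rarer than this get RR pinned to 1 and no SE; their frequency is still estimated |
| `tol` | 1e-8 | relative log-likelihood convergence |
| `max_iter` | 500 | optimizer cap; non-convergence is flagged, not hidden |
| `n_starts` | 3 | deterministic multistart jitters for $k \ge 2$ windows (one start for single SNPs, whose 2-parameter surface is well behaved) |
| `log_rr_bound` | log(1000) | cap on \|log RR\|; an estimate at the bound marks separation (a haplotype seen only transmitted) |

The multistart jitters are deterministic by design: fits run inside seeded
simulations and must not perturb the caller's random-number stream.

The reference haplotype is the most frequent one under a null pre-fit, and
for single SNPs the minor allele is consequently the effect allele. When
strata are compared, the reference is fixed from the pooled fit so that
RRs are comparable across strata.

## Gene-environment interaction

For a binary maternal exposure, `fit_strata()` fits the exposed and
unexposed families *independently* — separate haplotype frequencies and
separate RRs. Stratum-specific frequencies are a real feature of pooled
multi-ethnic data (exposure prevalence differs across ancestries, and so do
allele frequencies), and sharing them would leak information between
strata. Families with unknown exposure contribute only to the unstratified
child-effect fit.

The interaction measure is the relative-risk ratio
$\mathrm{RRR} = \mathrm{RR}_{\text{exposed}} / \mathrm{RR}_{\text{unexposed}}$,
tested on the log scale with a Wald statistic (`rrr_wald()`):

$$
\log\widehat{\mathrm{RRR}} = \log\widehat{\mathrm{RR}}_1 -
\log\widehat{\mathrm{RR}}_0,\qquad
\mathrm{se}^2 = \mathrm{se}_1^2 + \mathrm{se}_0^2,
$$

with a two-sided normal p-value — the strata are disjoint families, so the
estimates are independent. An RRR below 1 with stratum RRs straddling 1 is
a *qualitative* interaction: the allele is protective under the exposure
and deleterious without it (or vice versa). `rrr_from_rr()` exposes the
same arithmetic for published stratum estimates whose standard errors must
be back-calculated from confidence intervals.

`gxe_scan()` composes sliding windows (`sliding_windows()`, which never
cross a chromosome boundary), stratified fits and the Wald test into one
table per (window, haplotype), ranked by p-value. Windows where a stratum
cannot be fitted are skipped and counted rather than silently dropped.

## Multiplicity, QQ and Manhattan tables

`storey_qvalues()` implements the q-value procedure: $\hat\pi_0$ is
estimated on the grid $\lambda = 0.05, 0.10, \dots, 0.95$ by
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$, smoothed with a
3-df cubic smoothing spline and read off at the largest $\lambda$, then
clamped to $(0, 1]$. Sorted q-values are the step-down minima of
$\hat\pi_0\, m\, p_{(j)} / j$, so a q-value of 0.1 is an estimated false
discovery rate of 10% among the calls at that threshold. With $m < 100$
the tail smoother is too noisy to trust and $\pi_0$ is forced to 1 with a
warning, which makes the procedure exactly Benjamini-Hochberg — a property
the tests assert on exhaustive permutations.

`qq_points()` returns plot *data*: expected quantiles
$-\log_{10}(i/(m+1))$ and a pointwise 95% band from the
$\mathrm{Beta}(i, m-i+1)$ law of uniform order statistics. The band is
pointwise, not simultaneous: under the global null about 5% of points fall
outside it, and whole-curve excursions are more common than a simultaneous
band would suggest. `manhattan_table()` adds cumulative coordinates and a
highlight flag (default $p < 10^{-6}$). Rendering (`plot_qq()`,
`plot_manhattan()`) is a convenience; the tested artifact is the table.

## Asymptotic power

`asymptotic_power()` evaluates the Wald RRR test's power from the expected
per-family Fisher information of the single-SNP triad likelihood. The 15
ascertained (mother, father, child) genotype categories have closed-form
probabilities (`triad_category_probs()`); the $2\times 2$ expected
information over $(p, \log \mathrm{RR})$ is computed by numerical
differentiation of their logs and inverted, and the $\log \mathrm{RR}$
block is extracted — so the cost of estimating the allele frequency is
included, matching the full-ML analysis the scan performs. Then

$$
\mathrm{var}(\log \mathrm{RRR}) = \frac{1}{n_1 I_1} + \frac{1}{n_0 I_0},
\qquad
\text{power} = \Phi(z - z_{1-\alpha/2}) + \Phi(-z - z_{1-\alpha/2}),
$$

with $z = |\log \mathrm{RRR}|/\mathrm{sd}$. At $\mathrm{RRR} = 1$ this is
exactly $\alpha$. Two deliberate consequences of evaluating the
information *under the alternative* (each stratum at its own RR):

* power is not exactly symmetric in $\mathrm{RRR} \mapsto 1/\mathrm{RRR}$
  (a protective minor allele carries less information than a deleterious
  one at the same frequency); the identity is exact only jointly with
  allele relabeling $p \mapsto 1-p$, which the tests assert;
* agreement with Monte-Carlo power is excellent at the design points we
  validate (within the Monte-Carlo error at $n = 1000$ per the acceptance
  suite).

The information calculation is itself checked against an independent
score-covariance computation (the information equality).

## The synthetic-data generator

`simulate_study()` emulates the structure of a multi-site triad GWAS so
that every pipeline stage is testable without access to controlled data:

* exposure strata of configurable sizes, each with its own haplotype pool
  and RR vector;
* **exact case ascertainment by rejection sampling**: a drawn family is
  accepted with probability $\text{child risk}/\max_h R_h^2$. This is
  exact under the multiplicative model, trivially correct to audit, and
  fast when RRs are moderate. The empirical 15-category distribution is
  tested against `triad_category_probs()` by goodness-of-fit at
  $n = 20{,}000$;
* dyads by deleting one random parent in a configurable fraction of
  families (default 314/1908, matching the triad/dyad split of the study
  design this package targets);
* contamination *after* ascertainment: per-call missingness, symmetric
  per-allele flip errors (which intentionally create Mendelian
  inconsistencies for the QC surface to find), and missing exposure
  records;
* a truth record sufficient to recompute any summary (phased parental
  haplotypes, transmissions, strata, dropped parents).

All randomness flows from the single mandatory seed: `simulate_study()`
seeds R's stream once and draws everything sequentially from it.

One property of ascertained sampling worth knowing: the *founder* allele
frequency among case families is tilted toward the risk allele, because
each parent's transmitted haplotype has probability
$p_h R_h (\sum_g p_g R_g)/\mu$ rather than $p_h$. At $\mathrm{RR} = 2$,
$p = 0.3$ the founder pool sits at 0.381, not 0.30. The generator
reproduces this exactly and the tests assert the tilted value — a naive
"founders match the pool" check would be wrong.

What the generator does **not** emulate: linkage disequilibrium between
loci that are not in the same window (null SNPs are independent),
recombination, admixture or other population structure, genotyping batch
effects, and exposure prevalence that varies with ancestry. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to those real-data features.

## Quality control

`apply_qc()` applies, in a fixed order: (1) removal of individuals with
call rate below 10% (a removed child takes its family along — the design
needs the case); (2) recomputation of per-SNP statistics; (3) removal of
SNPs failing any of: founder HWE $p < 0.001$ (children are ascertained
cases and violate HWE by design, so HWE is tested on parents only, pooled
across families), missingness $> 5\%$, MAF $\le 5\%$, Mendelian-error rate
$\ge 1\%$; (4) masking of residual Mendelian-inconsistent family genotypes
at the offending locus. The report counts every criterion separately while
removing each SNP once — the remaining count respects the union, not the
sum. The 10% call-rate default is deliberately permissive (it mirrors the
practice of the study design this package targets) and is configurable.
Masking is skipped when the Mendelian criterion is disabled
(`mendel_rate_max = 1`), so fully vacuous thresholds are a no-op.

The Mendelian check is a vectorized dose-bound argument (a parent with 0
copies transmits 0, with 2 copies transmits 1, otherwise either), verified
in the tests against a brute-force enumeration of transmissions, and its
exactness for dyads and missing genotypes falls out of the same bounds.

## Numerical choices and degenerate inputs

* Monomorphic markers: HWE returns statistic 0 / p 1 with a flag; LD
  (`ld_pairwise()`) is undefined and returned as `NA` with a flag.
* Families whose child is untyped across a window are dropped from that
  window with a warning (they carry no information); families
  Mendelian-inconsistent at a window are excluded from that window only.
* A haplotype seen only in transmitted position would diverge; its
  $\log \mathrm{RR}$ is capped at `log_rr_bound` and flagged.
* Half-missing genotype calls ("A 0") are treated as fully missing.
* Genotypes are stored unordered (allele-dose coding); phase is always
  reconstructed, never read from input.
* PED/MAP round-trips are byte-identical under the package's
  normalization: single spaces, sorted allele pairs, absent parents as
  absent rows with ids preserved on the child row.

## Validation regimes and problem sizes

The acceptance suite exercises the regimes the package is designed for,
at sizes chosen to make Monte-Carlo error small relative to the assertion:
null-scan calibration at 500 SNPs x 1000 families (type-I error within two
Monte-Carlo SEs of 5%; QQ points inside the 95% band at a >= 93% rate);
interaction recovery at 2000 triads, MAF 0.4, RRR 0.6 over 200 replicates
(median bias of $\log \mathrm{RRR}$ under 0.03, CI coverage in
[0.92, 0.98]); and power validation at 1000 triads, MAF 0.2,
RRR 1.6 against 1000 Monte-Carlo scans (agreement within 3 points).
`scripts/acceptance.R` re-runs the same computations from scratch at a
caller-supplied seed.

## Known limitations

* Maternal-genotype and parent-of-origin effects are not modelled; the
  likelihood attributes all genetic effect to the child's genotype.
* Only binary exposures and two strata; no covariate adjustment beyond
  stratification.
* Closed-form power is single-SNP only; haplotype-window power requires
  simulation.
* The full HWE-based retrospective likelihood is used (founder frequencies
  carry information); a variant conditioning on parental genotypes would
  be slightly more robust to founder-HWE violations and is a possible
  extension.
* The HWE QC test is the 1-df chi-square, adequate at GWAS scale; an exact
  test would serve small founder counts better.
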