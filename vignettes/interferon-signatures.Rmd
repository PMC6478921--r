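---
title: "Methods: interferon subtype signatures in SLE cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interferon subtype signatures in SLE cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnsig)
```

`ifnsig` implements a pipeline for asking *which* interferon drives the
interferon gene signature (IGS) of an SLE expression cohort, and what that
signature relates to — disease activity, time, and cell composition. This
vignette is the package's own account of the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices a maintainer should know about.

## Reference signatures from moderated differential expression

Subtype signatures are built from two-group differential expression with
empirical-Bayes variance moderation. For gene $g$ with pooled residual
variance $s_g^2$ on $d = n_1 + n_2 - 2$ degrees of freedom, the $s_g^2$ are
modelled as scaled-F draws around an inverse-chi-square prior with
parameters $(d_0, s_0^2)$, estimated by matching the mean and variance of
$\log s_g^2$ through digamma/trigamma identities (a Newton iteration
inverts the trigamma function to tolerance $10^{-10}$). The posterior
variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}$$

gives the moderated $t = \Delta\bar x / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$
on $d_0 + d$ degrees of freedom, with Benjamini–Hochberg q-values. Two
limits are useful for testing and exposed through the `d0` argument:
`d0 = 0` reproduces the ordinary pooled t exactly, and constant $s_g^2$
across genes drives $d_0 \to \infty$ (complete shrinkage). When the
observed log-variances underdisperse the scaled-F reference
(`var(e)` at or below `trigamma(d/2)`), the prior degrees of freedom are
infinite and the shrinkage target is the bias-corrected mean
$\exp(\overline{\log s^2} - \psi(d/2) + \log(d/2))$ — note this is *not*
the raw common variance, a property shared with the reference
implementations of these formulas. Genes with zero pooled variance are
excluded from prior estimation; if all genes are constant, estimation
aborts.

Signature membership uses strict cuts on the *linear* fold-change scale:
a gene enters the up set when $q < q_{\max}$ and $2^{\mathrm{lfc}} >
\mathrm{fc}_{\min}$ (defaults $q_{\max} = 0.01$, $\mathrm{fc}_{\min} = 2$
for reference signatures; the broader DE screen uses $q < 0.2$ to favour
sensitivity over purity). Both cuts are strict, so a gene at exactly
$q = 0.01$ is excluded; loosening either threshold can only add genes
(monotonicity, property-tested).

The Venn partition of the subtype signatures reports every disjoint
membership cell plus two derived sets: the type I **core** (intersection of
the three type I up-sets) and the type I/II **shared** subset (core ∩ type
II set); the core count is conventionally reported as
`core_only + shared`, e.g. 146 + 54 = 200 under the published topology.
Only up-regulated transcripts enter the partition — induced-transcript
counts are what the partition describes — and the same assumption is made
when the synthetic universe is built.

The minimum gene-set overlap of three transcripts is justified by the
independence power law `minimal_overlap_error(k, fdr) = fdr^k`: at the DE
screen's FDR 0.2, one overlapping transcript is a false discovery with
probability 20%, two with 4%, three with 0.8%.

## Single-sample enrichment

The enrichment engine is written from scratch (it is the analytical core of
the package, not a wrapper). For each gene the expression values across
samples are converted to a kernel cumulative score

$$\hat z_{gj} = \frac{1}{n}\sum_k \Phi\!\left(\frac{x_{gj} - x_{gk}}{h_g}\right),
\qquad h_g = s_g/4,$$

i.e. a Gaussian-smoothed ECDF with bandwidth a quarter of the gene's SD
(the cited method's default; constant genes get 0.5 everywhere, and the
transform requires at least 3 samples for the bandwidth to mean anything).
Within each sample, genes are ranked by $\hat z$ descending and the rank is
symmetrized, $r = |N/2 - \mathrm{rank}|$, so both extremes of the ranking
carry weight. A Kolmogorov–Smirnov-like walk then traverses the ranked
list: signature genes step up by $r^\tau / \sum_{\mathrm{set}} r^\tau$
(default $\tau = 1$), others step down by $1/(N - m)$. Because both step
families sum to one, every deviation lies in $[-1, 1]$.

Two score variants are exposed, because heatmaps of such scores contain
both positive and negative values around zero and the field uses both
conventions: the default `difference` score is the signed sum of the
maximum positive and minimum negative deviations; `two_sided` returns the
single largest-magnitude deviation with its sign. Numerical choices: ties
in $\hat z$ break by gene symbol (lexicographic) so results are
deterministic; in `two_sided` mode an exact magnitude tie between the
positive and negative deviation resolves to the positive one (the tie is a
rational-arithmetic event that genuinely occurs, and unstated it would
leave the sign at the mercy of floating-point accumulation order).
Signatures with fewer than `min_set_size = 3` genes present in the matrix
are skipped with a warning — the three-transcript floor from the overlap
power law above. When a signature carries down-regulated genes the score is
ES(up) − ES(down).

Because the score is a function of ranks of per-gene ECDFs, it is exactly
invariant under per-gene affine increasing transformations and under gene
reordering, and equivariant under sample permutation — all property-tested.
It is *relative*: a sample's score for one set depends on what the other
genes do, so un-induced control sets drift negative in strongly induced
patients (visible in the README example), and the score saturates near its
bounds once a set's genes occupy the top of the ranking. That ceiling is
why mechanism checks (e.g. monocyte-fraction monotonicity) are run at
moderate induction, where the response is still linear.

## Positivity, effect sizes, activity strata

A patient is **positive** for a signature when their score strictly exceeds
the control mean plus `sd_multiplier = 2` control SDs (sample SD, $n-1$
denominator), computed per signature from at least two controls; constant
controls give a zero-width threshold and a warning. Activity strata split
SLE patients at SLEDAI ≥ 6 (active). Group separation is quantified by
Welch's unequal-variance t and Hedges'
$g = (\bar a - \bar b)/s_{\mathrm{pooled}}$; the small-sample correction
$J = 1 - 3/(4(n_1+n_2) - 9)$ is available but off by default, matching the
plain pooled-SD convention of the calculators used in this field.
Signatures with Welch $p \ge 0.05$ are flagged `N.S.` and the table is
ordered by $g$ descending — the convention for naming a tissue's dominant
subtype.

## Activation Z-scores

The directional score against a reference contrast is
$Z = \sum_i w_i x_i / \sqrt{\sum_i w_i^2}$ with unit edge weights by
default, where $x_i = \pm 1$ records whether the observed fold-change sign
agrees with the reference direction. Matching is restricted to observed
genes significant at $q < 0.2$; reference genes absent from that set are
*dropped*, not counted discordant (the score is built "strictly from the
experimentally observed information"; `include_nonsignificant = TRUE`
switches to matching against all observed genes). With unit weights
$Z = (c - d)/\sqrt{c + d}$, bounded by $\sqrt{n}$, and antisymmetric under
a global direction flip — all verified by enumeration. Significance uses
the conventional constants 1.96 (95%) and 2.54 (99%); the 99% constant is
kept verbatim as used in the field even though the exact normal quantile is
2.576, and `exact = TRUE` switches to exact quantiles.

## Time-course gain/loss

Per patient and signature, the across-time SD of the score is compared to a
threshold; the default rule takes the **largest control-score SD across
signatures** (config alternatives: per-signature control SD, or a fixed
0.2). Patients above threshold are categorized by their first and last
positivity calls: negative→positive is `gain`, positive→negative `loss`;
above-threshold patients whose endpoints agree are `fluctuating` — the
residual class has to exist so that categories partition patients (ties at
the threshold are non-significant, hence `stable`). Patients missing a
timepoint are excluded with a warning. Whether control SDs should pool
across signatures before taking the maximum is genuinely ambiguous; both
behaviours are options (`max_control_sd`, `per_signature_control_sd`).

## Regression, eigengenes, ANOVA

Relating the IGS to cell-type scores uses OLS with the slope's two-sided
p-value and $r^2$; transcripts shared between the IFN signature and the
cell-type signature are removed first (`remove_overlap()`) so common genes
cannot manufacture the association. Module eigengenes are the first
principal component of the per-gene standardized module submatrix,
sign-oriented so the mean correlation with module genes is positive, with
Pearson correlations against the binary disease indicator and SLEDAI.
Three-or-more group comparisons use one-way ANOVA with Tukey HSD
(Tukey–Kramer for unequal n); two-group inputs are directed to
`welch_t()`.

## The synthetic cohort generator

The generator exists so that every stage is testable end-to-end offline; it
emulates the statistical structure the analysis assumes, not microarray
physics. Baseline expression is $x_{gj} = \mu_g + b_{g,\mathrm{subj}} +
\varepsilon_{gj}$ with $\mu_g \sim N(7, 1.5^2)$ (log2 units), a
between-subject random effect $b \sim N(0, 0.3^2)$ shared across a
patient's timepoints, and residual noise $\varepsilon \sim N(0, 0.5^2)$.
The subject effect matters: without it, a stable patient's within-
trajectory variability would equal the between-control variability and the
max-control-SD rule could not separate stable from changing patients even
in principle.

The signature universe is laid out deterministically with the published
topology: a type I core (default 200 genes, of which 54 also induced by
the type II interferon), unique blocks per subtype (default 50), five
cell-type/process modules (monocyte, T, B, plasma cell, cell cycle;
default 30 each), remaining genes background. IGS-positive patients
(default fraction 0.7, between the observed active/inactive positivity
rates) receive additive log2 induction of the **dominant** (largest
$\delta$) subtype on that subtype's signature genes; defaults
$\delta_{\mathrm{IFNB1}} = 1.5$, $\delta_{\mathrm{IFNA2}} =
\delta_{\mathrm{IFNW1}} = 0.75$ describe an IFNB1-dominant cohort.
Induction is monocyte-weighted: a deterministic ~3:1 majority of signature
genes is monocyte-biased and scales with the sample's monocyte fraction
(relative to the 0.2 reference), the lymphocyte-biased minority is
attenuated ×0.33 — encoding, as a design input, the observation that
monocytes carry the IGS. Cell fractions are drawn on the simplex
(gamma-normalized, monocyte mean 0.2); cell-type module genes shift with
$2\log_2(f/f_{\mathrm{ref}})$. A latent activity $a \sim N(0,1)$ drives
plasma-cell and cell-cycle modules in *every* sample (0.5·max(a,0)) and is
recorded as SLEDAI = max(0, round(5 + 3a)) for patients only — so SLEDAI
correlates with those modules but not with the IGS, and at $\delta = 0$
patients and controls are exchangeable (the basis of the calibration
tests). Time courses ramp each patient's induction multiplier linearly
(gain 0→1, loss 1→0, stable flat), and the truth table records the planted
category. All randomness flows from one integer seed; generation is
byte-reproducible.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: probe-level artefacts, batch and platform
effects, heavy-tailed or correlated gene noise, realistic LD between
signature genes, missing clinical covariates, dropout, or the composition
of real PBMC beyond three cell classes. Recovery rates on this generator
are statements about the pipeline's correctness under its own assumptions,
not about clinical sensitivity.

## Problem sizes and test design

The test suite runs cohorts of 300 genes (50-gene core, 13 shared, 20-gene
unique blocks, 15-gene modules) with 10–30 samples per group: large enough
that every structural feature exists, small enough that the full suite —
including 500-cohort calibration and 100-run recovery sweeps — completes in
about two minutes. Oracle-equivalence tests compare the enrichment walk
against an independently coded brute-force implementation on random
20-gene × 8-sample matrices in both score modes, and the summary statistics
(BH, Welch, Hedges, eigengene) against textbook-formula oracles at
tolerance $10^{-10}$. The published 200/146+54 Venn counts are checked on a
synthetic universe constructed at those sizes, since the original
supplementary gene lists are an external download.

## Known limitations

- The enrichment score saturates near ±its bound under strong induction;
  comparisons of very strong signatures compress.
- Welch/Hedges statistics treat per-sample scores as independent; the
  kernel ECDF couples samples weakly, which is visible only at very small
  n.
- The moderated-t prior assumes a single variance population; no robust
  down-weighting of variance outliers is implemented.
- `read_expression()` collapses duplicate gene rows by keeping the
  highest-mean row — a convention, not an inference; row identity is
  case-sensitive.
- Value round trips through the TSV writers are exact to within one unit
  in the last place of a double, not bit-exact.
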