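---
title: "Methods: signature-reversal repurposing and co-prescription analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-reversal repurposing and co-prescription analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrev)
```

# Overview

`sigrev` chains two analyses that are usually run separately. The
transcriptomic arm asks whether a candidate drug's expression signature is
the *reverse* of a disease signature: per-study differential profiles are
expressed as signed Z scores, meta-combined across independent studies, and
compared with a library of compound-driven profiles by correlation and
rank. The epidemiological arm asks whether, in a prescription registry,
exposure to the candidate drug class is associated with reduced
prescription of the established therapy, via cohort construction from
ATC-coded dispensing events and logistic regression. A third module
generates synthetic inputs with the statistical structure each stage
assumes, so the whole pipeline is testable end to end.

# Differential Z profiles

For each gene the model is ordinary least squares on normalized log-scale
expression,

$$ y_{ij} = \beta_0 + \beta_1\,\mathrm{group}_j + \gamma^\top c_j +
\varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma_i^2), $$

with `group` an indicator for the test condition and $c_j$ optional
covariates (categorical covariates are one-hot encoded against a
lexicographically first reference level). The contrast coefficient's t
statistic is referred to the exact t distribution with the residual
degrees of freedom, and the two-sided p-value becomes a signed Z score
$z = \mathrm{sign}(t)\,\Phi^{-1}(1 - p/2)$.

**Why plain OLS and not moderated variance.** Shrinking per-gene variances
(empirical Bayes, as limma does) improves power at small $n$, but the
downstream contract here is only a per-gene signed Z on a common scale, and
exact OLS keeps the stage self-contained and directly checkable against the
classical pooled two-sample t (`t.test(var.equal = TRUE)` is the test
oracle). This is a deliberate simplification: with very few samples per
group, individual profiles are noisier than a moderated analysis would be,
which matters less after meta-combination.

Numerical conventions:

* **Z cap.** $|z| \le 8.21$, the Z at $p \approx 2.2 \times 10^{-16}$;
  smaller p-values underflow and would give infinite quantiles.
* **Zero residual variance.** Genes whose residual variance is numerically
  zero (relative to the data's scale) get $z = 0$ and a `flag`, rather than
  being dropped, so gene universes stay aligned across studies.
* **Duplicates.** Duplicate gene symbols are mean-collapsed at load time
  (probe-level duplication); symbol collisions at cross-species
  harmonization keep the entry of maximum $|z|$, preserving the extreme
  responders that drive concordance statistics.
* **Species harmonization.** Rodent-to-human mapping is plain symbol
  upper-casing (`Nr4a1` → `NR4A1`). This is a stand-in for a real ortholog
  map: it is idempotent and covers the common case of one-to-one
  orthologs with case-styled symbols, but silently misses renamed or
  many-to-many orthologs.

# Composite meta-profiles

Per-study Z profiles are combined by Stouffer's rule per gene,
$S_g = \sum_i z_{gi} / \sqrt{n_g}$. Two choices were genuinely open:

* **Per-gene $n$.** When a gene is missing from some studies, we divide by
  the count of studies actually reporting it, not the global study count;
  this keeps $S_g$ approximately standard normal for partially measured
  genes (dividing by the global count would shrink them toward 0).
* **Union vs intersection.** The default keeps the union of genes
  (`min_studies = 1`); setting `min_studies` to the number of inputs gives
  intersection semantics. Both are supported because neither convention is
  canonical for cross-platform series.

Under independent standard-normal inputs $S$ is standard normal; the test
suite checks the sample variance of $S$ at $G = 10{,}000$, $N = 5$ against
[0.94, 1.06].

# Connectivity scoring

Each library compound is correlated (Pearson) with the query over their
shared genes; `n_overlap` is reported so heterogeneous libraries are
auditable, and compounds sharing fewer than `min_overlap` genes (default
50) are an error rather than a silent drop. The per-compound score is the
library-standardized correlation

$$ Z_c = \frac{r_c - \bar r}{\mathrm{sd}_{pop}(r)}, $$

with the *population* standard deviation across the library. The
literature reports "correlation Z scores" without a formula; query-wise
standardization is deterministic and reproduces rank structure, which is
what the repurposing decision uses. A permutation mode
(`method = "permutation"`, default 1,000 shuffles of the query's gene
labels) is provided when per-compound significance, rather than rank, is
wanted. Ranks are assigned on descending Z (`rank_pos`) and ascending Z
(`rank_neg`) with ties broken by compound name, so output is deterministic;
without ties `rank_pos + rank_neg = M + 1`.

Profile–profile correlation estimates use the Fisher transform for the 95%
CI, $\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$, and the t-based
p-value on $n - 2$ df; at $|r| = 1$ the CI is clamped to $\pm 1$ with a
warning and $p = 0$. At least 4 shared genes are required.

Sign concordance takes the `top_k` genes of one profile by $|z|$ among
those present in the other, counts opposite signs, and computes the exact
two-sided binomial p at success probability 1/2 by tail summation, doubling
the smaller tail and capping at 1. A gene with $z = 0$ in either profile
counts as not opposite.

# Registry cohorts and the co-prescription model

`build_cohort()` keeps persons with at least one in-window dispensing whose
ATC code falls under the qualifying set (default illustrative: the `N05`
psycholeptic and `N06` psychoanaleptic groups; the real qualifying
medication list is study-specific configuration). Per drug group, the
binary exposure flag is `in-window count >= threshold` (default 1; the
"10 or more prescriptions" sensitivity row uses ≥ 10). Shipped group
defaults: lithium `N05AN01`; cardiotonic steroids `C01AA05` (digoxin) and
`C01AA04` (digitoxin).

* **Age** is whole years at the observation-window end,
  `floor(days/365.25)` (configurable to window start or first qualifying
  prescription). The 365.25-day year is used instead of calendar-birthday
  arithmetic so that shifting all dates and the window by a common offset
  leaves the cohort exactly unchanged; the price is an occasional one-year
  difference exactly on anniversaries.
* **Death handling**: persons are retained regardless of death date
  (prescription-ever semantics); `require_alive` optionally drops persons
  who died before the window.
* **Sex** enters models as a male indicator with female the reference
  (lexicographic rule). In sex-stratified sensitivity rows the sex
  covariate is dropped — it is constant there and the design would
  otherwise be rank deficient.

The association model is maximum-likelihood logistic regression fit by
Newton–Raphson (equivalently IRLS), written in full rather than delegated
so the stage is auditable: the score and observed information are
accumulated directly, iteration stops when the largest score component
falls below `tol` (default 1e-8, with a numerically-nil-step fallback)
within `max_iter` (default 25), and the deviance trace is kept so monotone
convergence is testable. Standard errors are Wald, from the inverse
observed information, and CIs are symmetric `estimate ± 1.96·SE`, matching
the conventional presentation (profile-likelihood intervals are out of
scope). Any coefficient beyond ±15 on the log-odds scale flags the fit as
separated and non-converged. On a dataset that collapses to a 2×2 table,
the exposure-only fit equals the closed form `ln(ad/bc)` with Woolf SE
`sqrt(1/a+1/b+1/c+1/d)` — both identities are asserted in the tests, and
`stats::glm` serves as an independent oracle for the general case. The
crude 2×2 analysis offers a Haldane–Anscombe continuity option (0.5 added
to every cell when any cell is zero); without it a zero cell is an error.

The sensitivity grid re-derives the cohort and refits per row: full
cohort, positivity threshold ≥ 10, age > 40, age > 70, men, women. Failed
rows (e.g. an empty stratum) are reported with NA statistics and the grid
continues.

# What the generators emulate — and what they do not

**Expression** (`simulate_expression_studies`): a sparse ±1 signature on a
chosen fraction of genes; per-study effect multipliers uniform in
[0.75, 1.25]; i.i.d. Gaussian noise on the log scale (matching the OLS
assumptions); baseline means N(7, 1). Not emulated: probe-level structure,
batch effects, correlated genes, heavy tails, platform differences. A
passing calibration test therefore shows the statistics behave as designed
under their own assumptions — not that real microarray series are this
clean.

**Compound libraries** (`simulate_drug_library`): planted profiles are
$z = \rho \tilde s + \sqrt{1-\rho^2}\,\varepsilon$ with $\tilde s$ the
standardized target signature, so their expected correlation with the
signature is $\rho$; the rest are pure noise. Real drug libraries have
correlated compounds (shared mechanisms), cell-line specificity and
heterogeneous gene coverage; `n_overlap` handling is exercised by tests,
but mechanism-level structure is not simulated.

**Registries** (`simulate_registry`): ages truncated-normal(50, 18) on
[18, 95]; exposure prevalence logit-linear in age (intercept −7, slope
0.06/yr, i.e. cardiotonic-like use concentrated in the elderly — this
builds in confounding so crude and adjusted estimates differ measurably);
outcome from the logistic model with defaults β₀ = −5.75 (≈1% baseline
outcome prevalence), β_age = 0.02/yr, β_sex = 0.3, β_exposure = −1.15;
each positive status materialized as 1 + Poisson(λ−1) dated events with
λ = 10, chosen so that a ≥10-prescription positivity rule retains roughly
half the positives, mirroring the attenuation a registry analysis sees
when hardening the exposure definition. Dates are uniform in the window
with no within-person temporal structure, there is no prescription
sequencing, no death process, and ATC codes come from a small illustrative
pool — so the generator supports association analyses, not time-to-event
or causal-ordering questions.

# Problem sizes and numerical checks

The test-suite and acceptance-script simulation scales are the package's
own choices, sized so the statistical checks are sharp: differential
calibration at G = 5,000 genes (binomial tolerance [0.03, 0.07] on the
null p < 0.05 fraction), Stouffer variance at G = 10,000 and N = 5,
connectivity retrieval at M = 100 compounds × G = 1,000 genes × 100 seeded
runs (5 compounds planted at ρ = 0.5 must all rank in the top 10 in ≥ 95
runs), registry recovery at N = 200,000 persons × 20 seeds (mean adjusted
estimate within ±0.15 of the injected −1.15; 95% Wald CI covering truth in
≥ 17/20), and Fisher-CI coverage at ρ = −0.24, n = 300, 1,000 replicates
(93–97%). Rank structure is verified against a full-sort brute force for
libraries up to M = 20, and small-sample worked examples (the pooled
two-sample t on {1,2,3} vs {4,5,6}; the bundled 30-gene reversal table
giving 24/30 at exact binomial p ≈ 1.43 × 10⁻³) are frozen in the tests.

# Known limitations

* Symbol upper-casing is not an ortholog map; use a curated mapping for
  real cross-species work.
* OLS profiles are noisier than moderated-variance profiles at very small
  group sizes.
* The library-standardized Z is relative to the queried library: adding or
  removing compounds shifts every Z (ranks are the stable output; the
  permutation mode gives absolute per-compound calibration).
* Registry analysis is purely cross-sectional within the window: no
  prescription ordering, dosage, or survival handling, and the logistic
  MLE carries the usual small-cell bias when the joint-exposure cell is
  rare.
* The binomial reversal test treats top-gene selection as fixed; it does
  not account for the selection step's own noise.
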