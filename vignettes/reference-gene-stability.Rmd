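---
title: "Reference-gene stability: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

# The problem

RT-qPCR quantifies a target transcript relative to reference genes assumed to
be constitutively expressed. A reference gene that drifts with the condition
under study silently biases every downstream fold-change. Validation studies
therefore measure a panel of candidates (here, panels like 12 genes across 36
samples with 3 technical replicates) and score their expression stability
with several algorithms whose assumptions differ; a comprehensive rank
aggregation then reconciles them. This vignette documents the models as
implemented, the conventions chosen where the literature is ambiguous, and
what the bundled simulator does and does not emulate.

# Data model

The central object is a genes × samples matrix of quantification cycles
(Cq). Cq is log-scale by construction — one cycle corresponds to one
multiplication by the amplification factor *A* — which motivates two
package-wide conventions:

* **Technical replicates** are collapsed by the arithmetic mean of Cq
  (`average_technical_replicates()`), with no outlier rejection. Averaging
  on the cycle scale is the standard treatment of within-plate replication.
* **Missing wells** are accepted on input (`NA`), reported by
  `validate_cq_matrix()`, and handled by the workflow as complete-case:
  any sample missing a gene is dropped with a message. How no-amplification
  wells should be treated is genuinely underdetermined in validation
  practice; dropping whole samples is the least-surprising policy and is
  always logged so the user can see it happened.
* The **valid Cq range** defaults to (0, 45], a ceiling just above the
  common 40-cycle protocol; it is configurable because instruments differ.

# The four stability algorithms

## geNorm

Cq is first transformed to relative quantities
$Q_{ji} = A_j^{\min_i Cq_{ji} - Cq_{ji}} \in (0, 1]$. The pair variation
$V_{jk} = \mathrm{SD}_i\!\left[\log_2 (Q_{ji}/Q_{ki})\right]$ uses the
sample SD (n−1 denominator), as do all SDs in the package. Stability
$M_j$ is the mean of $V_{jk}$ over surviving partners; iterative exclusion
removes the max-M gene until two remain.

Three conventions matter:

* **Reported M is the value at the exclusion step**, not the first-round M.
  This is what produces the characteristic *tied rank-1 pair*: the last two
  genes each have M equal to the variation of their own pair, an identity
  that holds for any input and is asserted as a structural test.
* **Amplification factors default to 2** (100% efficiency). The classical
  tool default; per-gene measured factors from standard curves can be
  supplied, and with all factors 2 the pair variation coincides exactly
  with the comparative ΔCt pair SD (tested to 1e−12).
* **Ties on max M during exclusion** remove the later gene in input order —
  an arbitrary but deterministic rule.

## Pairwise variation and the optimal gene number

$NF_n$ is the per-sample geometric mean of Q over the top-n genes of the
geNorm ranking (final pair ordered by input order), and
$V_{n,n+1} = \mathrm{SD}_i[\log_2(NF_n/NF_{n+1})]$ for $n = 2 \dots G-1$.
`recommended_n` is the smallest n with V below the threshold (default 0.15,
the conventional cutoff). When *every* V is already below the threshold the
recommendation is the minimum, n = 2, and the full profile is returned: in
that regime practitioners read the *trend* of the profile, a judgement that
is deliberately not automated because it has no agreed formalization.

## Model-based (NormFinder-style) stability

The model is $Cq_{ji} = b_j + L_i + \varepsilon_{ji}$ with loading offsets
$L_i$ shared by all genes of a sample and gene noise
$\varepsilon_{ji} \sim N(0, \sigma_j^2)$. Centering each sample over the
$k$ genes removes $L_i$ but correlates the residuals; the per-gene variance
$s_j^2$ of centered values satisfies
$E[s_j^2] = \sigma_j^2 (1 - 2/k) + \tfrac{1}{k^2}\sum_g \sigma_g^2$, which
inverts to the unbiased moment estimator
$\hat\sigma_j^2 = \max\!\big(0, (s_j^2 - \bar m/(k-1)) \cdot k/(k-2)\big)$
with $\bar m$ the mean of the $s^2$. The clamp at zero is standard moment
practice and makes 0 the best achievable stability. The $k/(k-2)$ factor is
why at least three genes are required.

With declared groups, gene-by-group deviations $d_{gj}$ (group means of
centered values, centered again across groups per gene) are scored on top of
the within-group noise. Their true variance $\gamma^2$ is estimated by
moments — observed variance of $d$ minus its average sampling noise, clamped
at 0 — and each deviation is shrunk by
$\gamma^2/(\gamma^2 + \sigma^2_{gj}/n_g)$ (empirical Bayes; when
$\gamma^2 = 0$ all deviations shrink fully to zero, the 0/0 case being
defined as 0). Stability is the mean over groups of
$|\tilde d_{gj}| + \sqrt{\sigma^2_{gj}/n_g}$. This is a method-of-moments
operationalization of the model-based approach defined by this package;
numeric agreement with any historical implementation is not claimed, but
parameter recovery is verified by simulation (below), as are the loading-
and primer-offset invariances. Ungrouped mode is the default since stability
panels are often analyzed without a declared design.

## BestKeeper

Pure descriptives of raw Cq: arithmetic and geometric means, range, spread
and CV, plus the Pearson correlation (with two-sided p-value) of each gene
against the BestKeeper index — the per-sample geometric mean Cq over all
candidates. The ranking statistic is the spread, for which two estimators
are offered because the original tool's convention is ambiguous:
`sample_sd` (default; SD about the arithmetic mean) and `mad_geo` (mean
absolute deviation about the geometric mean). The choice is recorded in the
result object. SD above one cycle is flagged "inconsistent", an advisory
heuristic only. BestKeeper intentionally operates on *raw* Cq, so unlike the
other methods it is sensitive to loading differences — a documented and
tested property, not a defect.

## Comparative ΔCt

Pair SDs of raw Cq differences, averaged per gene over its $G-1$ partners.
Equivalent to a single (non-iterated) geNorm round at factor 2; kept as its
own method because published tables report it separately.

# Rank aggregation

Each method's stabilities are converted to **competition ranks** (ties share
the minimum rank; the next rank skips by the tie size). The aggregate score
is the geometric mean of a gene's ranks — raw ranks, with no re-ranking
between steps: applied to the published seven-condition rank tables shipped
in `inst/extdata/`, this rule reproduces all seven published overall
orderings exactly, which is the strongest available evidence for it.
Score ties are broken by (i) arithmetic mean rank, then (ii) the
model-based method's rank when present, then (iii) input order. The chain
was chosen because it resolves both ties occurring in those published
tables in the printed direction (one separable by mean rank; one where mean
ranks also tie and the model-based ranks decide); every invoked tie-break
is logged in the result. The geometric mean is bounded by the min and max
input rank (AM–GM), which is asserted as a property test.

# Standard curves

Efficiency comes from OLS of Cq on log10 template amount over a dilution
series (at least three distinct concentrations; the classical design is six
10-fold dilutions spanning 1e4–1e9 copies/µL):
$E = (10^{-1/\text{slope}} - 1) \times 100$, $A = 1 + E/100$. R² is the
squared Pearson correlation, identical to the determination coefficient of
the simple regression. The x-axis is strictly log10 of copy number; natural
log is not accepted, which avoids a silent 2.3-fold unit error. A positive
slope warns (anti-correlated curve) but still returns a value; slope 0 and
collinearity-free degenerate designs are errors.

# Candidate pre-selection from RNA-seq

The screening filter applied before any wet-lab work: remove genes with
TPM < 5 in at least 2 stages; variance-stabilize (default `log2(tpm + 1)`,
monotone and variance-flattening on the TPM scale; an Anscombe-type
`2*sqrt(tpm + 3/8)` variant is provided); compute each gene's SD across
stages; within each homolog family choose the lowest-SD gene among those
with TPM > 1000 in at least 8 of the stages, reporting the reason for every
kept and rejected homolog. Because the transform is a design choice rather
than a canonical definition, SD rankings under a different VST may differ
slightly; the filter thresholds themselves are applied verbatim. Filtering
reads raw TPM only, so it commutes with the transform (tested).

# The synthetic-data generator

`simulate_cq_experiment()` draws from
$Cq_{jir} = B_j + L_i + \Delta_{g(i),j} + \varepsilon_{ji} + \tau_{jir}$ —
exactly the additive log-scale model the stability methods assume, plus a
technical-replicate layer. Defaults describe a realistic validation panel:
12 genes × 36 samples × 3 replicates; baselines evenly spread over 12–32
cycles (abundant rRNA-like to scarce transcription-factor-like templates);
loading SD 1 cycle (a typical spread of RNA input across independently
prepared samples); per-gene noise SDs evenly spread over 0.05–1.2 cycles so
the panel contains clearly stable and clearly unstable candidates; technical
SD 0.1 cycles (within-plate pipetting). Group effects are zero unless
requested. A fixed seed gives byte-identical output.

What it emulates well: loading artifacts, heterogeneous gene stability,
condition-specific shifts, replicate noise, dilution-series curves (via
`simulate_standard_curve()`), and TPM matrices with planted filter
violations (`simulate_tpm_matrix()`). What it does not emulate: PCR
kinetics and efficiency drift, inhibition, non-Gaussian dropout of
high-Cq wells, and correlated biological noise between genes. Passing
recovery tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to every real-world artifact.

# Verification strategy and problem sizes

Every statistic has an independent brute-force oracle (naive loops from the
definitions) checked to 1e−10 over batches of random matrices, plus frozen
hand-computed values on a 3-gene × 4-sample toy matrix. Cross-method
identities (geNorm pair variation = ΔCt pair SD at factor 2; ΔCt stability
= first-round geNorm M) are tested at 1e−12, as are the loading- and
offset-invariances. Simulation checks use 100 seeded replicates: ungrouped
noise recovery at n = 200 samples (mean estimate within 10% for σ ≥ 0.2 —
below that the zero-clamp biases the moment estimator upward, which is why
small σ are excluded); top-2 placement of the least-noisy gene at the
default 36-sample design; and expulsion of a gene given a +1.5-cycle group
effect from the grouped top 3. The pairwise-variation decision rule is
exercised on a hand-constructed 6-gene × 8-sample matrix built from
orthogonal ±1 (Walsh) patterns whose profile provably first dips below 0.15
at n = 4. These sizes keep the full suite under half a minute while leaving
each check statistically sharp.

# Known limitations

* The model-based scores are this package's moment formulation; other
  implementations of the same idea may differ numerically (orderings agree
  under the model).
* The geNorm "trend" reading of an all-below-threshold V profile is not
  automated.
* BestKeeper is reduced to descriptives plus index correlation; the original
  tool's regression diagnostics are out of scope.
* Candidate pre-selection depends on the chosen VST; only the thresholds are
  canonical.
* Aggregation requires at least two methods; with one method the workflow
  warns and skips it (a geometric mean of one rank is vacuous).
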