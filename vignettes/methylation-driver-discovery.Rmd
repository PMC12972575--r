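---
title: "Discovering methylation-silenced drivers of drug resistance: methods and design"
author: "methDriveR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering methylation-silenced drivers of drug resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methDriveR)
```

## The problem

In EGFR-mutant lung adenocarcinoma, a fraction of patients are resistant to
third-generation EGFR inhibitors such as osimertinib from the outset
(primary resistance). One candidate mechanism is epigenetic: promoter
hypermethylation silences a gene whose product sensitizes tumor cells to the
drug, so hypermethylation, low expression, and high IC50 travel together.
Public tumor cohorts carry expression and methylation profiles but no
measured drug response, so the search has to proceed in three stages:

1. **Impute** each patient's log2(IC50) from expression, using a ridge model
   trained on a cell-line panel with measured drug response.
2. **Screen** every gene twice against the imputed response — its expression
   (Spearman correlation plus an empirical-Bayes moderated regression
   statistic) and its promoter methylation (same pair of statistics on
   gene-level beta values) — and intersect under the sign constraint
   *expression negatively, methylation positively correlated with IC50*.
3. **Rank** the surviving candidates by stability selection: LASSO
   regression of the imputed response on candidate expression, refit on
   bootstrap resamples of the patients, keeping each gene's selection
   frequency. Genes above a 50% frequency are the stable set; the
   top-frequency gene is the headline candidate.

methDriveR implements all three stages, the validation-assay calculators
(MSP relative methylation, delta-delta-Ct, CCK-8 viability, 4PL IC50, the
two-sample t-test), and a synthetic-cohort generator with planted drivers
that serves as the package's acceptance surface.

## The imputation model

Ridge regression is the documented core of expression-based drug-response
imputation tools. With standardized training columns $Z$ and centered
response $y$, the weights solve

$$\hat\beta = \arg\min_\beta \; \lVert y - Z\beta \rVert^2 + \lambda \lVert \beta \rVert^2,$$

computed exactly through the SVD (valid for any $n$, $p$ and $\lambda > 0$).
The penalty is tuned by 10-fold cross-validation over 21 log-spaced points
in $10^{-3}$–$10^3$ (ties toward the smaller penalty), with
standardization re-estimated inside each training fold. Before training,
genes below the 0.2 variance quantile are dropped, and patient columns are
quantile-normalized onto the training reference distribution (the mean of
the sorted training columns) so that monotone platform shifts cancel.
Power-transform homogenization used by some imputation tools is not
reproduced; quantile normalization is the documented simplification. The
output unit is log2(µmol/L) everywhere downstream.

## The screens

**Spearman screen.** Per feature, the correlation is the Pearson
correlation of mid-ranks (the standard tie convention, deterministic), with
a p-value from the t approximation on $n-2$ degrees of freedom and
Benjamini–Hochberg q-values across all testable features. Constant
features have no defined rank correlation; they are flagged and excluded
from the BH denominator rather than silently zeroed.

**Moderated screen.** Per feature, a simple linear regression of the
feature on the imputed response. Residual variances $s_g^2$ (each with
$d = n-2$ degrees of freedom) are shrunk toward a common prior by
empirical Bayes: the prior degrees of freedom $d_0$ and prior variance
$s_0^2$ are estimated by moment-matching the log residual variances
(digamma/trigamma moment equations, solved by Newton inversion of the
trigamma function), and the moderated t is

$$\tilde t_g = \frac{\hat b_g}{\sqrt{\tilde s_g^2 / S_{xx}}}, \qquad
\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

with p-values on $d_0 + d$ degrees of freedom. Setting the prior degrees
of freedom to zero recovers the classical per-feature t exactly (tested to
1e-9), and the estimator agrees with an independent empirical-Bayes
implementation on simulated data (tested).

**Combination.** A feature is "significant" when both raw p-values fall
below alpha (default 0.05) in the required direction. The two statistics
are combined by intersection, and no multiplicity correction gates the
primary filter; q-values are reported alongside. Both choices are
configurable. The rationale: the intersection of two related but
differently-powered tests is a conservative, simple gate, and the final
arbiter of a candidate is the stability selection, not the screen.

**Methylation aggregation.** Probes are aggregated to gene level over the
promoter region classes TSS1500, TSS200, 5'UTR and 1stExon by default —
promoter methylation is the silencing mechanism under study, and the
validated locus class in this setting is TSS1500. The default combiner is
the arithmetic mean across qualifying probes; a `max_abs_corr` option picks
the single probe most correlated with the response when a probe-level view
is wanted. Genes with no qualifying probe are dropped with a message.
Screening gene-level aggregates first (rather than per-probe) matches how
candidate counts are reported in this literature and keeps the two omics
keyed by the same identifier.

## Stability selection

The LASSO is fit by cyclic coordinate descent with soft thresholding on
internally standardized columns, minimizing
$\frac{1}{2n}\mathrm{RSS} + \lambda \sum_j |\beta_j|$; convergence is
declared when the largest coefficient change in a sweep drops below 1e-7
(cap 1e4 sweeps), and a debug mode asserts the objective never increases.
The penalty grid descends from $\lambda_{\max}$ (the smallest penalty with
an all-zero solution) to $\lambda_{\max}/1000$ in 100 log-spaced steps with
warm starts; cross-validation ties break toward the larger (sparser)
penalty.

Bootstrap stability selection resamples patients with replacement B times
and records, per gene, the fraction of resamples with a nonzero
coefficient. Under the default `fixed_full_data` policy the penalty is
tuned once on the full data and reused in every resample; `retune_each`
re-tunes inside every resample and is retained for fidelity experiments.
The fixed policy is the default because re-running a 100-point
cross-validation inside every one of thousands of resamples buys little
beyond desk cost at this problem size. Resamples with fewer than three
distinct patients are redrawn and counted. The stable set is the genes
with frequency strictly above 0.5, ranked by frequency with ties broken by
gene id so the ranking is reproducible; a tie at the maximum frequency
counts all tied genes as rank 1.

Model fit is summarized by the Pearson correlation r between predicted and
actual (imputed) log2(IC50) and its square. The coefficient of
determination is *defined* as $r^2$ here, so the pair is internally
consistent by construction.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes —
not any real biology. All distributional choices are stand-ins:

* **Training panel**: log2 expression i.i.d. normal per gene with
  gene-specific mean U(3, 10) and SD U(0.5, 1.5); measured response
  $y = X_{\text{sub}}' w + \varepsilon$. Twenty genes carry nonzero weight;
  response-relevant genes get baseline SD U(1.0, 1.5) (response signal
  rides on variable genes, which also keeps it clear of the variance
  pre-filter). The panel has 800 cell lines by default — the scale of a
  GDSC-class drug screen. This matters statistically, not just
  cosmetically: with independent genes, ridge estimation noise spreads over
  all ~2000 coordinates, and a few hundred training lines leave the
  imputed response dominated by noise. At n = 800 the imputed-vs-latent
  correlation is ~0.6, enough for the screens to see the planted pattern.
* **Planted drivers** (default one): promoter (TSS1500) beta Uniform(0,1)
  per patient, clipped to [0.01, 0.99]; a co-methylated 5'UTR probe
  (SD 0.15) and an independent Body probe exercise region-aware
  aggregation; expression $= \text{baseline} - 5(\beta - 0.5) + N(0, 0.4)$
  (about a 5 log2-fold silencing range); latent true log2(IC50)
  $= \sum_g w_g x_g + 2\beta_{\text{driver}} + N(0, 0.5)$. The driver's
  response weight is $-U(1.1, 1.4)$, about four times the background
  weights $\pm U(0.1, 0.3)$: the planted driver is the dominant single
  determinant of resistance, mirroring the premise that a core resistance
  gene exists to be found. Non-driver genes carry one TSS1500 probe whose
  beta is independent of everything.
* **Assay generators** invert their quantification formulas exactly at
  zero noise: MSP Ct pairs satisfy
  $Ct_U - Ct_M = \log_2(m/(1-m)) + \text{noise}$, and viability curves are
  4PL evaluations plus Gaussian noise.

What the generator does **not** model: co-expression structure, array
chemistry (M-values, probe-type bias), copy number, mutation-driven
expression effects, or count-level noise (expression is simulated directly
on log2 scale because that is the scale every consumer uses). Passing the
recovery tests therefore shows the pipeline finds the planted pattern under
its own assumptions — it does not certify performance on real cohorts,
where correlated genes make imputation easier but confounding harder.

## Numerical and edge-case choices

* Ridge at $\lambda = 0$ on rank-deficient designs is refused with advice
  rather than silently pseudo-inverted.
* $\lambda_{\max}$ uses the same inner-product summation order as the
  coordinate-descent updates, so "all-zero at $\lambda_{\max}$" holds
  exactly in floating point.
* The MSP rate is computed as $100/(1 + 2^{Ct_M - Ct_U})$, which only
  exponentiates the Ct difference and cannot overflow for any finite pair.
* The 4PL fit runs on log-dose with multi-start over hill
  $\in \{0.5, 1, 2\}$ (each with a nudged second start: a start that
  already fits the data exactly degenerates the initial Jacobian check)
  and best-RSS selection; asymptotes are box-bounded (top [80, 120],
  bottom [-5, 20]) to stabilize sparse curves. Recovery on noisy curves is
  quoted for three replicate wells per dose, the standard CCK-8 plate
  layout.
* A two-sample t-test on two constant, equal groups returns t = 0, p = 1
  by convention, with a message.
* One master seed derives every stage seed (a fixed seed stream indexed by
  stage name), so a single integer reproduces an entire run; reports are
  byte-identical across repeated runs apart from elapsed-time fields.

## Problem sizes used in the tests

The bundled tests run the full pipeline at 2000 genes x 80 patients with
an 800-line panel and B = 500 bootstrap resamples for the recovery checks
(ten master seeds), and a 300-gene / 150-line / 60-patient configuration
for the faster unit-level checks. B = 500 is the package's test-scale
choice for stability selection; the frequency estimates it produces are
Monte-Carlo stable to well under 0.1 (tested), and B is fully
configurable for production runs where a 10,000-resample run is wanted.

## Known limitations

* The screens assume an approximately monotone feature-response relation;
  non-monotone regulation will be missed by design.
* The combined filter's alpha applies to raw p-values; with many truly
  null genes the candidate set carries the corresponding false-positive
  rate into the stability stage, which is why stable-set membership — not
  screen significance — is the package's ranking currency. Under a pure
  null, a gene that survives the screens by chance can still achieve a
  high bootstrap frequency (the resamples reuse the same data that
  selected it); conclusions should rest on the planted-signal contrast,
  not on a single frequency in isolation.
* Imputed IC50 is itself an expression summary: correlating expression
  with an expression-derived response is partly self-referential, and the
  direct methylation term of a real driver is invisible to a panel trained
  without methylation. The synthetic generator reproduces exactly this
  blind spot, which is why recovery operates through the
  expression-mediated path.
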