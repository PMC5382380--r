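---
title: "Methods: gene-environment interaction analysis of methylation arrays"
author: "gxewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-environment interaction analysis of methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxewas)
```

This vignette is the package's account of the statistical methods it
implements, the assumptions behind them, the parameters that matter, and
the choices made where the design was genuinely open. The companion README
shows the pipeline in action; here we explain *why* each stage looks the
way it does.

## The scientific setting

The pipeline targets small epigenome-wide studies of gene-environment
interaction: a binary prenatal exposure crossed with a binary genetic
susceptibility stratum (PON1 192 Q/Q homozygotes versus R-allele
carriers), whole-blood 450K-style beta values for each child, and
continuous cardio-metabolic outcomes. The scientific question is whether
exposure leaves methylation marks *specifically in the susceptible
genotype group*, and whether those marks mediate exposure effects on
outcomes such as serum leptin or body-fat accrual.

Methylation is measured as a beta value (methylated fraction, in (0,1))
and modelled on the M scale, $M = \log_2 \beta/(1-\beta)$, where linear
model residuals are closer to homoscedastic Gaussian. Betas are clamped to
$[10^{-6}, 1-10^{-6}]$ before the logit so the transform is a strictly
monotone bijection; the inverse uses $1/(1+2^{-M})$ to stay finite for
large $|M|$.

## Preprocessing

**Filters.** Pre-normalisation, probes are removed with one reason each,
in priority order: a SNP within 3 bp of the interrogated CpG; failure of
the Greedycut-style pruning; a missing value in any sample.
Post-normalisation, non-CpG probes (classes `ch`/`rs`) and sex-chromosome
probes go. Chromosome labels are normalised case-insensitively with the
alias map {X, chrX, 23} / {Y, chrY, 24}, because manifests in the wild mix
these conventions. Both filters are idempotent, and the report's reason
counts sum to the total removed.

**Greedycut.** The published algorithm is cited in the literature without
parameters, so the package implements a transparent greedy analogue:
iteratively remove the probe *or* sample with the highest fraction of
detection p-values above the threshold (default 0.01) until no entry
fails; ties break probe-before-sample, then by lexical id. This keeps the
procedure exactly reproducible and testable against hand-enumerated toy
matrices.

**Normalisation.** Within-array beta-mixture quantile dilation is
published machinery outside this package's contribution; `normalize_dataset()`
is an explicit pass-through by default, with a rank-based quantile option
(via limma) for users who want sample distributions equalised. The choice
is recorded on the dataset object.

**Batch diagnostics and adjustment.** Scores on the first eight principal
components of the M matrix are tested against candidate batch covariates —
Kruskal–Wallis for factors with more than two levels, two-sided Wilcoxon
rank-sum for two-level factors; single-level covariates are flagged, not
tested. Adjustment is location-only on the M scale: per probe, an OLS fit
of `M ~ protected covariates + batch` estimates the batch offsets, and the
mean-centred batch component is subtracted. Because joint-fit residuals
are orthogonal to both design blocks, batch-level means of the residuals
(after projecting out protected covariates) are *exactly* equalised, and
protected-covariate coefficients refit on adjusted data equal the
joint-fit estimates to machine precision. There is deliberately no
empirical-Bayes shrinkage and no variance step: at these sample sizes a
transparent estimator whose algebraic guarantees can be asserted in tests
was preferred over a reimplementation of shrinkage machinery. The cost is
that per-probe offset estimates carry sampling noise of order
$\sigma/\sqrt{n_b}$, so adjusted values move even when no batch effect
exists; the tests therefore assert the invariants that matter downstream —
planted-DMP recovery changes by under 2 percentage points on batch-free
data — rather than raw value identity. Protected covariates default to
exposure, carrier and sex; which covariates the original batch correction
protected is not recoverable, so this is flagged as a package choice.

## Cell-type composition

Whole blood is a mixture; the package estimates per-sample proportions of
granulocytes, CD4+ and CD8+ T cells, B cells, monocytes and NK cells by
constrained projection onto reference methylomes. Signature probes are
chosen among the `n_variable` (default 100,000) most variable probes in
the mixture data, ranked by how strongly the reference types differ: with
replicated reference columns this is the one-way F statistic; with a
single methylome per type it reduces to the between-type variance. The
top `n_top` (default 500) form one overall ranked list — whether "top 500"
means per type or overall is ambiguous in the source description; overall
was chosen and both knobs are configurable, capped at the probe count so
small simulations degrade gracefully. Proportions solve
$\min_w \lVert \beta_s - Rw \rVert_2^2$ subject to $w \ge 0$, $\sum w = 1$,
via non-negative least squares with a heavily weighted (1000×) appended
equality row, then renormalisation; that matches the classical constrained
projection to numerical tolerance without a QP dependency. A rank-deficient
reference (e.g. two collinear cell types) is a hard error naming the
offending pair. Estimated proportions are checked against groups by
one-way ANOVA and against outcomes by simple regression; they are *not*
used as model covariates downstream, mirroring the source design where
composition showed no group association.

## DMP detection

Per probe, two OLS fits on M values, both sex-adjusted:

* **Model A** `M ~ exposure + carrier + exposure:carrier + sex`. The
  criterion is p(interaction) ≤ 0.1 *and* p(exposure in carriers) ≤ 0.001,
  where the latter is the t-test of the linear combination
  $\beta_{exposure} + \beta_{interaction}$ using the full-model residual
  variance. Using the full model keeps all 48 samples' variance
  information; the alternative — a stratified `M ~ exposure + sex` fit on
  carriers only — is available behind `stratified = TRUE`, and the two
  agree within ~10% relative on well-behaved probes (they differ in
  residual degrees of freedom, so exact agreement is not expected and not
  asserted).
* **Model B** `M ~ exposure + carrier + sex`, with p(exposure) ≤ 0.001 and
  p(genotype) ≤ 0.1.

Both calls additionally require the **extreme-group filter**: the
exposed-carrier cell's mean must be strictly the maximum (hyper) or
strictly the minimum (hypo) of the four design cells. Ties fail the filter
(the "highest or lowest" reading taken strictly). Group means for this
filter are computed on the beta scale — the interpretable methylation
fraction — while the fits run on M; the source does not state which scale
its filter used, and beta was chosen as the scale on which "mean
methylation level" is usually reported. Thresholds are raw p-values by
design (no multiplicity correction at the DMP stage); BH or Bonferroni can
be applied downstream by the user. Zero-variance probes are flagged
`invariant_probe` and excluded; carrier coding pools QR with RR.

## DMR calling

The region caller is a deliberately simplified kernel smoother in the
spirit of limma-based region callers, with the same statistical skeleton
but every step explicit:

1. per-probe pooled-variance two-sample t on M values, exposed carriers
   versus one of the other three cells (all three contrasts are scanned;
   a region significant in any contrast qualifies, reported with
   per-contrast provenance);
2. Gaussian-kernel smoothing of $t^2$ along each chromosome — bandwidth
   $\sigma = \lambda/C$ with $\lambda = 1000$ bp, $C = 2$ (standard
   conventions for this family of callers; configurable), kernel truncated
   at $\lambda$;
3. p-values from a scaled $\chi^2$ whose first two moments match the
   weighted mean of squared t variables — the exact $t_\nu^2$ moments
   ($\mathbb{E} = \nu/(\nu-2)$, matching variance) are used rather than
   the $\chi^2_1$ approximation, which keeps the null calibrated at the
   modest degrees of freedom (≈ 21–23) these designs give;
4. genome-wide Benjamini–Hochberg adjustment per contrast;
5. grouping of consecutive significant probes (P_adj < 0.05, strict) at
   most $\lambda$ apart, keeping clusters with ≥ 2 CpGs, region
   significance = minimum member P_adj;
6. the extreme-group direction filter on region-mean betas, consistent
   with the DMP module.

An isolated probe's smoothed score is its own $t^2$; a constant $t^2$
across a dense window is returned unchanged. Unsorted positions are an
error rather than silently re-sorted. BED export converts the 1-based
inclusive intervals to 0-based half-open, with score
$-10\log_{10} P_{adj}$ capped at 1000.

Because smoothing spreads evidence to neighbours within $\lambda$, called
regions extend one to two probes beyond a planted region's edge; at the
default probe spacing (~500 bp) recovered intervals still overlap planted
8-probe regions with Jaccard well above 0.6, which is what the recovery
tests assert.

## Integration and enrichment

A DMP overlaps a DMR when its position lies in the region's closed
interval on the same chromosome; the overlap percentage is reported to one
decimal. The high-confidence gene list is the unique non-empty gene
symbols of overlapping DMPs, splitting multi-gene annotations on `;` —
whether such lists should also include DMR-spanned genes is not fully
determined by the source, so DMP-based was chosen and the DMR genes remain
available on the region table.

All enrichment uses the two-sided Fisher exact test with the classical
convention (sum of all tables with probability ≤ the observed table's),
which is asserted against an exhaustive hypergeometric tail-sum oracle in
the tests. The 2×2 table contrasts significant DMPs against the *rest of
the analysed background*; the background is the filtered probe set, not
the full array, since that is the measured universe. A zero count in the
DMP-in-category cell reports OR = 0 with a `zero_cell` flag rather than
NaN. Genomic-annotation enrichment is unadjusted by default (matching the
p < 0.05 convention for such figures); TFBS enrichment applies Bonferroni
across the number of TFBS tested; gene-set enrichment ranks by
$-\log_{10} p$. Disease mapping keeps associations with score strictly
above 0.1.

## Mediation

The Baron–Kenny causal-steps screen fits four OLS models per (mark,
outcome) pair — outcome~exposure, mark~exposure, outcome~mark,
outcome~exposure+mark — each with p < 0.05 as the per-model criterion.
Leptin is ln-transformed once, upstream, with a hard error on
non-positive values; leptin and body-fat models adjust for sex, BMI-Z
outcomes do not (Z scores are already sex-standardised). Mediation is
*partial* when models 1–3 pass, the mark stays significant in model 4,
and the model-4 exposure coefficient is smaller in magnitude than in
model 1; it is *full* when additionally the model-4 exposure effect is
not significant at the same level — the operationalisation of "drops to
zero", since no test for exact nullity exists. The screen runs on
R-allele-carrier samples by default (the gene-environment framing of the
question); `scope = "all"` uses everyone. Candidates are restricted to the
DMP ∩ DMR overlap set; marks outside it are never tested.

The indirect effect ACME = a·b (model-2 exposure coefficient × model-4
mark coefficient) is bootstrapped by nonparametric case resampling: both
models are refit per resample, the 95% interval is the percentile
interval, and the two-sided p is $2\min(\hat F(0), 1-\hat F(0))$ floored
at $2/n_{boot}$. Resamples that lose an exposure level are redrawn (capped
at 100 retries). This a·b bootstrap is a documented stand-in for the
quasi-Bayesian machinery of dedicated mediation packages; under the
double-null (a = b = 0) the percentile interval is conservative —
empirical coverage of zero runs ≈ 99% rather than 95% — which is the
well-known behaviour of product-of-coefficients intervals and is the
direction of error one wants in a screen.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions so the whole chain is
testable without any external download. What it plants, and why:

* **Design**: group sizes 11/13/12/12 (unexposed-QQ, exposed-QQ,
  unexposed-carrier, exposed-carrier), n = 48, balanced sex within group,
  ages 6–11.
* **Baselines**: per-probe means from a bimodal beta mixture (45%
  low-methylated, 45% high, 10% intermediate), clamped to [0.03, 0.97],
  reproducing the boundary-heavy histogram of real arrays. Sample values
  are Beta(mφ, (1−m)φ) draws with precision φ = `noise_dispersion` = 50,
  i.e. a beta s.d. of ≈ 0.06–0.07 at mid-range — typical of replicate
  variability on these arrays. The source reports no per-group variances,
  so φ is a calibration choice, made once.
* **Cell mixture**: six reference methylomes, 600 signature probes per
  type with offsets 0.35–0.55 (every type has ≥ 500 probes discriminating
  by ≥ 0.3); samples are convex combinations with Dirichlet(18, 3×5)
  weights — granulocyte-dominant with an inter-individual granulocyte
  s.d. of ≈ 0.085, in the range observed for children's whole blood. A
  markedly more diffuse composition would make chance group imbalances in
  composition masquerade as methylation signal, which real studies handle
  by checking composition–group associations (as the pipeline does).
* **Planted DMPs/DMRs**: beta-scale shifts (default Δβ = 0.15, random
  sign) applied *only* to the exposed-carrier group, at isolated probes
  (50) and in runs of adjacent probes (five 8-probe regions), with
  mid-range baselines (0.30–0.65) so shifts stay inside (0,1) — shifts
  that would escape the unit interval are rejected with an error.
* **Batch**: round-robin assignment (orthogonal to the design) of 4
  levels with centred M-scale offsets, 0.5 M units per level step; a
  confounded mode assigns batch by exposure to exercise the diagnostic
  error path.
* **cis-SNP cluster**: nine adjacent promoter probes shifted +0.1 beta
  per T allele of a C/T polymorphism (genotype frequencies 0.3/0.5/0.2),
  and enzyme activity generated as
  `28 + 30·carrier − 3·M_promoter + N(0, 2.5)` so the targeted models
  have their documented signals.
* **Mediation**: three marks get `a·exposure` added on the M scale
  (a = 1.2) and feed outcomes with slopes b and direct effects c′ on the
  analysis scales (leptin on the ln scale, back-transformed for storage).
* **Genome layout**: one synthetic chromosome per 10,000 probes, ~2% of
  probes relabelled chrX, 1-based positions spaced 500 bp ± 25%.
* **Determinism**: a single master seed; the caller's RNG state is saved
  and restored, and the same seed is byte-identical.

What the generator does **not** emulate: Infinium I/II chemistry
differences and IDAT-level noise, realistic linkage disequilibrium,
probe-probe correlation beyond planted regions and shared cell
composition, age/sex methylation drift, and genomic annotation realism
(gene/TFBS labels are synthetic). Passing tests therefore demonstrate that
the *algorithms* behave as specified under known truth — calibrated nulls,
recovery of planted signal, exact bookkeeping — not that the pipeline's
thresholds are optimal for any particular real cohort.

For the dedicated mediation validation (`simulate_mediation_data()`), the
residual s.d. of the mark and outcome default to 0.35, giving each planted
unit path a signal-to-noise ratio of ≈ 3 at n = 24 — the
strongly-detectable regime in which the causal-steps classification is
expected to succeed; halving the signal-to-noise ratio drops the full-
classification rate below 90%, which is worth remembering when reading
real-data screens of this size.

## Numerical choices and degenerate inputs

* Logit clamp ε = 1e-6; simplex tolerance 1e-6; probe/sample ids must be
  unique; the manifest must cover every beta row.
* OLS fits share one design matrix across probes and are computed by
  matrix algebra (coefficients, full-model residual variance, contrast
  t-tests) — a rank-deficient design is a hard error, zero-variance
  responses are flagged per probe.
* Greedycut ties: probe before sample, then lexical id.
* Extreme-group ties fail the filter (strict inequalities).
* Zero pooled variance in a DMR contrast gives t = 0, p = 1, flagged.
* Fisher zero cells: OR reported as 0 (or ∞) with a flag; p remains exact.
* Bootstrap resamples with a single exposure level are redrawn, capped.
* Single-level covariates in diagnostics are flagged and skipped;
  singleton batches and batch-design confounding are hard errors naming
  the collision.

## Problem sizes used in the validation

The shipped tests and the acceptance script run at the study's own scale:
20,000 probes × 48 samples for null calibration (one seed for the DMP
tail; 20 seeds for the DMR caller) and DMP recovery; 20 seeds of the
default planted-DMR configuration for region recovery; 48-sample
Dirichlet mixtures for deconvolution; exhaustive Fisher-oracle
enumeration over all 2×2 tables with n ≤ 40 plus a seeded sample of
tables up to n = 200 (the full n ≤ 200 enumeration is ~1.4M tables and
adds nothing but runtime to a comparison whose observed agreement is at
machine precision); 50 seeds for the full-mediation regime and 200
replicates for null ACME coverage. These sizes were chosen so the whole
validation completes in a few minutes on a single core while keeping
every check at its intended statistical resolution.

## Known limitations

* The batch adjustment is location-only; heteroscedastic batch effects
  (variance differences) pass through untouched.
* The DMR caller assumes independent probe noise within the smoothing
  window under the null; shared cell-composition signal induces mild
  positive dependence at signature-dense loci, which BH tolerates but
  does not exploit.
* The mediation screen inherits all causal-steps caveats: no
  sensitivity analysis for unmeasured confounding of the mark-outcome
  path, and single-mediator models only.
* Moderated (empirical-Bayes) variance estimation is deliberately out of
  scope at both the DMP and DMR stages; at n = 48 the raw-variance tests
  are the documented design.
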