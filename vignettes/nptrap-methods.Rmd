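---
title: "Models and methods behind nptrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nptrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nptrap)
```

# The measurement this package models

A 4sU pulse labels RNA synthesized during the labeling window; after
alkylation and reverse transcription, incorporated 4sU reads as a T>C
mismatch against the reference. QuantSeq-style libraries sequence one
3'-anchored fragment per transcript, so per-gene counting reduces to
tallying reads over 3'UTRs: `ReadCount` for all reads, `TcReadCount` for
reads carrying at least one quality-filtered T>C conversion. Splitting the
same lysate into a cytosolic-RNA fraction and a ribosome-IP (TRAP) fraction
yields matched transcriptome and translatome libraries, and the T>C channel
splits each of them into nascent and pre-existing components.

# Labeling kinetics

Each transcript follows first-order birth-death dynamics with synthesis
rate `k_syn` (molecules/h) and degradation rate `k_deg` (1/h). At steady
state the fraction of the pool synthesized during a pulse of length `t` is

```
f = 1 - exp(-k_deg * t)
```

(`nascent_fraction()`). Two regimes are exposed on `sim_design()` because
the source experiments do not determine one:

* `"steady_state"` — each condition sits at its own kinetic steady state.
  Planted log2 effects on `k_syn` are then realized *exactly* in expected
  counts, which is the regime in which parameter-recovery tests
  ("planted log2FC = 2") are well defined. This is the default for
  `simulate_counts()`.
* `"step"` — condition parameters switch at the start of the pulse, and
  abundance relaxes as `A(t) = A_inf + (A_0 - A_inf) exp(-k_deg t)`. This
  is the regime of an acute-stress experiment (stressor and 4sU added
  together) and the only regime in which the detection-sensitivity
  estimator below is consistent: reads gained after an acute induction are
  purely nascent, because the pre-existing pool (`A_0 exp(-k_deg t)`)
  does not depend on the new synthesis rate. The pipeline default config
  uses `"step"`.

An honest consequence, visible in the README example: under `"step"`,
RNA-level regulation is attenuated by turnover within the pulse (a 4-fold
synthesis change moves a slow-turnover pool only slightly in 3 h) while
translation-efficiency changes act immediately, so *exclusive* genes are
recovered essentially perfectly and *forwarded*/*buffered*/*intensified*
recovery drops to roughly one half at the default effect size.

# Conversion chemistry and its noise model

A read from a labeled molecule covering `nU` uridines acquires at least one
T>C with probability

```
detection_sensitivity(p_conv, nU) = 1 - (1 - p_conv)^nU
```

Defaults: `p_conv = 0.024` per uridine (the observed scale of median T>C
conversion rates, 2.3–2.7%) and a background channel in which *every*
substitution type (including background T>C) occurs independently at
`p_err = 0.001` per eligible base (the observed "< 0.2% for any other
conversion" order of magnitude). In `simulate_counts()` the per-read
detection probabilities are therefore

```
nascent:       1 - ((1 - p_conv) (1 - p_err))^nU
pre-existing:  1 - (1 - p_err)^nU
```

and the read-level simulator (`simulate_reads()`) realizes the same model
base by base, which is what makes the counting round trip
(simulate reads -> `tally_gene_counts()` -> tcount) testable against a
closed form.

Counting parameters follow the SLAM-DUNK conventions the quantification
layer reimplements: 12 nt clipped from the 5' end, terminal adenine runs
longer than 4 nt removed as residual poly(A) tail, base quality >= 27 for a
position to count, and one T>C event sufficient to call a T>C read. All are
configurable. Trimming is deliberately one-shot (a `trimmed` flag makes a
second application a no-op), since re-clipping an already clipped read
would remove real sequence.

# Sensitivity estimation and decomposition

Because detection sensitivity `s < 1`, the non-T>C pool contains undetected
nascent reads. The estimator (`estimate_sensitivity()`) exploits acutely
induced genes: after scaling both conditions to a common depth, genes are
ranked by induction ratio (pseudocount 1) and for the top `k` (default 3)

```
s = sum(Tc_treated - Tc_control) / sum(N_treated - N_control)
```

The excess-over-control numerator removes the pre-existing T>C background;
the alternative `Tc_treated / (N_treated - N_control)` form is available as
`formulation = "treated"` since the source description is ambiguous between
the two. Replicates are summed within condition first (the statistic is a
pooled proportion). Corrected proportions are `min(raw / s, 1)`; the
correction provably helps whenever `s < 0.95` and this is asserted on a
grid of `(p_conv, nU)` in the tests.

Practical limits, also visible in the tests: the estimator assumes the
induced genes' gained reads are purely nascent (acute induction), and that
the induction does not reshape library composition (the fixtures use
mid-abundance induced genes for this reason; with few genes and a dominant
induced gene, common-depth scaling distorts the excess).

# Differential expression

Per gene, a negative-binomial GLM with log link, size-factor offsets and a
two-level condition term; the Wald statistic uses the observed Fisher
information. Choices that matter:

* **Size factors** are median-of-ratios over a geometric-mean
  pseudo-reference, rescaled to geometric mean 1; with no everywhere-positive
  gene the reference falls back to positive-entry geometric means (warning).
* **Cross-assay normalization**: T>C and non-T>C matrices are always
  modelled with factors computed from the *total* read counts. The
  acceptance suite demonstrates why: a doubling of the labeled fraction at
  constant totals is fully detected with total-read factors and erased when
  factors are recomputed from the T>C counts themselves.
* **Dispersion** is method-of-moments on normalized counts using
  within-group residual variance, shrunk toward an `a/mu + b` trend fit by
  untrimmed OLS (trimming the right tail of the skewed MoM distribution
  biases the intercept low; at planted dispersion 0.05 the untrimmed fit
  gives a median moderated estimate of 0.049 and null type-I error 0.0495
  at nominal 0.05). The moderation weight is `df / (df + 10)`.
* **No LFC shrinkage** — DEG calling uses raw thresholds
  (`p_adj < 0.05`, `|log2FC| > 1.5`), so shrinkage would change the
  threshold's meaning.
* **Independent filtering**: genes with mean normalized count below 5 are
  excluded before BH.
* **Degenerate genes**: an all-zero condition triggers a 0.5-count ridge
  and a `ridged` flag rather than an infinite estimate.

At desk scale (3 vs 3, dispersion 0.05, mean 500) the analytic SE of a
log2FC is ~0.27, so point recovery is validated as Wald-interval coverage,
not as a fixed error band.

# deltaTE

RNA and TRAP samples are fit jointly per gene with
`condition + assay + condition:assay` and total-read size-factor offsets.
The interaction coefficient is the translation-efficiency change; by
construction `lfc_te = lfc_trap - lfc_rna`. Dispersion is estimated jointly
across the four condition x assay cells — per-assay dispersions would break
the interaction Wald test's calibration. Classification (default
`alpha = 0.05`, `lfc_threshold = 0`, significance-only as in the deltaTE
convention; the DEG pipeline's 1.5 threshold is *not* reused):

* *intensified*: TE and RNA both significant, same sign
* *buffered*: TE and RNA both significant, opposite signs
* *exclusive*: TE significant, RNA not
* *forwarded*: RNA and TRAP significant (same sign), TE not
* *undetermined*: anything else

The same-sign requirement for *forwarded* is configurable
(`require_same_sign_forwarded`), as the convention is not fully specified
in the sources this follows. Samples present in only one assay are
rejected, not imputed.

# Category statistics

`mann_whitney_u()` computes U with midranks; p-values are exact (full
enumeration of the null distribution via the subset-sum recurrence) when
`n_x + n_y <= 16` without ties, otherwise normal with tie-corrected
variance and continuity correction. A numerical fact worth knowing: the
worst-case disagreement between the exact two-sided p and the
continuity-corrected normal approximation over all `8 <= n_x + n_y <= 16`
is 0.0305 (at `n_x = n_y = 4`), concentrated at mid-range p-values; in the
tails, where decisions happen, agreement is far tighter. A claimed 0.01
bound for this range is unattainable for any sample split, and the
acceptance suite documents this with a deliberately failing assertion next
to the attainable one.

ECDF shift tests compare a gene set against *all other* genes (the set is
excluded from the background to avoid self-comparison bias). Sets with
fewer than 5 members in the universe are skipped. ORF-length
stratification bins genes (default: universe quartiles), compares
translatome vs transcriptome proportions per bin, and summarizes the trend
as the Spearman correlation between bin midpoints and median proportion
differences. Over-representation uses the hypergeometric upper tail with
BH across sets; gene sets load from GMT. No annotation databases are
bundled — real pathway sets must be user-supplied.

# What the synthetic world does and does not establish

The generator reproduces the *statistical structure* the analysis assumes:
3'-anchored fixed-length sense reads, NB count noise (default dispersion
0.05), first-order labeling kinetics, per-uridine conversion with a
uniform background error channel, a translatome `loading_lag` on the
nascent fraction (optionally ORF-length-dependent, reproducing the
qualitative length-dependent trend). It does not emulate alignment error,
multimapping, SNPs, UMIs/PCR duplicates, adapter read-through, 3'UTR
annotation error, or inter-gene uridine-content/quality correlations. A
green suite therefore establishes internal correctness and statistical
calibration of the methods — not agreement with any particular deposited
dataset, whose headline gene counts depend on a genome annotation and
sequencing depths outside desk scale.

# Numerical notes

* All generators take explicit integer seeds; per-sample substreams are
  derived by fixed offsets below 2^31, and RNG state is restored after use.
* The NB IRLS clamps the linear predictor to ±30, iterates to `1e-10`, and
  flags non-convergence; log2FCs are invariant to common count rescaling
  only up to the change in the Poisson part of the NB variance (~1e-3
  log2 units at the tested scales).
* tcount TSVs use tabs, '.' decimals, empty fields for NA; manifests store
  paths relative to the output directory so identical seeds give
  byte-identical trees anywhere.
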