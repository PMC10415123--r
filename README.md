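# nptrap

Analysis toolkit for experiments that combine **4sU metabolic RNA labeling
(SLAM-seq/QuantSeq)** with **translating-ribosome affinity purification
(TRAP)** to read out the *nascent* transcriptome and translatome at the same
time — for example, dissecting how ER stress reprograms transcription and
translation within a single 3 h labeling pulse.

During a 4sU pulse, newly made RNA incorporates 4-thiouridine; after
alkylation chemistry and reverse transcription those positions read as
**T>C conversions**, so reads carrying a conversion mark nascent molecules.
Sequencing paired cytosolic-RNA and ribosome-IP (TRAP) libraries then lets
one ask, per gene, whether a stress response is driven by new transcription,
by ribosome loading, or both.

The package provides, in one tested pipeline:

* **Simulation** (`generate_transcriptome`, `assign_regulation`,
  `simulate_counts`, `simulate_reads`) — ground-truth transcript models with
  first-order turnover kinetics (nascent fraction `1 - exp(-k_deg * t)`),
  planted regulation modes, negative-binomial counts and read-level data
  with per-uridine conversion and background-error channels. Everything
  downstream is testable against known truth, with no external data.
* **Conversion counting** (`trim_read`, `count_conversions`,
  `tally_gene_counts`, `conversion_rate_summary`) — a SLAM-DUNK-style
  quantification layer producing per-gene *tcount* tables (`ReadCount`,
  `TcReadCount`, conversion-rate QC), with 5' adapter clipping and residual
  poly(A) removal.
* **Decomposition** (`nascent_proportion`, `estimate_sensitivity`,
  `correct_proportion`, `pre_existing_counts`) — nascent proportions
  `TcReadCount / ReadCount`, a top-induced-gene estimator of the T>C
  detection sensitivity `s` (a read from a labeled molecule covering `nU`
  uridines is detected with probability `1 - (1 - p_conv)^nU`), and
  sensitivity-corrected proportions `min(raw / s, 1)`.
* **Differential expression** (`size_factors_median_of_ratios`,
  `nb_wald_test`, `call_degs`) — per-gene NB GLM with log link and Wald
  tests, moderated method-of-moments dispersions, BH adjustment, and the
  cross-assay normalization rule that matters for labeled fractions: **T>C
  counts are always modelled with size factors computed from total reads**
  (recomputing factors from the T>C counts themselves silently absorbs
  global labeling changes — the package tests this anti-pattern).
* **deltaTE** (`fit_interaction_model`, `classify_regulation`) — joint
  NB GLM over RNA + TRAP samples with a condition x assay interaction;
  `deltaTE` is the interaction (translation-efficiency change) and genes
  are classified as *forwarded*, *exclusive*, *intensified*, *buffered* or
  *undetermined*.
* **Category statistics** (`mann_whitney_u`, `ecdf_shift`,
  `stratify_by_orf_length`, `hypergeometric_ora`) — ECDF shift tests of
  gene sets against the background, nascent-proportion group comparisons,
  ORF-length-stratified trends, and GMT-based over-representation analysis.

## Worked example

```r
library(nptrap)

models <- generate_transcriptome(n_genes = 500, seed = 42)
models <- assign_regulation(models, effect_size_log2 = 2, seed = 43)
design <- sim_design(library_size = 5e5, kinetics = "step", seed = 44)
sim    <- simulate_counts(models, design)

pool <- function(assay, cond) {
  ids <- sim$samples$sample_id[sim$samples$assay == assay &
                               sim$samples$condition == cond]
  sum_tcount(sim$tcount[ids])
}

# detection sensitivity from the most strongly induced genes
sens <- estimate_sensitivity(pool("rna", "control"), pool("rna", "stress"))
#> T>C detection sensitivity estimate: s = 0.4801 (excess formulation)
#> genes used: G00002, G00279, G00469

# the analytic sensitivity of those genes is 0.4287, so the pooled
# estimate lands within ~0.05 on a 4-fold induction at this depth

props <- correct_proportion(nascent_proportion(pool("rna", "control")), sens)
median(props$corrected_proportion, na.rm = TRUE)
#> [1] 0.407   # corrected nascent proportion over a 3 h pulse

cond <- factor(rep(c("control", "stress"), each = 3),
               c("control", "stress"))
ids_r <- sim$samples$sample_id[sim$samples$assay == "rna"]
ids_t <- sim$samples$sample_id[sim$samples$assay == "ptrap"]
rna  <- tcount_matrices(sim$tcount[ids_r], "total")
trap <- tcount_matrices(sim$tcount[ids_t], "total")

de   <- nb_wald_test(rna, cond, size_factors_median_of_ratios(rna))
degs <- call_degs(de, alpha = 0.05, lfc_threshold = 1.5)
#> 11 up, 1 down  (acute induction: RNA pools move only as fast as turnover)

fit <- classify_regulation(
  fit_interaction_model(rna, trap, cond, cond,
                        size_factors_median_of_ratios(rna),
                        size_factors_median_of_ratios(trap)))
table(fit$category)
#>     buffered    exclusive    forwarded  intensified undetermined
#>           23           93           29           28          327
```

Under acute (`"step"`) induction the translational modes are recovered
essentially completely (*exclusive* recall 1.00 against the planted truth)
while RNA-level modes are attenuated by mRNA turnover within the 3 h pulse
(recall ~0.5) — exactly the asymmetry such an experiment produces. Under
`kinetics = "steady_state"` the planted fold changes are realized exactly
and per-mode recall is 0.80–0.98 (see `test-acceptance.R`, criterion 7).

## Command line

```sh
inst/cli/nptrap run      --outdir out --seed 1            # full pipeline
inst/cli/nptrap simulate --outdir out --seed 1
inst/cli/nptrap count    --sam reads.sam --ref utrs.fa --out tcount.tsv
inst/cli/nptrap decompose --control c.tsv --treated t.tsv --out props.tsv
inst/cli/nptrap de       --counts tc.tsv --meta meta.tsv --norm-from total.tsv --out de.tsv
inst/cli/nptrap deltate  --rna rna.tsv --trap trap.tsv --meta meta.tsv --out dt.tsv
inst/cli/nptrap genesets --lfc de.tsv --gmt sets.gmt --out genesets/
```

`nptrap run` writes a deterministic directory tree (`counts/`,
`decomposition/`, `de/`, `deltate/`, `genesets/`, `logs/`) plus a manifest;
the same config and seed reproduce every output byte for byte.

See the methods vignette (`vignettes/nptrap-methods.Rmd`) for the model,
parameter defaults, and the limits of what the synthetic verification
establishes.
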