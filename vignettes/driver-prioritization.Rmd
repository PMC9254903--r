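---
title: "Multi-omics driver-gene prioritization: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics driver-gene prioritization: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicdriver)
library(dplyr)
```

## The scoring model

omicdriver ranks candidate cancer driver genes in a configurable panel
(by default the 37 genes encoding ATP-dependent chromatin remodellers
of the SWI/SNF, ISWI, INO80 and CHD families) by counting, per gene and
per cancer type, how many of five independent evidence conditions hold:

1. **Recurrent focal copy-number alteration** — the gene's G-score in
   the amplification or deletion direction reaches 0.1 with a
   permutation q-value at or below 0.25.
2. **Mutation-caller consensus** — at least 2 of up to 5
   driver-detection algorithms call the gene significantly mutated
   (the m-index).
3. **Recurrent fusion** — the gene participates in fusion events
   observed at least twice.
4. **Differential expression** — the gene is significantly up- or
   down-regulated in tumours against matched normals.
5. **Prognostic association** — expression predicts overall survival
   in either direction at p < 0.1.

The cancer-specific score is the count of satisfied conditions,
$\mathrm{CS} = \sum_{k=1}^{5} X_k$ with $X_k \in \{0, 1\}$, and the
pan-cancer overall score sums CS over the $i$ cancer types analysed,
$\mathrm{PCO} = \sum_{n=1}^{i}\sum_{k=1}^{5} X_k$. Because the five
conditions are binary, PCO decomposes exactly into per-channel
contributions; the package verifies this conservation on every run.

An unevaluable condition (a cancer type without matched normals, a
survival cohort with too few events, a panel with fewer than two caller
columns) scores 0 rather than being dropped from the denominator: the
formula's range stays 0–5 everywhere, and cancers without normals can
reach at most 4. Each flag carries a reason string naming the stage
result it came from.

## Stage models and defaults

### Copy number ("GISTIC-lite" and ingestion)

Real GISTIC 2.0 output can be ingested directly
(`ingest_external_scna()`), in which case its G-scores, q-values and
optional peak membership are honoured and only the threshold rule is
re-applied. For self-contained runs the package computes a simplified
gene-level recurrence score from segmented copy-number profiles:
segments are mapped to genes by length-weighted mean log2 ratio
(no-segment genes are imputed to diploid 0 and counted), and

$$G_\mathrm{amp}(g) = \frac{1}{N}\sum_s \max(0,\; x_{gs} - \theta),
\qquad
G_\mathrm{del}(g) = \frac{1}{N}\sum_s \max(0,\; -x_{gs} - \theta),$$

with amplitude floor $\theta = 0.1$. This blends alteration frequency
and amplitude like GISTIC's marker-level score but at gene resolution;
it does not attempt peak deconvolution, so "located in a peak region"
is approximated by gene-level significance, and the output provenance
records which mode produced each flag. The null distribution permutes
each sample's gene-value vector across genes and pools the resulting
null G-scores across genes and permutations — pooling stabilizes tail
estimates for panels of a few hundred genes — and q-values are
Benjamini–Hochberg over the panel. The default 500 permutations with a
237-gene panel give over 10^5 pooled null draws; tests verify the
Monte-Carlo p against exact enumeration of the pooled marginal on a
small matrix.

### Mutation consensus

Mutation frequency is the number of mutated specimens over total
specimens; silent/synonymous rows are excluded at parse time (the
mapping table is in `read_maf_lite()`), a documented and configurable
choice since driver evidence concerns protein-altering events. The five
external algorithms are consumed as a boolean call matrix and never
re-implemented. When no matrix is supplied, a pseudo-caller ensemble
flags gene $g$ when the one-sided binomial tail
$P(X \ge n_\mathrm{mut} \mid n, \lambda_\mathrm{bg})$ falls below a
caller-specific $\alpha_j$, then flips each call with probability
$\varepsilon_j$ (defaults $\alpha = (0.001, 0.005, 0.01, 0.01, 0.05)$,
$\varepsilon = 0.02$). All pseudo-callers test the same statistic, so
their noise-free calls are nested by $\alpha$ — a deliberate, documented
difference from five genuinely complementary algorithms.

### Fusions

Recurrence is defined pan-cancer: an ordered 5'→3' pair observed at
least twice across all specimens (orientation matters in fusion
biology; an unordered mode exists). The per-cancer scoring condition
defaults to `within_cancer` — at least 2 events of the gene inside that
cancer type — keeping all five CS conditions cancer-specific; the
alternative `pan_cancer_pair` mode (any event in the cancer plus
membership in a pan-cancer-recurrent pair) is a config switch, because
the two readings of "recurrent" cannot both be primary.

### Differential expression

Per-patient differences $d_i = \log_2(\mathrm{FPKM}_{T,i}+1) -
\log_2(\mathrm{FPKM}_{N,i}+1)$ are tested with the Wilcoxon signed-rank
test: zero differences dropped (the classical convention), exact
two-sided p for effective $n \le 25$, tie-corrected normal
approximation with continuity correction above that. The exact null is
computed by dynamic programming over doubled midranks, which stays
exact under tied $|d_i|$ where classical tables do not apply;
`stats::wilcox.test` and a full $2^n$ sign-flip enumeration serve as
independent cross-checks in the test suite. Significance is BH
q < 0.05 within a cancer type with a 1.5-fold median-change floor —
the source analysis names the test but not its threshold, so this
default is declared, recorded in provenance, and configurable
(`de_q`, `fc_min`). Cohorts with fewer than 10 matched pairs (or none)
report every gene unflagged with the reason recorded.

The auxiliary dosage analysis first applies the broad-expression filter
(FPKM ≥ 1 in ≥ 90% of tumour specimens, both bounds inclusive), then a
two-sided Pearson test of copy-ratio against $\log_2(\mathrm{FPKM}+1)$;
a gene is "correlated" when r > 0 and p < 0.001. This table informs
interpretation and is not one of the five scored conditions.

### Survival

Each gene is a univariate factor in a Cox proportional-hazards model of
overall survival with Breslow tie handling and a two-sided Wald test.
The covariate is the standardized $\log_2(\mathrm{FPKM}+1)$ — the
less lossy reading of "univariate factor"; HR is per 1 SD — with a
median-dichotomized option (`covariate = "median"`). p < 0.1 with
HR > 1 is poor prognosis, with HR < 1 good prognosis; the scored flag
is "good or poor". The raw p is gated without multiplicity correction,
mirroring the source convention; a BH column is emitted alongside for
transparency. Cohorts below 20 samples or 5 events, constant
covariates, and monotone-likelihood fits (flagged via the coefficient
and standard-error magnitudes) are reported unevaluable, never silently
returned.

### Ranking

Genes are ordered by descending PCO; ties break by maximum
single-cancer CS, then pan-cancer G-score magnitude, then gene id.
The tie rule is an artifact of this implementation (the scoring scheme
itself never ranks ties) and exists purely so output is deterministic.

## The synthetic cohort generator

`simulate_cohort()` generates per-cancer bundles emulating the data
layers the analysis consumes, with planted drivers as ground truth:

* **Copy number** — arm-scale background blocks with log2 ratio
  ~ Normal(0, 0.05) (near-diploid, straddling the 0.1 amplitude floor),
  plus focal 0.5–5 Mb events covering each planted gene in a
  Bernoulli(0.4) fraction of tumours at amplitude ~ |Normal(0.5, 0.1)|,
  signed by direction.
* **Mutations** — per-gene-per-specimen Bernoulli events at background
  rate 0.01, multiplied by 8 for planted drivers (echoing an 8% driver
  frequency against a ~1% background).
* **Fusions** — Poisson background events over random ordered pairs
  (0.02 per specimen) plus 4 planted events per driver pair per cancer
  type.
* **Expression** — $\log_2\mathrm{FPKM} = \mathrm{base}_g +
  \beta_\mathrm{cn}\,x_{gs} + \delta\,[\mathrm{planted}] +
  \varepsilon$, with per-gene baselines ~ Normal(3, 1), dosage slope
  $\beta_\mathrm{cn} = 1$ applied to the realized gene-level copy
  ratio (so the dosage correlation has signal by construction), planted
  shift $\delta = 1.5$ log2 units, and noise sd 0.5. A shared
  per-patient effect is available (`patient_sd`) but defaults to 0:
  a nonzero value induces cross-gene dependence that is realistic for
  library-size artefacts but invalidates per-run independence-based
  calibration diagnostics such as a KS test of p-value uniformity, so
  the default keeps genes exchangeable under the null.
* **Survival** — exponential proportional hazards with baseline
  log(2)/730 per day (two-year median), linear predictor
  $\theta \sum z_g$ over the standardized log-expression of
  prognosis-channel genes ($\theta = 0.7$ per SD), administrative
  censoring at 10 years plus exponential dropout at 1.5× the baseline
  hazard (≈ 40% events).

Every layer of every cancer type draws from its own child stream of the
master seed (`child_seed()`), so identical (config, seed) reproduce
byte-identical bundles and disabling one channel leaves the other
layers' draws untouched. Survival times are deliberately a function of
realized expression, so removing an expression channel shifts event
times for the affected genes — a coupling, not a leak. 200 decoy genes
(default) make rankings non-trivial.

What the generator does **not** emulate: genome-wide SCNA processes
(chromothripsis, whole-genome doubling, arm-level events), mutational
signatures and hypermutators, expression heteroscedasticity and batch
structure, informative censoring, or inter-gene co-expression modules.
Passing recovery tests therefore demonstrates that the pipeline's logic
is correct and calibrated under clean planted signal — not that these
thresholds are optimal for any particular real tumour atlas.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive internally; BED input shifts starts
  by +1 on read and back on write.
* Overlapping segments within one sample keep the longer segment, with
  a warning and an accounting entry (`io_log()`); total rows in always
  equals kept plus dropped.
* Gene/sample pairs without segments impute to 0 (diploid) —
  conservative toward no call.
* An all-constant copy-number matrix yields p = q = 1 everywhere; an
  observed G-score of 0 yields p = 1 by the ≥-tail convention.
* Signed-rank testing with all-zero differences returns p = 1, no flag.
* Zero-variance vectors in the Pearson stage report "zero variance",
  not a correlation.
* Stage tables are written at 6 significant digits in a fixed order
  (gene, then cancer type), so identical runs are byte-identical.

## Validation protocol and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`) runs, at
sizes chosen to keep the default check fast while leaving Monte-Carlo
error well inside the asserted margins:

* the colorectal CHD7 worked example (CS = 4 of 5) and the full-house
  CS = 5 bound;
* oracle equivalence: 100 random paired vectors (n ≤ 10) against the
  2^n sign-flip enumeration, and permutation G-score p-values against
  the exact pooled-null enumeration on a 5 × 4 matrix;
* parameter recovery: < 10% mean log-HR bias over 200 two-group
  exponential cohorts (true HR 2, n = 500); planted focal
  amplifications (f = 0.4, µ = 0.5, N = 200, 237 genes) recovered in
  ≥ 95% of 100 seeds with decoy flag rate ≤ 5%;
* null calibration: 12 single-cancer null cohorts (n = 150, 237
  genes) for survival-p uniformity (KS at α = 0.01) and the DE null
  flag rate, plus 3 null cohorts of 32 cancer types (n = 60 each)
  verifying that no gene reaches PCO > 20;
* end-to-end recovery: the three default multi-channel planted drivers
  occupy the top 3 PCO ranks in ≥ 95% of 40 seeds (5 cancer types,
  n = 120, 237 genes);
* conservation and byte-level determinism of every written table.

## Known limitations

* GISTIC-lite is not GISTIC: no marker-level peaks, no arm/focal
  separation, no confidence intervals. For real cohorts, run GISTIC
  and use the ingestion path.
* The pseudo-caller ensemble shares one test statistic; it validates
  the m-index plumbing, not caller complementarity.
* The "recurrent fusion" condition has two defensible readings
  (within-cancer vs pan-cancer pair); both are implemented and the
  choice is surfaced in configuration and provenance rather than
  silently resolved.
* Survival fits are univariate by design; no adjustment for stage,
  age or subtype, and no competing risks.
```{r session}
sessionInfo()
```
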