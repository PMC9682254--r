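---
title: "Methods: scoring, the CFR statistic, and survival-optimal stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, the CFR statistic, and survival-optimal stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfratio)
```

## The model in brief

Bulk tumor expression reflects a mixture of malignant cells, immune
populations, and stroma. Cancer-associated fibroblasts (CAFs) — the dominant
stromal population — impede cytotoxic T-cell infiltration and function, so
the *balance* between CD8+ T cells and CAFs is a more informative readout of
the immune contexture than either population alone. `cfratio` quantifies
both compartments with rank-based single-sample enrichment scores and
summarizes their balance as the CFR, then asks two clinical questions: does
the CFR stratify survival, and does it stratify response to checkpoint
inhibition?

## ssGSEA scoring

For each sample, all genes are ranked by expression. For a gene set with
matched size $m$ in a matrix of $G$ genes, the enrichment score is the sum,
over positions $i$ of the decreasing-expression walk, of the difference
between two running fractions:

$$ES = \sum_{i=1}^{G}\Big[P^w_{\mathrm{in}}(i) - P_{\mathrm{out}}(i)\Big],
\qquad
P^w_{\mathrm{in}}(i) = \frac{\sum_{k \le i,\,k \in S} r_k^{\alpha}}
                            {\sum_{k \in S} r_k^{\alpha}},
\quad
P_{\mathrm{out}}(i) = \frac{\#\{k \le i,\,k \notin S\}}{G - m},$$

where $r_k$ is the ascending midrank of gene $k$ in that sample (the most
highly expressed gene carries weight $\approx G^\alpha$).

Choices that matter:

* **`alpha` (default 0.25).** The rank-weight exponent of the original
  single-sample formulation and of the reference implementation's default.
  `alpha = 0` weights all set genes equally; larger values emphasize the top
  of the ranking. Configurable, not tuned.
* **Normalization (default global range).** All ES are divided by
  $\max ES - \min ES$ over the entire table — the cross-sample convention of
  the reference implementation; a per-signature-range mode is available.
  Because the divisor depends on the score table, scores (and CFR values)
  from different invocations are **not comparable**; joint scoring is
  required for cross-cohort comparisons.
* **Ties.** Expression ties receive midranks, and the walk order among tied
  genes is fixed by gene identifier, so scores are deterministic and
  invariant to the storage order of rows. A constant sample still has a
  defined (equal-across-samples) score.
* **Missing data.** Genes with missing expression in a sample are excluded
  from that sample's ranking (with a reported count), not imputed: rank
  methods have no natural imputation and silent zero-filling would bias the
  running fractions. Set genes absent from the matrix are dropped; per-set
  coverage is always reported. Fewer than 2 matched genes gives an `NA`
  column; a set covering every gene is an error because the complement
  fraction is undefined.
* **Input scale.** Because the score depends only on within-sample ranks,
  FPKM-to-TPM conversion (`fpkm_to_tpm()`) and `log2_transform()` leave it
  unchanged; they are provided so absolute values are comparable in reports.
  Whether scoring runs on TPM or log-TPM is therefore immaterial and left
  undecided. Duplicate gene rows are collapsed by maximal row mean
  (`max-mean`), the array-era convention; ties fall back to first occurrence
  with a warning.

## The CFR and its two forms

In score space the CFR is deliberately a **difference**,
$CFR_j = ES(\mathrm{CD8}, j) - ES(\mathrm{CAF}, j)$ (scores live on an
interval scale where a quotient is not meaningful and can cross zero); for
stained-slide area measurements it is a true **ratio** of CD8-positive to
$\alpha$-SMA-positive area. Both forms are kept verbatim and the `form`
field of a `CfrResult` records which one produced the values. For IHC,
multiple evaluated regions are summed *before* the ratio is taken
(sum-then-ratio); samples with zero fibroblast area are flagged unevaluable
rather than infinite. The same construction applied to any of the 24 shipped
immune-cell signatures is the ICFR.

The shipped registry contains the published 38-entry CD8 marker list kept
verbatim after deduplication (36 genes; two symbols appear twice in print).
Its legacy identifiers are intentionally **not** modernized — scoring is
exact identifier matching, and silent symbol updating would change scores
unreproducibly; `apply_aliases()` lets the user opt in. The 8-gene CAF list
is the MCP-counter fibroblast signature. The remaining 23 immune-cell lists
are reconstructions from standard marker-gene knowledge (the original
curated lists are not redistributable here); they are labeled as such in
their `source` tags and should be treated as replaceable inputs via
`load_gmt()`. The composite immune score defaults to the union of the 24
immune-cell lists and accepts any substitute meta-signature.

## Survival-optimal dichotomization

`optimal_cutpoint()` implements maximally selected rank statistics with
log-rank (Savage) scores $a_i = \delta_i - \hat\Lambda(t_i)$
(Nelson–Aalen). For a candidate cutpoint $c$ with $m$ samples below it,

$$S(c) = \frac{\sum_{i:\,x_i \le c} a_i - m\bar a}
             {\sqrt{\tfrac{m(n-m)}{n(n-1)}\sum_i (a_i-\bar a)^2}},$$

and the selected cutpoint maximizes $|S(c)|$. Numerical conventions:

* Candidates are the observed marker values whose low-group proportion lies
  in $[\max(0.1, q_{lo}), \min(0.9, q_{hi})]$ (defaults $q_{lo}=0.1$,
  $q_{hi}=0.9$): the convention of the method, preventing degenerate splits.
  Exact ties in $|S|$ are broken toward the candidate nearest the marker
  median.
* Because the statistic depends on the marker only through its order, the
  optimum is invariant under strictly increasing marker transforms.
* The reported `p_approx` is the Lausen–Schumacher improved-Bonferroni bound
  for the maximum of the selection process. It is an upper bound and can be
  anticonservative at small $n$ relative to the exact permutation law, so a
  seeded permutation p-value (`permutation_B`) is offered. The naive
  log-rank p *at the selected cutpoint* is badly anticonservative and is
  never reported as the selection p.
* `dichotomize()` labels `high` iff the value strictly exceeds the cutpoint
  (boundary values are `low` — arbitrary but fixed and documented).
* Cutpoints may be fit on one cohort and applied to another (pass the fitted
  `Cutpoint` object); whether to transfer or refit is a user decision the
  package does not make.

The four-class comparator (`four_class()`) cross-classifies samples by
independent CD8 and CAF cutpoints; `infiltration_clusters()` runs seeded
K-means (50 restarts) on the immune-cell score matrix and orders clusters by
their mean composite immune score so labels are reproducible and
interpretable.

## Survival and association methods

Kaplan–Meier estimation, the log-rank test and Cox regression are delegated
to the `survival` package behind this package's interfaces, with fixed
conventions: Efron tie handling (the modern default; the alternative was not
prescribed), log-log confidence bounds and Brookmeyer–Crowley-style median
intervals, medians reported as not reached when the curve never crosses 0.5,
and times treated as months throughout. Monotone likelihood and
non-convergence in Cox or logistic fits are surfaced as errors rather than
returned as huge coefficients. Independent hand-coded oracles (product-limit
loop, O/E table, grid-search Efron partial likelihood) verify the
delegation in the test suite.

The association battery fixes conventions the analysis plan would otherwise
leave open:

* **Contingency tests.** A pure decision tree of the count table: Fisher's
  exact test when any expected count < 1 or $n < 20$; otherwise chi-square,
  with Yates correction when the table is 2×2 and any expected count < 5.
* **Spearman.** $\rho$ is the Pearson correlation of midranks; p by the
  t-approximation; CI by Fisher z with the rank-correlation variance
  correction $\sqrt{(1+\rho^2/2)/(n-3)}$ — a documented choice, since
  printed intervals rarely state their method.
* **ROC AUC.** Mann–Whitney with half-credit ties; no parametric binormal
  fitting.
* **Multiplicity.** Benjamini–Hochberg is the only adjustment offered (the
  mutation-enrichment use case reports FDR-style q-values).
* **Reporting.** Rates are kept unrounded internally; report layers round
  percentages to one decimal and ratios to two.

## The synthetic world

`generator_config()` states the world once; the defaults are not tuned to
test outcomes:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 500 | typical discovery-cohort scale |
| latents | bivariate Gaussian → logistic | bounded "infiltration fractions" in (0,1) |
| `rho` | 0.4 | the moderately positive CAF–immune correlation reported for bulk cohorts |
| `signature_size` | 30 | typical curated marker-list size |
| `beta` / `noise_sd` | 2 / 1 | signal-to-noise 2: clear but not trivial recovery |
| `n_background_genes` | 1000 | enough unregulated genes for stable ranks |
| survival | Weibull shape 1, scale 24 mo | exponential baseline, realistic median |
| `gamma` | 2 | log-hazard per unit latent difference; with sd(Δ)≈0.23 this gives a detectable group log-HR ≈ −0.6 at n = 500 |
| `censor_horizon` | 60 mo | uniform administrative censoring, ~35–40% censored |
| `eta0`, `eta1` | −1, 2 | overall response rate near 30%, odds increasing in Δ |

Responders are assigned PR (complete responses are rare at this scale) and
non-responders split 60/40 into SD/PD, matching the stable-disease
predominance of checkpoint-inhibitor cohorts; the simulated PD-L1 TPS is
weakly linked to the latent difference (`tps_slope`) so the biomarker
combination exercise has two partially overlapping predictors. One global
seed drives deterministic per-component substreams, so cohorts are
bit-reproducible.

What the generator deliberately does **not** emulate: real gene-level
expression distributions, batch effects, signature co-expression beyond the
latent shifts, competing risks, or informative censoring. A green
end-to-end test therefore establishes that the pipeline recovers the stated
latent structure — not that any particular real cohort would reproduce a
given hazard ratio.

## Known limitations

* Cross-invocation score comparability (see normalization above).
* Batch correction is out of scope; merged multi-platform inputs must be
  corrected upstream.
* The maximally selected p-approximation is a bound; for small cohorts use
  the permutation p.
* IHC inputs are consumed as area numbers; segmentation and staining
  quality are upstream concerns.
* No MAF/VCF parsing: mutation enrichment consumes a binary gene × sample
  indicator matrix.
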