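---
title: "Differential co-expression analysis with dcnet: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression analysis with dcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
library(dplyr)
```

Co-expression — the correlation of two genes' expression across samples —
is a proxy for shared regulation. When a disease rewires transcriptional
control, pairs of genes can gain, lose, strengthen, weaken or even reverse
their co-expression without either gene changing its mean level. `dcnet`
detects such pairs between two conditions, aggregates them into
*dysregulated* hub genes, and carries the result through network assembly,
clinical-trait association and cross-species conservation analysis.

This vignette is the package's methods account: the statistical model at
each stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design decisions taken where
more than one reasonable choice existed.

## 1. The pair-level model

For genes $i,j$ and condition $c \in \{A, B\}$ (by convention A is the
disease condition), the package computes Spearman's rank correlation
$r^{(c)}_{ij}$ with average ranks for ties. Rank correlation is used
throughout: bulk expression values are heavy-tailed and platform-dependent,
and ranks make every statistic invariant to monotone per-gene transforms
(a property the test suite asserts exactly).

The change statistic is the classical two-sample comparison of correlations
through Fisher's variance-stabilizing transform $z = \operatorname{atanh}(r)$:

$$ Z_{ij} = \frac{z^{(A)}_{ij} - z^{(B)}_{ij}}
   {\sqrt{1/(n_A-3) + 1/(n_B-3)}}, \qquad
   p_{ij} = 2\,\Phi(-|Z_{ij}|). $$

Two-sided p-values are the default because both gained and lost
co-expression are of interest; `dce_test()` is symmetric under swapping
conditions (Z flips sign, p is unchanged). The $1/(n-3)$ variance is the
Pearson-theory value; for Spearman correlations it is slightly conservative
at $\rho = 0$ (the exact null variance is $1/(n-1)$) and slightly
anti-conservative at large $|\rho|$ (the asymptotic variance carries a
$\approx 1.06$ factor). At the cohort sizes the method is meant for
(hundreds of samples per condition) the Gaussian tail matches a
condition-label permutation null to well within Monte-Carlo error, which
the acceptance suite verifies directly at $n = 500$.

### Multiple testing

All $G(G-1)/2$ pairs are one family: `by_adjust()` applies the
Benjamini–Yekutieli step-up rule
$p_{(i)} \mapsto \min_{j \ge i} \min\{1,\; m\,c(m)\, p_{(j)}/j\}$ with
$c(m) = \sum_{k=1}^m 1/k$, which controls FDR under arbitrary dependence —
the right regime here, since pairs sharing a gene are strongly dependent.
The default discovery cutoff is adjusted $p < 0.01$. BY is deliberately
conservative: in the calibration runs the realized false-discovery
proportion sits near $10^{-3}$ at the nominal $10^{-2}$, while recall on
planted signal at $(\rho_A, \rho_B) = (0.5, 0)$, $n = 300/300$ stays above
0.98.

### Change classes

`classify_pair()` reads the two per-condition co-expression calls (default
$\alpha_{co} = 0.01$, from the Fisher-z test of each correlation against
zero) and assigns exactly one of: `A_only`, `B_only`, `increased`,
`decreased`, `reversed_neg_to_pos`, `reversed_pos_to_neg`, `neither`.
"Increased/decreased" compares $|r_A|$ with $|r_B|$ and requires sign
agreement; reversal requires both calls significant with opposite signs.
The classes partition any input set (a property test), so
`change_summary()` counts are conservation-exact, and the headline
strengthened-to-weakened ratio is
$(\#A\_only + \#increased)/(\#B\_only + \#decreased)$, reported as
infinite (with a warning) when nothing weakened.

### Robustness checks

Two resampling diagnostics mirror common practice for correlation
estimates, each defaulting to 100 rounds:

* `half_sample_stability()` recomputes each tracked pair's correlation on
  random $\lfloor n/2 \rfloor$-subsets drawn *without replacement* and
  reports the per-pair mean and sd. Note a subtlety the tests encode: the
  per-pair sd around the subsample mean carries a finite-population factor,
  $\sqrt{1/m - 1/n}$ for null pairs ($m = \lfloor n/2\rfloor$), while the
  pooled dispersion of resampled correlations around zero is the fresh-draw
  value $1/\sqrt{m-1}$. Both are checked against their own closed forms.
* `shuffle_null()` permutes every gene's sample labels independently —
  destroying all pair structure while keeping marginals — and reports
  per-pair null quantiles (2.5/97.5/99.5%), a confidence band for each
  observed correlation.

Inside these resamplers only, correlations of exactly $\pm 1$ (possible in
small monotone subsamples) are clamped to $\pm(1 - 10^{-15})$ before the
z-transform; the main pipeline instead raises an error, because a perfect
correlation at cohort scale indicates a degenerate input.

## 2. From pairs to genes and networks

`partner_table()` turns the significant pair set into a symmetric
partner-set map; a gene's *partner count* is its degree in the DCE graph.
`gene_summary()` assembles the per-gene survey: partner count, Welch-t
differential expression (two-sided, on log-scale values; direction is the
sign of the disease-minus-control mean), membership flags for
user-supplied disease/aging/TF gene lists, and one-sided hypergeometric
enrichment of each gene's partner set against those lists
(`enrichment_test()`, $P(X \ge x)$ with $X \sim$ Hypergeom$(n, K, k)$;
the enrichment universe defaults to the genes surviving preprocessing). A
legacy `mode = "literal"` reproduces a historically common but non-standard
2×2 construction whose fourth cell is $n - k$; it is provided for
comparability, never as the default.

`select_dysregulated()` applies the selection rule: more than 50 partners
(strict), and (differentially expressed at $p < 0.01$ with partners
enriched in disease genes at $p < 0.05$) or (a known disease gene with
partners enriched in DEGs at $p < 0.01$). The DEG-enrichment cutoff is the
stricter of the two because DEG lists are large and easily enriched;
both cutoffs are arguments.

`build_core_network()` connects selected genes by co-expression
($|r| > 0.3$ in the disease condition by default — the network describes
disease-state regulation; a `condition = "max"` switch uses the larger of
the two $|r|$'s since the choice is genuinely open) and/or by DCE
significance. Nodes with no qualifying edge are removed and reported as
islands. `extract_subnetwork()` gives a hub-centric view with per-member
change classes; `subnetwork_enrichment()` tests member sets against gene
sets; `rank_tf_coexpression()` ranks transcription factors by signed
correlation with a target (most negative first — the repressor-candidate
view — with an $|r|$ view alongside). `connectivity()` provides the
WGCNA-style soft-threshold degree $k_g = \sum_{j \ne g} |r_{gj}|^\beta$
with the conventional $\beta = 6$, for relating dysregulation degree to
ordinary co-expression connectivity.

## 3. Clinical traits

`trait_correlation()` is per-gene Spearman correlation with a trait over
samples with observed trait values. For a dysregulated pair $(g_1, g_2)$
and trait $t$, `pairwise_partial_table()` reports both marginal
correlations and both first-order partial correlations

$$ r_{g_1 t \cdot g_2} =
   \frac{r_{g_1 t} - r_{g_1 g_2}\, r_{g_2 t}}
        {\sqrt{(1 - r_{g_1 g_2}^2)(1 - r_{g_2 t}^2)}} $$

flagging pairs where conditioning on the partner *improves* the
association ($|$partial$| > |$marginal$|$) — the suppressor pattern in
which two correlated genes' opposing couplings to a trait mask each other
marginally. Rank-based correlations feed the formula by default, keeping
the whole pipeline on one statistic (the partial-correlation-of-ranks
equals the correlation of rank-regression residuals to $10^{-10}$, an
oracle the tests check); a Pearson mode is available since either
convention is defensible. Missing trait values are dropped
pairwise-complete, with $n$ reported per association.

## 4. Cross-species conservation

Microarray probes collapse to genes by maximum mean expression
(deterministic tie-break by probe ID); many-to-many homolog maps resolve
to one-to-one greedily by combined mean expression, consistent with the
probe rule. Two statistics then compare species:

* `expression_profile_similarity()` — Spearman correlation over homologous
  genes between every cross-species sample pair (subsampled, default
  $10^5$ pairs, fixed seed), summarized by the median. This measures
  conservation of expression *profiles* (driven by per-gene baselines).
* `coexpression_conservation()` — aligns shared homolog pairs and reports
  (i) the Spearman correlation between the two pair-correlation vectors
  ("correlation of correlations"), (ii) the fraction of co-expressed pairs
  (significant in at least one dataset by default; a `scope = "both"`
  switch narrows it) whose correlations disagree in sign, and (iii) the
  fraction of pairs with significant cross-dataset differential
  co-expression — reusing the same `dce_test()` + `by_adjust()` machinery
  as the two-condition analysis, at adjusted $p < 0.01$.

The two statistics are deliberately decoupled: expression profiles can be
strongly conserved while co-expression structure is not, and the generator
can produce exactly that situation (shared gene means, divergent
correlations).

## 5. The synthetic-data generator

All tests and the acceptance script run on data from `simulate_dataset()`
and friends, built so that every statistical structure the pipeline
estimates has a planted, recorded truth.

**Model.** Each condition is multivariate normal with unit variances.
Correlation structure comes from disjoint components: *blocks*
(equicorrelated clusters, a stand-in for co-regulated modules; positive
definiteness requires $\rho > -1/(m-1)$ and is validated at construction)
and *hubs*. Background pairs are exactly independent, which makes type-I
error tests clean. Gene baselines are drawn once per dataset from
$N(0, \text{mean\_sd}^2)$ with `mean_sd = 2` — a log2-scale spread typical
of expression data, and the ingredient that makes sample-profile
correlations (and hence cross-species profile similarity) non-degenerate.
`noise_sd` is a pure marginal scale; planted correlations are specified
directly and are not attenuated by it. An optional monotone $2^x$
transform mimics a skewed expression scale; because the pipeline is
rank-based, every statistic is invariant to it, and the tests assert so.

**Hubs.** A literal star matrix (hub–partner $\rho$, partners mutually
independent) stops being positive definite once $m\rho^2 > 1$, so a
100-partner hub at $\rho = 0.7$ cannot exist as stated. The generator
instead uses a latent factor: partners load on a shared factor with
loading $\sqrt{\max(|\rho_A|, |\rho_B|)}$ in *both* conditions, and the
hub couples to the factor with per-condition strength $\rho_c / a$. The
hub–partner correlation is then exactly $\rho_A$ / $\rho_B$, the partner
module's internal correlation is identical across conditions (so
partner–partner pairs are *not* differentially co-expressed, and the DCE
graph is exactly the planted star), and the matrix is positive definite
for any partner count. This also reads naturally: a module that exists in
both states, which the hub joins only in the disease state.

**Rank attenuation.** Planted latent correlations are Gaussian-scale; the
observable Spearman correlation converges to
$(6/\pi)\,\mathrm{asin}(\rho/2)$ (e.g. $0.6 \mapsto 0.580$).
`spearman_target()` exposes the map, and all truth-based tests compare
against it, at tolerance 0.03 by $n = 2000$.

**Later stages** extend the same object deterministically (one global seed
expands into fixed per-stage child seeds, so adding a stage never perturbs
earlier draws): `add_clinical_trait()` (trait = weighted gene sum + noise;
expected correlation $w/\sqrt{w^2 + \sigma^2}$ in closed form),
`add_batch_effects()` (per-batch per-gene additive offsets, recorded
exactly so correction can be checked as an identity), and
`add_species_pair()` (a second species sharing per-gene means whose
planted components keep their correlation with probability $1 - d$ and are
otherwise re-drawn). The redraw mode is explicit: `"mixed"` (sign flip or
zero, equal odds — the default), `"zero"` (pure loss of co-expression,
under which conservation decays to independence at $d = 1$), `"flip"`
(pure sign reversal, generating sign-inconsistent pairs). Perturbation is
applied per component and recorded per pair; conservation studies use
two-gene blocks, where the two coincide.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real cohorts: count noise (no negative-binomial
read-level model), brain-region or cell-composition structure,
batch-by-condition confounding, non-linear gene–gene dependence, and
realistic gene-set topology. The generator's role is to verify the
estimators against known truth, not to imitate a specific dataset.

## 6. Preprocessing choices

* `quantile_normalize()` maps every sample onto the mean-of-sorted
  reference (ties get the mean of the reference values they span;
  idempotent; implemented via limma's quantile normalization). Note it is
  only a smooth, correlation-preserving map when the gene panel is
  reasonably large; on toy matrices with a handful of widely-spaced genes
  it effectively discretizes values.
* `adjust_covariates()` regresses each gene on intercept + covariates
  (categoricals one-hot, one level dropped) and keeps residuals + grand
  mean, so per-gene means are untouched ($10^{-10}$ tolerance).
  Rank-deficient designs error naming the collinear columns;
  single-level covariates are skipped with a warning. Adjustment is
  applied per condition in the intended workflow — conditions are
  processed separately — with a joint fit available by passing the
  combined matrix; the choice is left to the caller because either is
  defensible.
* `center_batches()` standardizes each gene within each batch to the
  pooled gene mean/sd. This is a deliberate simplification of
  empirical-Bayes batch correction (ComBat): self-contained, exactly
  testable against planted offsets, and adequate for location/scale batch
  artefacts; it does not shrink per-gene batch estimates, so very small
  batches are noisier than ComBat would be. Singleton batches error;
  zero-variance genes within a batch get location-only adjustment with a
  warning.
* `flag_outlier_samples()` flags samples whose mean Spearman correlation
  to the others falls more than `z` (default 3) sd below the mean of those
  statistics — an automatic operationalization of the usual visual
  PCA/clustering screen. The statistic's distribution is mildly
  left-skewed, so with many samples expect an occasional false flag at
  z = 3; the threshold is an argument.
* `filter_genes()` drops genes with missing values (rather than imputing:
  pairwise-complete samples would make $n$ vary per pair and complicate
  the Z statistic) and genes constant in either condition (undefined
  ranks), reporting counts.

## 7. Numerical and engineering notes

* All-pairs Spearman ranks each gene once, then accumulates blocked
  cross-products of the scaled rank matrix (`block_size = 500` by
  default): memory $O(\text{block}^2 + G \cdot n)$, equality with the
  naive per-pair computation to $10^{-12}$ (asserted over random
  matrices). Pair tables are tibbles under a canonical key
  (`gene_i < gene_j` lexicographically); every module addresses pairs by
  that key, so record order never matters.
* `spearman_pairs()` computes the same statistic for an explicit pair
  list, which is how the tests and the acceptance script work at
  10,000-pair scale without materializing 200 million background pairs.
* Per-condition co-expression p-values default to the Fisher-z form for
  internal consistency with the difference statistic; the exact-t form is
  one flag away (`method = "t"`). The two agree closely except in the far
  tails, where the t-tail is heavier.
* Degenerate inputs error early and name the offender: constant genes at
  the correlation step, $|r| = 1$ into `fisher_z()`, $n < 4$, impossible
  enrichment counts, empty selections.

## 8. Problem sizes used in the checks

The packaged tests and `scripts/acceptance.R` run, per invocation: 5,000
null pairs at $n = 200$ for type-I calibration; 10,000 pairs (5% planted)
at $n = 300$ over several seeds for FDR/recall; a 1,000-gene, 100-partner
hub at $n = 500$ for end-to-end recovery; 200 planted pairs at five
divergence levels for conservation; and 10,000-round permutation and
100-round resampling checks. These sizes were chosen as the smallest at
which the asymptotic approximations the method relies on are visibly in
force; everything scales up by argument.

## 9. Known limitations

* The Fisher-z variance is the Pearson-theory value; at small $n$
  (tens of samples) the Spearman null is mildly mismatched and the
  permutation check (`shuffle_null`, or a condition-label permutation) is
  the more trustworthy reference.
* BY's conservatism is a choice of safety over power; with independent-ish
  pairs it over-controls by roughly the $c(m)$ factor.
* Batch centering does not protect against batch-condition confounding —
  no location/scale method can; design balance must come from the data.
* First-order partial correlations control one partner at a time; they do
  not attempt graphical-model-style full conditioning.
* The hypergeometric enrichment treats genes as exchangeable; it inherits
  all the usual caveats about gene-set size and universe choice.
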