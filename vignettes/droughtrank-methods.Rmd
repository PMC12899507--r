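---
title: "Methods: drought-tolerance evaluation and trait-transcriptome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought-tolerance evaluation and trait-transcriptome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtrank)
```

`droughtrank` implements the quantitative backbone of a multi-variety crop
drought study: screening a germplasm panel by germination behaviour,
condensing a physiological trait panel into a single tolerance score per
variety, and linking that phenotypic picture to transcriptome structure
through co-expression modules, hub genes, Mantel tests and qPCR validation.
This vignette documents the models, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic-data generator
does and does not emulate.

## Germination screening

For each variety and treatment the package computes, from daily counts of
newly germinated seeds ($G_n$ on day $D_n$, $N$ seeds sown, $N_e$ emerged):

* germination rate $GR = N_e / N \times 100$;
* germination energy $GE = G_t / N \times 100$, where $G_t$ is the mean of
  the two highest daily counts — an early-vigour measure. When only one day
  is recorded, $G_t$ falls back to that day's count. The denominator is
  taken as the total seeds sown; no alternative is documented for the
  original formulation, and this choice keeps $GE \le 100$.
* germination index $GI = \sum_n G_n / D_n$, which rewards fast
  germination.

Stress tolerance is expressed as the ratio of each index under osmotic
stress to its paired control (the *tolerance indicator*). The ratio is
scale-invariant, equals 1 for no effect, and is applied uniformly to the
three germination indices plus root and shoot length.

Varieties are grouped by K-means on the column-standardized relative
indices. The reference statistical software for this kind of screening does
not document its K-means defaults, so the package standardizes explicitly,
uses 25 restarts, and exposes the seed; groups are relabelled `I..k` by
decreasing centroid mean so that group `I` is always the most tolerant and
labels are reproducible. When `k` equals the number of varieties the
saturated partition is returned directly. Missing cells are mean-imputed
within column, with a warning.

## Fuzzy membership and the composite D score

Each trait column is rescaled to $[0, 1]$ by a direction-aware min-max
(membership) function: benefit traits use $U = (x - x_{min}) / (x_{max} -
x_{min})$, cost traits (the damage markers MDA and REC by default) reverse
the scale. The composite score is the convex combination
$D(v) = \sum_t w_t\, U(v, t)$ with uniform weights by default: on published
four-variety evaluation tables the printed D row is exactly the arithmetic
column mean, so uniform weighting reproduces it and is the defensible
default. Grey-derived weights ($w_t \propto$ mean relational coefficient of
trait $t$) are available as an option, as the two methods are often
combined in practice.

Reported D values are rounded *half-up* to three decimals
(`round_half_up()`): R's default half-to-even rounding would print 0.971
for a score of 0.9715, where evaluation tables conventionally print 0.972.
Ranks descend by full-precision D with ties broken by variety identifier.

For raw time-course data the per-variety trait value fed into the
evaluation is the stress/control ratio of cell means, averaged over
timepoints (`trait_responses()`); the original study does not state how its
membership inputs were derived from the time course, so this convention is
documented rather than asserted, and membership values can always be
supplied directly (`values_are_memberships = TRUE`).

Where prose and table orderings of published rankings disagree, the package
follows the numbers; `evaluate_varieties()` flags any disagreement between
the D ranking and the grey relational ranking rather than resolving it.

## Grey relational analysis

After direction-aware normalization the ideal reference series is 1 for
every trait. With per-cell deviations $\Delta(v,t) = |x(v,t) - 1|$ and
global extremes $\Delta_{min}, \Delta_{max}$, the relational coefficient is

$$\xi(v,t) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
                  {\Delta(v,t) + \rho\,\Delta_{max}}$$

and the relational degree $\gamma(v)$ is the mean of $\xi(v,t)$ over
traits. The distinguishing coefficient $\rho$ defaults to 0.5, the
grey-systems convention; increasing $\rho$ smooths the contrast between
series. A variety identical to the reference attains $\gamma = 1$; if all
varieties are identical the degenerate case returns $\gamma = 1$ for all,
with a warning.

## DEG set logic and enrichment

Differential expression estimation itself is an input: the package consumes
per-contrast tables of gene, log2 fold change and p-value. Filtering reads
the conventional "log2 fold change of 2.0, p < 0.05" threshold literally
(`lfc_cut = 2`, i.e. a 4-fold change; set `lfc_cut = 1` for the 2-fold
reading) with a strict raw-p cut; Benjamini-Hochberg adjustment is
available but off by default since the emulated workflow filtered on raw p.
Multi-contrast intersection reports the shared set and all Venn region
cardinalities.

Enrichment is a generic upper-tail hypergeometric test over GMT gene sets
with BH adjustment across terms. The universe defaults to all annotated
genes and can be overridden with the expressed-gene set; which universe the
original enrichment tools used is not stated, so both are supported and
neither asserted. No ontology topology or gene-length bias correction is
attempted.

## Co-expression network

The network layer is intentionally a transparent simplification of full
weighted co-expression pipelines. Expression is $\log_2(x+1)$-transformed
(FPKM-like abundances are heavy-tailed), pairwise Pearson correlations are
raised to an unsigned power adjacency $w = |r|^\beta$ with $\beta = 6$, and
modules are obtained by average-linkage hierarchical clustering on $1 - w$
cut at an explicit module count. Soft-threshold selection, topological
overlap and dynamic tree cutting are deliberately out of scope: the
scientific content downstream — module-trait correlation, hub extraction,
Mantel tests — is the package's focus, and an explicit module count makes
the detector deterministic and testable.

Module eigengenes are the first principal component of the standardized
member profiles, unit variance, sign fixed so the mean member correlation
is non-negative. Module-trait relationships are Pearson correlations with
two-sided p-values. Hub genes are ranked within module by degree in the
edge-thresholded graph (`edge_threshold = 0.8` on $w$), ties broken by mean
incident weight then gene id, top five by default. The edge definition
behind published degree rankings is typically unstated; these defaults are
conventions, not claims. Edge lists are exported with each undirected edge
once (`source < target`) and a sign column from the signed correlation.

## Mantel tests and per-gene correlations

`mantel_test()` correlates upper triangles of two sample distance matrices,
permuting one matrix's rows and columns jointly. The permutation p uses the
add-one estimator $(1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)$, so p is
never zero and never below $1/(n_{perm}+1)$; for seven or fewer samples an
exact mode enumerates all $n!$ permutations. The default distance is
Euclidean on standardized columns so heterogeneous trait panels contribute
comparably. Because published figures of this kind are ambiguous about
whether genes enter as distance matrices or as individual vectors, both
modes exist: `mantel_test()` for matrices and `gene_trait_correlation()`
for per-gene permutation correlations with sign classification, the latter
run per variety to expose cross-variety sign reversals.

## qPCR relative expression

`delta_delta_ct()` implements $2^{-\Delta\Delta C_t}$ with amplification
efficiency fixed at 2 (perfect doubling; no efficiency correction).
Technical replicates are averaged within biological sample before
biological aggregation; the biological SD of $\Delta C_t$ is propagated to
a fold-change interval, reported but not tested against any external value.
The calibrator condition has fold 1 exactly, and the log2 fold is
antisymmetric under swapping condition and calibrator.
`concordance_with_rnaseq()` reports Pearson correlation and sign agreement
over shared genes.

## The synthetic-data generator

No public expression data are available for this design at desk scale, so
the package ships a seeded generator (`simulate_study()`) that reproduces
the *statistical structure* the analysis assumes. Every layer is a monotone
function of a latent per-variety tolerance $\tau \in [0,1]$ plus noise:

* **Germination** (28 varieties, $\tau$ evenly spaced on $[0.05, 0.95]$):
  control counts are binomial (92% germination over 90 seeds — three dishes
  of 30, pooled) spread over an early-peaked 10-day schedule; stress thins
  each day's count binomially with retention $0.2 + 0.8\tau$.
* **Traits** (4 focal varieties, $\tau$ = 0.9/0.8/0.3/0.2; days 3, 5, 7,
  10; 3 replicates): each of the 14 traits interpolates between a
  sensitive-variety and a tolerant-variety day-10 effect (growth and water
  status decline; damage markers rise most in sensitive lines; osmolytes
  and antioxidants rise most in tolerant lines, proline by more than an
  order of magnitude), ramping linearly with stress duration, with 2%
  fractional replicate noise — magnitudes loosely calibrated to what
  PEG-6000 seedling trials report, as configuration values rather than
  claims.
* **Expression** (2000 genes, 12 samples = 2 varieties x 2 treatments x 3
  replicates, 6 planted modules): per-module latent factors are
  orthogonalized across samples — at 12 samples, i.i.d. factors can be
  accidentally collinear and the planted partition would not be
  identifiable by *any* method — then given small module-specific stress
  shifts; genes load on their module's factor with log-scale residual SD
  0.3. The last module is a small variety-discordant group riding the
  CAT-linked factor with opposite sign in the two varieties, planting the
  tolerant-positive / sensitive-negative hub pattern. Three traits track
  three module factors at correlations 0.9, 0.85 and -0.8.
* **DE contrasts**: a planted shared set (150 genes) passes the thresholds
  in all three contrasts by construction; 100 contrast-specific DEGs each;
  null genes have $p \sim U(0,1)$ and log2 fold changes from $N(0, 0.5)$
  truncated at $\pm 1.5$, so in this noiseless-threshold regime filtering
  plus intersection must recover the planted set exactly for every seed.
* **Annotation**: three "responsive" terms draw 70% of their members from
  the shared set; background terms are uniform.
* **qPCR**: stressed Ct values shift by $-\log_2(\text{fold})$ cycles
  against a constant reference gene, with 0.15-cycle noise.

What the generator does **not** emulate: read-level data, mapping and
quantification noise, gene-length and GC biases, correlated measurement
error between traits, batch effects, and the long-tailed module size
distribution of real co-expression networks. Passing recovery tests on
synthetic data therefore certifies the *pipeline logic* — not the
biological validity of any particular threshold on real data.

## Numerical conventions and degenerate inputs

* Half-up decimal rounding for printed-table comparisons; full precision
  retained everywhere else.
* Constant trait columns: error by default, membership 0.5 with a warning
  when configured (`on_constant = "half"`).
* Constant gene or trait vectors in correlation steps: removed or reported
  as missing, with warnings; eigengene sign convention resolves the PCA
  sign ambiguity.
* All stochastic steps (K-means restarts, permutations, the generator)
  take explicit integer seeds and restore the caller's RNG state.
* Ties in every ranking break by identifier, making outputs
  order-invariant.

## Problem sizes used by the test suite

The suite validates the enrichment engine against exhaustive enumeration on
universes up to 20 genes, the Mantel exact mode against full enumeration at
4-5 samples, Mantel calibration with 1000 null simulations at 8 samples and
99 permutations, and the end-to-end golden run at the generator defaults
(2000 genes, 12 samples, 28-variety screen). These sizes exercise every
code path at full statistical fidelity while keeping the suite fast.

## Known limitations

* The module detector requires the module count as input; it does not
  estimate it.
* Enrichment treats gene sets as flat lists.
* qPCR assumes perfect amplification efficiency.
* The raw-data path from replicate trait tables to membership values is a
  documented convention; published membership tables can be consumed
  directly when available.
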