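---
title: "Clonal fate analysis of perturbed lineage-traced single cells: methods"
author: "clonalfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal fate analysis of perturbed lineage-traced single cells: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalfate)
```

# Scope

`clonalfate` implements the bespoke computations of a joint
CRISPR-perturbation + lineage-barcoding single-cell experiment in the
embryonic mouse forebrain setting: heritable 37-bp lineage barcodes are
electroporated into ganglionic-eminence progenitors together with an sgRNA
(a perturbation arm such as gMeis2, against a gLacZ control arm), and the
descendants are read out by scRNA-seq. The package covers

* clone calling from raw barcode reads (anchored extraction, Phred
  filtering, UMI collapsing, Hamming clustering, cell-to-clone assignment);
* clone-level fate statistics (class intersections in the style of an UpSet
  plot, clone sizes);
* a lineage-coupling statistic — observed/expected clone sharing between
  cell states with a subsampling null, empirical p-values and FDR;
* differential cell-type composition between arms by Poisson regression
  with batch covariates and exposure offsets, plus descriptive log10
  proportion ratios and module-score regressions;
* a balanced L1-regularized logistic classifier of interneuron (IN) versus
  projection-neuron (PN) fate with per-gene scores on the unit interval;
* promoter/enhancer annotation of ChIP peaks (nearest TSS, promoter
  windows, shared/exclusive two-factor sites, Chi-squared enrichment,
  target-gene assignment).

Everything upstream (alignment, UMI counting, clustering, integration,
peak calling) and downstream (pseudobulk differential expression, GO
enrichment, module *detection*) is out of scope; the package consumes
their outputs as plain tables.

# The synthetic-data generator

Because the real studies rest on deposited sequencing data, every stage
here is validated against a generator with known ground truth
(`sim_config()`, `simulate_clones()`, `synthesize_fastq()`,
`simulate_expression()`). The generator emulates:

* clones of mixed classes: per batch and arm, `n_progenitors` barcoded
  progenitors found clones whose sizes follow `clone_size_law` and whose
  cells draw classes iid from the arm's class probabilities;
* a perturbation-induced fate shift: the perturbed arm moves probability
  mass `fate_shift_delta` from PN to the IN classes (equal split between
  IN-MGE and IN-CGE unless configured). The shift acts on whole clones as
  they are generated, matching a clone-level view of fate switching;
* barcode reads: 5' anchor + 37-bp barcode + 3' anchor, with iid per-base
  substitution errors on the barcode and Phred scores from a configurable
  normal model (default mean 37, sd 2, clipped to [2, 41]). Each cell owns
  a small pool of UMIs that reads resample, emulating PCR jackpotting;
* expression: negative-binomial counts where a configurable set of
  informative genes separates PN from IN cells at a configurable log2 fold
  change, applied symmetrically around each gene's base mean.

One root seed determines everything; child seeds for each stage come from
a fixed affine congruential scheme (`derive_seed()`), so stages can be
re-run independently and reruns are bitwise identical.

**Defaults and why.** The default clone-size law (sizes 1–6, mode at
singletons, mean ≈ 2.4) reflects the sparse clone recovery typical of
transposon lineage tracing read out by droplet scRNA-seq, where most
recovered clones are small and many are singletons. The default class
probabilities (mitotic 0.20, PN 0.50, IN-MGE 0.15, IN-CGE 0.15) put PN
cells in the majority, as in lateral-GE electroporations. The default
barcode layout is three random stretches (9 + 8 + 8 bp) each closed by a
4-bp fixed bridge: barcodes of this protocol family interleave short
random stretches with fixed linker bases over 37 bp, but the exact
arrangement is not public, so the layout is configuration, not contract.

**What the generator does not emulate** — ambient RNA, doublets,
cell-cycle structure, barcode chimeras, indel errors (substitutions only
by default, which keeps the fixed-length Hamming model exact), cell-barcode
collisions. Tests passing on this generator therefore show algorithmic
correctness and statistical calibration under the stated model, not
robustness to every artefact of real libraries.

# Clone calling

Extraction scans each read for the 5' and 3' anchors at a common offset,
allowing `anchor_mismatch_tol` mismatches per anchor, and takes the
smallest matching offset. Quality filtering keeps barcodes whose **mean**
Phred over the 37 bases is at least 30; protocol write-ups state the
threshold without naming the statistic, so the statistic is a choice — a
`min` mode is available for the stricter reading. UMI collapsing counts distinct
(cell, UMI, barcode) triples.

Clustering joins barcodes into single-linkage connected components at
Hamming distance ≤ 3 (the conventional cluster distance for this
protocol). Single linkage was
chosen over centroid clustering because it gives a fixed "cluster
distance" an exact meaning and admits a brute-force oracle. The cluster id
is the lexicographically smallest member, making the mapping deterministic
and order-invariant; since cross-component distances exceed the threshold,
clustering the cluster ids is the identity.

Cells become clones as connected components of the bipartite
cell–barcode-cluster graph within each batch: cells sharing any cluster
are one clone, and a multi-barcode cell merges its clusters. The
multi-barcode rule is our documented choice; bipartite merging is the
least-commitment rule consistent with barcodes being heritable labels.
Clone ids are scoped per batch so identical library barcodes in different
embryos remain distinct clones (collision guard). `min_umi` defaults to 1
because read-support filters vary between upstream pipelines; it is
exposed for stricter use. The default library generator enforces a
minimum pairwise Hamming distance of 7 = 2·3 + 1 between library barcodes
so that distance-3 clusters around two different true barcodes can never
touch.

# The lineage-coupling statistic

For an ordered state list, `O[i, j]` counts clones with at least one cell
in state *i* and one in state *j*; the diagonal counts clones present in
the state. The expected matrix under no coupling is the independence
expectation from O's own marginals,

$$E_{ij} = \frac{(\sum_k O_{ik})(\sum_k O_{kj})}{\sum_{k,l} O_{kl}},$$

which conserves the grand total exactly and makes the uniform matrix a
fixed point (O/E ≡ 1). Printed forms of this expectation in protocol
write-ups sometimes carry inconsistent indices; the marginal-product
reading above is the only one under which a ratio of 1 means no
coupling, and it is what we implement. Whether the diagonal belongs in
the marginals is a convention; the default
(`diag_mode = "incidence"`) keeps it, and a `"strict"` mode zeroes it
before computing marginals. Note that the strict mode has a purely
structural bias of $n_s/(n_s - 1)$ for $n_s$ equally shared states, so the
incidence mode is the sensible default.

The analysis recomputes O and E on 1,000 random 25% subsamples of clones
(without replacement), scores each off-diagonal pair by the **median**
O/E over trials, and attaches an empirical p: the fraction of trials on
the opposite side of 1 from the pair's coupling direction, with a
pseudo-count, $p = (k + 1)/(n_\mathrm{valid} + 1)$. Trials where a pair's
E is 0 are excluded for that pair and reported in `n_valid_trials`.
Off-diagonal p-values are Benjamini–Hochberg adjusted.

**Tie handling.** Trials whose ratio is exactly 1 carry no evidence of
coupling and are counted toward the null side (for either direction).
With near-saturated clone–state incidence the subsampled ratio
distribution develops an atom exactly at 1, and a strict inequality count
would convert "no evidence whatsoever" into an extreme p-value.

**Applicability regime and a known limitation.** Because E is derived
from O's own marginals, the full-data ratio under truly independent
assignment is not exactly 1 at small clone sizes: with three equal states
and fixed clone size $s$, the population ratio is
$3q_2/(q_1 + 2q_2)$ with $q_1 = 1-(2/3)^s$ and
$q_2 = 1 - 2(2/3)^s + (1/3)^s$ — about 0.64 at $s = 2$, 0.95 for sizes
3–8, and ≈ 1 for sizes ≥ 10. Singleton clones depress the ratio further
by inflating the diagonal marginals while contributing nothing off the
diagonal. The statistic is therefore meaningful for multicell clones
large enough to span the states under study. Accordingly, the package's
null-calibration study uses 500 clones of 10–20 cells over three equal
states (scores within [0.8, 1.2] and all BH q > 0.05 across seeds), and
its power study uses 340 small clones (2–4 cells, where a threefold
co-occurrence enrichment is arithmetically possible) with the pair's
joint clone-membership probability raised to 3× its independence value
while each state's marginal incidence is held fixed — inflating the
marginals alongside the joint rate would cancel in O/E by construction.

# Composition and module-score statistics

For each cell type and perturbed arm, `composition_poisson()` fits

$$\log \mathbb{E}[\text{count}] = \beta_0 + \beta_\text{arm}
  + \beta_\text{batch} + \log(\text{total cells in batch} \times \text{arm})$$

by Poisson regression and reports $\beta_\text{arm}$ — the log rate ratio
of the type's proportion, perturbed versus control — with a Wald p
(likelihood-ratio behind a flag) and BH adjustment across cell types
within the arm comparison. The exposure offset is our addition: the
offset is our design choice: without it, arm-level differences in
captured cell numbers masquerade as composition changes.
A cell type with zero cells in an arm is flagged `"separation"` and not
fitted on pseudo-data. In the single-batch two-sample case the estimate
reduces to the closed form $\log\!\big((c_p/t_p)/(c_c/t_c)\big)$, which
the tests exploit. Descriptive `log_ratio_composition()` reports
$\log_{10}$ proportion ratios pooled over batches with an optional
pseudo-proportion guarding zeros.

`module_score_effects()` regresses precomputed per-cell module scores on
arm, batch and per-cell detected-gene counts, per module and perturbed
arm, and Bonferroni-adjusts across all module × arm tests. Constant
scores are flagged degenerate (effect 0, p 1) rather than fitted.

# The fate classifier

`fit_fate_classifier()` reproduces the balanced design: the majority
class is downsampled to the minority size (seeded); expression is
library-size normalized (counts per 10^4, log1p) and standardized per
gene; two-thirds of the balanced cells train an L1-regularized logistic
model (`glmnet::cv.glmnet`, binomial family, penalty by cross-validation
with seeded fold ids) stratified so the training classes stay exactly
equal; the held-out third yields the validation accuracy. The encoding is
IN = 0, PN = 1, so positive coefficients mark PN-predictive genes.
`select_variable_genes()` ranks genes by variance of the normalized
expression (default top 3,000) with ties broken by gene id. The exact
normalization applied upstream of such data varies between pipelines;
log1p + unit variance is the documented default here. Gene scores on
the conventional [0, 1] reporting scale are the logistic transform of the signed
coefficient — 0.5 for a zero coefficient, above 0.5 toward PN, below
toward IN; raw coefficients are always available via `coef()`.

Standardization uses the full balanced matrix rather than training-only
moments; with thousands of cells the difference is negligible and the
choice keeps coefficients comparable across refits. Lasso (alpha = 1) is
the default penalty, matching the cited solver's usage; ridge/elastic-net
are exposed through `alpha`.

# Interval annotation

All interval operations use 0-based half-open (BED) coordinates
throughout. Peak reference points are summits when present, else interval
midpoints. Nearest-TSS distances are signed relative to the TSS strand
(positive downstream), with ties broken toward the smaller absolute
distance and then the lexicographically smallest TSS id. Promoter windows
are $[\mathrm{TSS} - h, \mathrm{TSS} + h)$ with $h = 5{,}000$ bp by
default: descriptions of such windows oscillate between peaks within
5 kb of a TSS and a ~5 kb region around a TSS (which could mean
±2.5 kb); we follow the within-5-kb reading and expose `half_width`.
Enhancer and two-factor overlaps use the any-overlap (≥ 1 bp) rule; no
minimum overlap fraction is imposed.
Shared-site counts are A-site-centric (a shared pair counts once per A
site), which keeps fractions like "shared/total A sites" well defined
under one-to-many overlaps. Enhancer enrichment across
shared/A-exclusive/B-exclusive site classes is Pearson's Chi-squared on
the 3 × 2 table without continuity correction (2 df); a zero expected
cell raises an error advising category merge. A peak's target genes are
the union of promoter-window genes and genes linked to any overlapped
enhancer.

# Numerical and testing choices

* Expected matrices are computed in double precision; the tests require
  agreement with exact marginal products to 1e-12 and exact grand-total
  conservation.
* Empirical p-values use the (k+1)/(n+1) estimator, so p = 0 never occurs
  with finite trials.
* All stochastic behaviour flows from explicit integer seeds; identical
  configurations are bitwise reproducible.
* Test problem sizes: 500 clones × 1,000 trials × 20 seeds for coupling
  calibration and power; 200 Poisson null simulations of 4 batches × 400
  cells; 50 seeds of ~4,000 cells for fate-shift sign recovery; one
  3,000-gene, ~3,400-cell classifier fit; 100–200 random instances per
  brute-force interval or clustering oracle. These sizes make the whole
  suite run in well under a minute of compute per module while keeping
  the binomial margins of the calibration checks comfortable.

# Known limitations

* The coupling statistic's small-clone bias (above) is a property of the
  marginal-derived expectation, not of this implementation; interpret
  scores from singleton-heavy clone tables with care, or restrict to
  multicell clones.
* Clone calling assumes substitution-dominated barcode errors; indels
  shift the fixed-length frame and would surface as anchor failures, not
  as miscalled clones.
* The Poisson composition model treats cell counts as independent given
  the offsets; clonal correlation within batches is not modelled (under
  the generator's clone structure the test suite's type-I error stays
  within its nominal band, but heavily clonal data may be
  overdispersed — a quasi-Poisson extension would be the natural next
  step).
* `composition_poisson` requires both arms present per comparison;
  multi-arm designs are handled as separate control-versus-arm fits.
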