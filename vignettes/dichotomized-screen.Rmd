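---
title: "Dichotomized expression-pattern screening: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dichotomized expression-pattern screening: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichoscreen)
```

## The screen

The package addresses a cell-taxonomy question: given single-cell RNA-seq
counts for neurons from labeled groups — here four autonomic ganglia
(sphenopalatine, stellate, coeliac, lumbar) and four pelvic clusters
(P1–P4) — which genes mark which subsets of groups? Rather than modeling
expression magnitude, the screen *binarizes*: a cell expresses a gene when
it has at least one unique read, and each group is summarized by its
expressing-cell proportion `p_i`. This is deliberately robust to depth and
normalization: a proportion of positive cells is insensitive to library
size except through detection, and the comparison of interest (expressed
throughout one set of ganglia, absent from the rest) is a statement about
proportions, not means.

Every ordered bipartition `(S1, S2)` of the `G` groups is scored

```
score = sum_{i in S1} (1/n_S1) log2(-1 + eps_pos + p_i)
      - sum_{j in S2} (1/n_S2) log2(eps_nega + p_j)
```

This is an equally weighted log-product of shifted proportions on each
side: group size never enters, so a 50-cell pelvic cluster counts as much
as a 2,700-cell ganglion, and because logs add, a single outlier group
(barely expressing on the rewarded side, or strongly expressing on the
penalized side) drags the whole split down — the score prefers clean
dichotomies over good averages.

### Parameters

* `eps_pos = 0.9` (dimensionless offset on the rewarded side). The term
  `log2(-1 + eps_pos + p_i)` is only defined for `p_i > 1 - eps_pos`; at
  the default, any `S1` group with 10% or fewer expressing cells forces the
  minimal possible score (`-Inf`) for that split. This is a hard gate, not
  a soft penalty: the screen refuses to call a gene "on" in a group where
  it is detected in one cell in ten. `scripts/acceptance.R` re-derives this
  10% boundary analytically and numerically.
* `eps_nega = 0.02` (offset on the penalized side). It floors the penalty
  term so that a completely silent `S2` group contributes
  `-log2(0.02) ≈ 5.64` rather than infinity; smaller values reward absolute
  silence more strongly. It must be positive — the only legitimate `-Inf`
  route is the `S1` gate.
* `top_k = 100`, with deduplication: scores are ranked over all
  `2^G - 2 = 254` ordered splits jointly ("irrespective of the comparison
  scored"), and a gene appearing with several splits keeps only its best.

### Numerical choices

Scores are computed vectorized (one genes-by-groups matrix of per-group log
terms, combined through two membership-weight matrices), with the `-Inf`
pattern applied afterwards from an indicator of gated groups; the test
suite checks equality with a naive per-gene, per-split loop at 1e-9.
`-Inf` is the IEEE value internally and the string `-inf` in serialized
output. Splits are enumerated canonically — split `k` places group `i` in
`S1` iff bit `i-1` of `k` is set, bits indexed along the input group order
— which makes enumeration deterministic and complement pairs easy to
locate. Both orientations of each unordered split are scored; there is no
symmetry shortcut. Ties in the ranking (rare with continuous proportions)
are broken by the larger `S1`-versus-`S2` proportion margin, then the split
encoding, then the gene identifier. Genes scoring `-Inf` on every split
remain in the full score matrix but are dropped from the ranked list: a
gene that discriminates nothing is not a top gene.

## Pattern taxonomy

The best split of each top gene is read against a group-role map
(sympathetic / parasympathetic / pelvic cluster, with the pelvic clusters
partitioned into cholinergic `{P1, P2, P4}` and noradrenergic `{P3}`
neurotransmitter phenotypes): pattern I is all sympathetic ganglia plus
pelvic clusters (no parasympathetic), II parasympathetic alone, III
sympathetic alone, IV parasympathetic plus some pelvic clusters, V and VI
the ChAT- and Th-linked synexpression splits, VII pelvic clusters in a
class by themselves on either side of the split, and "other" everything
else (typically splits that divide the sympathetic ganglia and are
uninformative). Two classification choices were genuinely open:

* **Pattern I membership.** Whether "sympathetic plus pelvic" requires all
  four pelvic clusters or any nonempty subset is not decidable from the
  consolidated counts alone; the default is the permissive reading
  (`require_all_pelvic = FALSE`), with the strict reading switchable. Under
  the defaults the more specific neurotransmitter patterns V and VI take
  precedence over IV and I, so the 254 splits partition cleanly: 14 I, 1
  each of II/III/V/VI, 14 IV, 30 VII, 192 other (verified combinatorially
  in the tests).
* **Pattern VII orientation.** "Expressed, or not expressed, exclusively in
  pelvic clusters" is implemented by testing pelvic-only membership of
  either side of the split.

## Quality control

Droplet filtering keeps cells with more than 1,500 and fewer than 11,000
detected genes and a mitochondrial fraction below 15% — all three strict
inequalities, mirroring "more than / less than / below". Mitochondrial
genes are flagged by feature-name prefix (default `mt-`, configurable), and
the mitochondrial fraction is mitochondrial counts over total counts per
cell. Neuron selection scores each cell by its mean normalized expression
over Stmn2, Stmn3, Gap43, Tubb3 and keeps cells strictly exceeding the
threshold; glial-doublet exclusion does the converse with Plp1, Ttyh1,
Fabp7, Cryab, Mal.

The default normalization is `log1p` of counts scaled to the median cell
depth. Regression-based normalization (sctransform-style Gamma–Poisson
fits) is out of scope here: the screen itself consumes raw binarized
counts, so normalization affects only marker gating, where depth removal is
the property that matters. Consequently the published numeric neuron
threshold (3, on the sctransform scale) is kept as a user-settable default
but is not meaningful on other scales; the alternative `"auto"` picks the
threshold that best separates a bimodal marker-score distribution — Otsu's
criterion, i.e. the histogram cut minimizing within-class variance, taken
at the midpoint of the maximizing plateau. A plain Otsu cut is wrong when
the distribution is *not* bimodal (after droplet filtering a library may
contain nothing but neurons, and any cut would bisect them), so the cut is
accepted only when the low class it isolates is genuinely marker-negative
— its mean score below 25% of the high class's mean. When no such
population exists, the stage passes all cells through; this replaces a
fixed-value fallback, which would import a threshold calibrated on one
normalization scale into another. The 25% ratio is scale-free and
deliberately coarse: marker-negative contaminants sit near zero, an order
of magnitude below any neuronal mode, while genuine neuronal substructure
(e.g. cells missing one of four markers) stays well above it.

All QC predicates are pure per-cell functions, so filters compose in any
order; reports carry per-cell flags that reproduce the retained counts
exactly, plus the chosen thresholds.

## Synthetic data

The generator exists to make every downstream stage verifiable without
external data, and its defaults are the study conditions, not knobs. Eight
groups with the roles above; group sizes follow the source datasets' neuron
counts scaled down fourfold for speed while preserving the strong size
imbalance — ganglia at 672 (stellate), 464 (sphenopalatine), 231 (lumbar),
59 (coeliac) cells, and the 1,223 pelvic neurons split 112/88/50/56 over
P1–P4 (the per-cluster split is not published; this is a plausible
imbalanced allocation chosen once). Two batches mirror the two sequencing
rounds.

Counts follow a zero-inflated negative binomial: a Bernoulli gate sets
whether a cell expresses the gene, and expressing cells draw
`1 + NB(mean - 1, dispersion)`. The shift makes the expressing-cell
fraction *exactly* the gate probability, so planted genes have exactly
binomial expressing fractions — the property the screen's recovery
guarantees are stated in. Planted genes take `p_on = 0.8` on one side of
their split and `p_off = 0.02` on the other, against a background of genes
at a uniform 30% expressing fraction; these stand in for dichotomized
marker genes and are not calibrated to any deposited dataset. Mitochondrial
content is simulated directly as a per-cell Beta fraction (mean 5% for
intact cells, 40% for low-quality droplets) converted to mitochondrial
counts and spread multinomially over the `mt-` genes — simpler than
modeling mitochondrial transcription, and exactly the quantity the QC
predicate reads. Low-quality droplets scale every expression probability by
0.05 (debris has low library complexity); glial doublets express both
neuronal and glial marker sets at full depth. Batch depth enters, if
enabled, as a multiplicative factor on count means only — the screen is
binarized, so depth is the relevant nuisance, and the gate probabilities
stay untouched.

What the simulation does *not* emulate: ambient RNA (hence pure neurons
have zero glial counts — real data would show a low ambient floor), UMI
collisions, read-level errors, batch effects on detection probability, and
any correlation structure between genes. Passing tests therefore
demonstrate that the algorithms recover planted structure under clean
sampling noise, not that thresholds transfer to a specific real dataset.

Determinism: generation is byte-identical under a fixed seed, and the
caller's RNG state is saved and restored around every draw.

## Problem sizes in the test suite

The suite exercises the screen at 200–1,000 genes by 8 groups (the full
254-split enumeration each time), recovery at 50 planted plus 500
background genes with 200 cells per group, QC exactness at quarter-scale
group sizes with 25 low-quality droplets and 15 doublets, and the property
suites (monotonicity, permutation equivariance) at 1,000 randomized cases;
these sizes give stable statistics for the 3-sigma binomial bounds the
tests assert while keeping a full run around ten seconds.

## Known limitations

* The screen has no null calibration or multiple-testing control — by
  design it is a ranking, not a test; sampling noise in small groups can
  surface background genes with pelvic-specific-looking splits at the
  bottom of a ranking (visible in the README example).
* The `"auto"` marker threshold assumes contaminants are marker-negative;
  populations with intermediate marker expression will not be separated.
* `classify_split` is defined relative to a role map with a single
  parasympathetic ganglion in the default design; other designs work, but
  the pattern semantics (I–VII) were conceived for the autonomic case.
* The pipeline treats cluster labels as given; clustering, integration and
  embedding are upstream tools outside this package's scope.
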