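---
title: "Methods: skin-virome marker selection and individual specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skin-virome marker selection and individual specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromark)
```

## Scope and model

`viromark` analyzes presence/absence profiles of viral taxa across a
repeated-measures forensic sampling design: subjects swabbed at three
anatomical sites over three time points, plus four contacted objects per
subject and negative controls. It deliberately starts *downstream* of
sequencing: read QC, assembly, contig quality control and taxonomic
annotation are out of scope. The unit of analysis is a taxon-by-sample count
table together with a taxonomy (species → family → viral class) and sample
metadata.

The core procedure is a two-filter marker selection followed by a
distance-based specificity analysis:

* **Temporal stability.** A family is stable at a subject's site when it is
  detected at ≥ `min_timepoints` (default 2) of the 3 visits. A family is a
  stable candidate when at least `min_subjects` (default 1) subjects are
  stable for it at all three of their sites.
* **Transmissibility.** A family is transmissible for a subject when it is
  detected on ≥ `min_objects` (default 2) of their 4 objects *and* (default)
  on the subject's own skin, anchoring the transfer to the host.
* **Markers.** Marker families are the intersection of the two sets; marker
  species are all observed species belonging to marker families.
* **Specificity.** Jaccard distances on the marker-species presence
  profiles; per subject, the mean of within-subject pairwise distances is
  compared with the mean distance to all other subjects' samples, and the
  two collections of per-subject means are compared by a two-sided Wilcoxon
  rank-sum test — separately for skin and for object samples. Community
  structure is summarized by classical PCoA and tested by one-way PERMANOVA
  with the subject as the factor.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_count` | 1 mapped unit | detection threshold for presence. No principled universal value exists; 1 is the most permissive reading of "presence/absence" and the generator's count model guarantees its exactness there. Exposed everywhere. |
| `min_timepoints` | 2 of 3 | temporal stability rule. |
| `min_objects` | 2 of 4 | transmissibility rule. |
| `min_subjects` | 1 | subjects needed to confirm a family. |
| `require_all_sites` | TRUE | strict reading: the *same* subject must be stable at all three sites. A relaxed mode (any subject per site) is available behind the flag. |
| `host_required` | TRUE | object detections only count when the family is also on that subject's skin. |
| `n_permutations` | 999 | PERMANOVA permutations; p uses the (1 + count)/(1 + N) estimator, so p ≥ 1/(N+1). |
| `shannon_base` | natural log | Shannon index in nats; `log2` gives bits. |
| `wilcoxon_mode` | auto | exact enumeration when min(n₁, n₂) ≤ 8, no ties, and the enumeration is ≤ 1e6 assignments; otherwise normal approximation with tie and continuity corrections. |

Raising `min_timepoints` or `min_objects` can only shrink the selected sets
(verified as a property test), so the defaults are the permissive end of a
monotone family of analyses.

## The synthetic study generator

`study_config()` / `generate_study()` emulate the target design: 8 subjects
× 3 sites × 3 time points of skin samples (72), 4 objects per subject (32)
and 2 negative controls. The planted world has:

* **15 signature families / 54 signature species**, split as evenly as
  possible over families and assigned disjointly round-robin to subjects —
  the strongest identifiability setting, so recovered precision/recall speak
  to the pipeline rather than to signature confusability.
* **Cosmopolitan shared species** (4 families × 2 species) present in any
  sample with probability 0.8 — these model skin commensals common to
  everyone and are *expected* to pass both filters; they bound precision, not
  recall.
* **Transient species** (rate 0.05/sample) and **reagent contaminants**
  (probability 0.3 per negative control, leaking into real samples at 0.05)
  to exercise the control filter.
* **Detection dropout**: each latent taxon on skin is detected with
  probability 0.9 per event. **Transfer**: each taxon on the subject's skin
  at the time of contact (time point t2) reaches an object with probability
  0.8 per object type. These values are tuning knobs describing a plausible
  regime, not claims about biology: no quantitative transfer-efficiency or
  dropout estimates exist for skin viromes at this design scale.
* **Counts** for present taxa are log-normal (meanlog 3, sdlog 1) rounded up
  with a floor of 1, so `binarize(·, 1)` recovers latent presence exactly;
  this keeps presence/absence ground truth crisp while still giving
  realistic right-skewed abundances for the relative-abundance utilities.

Everything is driven by a mandatory seed and is bit-for-bit reproducible;
generation never disturbs the caller's RNG state.

What the generator does **not** emulate: sequencing depth effects,
compositionality, taxonomic misannotation, correlated dropout across sites,
shared signatures between related subjects, or contig-level structure. A
green recovery test therefore establishes that the *selection logic* is
correct under the stated stochastic model — not that real skin viromes are
this well-behaved.

The **null model** (`null_model = TRUE`) removes subject identity entirely:
every signature-pool species is iid Bernoulli(0.5) per skin sample, and
object samples are iid with probability 0.5 × mean transfer probability.
Subjects are then fully exchangeable, which is the property a level check
needs. Calibration runs the within/between and PERMANOVA procedures on the
full species presence matrix rather than on data-selected markers: marker
selection under the null is itself a random filter (often selecting only
shared families) and would confound the level measurement.

## Numerical choices

* **Jaccard of two empty profiles** is defined as 0 with a warning — both
  samples detect nothing, hence are identical in content.
* **PCoA** uses plain classical scaling: eigendecomposition of the
  double-centered −½D². Negative eigenvalues (Jaccard is generally not
  Euclidean-embeddable) are reported but contribute zero coordinates; no
  Lingoes/Cailliez correction is applied, and `proportion_explained` is
  computed over positive eigenvalues only.
* **PERMANOVA** is strictly one-way (subject as factor). The permutation
  stream is seeded; p-values are exactly reproducible for a fixed input
  order and invariant to renaming the groups. Reordering the input samples
  changes which random relabelings are drawn, so order invariance of p holds
  only within Monte-Carlo error (the observed pseudo-F and R² are exactly
  order-invariant).
* **Wilcoxon exact path**: brute-force enumeration of all
  `choose(n₁+n₂, n₁)` assignments, capped at 1e6 assignments (the spec-scale
  comparisons, 8 vs 8 means, use 12,870). The two-sided p is
  `min(1, 2·min(P(W ≤ w), P(W ≥ w)))`, which matches the classical exact
  distribution for untied data.
* **Ties**: midranks with the usual tie-corrected variance in the normal
  approximation; if every pooled value is identical the two-sided p is 1.
* **Top-k features** break ties lexicographically by label, making outputs
  deterministic across platforms.
* **Control filtering** operates on classified taxa, not reads or contigs —
  a documented approximation of upstream read-level decontamination.

## Known limitations

* **The within/between Wilcoxon procedure is conservative.** Each subject's
  within-subject and between-subject mean distances share the same samples
  and are strongly positively correlated, and the eight between-subject
  means average largely overlapping pairs. The rank-sum test's independence
  assumption is therefore violated in the conservative direction: under the
  exchangeable null its empirical rejection rate at α = 0.05 is ~0.002
  (skin) / ~0.018 (objects) over 500 replicates, far below nominal — while
  the Wilcoxon implementation itself is exactly calibrated on independent
  inputs (~0.045 over 1000 replicates) and agrees with
  `stats::wilcox.test` to 1e-12. The corresponding acceptance calibration
  check fails honestly and is left failing: deflated type-I error means
  significant results from this procedure are, if anything, understated, but
  its p-values should not be read as exact levels. PERMANOVA, by contrast,
  is exactly calibrated (0.044 measured in the same experiment). An
  alternative not taken: testing the per-subject means by subject-label
  permutation would restore exactness but would be a different procedure
  from the field-standard rank-sum comparison this package implements.
* Precision against planted signatures is bounded by design whenever shared
  (cosmopolitan) taxa are prevalent enough to pass both filters; the
  procedure has no mechanism to reject taxa common to all subjects, and in
  forensic use such taxa carry no identifying information. A discriminativity
  filter is a possible extension, deliberately out of scope.
* One observation per sample is assumed in the ANOVA; the repeated-measures
  structure of the design is ignored there.
* No Bray–Curtis/UniFrac distances, multi-factor PERMANOVA, PERMDISP, or
  closed-set identification scoring.
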