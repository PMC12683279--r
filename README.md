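# viromark

Forensic analysis of the human skin virome: marker selection and
individual-specificity statistics for presence/absence viral profiles.

## The problem

The skin virome — dominated by tailed bacteriophages (class
*Caudoviricetes*) with a smaller complement of human DNA viruses such as
*Papillomaviridae* and *Polyomaviridae* — is individually distinctive,
persists over weeks to months, and transfers to surfaces a person touches.
That combination makes viral taxa candidate forensic markers: a trace virome
recovered from an object could in principle be linked back to the person who
handled it.

`viromark` implements the table-level analysis for studies with this design:
subjects are swabbed at three anatomical sites (forehead, left hand, right
hand) at three time points (0, 6 and 12 weeks), and once from each of four
contacted objects (cell phone, door handle, fabric, plastic), alongside
negative control swabs. Starting from a taxon-by-sample count table, a
taxonomy and sample metadata, the package:

1. **Binarizes** counts into presence/absence profiles (threshold
   configurable, default 1 mapped unit) and removes any taxon detected in a
   negative control.
2. **Selects stable families** — detected at ≥ 2 of the 3 time points at
   each of a subject's three sites (for at least one subject).
3. **Selects transmissible families** — detected on ≥ 2 of the 4 objects a
   subject touched, anchored to that subject's own skin profile.
4. **Intersects** the two sets into marker families and collects the
   observed species they contain.
5. **Quantifies individual specificity** of the marker profiles with the
   Jaccard dissimilarity
   `d(A, B) = 1 − |A ∩ B| / |A ∪ B|`
   (0 = identical detection sets, 1 = disjoint), comparing per-subject mean
   within-subject versus between-subject distances by two-sided Wilcoxon
   rank-sum tests, and visualizing/testing community structure with PCoA and
   one-way PERMANOVA (pseudo-F on distance-based sums of squares,
   permutation p-value). Alpha diversity uses the Shannon index
   `H = −Σ pᵢ ln pᵢ` with one-way ANOVA across groups.

All statistics are implemented from first principles and verified in the
test suite against independent references (`vegan::vegdist`,
`vegan::adonis2`, `ape::pcoa`, `stats::wilcox.test`, `stats::aov`) and
against brute-force enumeration oracles.

A **synthetic study generator** reproduces the full sampling design with
planted subject-specific signature species, cosmopolitan shared taxa,
transients, reagent contaminants, detection dropout and per-object transfer
probabilities, so every stage of the pipeline is testable against a known
ground truth — no sequencing data required.

## Worked example

```r
library(viromark)

# A study shaped like the target design: 8 subjects x 3 sites x 3 time
# points + 4 objects each, 15 planted signature families (54 species),
# detection probability 0.9 on skin, transfer probability 0.8 to objects.
cfg   <- study_config(detection_prob = 0.9, transfer_prob = 0.8, seed = 42)
study <- generate_study(cfg)

report <- run_marker_analysis(study$table, study$taxonomy, study$metadata,
                              marker_config(seed = 1))
report
#> Virome marker report
#>   stable families:        19
#>   transmissible families: 25
#>   marker families:        19
#>   marker species:         62
#>   skin within/between Wilcoxon p = 0.0001554
#>   object within/between Wilcoxon p = 0.0001554

recovery_metrics(study$truth, report)$family$recall
#> [1] 1
```

All 15 planted families are recovered (recall 1); the extra selected
families are the cosmopolitan shared taxa, which genuinely satisfy both
filters in this world — with their default prevalence of 0.8 they are stable
and transmissible, just not subject-specific. The within/between Wilcoxon
p ≈ 1.6e-4 is the exact-enumeration minimum for 8 vs 8 per-subject means:
marker profiles are far more similar within a subject than between subjects.

Community-level structure on the object samples:

```r
pres    <- remove_control_taxa(binarize(study$table, 1), study$metadata)
md      <- study$metadata
obj_ids <- md$sample_id[md$sample_class == "object"]
d       <- jaccard_matrix(pres[, obj_ids])
permanova(d, md$subject_id[match(obj_ids, md$sample_id)],
          n_permutations = 999, seed = 1)
#> PERMANOVA (one-way): pseudo-F = 15.7814 (df 7, 24), R^2 = 0.8215,
#>   p = 0.001 (999 permutations)

h <- shannon_per_sample(study$table[, obj_ids])
one_way_anova(h, md$object_type[match(obj_ids, md$sample_id)])
#> one_way_anova test: statistic = 2.4319, p = 0.08597 (greater)
```

Object viromes cluster strongly by subject (PERMANOVA p = 0.001) while
Shannon diversity does not differ significantly across the four object
types — the pattern expected when a personal virome transfers comparably to
different materials.

## Command line

An executable wrapper is installed at `exec/viromark` inside the installed
package; equivalently call `viromark_cli()` from R:

```sh
viromark simulate  --seed 42 --output-dir study/
viromark markers   --table study/table.tsv --taxonomy study/taxonomy.tsv \
                   --metadata study/metadata.tsv --output-dir results/
viromark diversity --table study/table.tsv --taxonomy study/taxonomy.tsv \
                   --metadata study/metadata.tsv --permutations 999 --seed 1 \
                   --output-dir results/
viromark compare   --distances results/jaccard_skin.tsv \
                   --metadata study/metadata.tsv --class skin
```

Options can also be given in a JSON config file (`--config`); explicit flags
win. Every JSON output embeds the resolved configuration and seed. Exit
codes: 0 success, 2 input-validation error, 1 runtime error.

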