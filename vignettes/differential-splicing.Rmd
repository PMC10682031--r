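---
title: "Detecting and testing differential alternative splicing from junction reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and testing differential alternative splicing from junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffAS)
```

## The problem

Bulk RNA-seq of the same tissue in two animal breeds (or any two conditions)
yields, after alignment, two kinds of splicing evidence: *junction reads*,
fragments that span a splice junction and therefore witness one particular
exon joining, and *coverage*, the fragment depth over exons and genes. diffAS
turns a transcript annotation plus per-sample junction counts and coverage
counts into a ranked table of alternative-splicing (AS) events that differ
between the two conditions, and tests the resulting gene list for functional
over-representation.

The pipeline has four stages, each usable on its own:

1. **Event detection** (`detect_events`): exon clusters are reconstructed per
   gene and isoforms are compared pairwise; every local structural difference
   is classified into one of nine event types.
2. **Quantification** (`psi_table`, `compute_psi`): junction reads supporting
   inclusion or exclusion of each event's alternative region are counted and
   summarized as PSI (percent spliced in).
3. **Differential testing** (`diff_splice`): per event, a Fisher exact test
   on the junction 2x2 and a second Fisher exact test on exon-versus-gene
   coverage are combined (Fisher's method) and BH-adjusted; a fold rule with
   a condition-exclusivity clause gates significance tiers.
4. **Enrichment** (`enrich`): one-sided hypergeometric over-representation of
   the differentially spliced genes against a generic gene-to-term map.

A seeded generator (`sim_config`, `generate_annotation`, `simulate_counts`)
emulates the whole design with known ground truth, so the pipeline is
testable end to end without any external data.

## Event model and classification

Internally all coordinates are 0-based half-open; conversion happens only in
the readers and writers (GTF is 1-based inclusive, BED 0-based half-open).
A junction is identified by chromosome, intron interval and strand — strand
is mandatory because donor/acceptor polarity is undefined without it.

Within a gene, isoforms are compared pairwise. The pair is segmented at every
exon boundary; maximal regions not interrupted by *shared exonic* sequence
(shared intronic stretches do not re-synchronize the pair) are matched
against type templates in a fixed priority order:

`retain_intron` → `mutually_exclusive` → `cassette_multi` → `cassette` →
`alt5prime` → `alt3prime` → `altstart` → `altend` → `unknown`.

More global patterns must pre-empt the local donor/acceptor shifts they
contain — a retained intron, read naively, also looks like a pair of
alt-site shifts. Anything matching no template is reported as `unknown` with
the triggering structure recorded in `reason`, never dropped. Duplicate
events from different isoform pairs (same type, region and junction sets)
are emitted once, and output order is invariant to input order.

Conventions where the field has no single standard, chosen here once:

* **altstart / altend** are defined as non-overlapping first/last exon
  clusters (transcript-boundary variation), labeled strand-aware: `altstart`
  is variation at the 5' end of the transcript. Variation of the outer
  (non-spliced) boundary of a terminal exon is not an event — it is
  transcription start/end scatter, not splicing — and is ignored.
* **alt5prime / alt3prime** labels follow junction polarity: a shift of the
  lower-coordinate junction side is a donor (5') shift on the plus strand
  and an acceptor (3') shift on the minus strand. Flipping the strand of a
  fixed structure therefore swaps the labels, while mirroring the
  coordinates *and* flipping the strand preserves every label (the
  transcription-order structure is unchanged); both properties are asserted
  in the test suite.
* **mutually_exclusive** and the terminal types have two alternative
  regions; the one with the lower genomic start is reported as `alt_region`
  and its isoform's junctions as the inclusion side, which keeps the choice
  deterministic and order-invariant.
* **retain_intron** has no junction unique to the retaining isoform — the
  only junction in the region belongs to the spliced form. The event
  therefore carries the spliced intron junction as its exclusion side and
  the retaining isoform's flanking constitutive junctions as the inclusion
  side. This is a junction-only approximation: in real data those flanking
  junctions are shared by both isoforms, so retention PSI from junctions
  alone overstates inclusion; genuine retention evidence is exon-body
  coverage, which is exactly what the coverage P-value channel contributes.
  The generator uses the same convention, so simulated recovery is exact;
  on real data the coverage channel should be given more weight for this
  type.
* **unknown** events assign their two unique-junction sets to
  inclusion/exclusion by a canonical lexicographic rule — arbitrary but
  deterministic; PSI for unknown events should be interpreted only as a
  relative usage measure.

## Quantification

PSI uses per-side junction normalization,

$$\psi = \frac{I/n_I}{I/n_I + E/n_E},$$

with $I, E$ the summed inclusion/exclusion junction reads and $n_I, n_E$ the
junction-set sizes. The normalization corrects the inclusion form's larger
junction opportunity (a cassette offers two inclusion junctions against one
exclusion junction). Undefined PSI (no reads, or an empty junction side)
propagates as `NA`, never as 0. PSI is scale-invariant and monotone in the
inclusion total; both are property-tested.

FPKM (`compute_fpkm`) and the symmetric bounded-ratio expression matcher
(`expression_matched`, default 2-fold) support restricting cross-condition
splicing-rate comparisons to genes of similar expression; the 2-fold default
is a package choice exposed as a parameter.

## The differential test

Per event, with replicates pooled within condition (the default models a
design with one pooled library per condition; per-replicate tables can be
passed as additional samples):

* `p_junction`: two-sided Fisher exact test on the raw inclusion/exclusion
  totals between conditions. Exact, parameter-free, and consistent with the
  use of Fisher tests elsewhere in the pipeline. An all-zero table is
  untestable (`NA`) and excluded from adjustment.
* `p_coverage`: Fisher exact test on alternative-region versus
  remaining-gene coverage between conditions.
* `p_combined`: Fisher's method, $X^2 = -2(\ln p_1 + \ln p_2)$ against
  $\chi^2_4$; Stouffer combination is available via
  `combination_method = "stouffer"`. If only one channel is testable it
  stands in directly.
* `p_adjusted`: Benjamini–Hochberg across all testable events
  (`adjustment_method = "none"` disables).
* **Fold rule**: an event qualifies when one condition's level is at least 4
  times the other's, or when it is present in only one condition (exactly
  one level zero/undefined: `breed_exclusive`, infinite fold). The level is
  PSI by default; `level_stat = "inclusion_total"` exposes the raw-count
  reading for designs where PSI is not meaningful.
* **Tiers**: `EXT` below adjusted 0.01, `SIG` below 0.05, both ANDed with
  the fold rule; thresholds are parameters (`alpha_sig`, `alpha_ext`,
  `fold_threshold`). The two alphas are package defaults — the tier
  vocabulary is standard but no canonical thresholds exist for it.

The two Fisher tests draw on overlapping evidence in real data (junction
reads contribute to coverage), so Fisher's method is mildly anti-conservative
there; the test suite asserts a null false-positive bound of 0.07 at the 0.05
level and logs the observed value. In the generator the two channels are
sampled independently, so simulated calibration is close to nominal (observed
about 0.04–0.05 on 10,000 null events).

## Enrichment

`enrich` is a one-sided upper-tail hypergeometric over-representation test
per term, BH-FDR across terms. Depletion is not tested (only enrichment is
reported downstream). The background universe is a parameter; the natural
default is all genes of the annotation. No gene-length bias correction is
applied — a known limitation for splicing gene lists, since long multi-exon
genes harbor more events.

## The generator and what it does (not) emulate

`generate_annotation` plants each requested event in its own gene as exactly
two isoforms realizing that type's template — every one of the nine types is
expressible pairwise, and planted truth stays unambiguous. Genes alternate
strand and tile one synthetic chromosome without overlap. Template geometry
defaults: 200 bp exons, 300 bp introns, 60 bp alt-site shifts, 5 kb
intergenic gaps.

`simulate_counts` draws, per event, condition and replicate, a Poisson event
total (mean `event_depth`, default 500 — junction-level depth typical of a
deep pooled muscle library; a negative-binomial overdispersion knob exists
but is off by default), then an inclusion total that is binomial with
success probability $w = n_I\psi / (n_I\psi + n_E(1-\psi))$ — i.e.
per-junction read rates proportional to isoform abundance, the model the
normalized PSI estimator inverts — and splits reads uniformly across each
junction set. Whole-gene coverage is Poisson at
`gene_depth_factor * event_depth`; alternative-region coverage is binomial
within it at a psi-scaled length fraction. Default PSIs are 0.8 vs 0.2,
exactly the four-fold level difference the fold rule is built around;
`n_replicates` defaults to 1 per condition, modeling one pooled library per
breed. The seed fixes all output byte-for-byte.

What passing tests on this generator do **not** show about real data: no
read-level error or mapping bias, no shared junctions between events (each
event owns its gene), junction and coverage channels independent rather than
overlapping, and no overdispersion by default. The generator validates the
statistical machinery and the classifier, not alignment artifacts.

## Numerical choices

* `fisher_exact_2x2` sums hypergeometric point probabilities
  `<= observed * (1 + 1e-7)`; the relative tolerance makes tie inclusion
  robust to floating-point representation. The suite sweeps every table up
  to total 40 against a binomial-coefficient enumeration oracle (agreement
  to 1e-10) and cross-checks `stats::fisher.test`.
* Reported percentages use half-up decimal rounding (`round_half_up`), not
  banker's rounding — plain arithmetic then matches conventional printed
  percentage tables; distribution tables re-derive their percent column from
  their own counts as an internal consistency check.
* Event identifiers are `gene|type|start-end`, with a deterministic suffix
  only on collisions, so detector and generator agree on identity and output
  is reproducible under permutation.
* Problem sizes in the suite — five planted events per type for classifier
  recovery, depth 2000 for PSI recovery, 10,000 null events for calibration,
  500 events for power — were chosen to make each statistical bound sharp at
  desk scale while keeping the full suite fast.

## Known limitations

* Pairwise event definition (then deduplication) rather than full
  multi-isoform module decomposition; complex nested differences fall into
  `unknown`.
* Junction-only retention PSI (see above).
* No replicate-aware dispersion modeling (GLM/beta-binomial); replicates are
  pooled within condition before testing.
* No novel-junction discovery: the annotation defines the junction universe.
* Combined structures at one intron (donor and acceptor both shifted) are
  labeled `unknown`, not decomposed into two alt-site events.
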