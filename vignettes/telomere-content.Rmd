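---
title: "Estimating telomere content from whole-genome sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating telomere content from whole-genome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomotif)
```

## The problem

Human telomeres are tandem arrays of the hexamer TTAGGG capping
chromosome ends. They shorten with each cell division; telomere
maintenance is re-activated in most cancers, and the tumour/normal
difference in telomere content is a biologically meaningful readout that
whole-genome sequencing already contains for free. The catch is that
reference genomes do not assemble telomeres well: reads sequenced from
telomeric DNA either pile up at a small number of reference locations
(mostly chromosome ends) or fail to align at all. A whole-genome pass to
find them is wasteful; a targeted one needs a principled definition of
"telomeric read".

`telomotif` supplies both pieces: a two-stage repeat matcher that defines
telomeric reads, and a scanner that visits only user-defined include
regions plus the unmapped read pool.

## The two-stage matcher

Stage 1 is deliberately crude: an exact substring test for
`stage1_repeats` (default 3) concurrent copies of the canonical motif,
on either strand. With defaults, a read passes iff it contains
`TTAGGGTTAGGGTTAGGG` or `CCCTAACCCTAACCCTAA`. Exact string search is
cheap enough to apply to every candidate read, and a read sequenced from
genuine telomeric DNA essentially always contains at least one clean run
of three canonical repeats.

Stage 2 runs only on gate-passing reads and tolerates the sequence
variation real telomeres carry (telomere-variant repeats such as TGAGGG
or TCAGGG vary in the first half of the unit while the G-tract is
conserved). A stage-2 repeat unit is:

* forward: any 3 bases over {A,C,G,T} followed by `GGG`
  (the last `motif_length - wildcard_prefix` bases of the canonical
  motif);
* reverse: `CCC` followed by any 3 bases — the exact reverse complement
  of the forward scheme.

A hit is a *maximal chain* of at least `stage2_min_repeats` (default 2)
contiguous units: a run that cannot be extended by one more whole valid
unit at either end. `stage2_find()` returns every maximal chain on both
strands with its offset, matched substring, repeat count and strand. A
read counts once toward telomere content if it has any hit, however many
hits it contains; per-substring tallies are reported separately as
`motif_variants`.

```{r matcher}
spec <- build_motif_spec()
spec
stage2_find("GGCGGGTTAGGGTAAGGG", spec)   # degenerate units still match
classify_read("TTAGGGTTAGGG", spec)$stage2_passed  # gated out: too short for stage 1
```

### Why maximal chains rather than regex-greedy matching

The natural implementation of stage 2 is a greedy regular expression
(`(?:[ACGT]{3}GGG){2,}`, and the reverse-complement pattern; both are
still serialized into reports as documentation of the unit scheme). But
leftmost-greedy match selection is direction-dependent: what is leftmost
on a read is rightmost on its reverse complement, so on G/C-rich spans
where forward and reverse runs overlap — or where a long G-run supports
chains in more than one unit phase — regex-greedy output is not
symmetric under reverse complement. Strand symmetry is a property we
consider non-negotiable for a strand-agnostic content estimate, so hits
are defined as the set of *all* maximal chains per strand instead. On
ordinary reads (no phase-ambiguous G/C runs) this coincides exactly with
the regex output; in the degenerate cases it reports each overlapping
maximal chain once per strand and phase. Read-level classification —
the quantity every downstream number is built from — is identical under
either definition whenever any hit exists at all.

Other matcher conventions: sequences are uppercased before matching
(some BAM writers emit lowercase); `N` never matches any position,
including wildcard positions, so no-call runs are never counted as
telomeric; empty sequences fail stage 1.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `canonical_motif` | `TTAGGG` | repeat unit (any A/C/G/T word) |
| `stage1_repeats` | 3 | concurrent exact copies required by the gate |
| `stage2_min_repeats` | 2 | minimum contiguous units per stage-2 hit |
| `wildcard_prefix` | 3 | leading bases of each unit free to vary |
| `strands` | `both` | match forward, reverse complement, or both |

The stage-2 threshold of two concurrent repeats is the point at which
read selection for telomere analysis correlates best with laboratory
assays; the three-repeat stage-1 gate keeps the expensive confirmation
off the overwhelmingly non-telomeric majority of reads. Matching both
strands is essential: standard libraries sequence both telomere strands,
so forward-only matching would undercount content by roughly half.
`wildcard_prefix` must be smaller than the motif length; setting it to 0
reduces stage 2 to exact repeat matching.

## Scanning: include regions plus unmapped reads

`telomere_scan()` iterates the include regions of a coordinate-sorted,
indexed BAM via the index, in (chromosome, start) order, and then streams
the unmapped reads. Conventions:

* **Coordinates** are 1-based inclusive everywhere (samtools region
  strings); BED input is converted on import.
* **Overlap**: a record belongs to a region if its alignment overlaps it
  by at least one base. A record overlapping several include regions is
  counted once, attributed to the first containing region in sorted
  order; de-duplication is by record identity (name, flag, reference,
  position) and happens *before* filtering, so each record is examined
  or filtered exactly once.
* **Unmapped** means the record's own unmapped flag, whether or not a
  placement coordinate is stored (aligners place unmapped mates at their
  mapped mate's position). Placed-unmapped records are excluded from
  region queries and collected only by the unmapped pass, so no record
  can appear in two categories.
* **Filters**: duplicate, secondary, supplementary and QC-failed records
  are excluded by default — the input is required to be duplicate-marked
  precisely so that PCR/optical duplicates can be removed — and each
  switch is configurable, plus a minimum read length (default 0).
* **Workers** partition the region fetches (forked processes); results
  are merged in sorted region order, so the report is a pure function of
  the inputs and the worker count only affects wall-clock time. JSON
  reports contain no timestamps and do not echo the worker count, so
  re-runs are byte-identical.

`telomere_full_scan()` examines every record instead, adding a
`genomic` category for stage-2-passing mapped reads outside all include
regions. It exists as the validation oracle for region mode (restricted
to the includes and unmapped categories the two agree exactly, a
property the test suite asserts on every fixture) and as a way to audit
an include-region list: a large `genomic` tally means the list misses
telomere-read sinks on that reference. In region mode the `genomic`
category is absent from the report — those reads were never examined —
not present-with-zero.

The unmapped pass streams the whole file and filters on the unmapped
flag; unlike a region query it cannot use the index, which costs time on
very large BAMs but guarantees every unmapped record is seen exactly
once. No default include-region list ships with the package: the right
list depends on the reference build, so the user supplies one (INI
`[INCLUDES]` or BED).

## Quantification

With `raw` the stage-2-passing read count (by default from the includes
and unmapped categories; the category set is configurable, and `genomic`
can be added after a full scan) and `total` the mapped + unmapped record
count taken from the BAM index statistics *before* any filtering:

$$\mathrm{content} = \mathrm{raw} \times S / \mathrm{total}, \qquad S = 10^6$$

labelled telomeric reads per million records. The index-statistics
denominator avoids a second full pass; a strict mode errors instead of
falling back to a counting pass when the index is missing. Content is
deliberately not converted to base pairs: without a laboratory
calibration the honest unit is relative content, which is also all the
tumour/normal comparison needs:

$$\log_2 \mathrm{ratio} = \log_2(\mathrm{content}_T / \mathrm{content}_N)$$

The ratio is antisymmetric under swapping the pair. A zero content on
either side is an error naming the offending sample; an optional
pseudocount (off by default) can be added to both sides instead.
Degenerate denominators (`total = 0`) error rather than producing
infinities.

## The synthetic fixture generator

`generate_fixture()` emulates exactly the read classes the matcher
definitions imply, with analytically known expected tallies:

* pure forward/reverse telomeric reads (whole-motif tilings),
* degenerate telomeric reads (three exact canonical repeats — so the
  stage-1 gate passes, as it does for real telomeric reads — followed by
  wildcard-varied units),
* near-miss reads (isolated canonical repeats separated by spacers;
  fail the gate),
* background reads (uniform random, rejection-sampled until they contain
  no gate string and no stage-2 window on either strand, so expected
  counts are exact rather than probabilistic),
* unmapped telomeric reads, optionally stored with a placement
  coordinate inside an include region,
* duplicate-flagged telomeric copies at an existing coordinate,
* telomeric reads mapped outside every include region (visible only to
  the full scan).

Class membership is verified at generation time by a naive
substring/window checker independent of the package matcher, and the
truth table is computed from the construction, never by running the
matcher under test. Fixtures are written as SAM first (inspectable as
text), then sorted, compressed and indexed. Reads are single-end, one
fixed length, with flat quality and no sequencing errors: the fixtures
exercise counting, filtering, attribution and normalisation logic, not
robustness to base-calling noise, GC bias, indels in repeats or
interstitial telomeric sequence — passing tests demonstrate the
bookkeeping is exact, not that the matcher thresholds are optimal for
any particular instrument. `generate_ratio_pair()` plants binomially
sampled telomeric counts at chosen fractions in a tumour/normal pair,
so the expected log2 ratio is known up to binomial sampling error.

Test problem sizes: matcher properties run on 10,000 seeded random
sequences (length ≤ 30–60, enriched for motif fragments and N bases,
checked against a brute-force window-enumeration oracle); scan
properties on a grid of 24 fixtures (8 class mixes × 3 region layouts,
including overlapping regions and placed-unmapped mates) of ~15–60
records each; ratio recovery on pairs of 1,500–2,000 records with
planted fractions 0.01–0.05, asserted within 3 binomial standard errors
(the null pair must land within the same band of 0). These sizes make
every expectation exact or tightly bounded while keeping the whole suite
to a few minutes.

## Known limitations

* Telomere *content*, not length: no conversion to kilobases, no
  purity/ploidy adjustment of tumour estimates, no GC or coverage-bias
  correction.
* Mismatches inside the conserved G-tract (`GGG`/`CCC`) are never
  tolerated; a sequencing error there drops a unit from a chain.
* Interstitial telomeric repeats inside include regions are counted like
  any other telomeric read; full-scan mode makes genome-wide
  interstitial content visible but does not model it.
* CRAM input and mate-pair rescue are out of scope; SAM/BAM only.
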