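---
title: "Methods: identifying and quantifying non-coding RNA fragments"
author: "ncrf package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and quantifying non-coding RNA fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncrf)
```

## The problem

Small RNA sequencing of animal tissue captures not only mature miRNAs but
also short fragments processed from longer non-coding RNA precursors:
tRNA-derived fragments (tRFs/tiRNAs) and the analogous rRNA-, snoRNA- and
snRNA-derived fragments (rRFs, snoRFs, snRFs). Their production is often
end-biased — cleavage favours one terminus of the precursor — and both
abundance and end bias shift under stress, in a tissue- and sex-specific
way. `ncrf` implements the complete desk-scale analysis: classify reads
against an annotated ncRNA precursor reference, identify fragments, measure
end bias, positional distributions and fragment-to-precursor enrichment,
prorate counts across libraries of different depth, and filter downstream
target-prediction and pathway tables.

Because studies of this kind often do not deposit raw sequencing data, the
package is built around a synthetic-library generator with per-read ground
truth. Every stage of the pipeline is validated by parameter recovery
against that ground truth rather than against any particular dataset.

## The measurement model

**Read structure.** Raw reads are fixed 36-mers: a 7-nt adaptor, then an
insert of up to 29 nt from an ncRNA precursor. Inserts shorter than 29 nt
leave trailing cycles the instrument fills past the insert; the simulator
represents that tail with a sentinel run (see below).

**Assignment.** After adaptor removal, each insert is aligned against all
precursors by an ungapped sense-strand scan tolerating at most 2
mismatches, reporting a best (minimum-mismatch) hit — the policy of
`bowtie -v 2 --best`, re-implemented natively because references here are a
few thousand short sequences at most. Multi-hit ties are resolved
deterministically: by a configurable class priority
(miRNA > tRNA > rRNA > snoRNA > snRNA > mtRNA > ra-ncRNA > others
alphabetically), then smallest start offset, then lexicographic precursor
id. The matcher is pinned to an exhaustive position-by-position oracle in
the test suite. Antisense transcripts are a *class of the reference*, not a
strand decision at alignment time: small RNA references are conventionally
oriented, so only sense matching is performed.

**Fragment definition.** With 29-nt maximal inserts, a read of 29 nt or
more may be a full-length precursor read, while reads of at most 27 nt are
taken as processed fragments (ncRFs). The 28-nt length satisfies neither
definition; such reads are tallied separately (`role = "gap"`) rather than
silently absorbed into either set, because that is the only reading
consistent with both bounds. Fragments are classified by terminus: 5' when
the start offset is within `end_tolerance` (default 2 nt) of the precursor
start, 3' when the end is within the same window of the precursor 3'
terminus, with 5' taking precedence, and internal otherwise. The tolerance
absorbs ragged cleavage; it is exposed as a parameter and recorded in the
`ncrf_fragments` object.

**Filters and statistics.**

* Precursors with fewer than 5 total mapped reads in a pool are dropped
  entirely (fragments and full-length reads both count toward the
  threshold — the most literal reading of a "reads mapping to them"
  filter).
* The enrichment of processing is `n_fragment / n_precursor` per precursor,
  where the numerator counts inserts ≤ 27 nt and the denominator inserts
  ≥ 29 nt; 1 means one fragment per full-length read. Zero denominators
  yield a missing ratio, flagged but retained. Family aggregation (tRNA
  isoacceptors such as GlyGCC, snoRNA ids such as snoRA3) sums numerator
  and denominator over members *before* dividing.
* Positional distributions split every precursor, regardless of length L,
  into 10 equal bins with integer edges `floor(b*L/10)`; each fragment is
  counted once, in the bin containing its start. Start-position counting
  (rather than spreading coverage across bins) is deterministic and
  consistent with the 5'-bias measurement.
* Cross-pool comparison prorates counts by total assigned reads relative to
  a designated reference pool (scale factor `ref_total / pool_total`);
  passing fragment totals instead prorates by ncRF reads only.
* Downstream tables are filtered with strict cutoffs: target predictions at
  score > 80, pathways at Benjamini–Hochberg adjusted p < 0.05. BH is
  computed with `stats::p.adjust`; the test suite checks it against a
  hand-coded step-up double loop to 1e-12.

## The synthetic-data generator

`simulation_params()` fixes the study conditions; `make_reference()` and
`simulate_sample()` generate data under them.

* **Composition.** Defaults emulate a rodent brain library: miRNA 0.80,
  ra-ncRNA 0.11, tRNA 0.04, rRNA 0.02, snoRNA 0.015, snRNA 0.01, mtRNA
  0.005. Per-group multiplicative effects (the `REGION_SEX_TREATMENT` grid
  of three brain regions × two sexes × control/scatter-radiation) encode
  treatment shifts of the kind reported for irradiated animals: a miRNA
  decrease with an ra-ncRNA increase in male cerebellum, and miRNA
  decreases with mtRNA/ra-ncRNA increases in hippocampus of both sexes.
* **Fragment lengths.** Discretised normal on the 15–27 nt support with
  class modes near 22 nt and spread 1.5 nt. Published size distributions
  constrain only the modes (via boxplot summaries), so the shape is a
  package choice, configurable per class, and not claimed as any study's
  truth.
* **End bias.** Probability that a fragment is 5'-anchored rather than
  3'-terminal: strong 5' bias for tRNA (0.95), ra-ncRNA (0.9) and snRNA
  (0.9), mixed ends for rRNA (0.5) and snoRNA (0.35), neutral otherwise.
  An internal-fragment rate (default 0) exercises the pipeline's internal
  bucket; by default fragments are emitted only from termini, so ground
  truth aligns with the end-bias statistic being measured.
* **Full-length emission.** Probability that a read is a full-length 29-nt
  precursor prefix rather than a fragment: 0.3 for most classes, 0.2 for
  miRNA (mature miRNAs dominate miRNA-derived reads). This sets the
  expected enrichment ratio per class at
  `(1 - full_length_prob) / full_length_prob`.
* **GC content.** Precursor bases are drawn i.i.d. at a per-class GC
  target (0.40–0.55), checked by direct base counting in the tests.

**Padding.** Reads shorter than 36 nt after adaptor + insert are 3'-padded
with a sentinel `N` run marking the insert boundary. An earlier design
padded by continuing the adaptor sequence, with padding recognised only via
a ≥ 5-nt adaptor-prefix recurrence; that design leaves 2–4 nt of
unremovable padding on 25–27-nt fragments, which then pass the 2-mismatch
filter as spurious 29-nt "full-length" reads and systematically depress
measured enrichment by ~10% — enough to breach the package's own ±15%
recovery property at some precursors. Since true inserts never contain `N`,
the sentinel makes padding removal exact while preserving the raw-read
shape. `trim_adaptor()` still removes adaptor-continuation padding when a
user simulates it that way, but anchored at the read end (a trailing
segment of ≥ 5 nt continuing the adaptor cycle), so a chance adaptor-like
k-mer inside an insert is never mistaken for padding.

**What the generator does not emulate.** Sequencing error and quality
variation (qualities are constant; the emulated pipeline performs no
quality filtering), chromosomal placement and genome-first mapping,
isoform/modification chemistry of tRNAs, and realistic cross-mapping
between paralogous precursors (reference sequences are random, so
multi-mapping is rare; real references share sequence between family
members). Passing recovery tests therefore demonstrate correctness of the
measurement logic, not robustness to noisy real-world references.

## Worked example

```{r pipeline}
params <- simulation_params(seed = 101, n_reads = 5000)
ref <- make_reference(params)
sample_cer <- simulate_sample(params, ref,
                              c(region = "CER", sex = "M", treatment = "SR"))

assignments <- classify_reads(sample_cer$reads, ref, params$adaptor)
mapping_rate(nrow(assignments), sum(assignments$status == "assigned"))

profile <- class_profile(assignments, pool_id = "CER_M_SR")
profile$classes[, c("class", "fraction", "gc", "size_median")]

frags <- call_fragments(assignments)
head(enrichment(frags, by = "family"))
end_fraction_summary(frags)$classes
```

Recovery against ground truth:

```{r recovery}
realized <- sample_cer$realized$class_fractions
measured <- setNames(profile$classes$fraction, profile$classes$class)
round(measured[names(realized)] - as.numeric(realized), 4)
```

## Numerical and design choices

* **Determinism.** All simulator randomness derives from `params$seed`
  (sample-level seeds are folded with the group key); identical seeds give
  byte-identical FASTQ and TSV outputs. Table writers emit floats at 6
  decimals with fixed column order.
* **Coordinates.** 0-based half-open throughout, lengths in nt, so bin
  edges and end-window arithmetic are unambiguous.
* **Degenerate inputs.** Empty references and zero-assigned pools are
  errors; classes without fragments yield all-zero, flagged bin
  distributions; zero-denominator enrichment rows are retained with a
  missing ratio; classes with only internal fragments are flagged
  uninformative in end-bias summaries rather than dropped.
* **Reads under 15 nt** after trimming are discarded (status
  `"too_short"`): below the fragment-length support of this design, and
  configurable.
* **Change flags.** `compare_groups()` needs an explicit relative-change
  threshold (default 10%) because qualitative increase/decrease calls are
  otherwise not a deterministic function; `appeared`/`disappeared` require
  exact zeros on the control/treated side.
* **Problem sizes.** The recovery suites simulate pools of 10^4 reads over
  28 precursors (7 classes × 4), where class fractions are recovered within
  ±2% absolute, per-class end bias within ±0.05 (classes with ≥ 200
  terminal fragments), and per-precursor enrichment within ±15% relative
  (precursors with ≥ 100 reads). These sizes give binomial standard errors
  comfortably inside those bands while keeping the full suite under a
  minute.

## Limitations

The matcher is exact but quadratic (insert length × reference size); it is
intended for curated ncRNA references of at most a few thousand short
precursors, not genomes. Target-prediction and pathway tables are consumed
as files exported from external tools (miRDB- and DAVID-style); the package
deliberately does not re-implement target scoring or enrichment testing,
only the score/significance filtering and set-overlap accounting applied to
their outputs.
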