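# ncrf

Identification and quantification of **non-coding RNA fragments (ncRFs)**
— tRNA-, rRNA-, snoRNA- and snRNA-derived fragments (tRFs/tiRNAs, rRFs,
snoRFs, snRFs) — from small RNA sequencing libraries, for researchers
profiling how ncRNA processing shifts across tissues, sexes and
treatments.

## What it computes

Reads (36-nt raw reads: 7-nt adaptor + ≤ 29-nt insert, or pre-trimmed
inserts) are assigned to an annotated ncRNA precursor reference by an
ungapped, sense-strand, best-hit scan tolerating at most 2 mismatches
(`bowtie -v 2 --best` semantics with deterministic tie-breaking). On top of
the assignments the package computes:

* **Class profiles** — per-class read fractions of 1, pooled GC content,
  and insert-size distributions with five-number summaries.
* **Fragment calling** — a read is an ncRF when its insert is ≤ 27 nt;
  reads ≥ 29 nt are full-length precursor reads; 28-nt reads belong to
  neither set and are tallied apart. Fragments are 5′, 3′ (within a 2-nt
  end window, 5′ taking precedence) or internal. Precursors with < 5
  mapped reads are excluded.
* **Enrichment of processing** — per precursor or per family (tRNA
  isoacceptor, snoRNA id):

  `ratio = n_fragment (≤27 nt) / n_precursor (≥29 nt)`

  A ratio of 1 means one fragment per full-length read; family aggregation
  sums numerators and denominators before dividing.
* **Positional bin distributions** — each precursor split into 10 equal
  bins; fragment starts counted per bin and normalised per class.
* **Prorated counts** — cross-pool rescaling by library size to a
  designated reference pool.
* **Comparative tables** — control-vs-treated change flags
  (up/down/unchanged/appeared/disappeared at an explicit relative-change
  threshold), target-prediction filtering (score strictly > 80),
  Benjamini–Hochberg pathway filtering (adjusted p strictly < 0.05), and
  Venn region counts for gene/term sets.

A seeded **synthetic-data generator** (`simulation_params()`,
`make_reference()`, `simulate_sample()`) emulates fragment-processed small
RNA libraries — ~80% miRNA composition, class-specific fragment-length
modes near 22 nt, configurable 5′/3′ cleavage bias, group-specific
composition shifts — and emits per-read ground truth, so the whole pipeline
is validated by parameter recovery without any external dataset.

## Worked example

```r
library(ncrf)

params <- simulation_params(seed = 101, n_reads = 5000)
ref    <- make_reference(params)
samp   <- simulate_sample(params, ref,
                          c(region = "CER", sex = "M", treatment = "SR"))

a <- classify_reads(samp$reads, ref, params$adaptor)
mapping_rate(nrow(a), sum(a$status == "assigned"))
#> [1] 100

profile <- class_profile(a, pool_id = "CER_M_SR")
profile$classes[, c("class", "fraction", "gc", "size_median")]
#>      class fraction    gc size_median
#> 1    miRNA   0.7410 0.482          22
#> 2    mtRNA   0.0052 0.416          22
#> 3     rRNA   0.0202 0.496          22
#> 4 ra-ncRNA   0.1684 0.374          23
#> 5    snRNA   0.0108 0.500          22
#> 6   snoRNA   0.0152 0.456          23
#> 7     tRNA   0.0392 0.528          21

frags <- call_fragments(a)
head(enrichment(frags, by = "family"), 4)
#>      family class n_fragment n_precursor ratio defined
#> 1 miRNA_001 miRNA        758         170  4.46    TRUE
#> 2 miRNA_002 miRNA        749         189  3.96    TRUE
#> 3 miRNA_003 miRNA        703         195  3.61    TRUE
#> 4 miRNA_004 miRNA        739         202  3.66    TRUE

end_fraction_summary(frags)$classes[, c("class", "frac_5prime")]
#>      class frac_5prime
#> 1    miRNA       0.489
#> 2    mtRNA       0.643
#> 3     rRNA       0.493
#> 4 ra-ncRNA       0.894
#> 5    snRNA       0.811
#> 6   snoRNA       0.278
#> 7     tRNA       0.962
```

Reading the output: this simulated scatter-irradiated male cerebellum pool
maps completely to the reference (the simulator emits no contaminant
reads); miRNA dominates at 74% with ra-ncRNA second, mirroring the
group-adjusted class weights; the miRNA enrichment ratios sit around 4 —
four fragments per full-length read, as implied by the class's 0.2
full-length emission probability; and the 5′-fraction column recovers the
configured cleavage biases (tRNA 0.96 ≈ strongly 5′-anchored, snoRNA 0.28 ≈
3′-dominant). Measured class fractions match the per-read ground truth
exactly on this pool:

```r
realized <- samp$realized$class_fractions
measured <- setNames(profile$classes$fraction, profile$classes$class)
round(measured[names(realized)] - as.numeric(realized), 4)
#>    miRNA    mtRNA ra-ncRNA     rRNA   snoRNA    snRNA     tRNA
#>        0        0        0        0        0        0        0
```

The methods vignette (`vignettes/ncrf-methods.Rmd`) documents the
measurement model, the simulator's defaults and what they do and do not
emulate, and every numerical design choice.

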