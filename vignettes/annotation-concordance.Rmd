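---
title: "Methods: transcript-aware annotation and concordance statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-aware annotation and concordance statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varconcord)
```

This vignette documents the statistical and algorithmic choices behind
`varconcord`: the annotation model, the concordance statistics, the
population-genetic summaries, and the synthetic-data generator used to
validate all of them. It is written for a reader who wants to know *why*
each default is what it is, not just what the functions do.

## 1. The annotation model

### Transcript models and the genomic partition

A transcript model (`transcript_model()`) is a strand-aware set of exon
intervals on one contig, optionally with a CDS sub-interval for coding
transcripts. Every genomic base is assigned a *fine consequence term*
relative to each transcript it falls near:

| rank | fine term       | definition                                                    |
|-----:|-----------------|---------------------------------------------------------------|
| 1    | `exonic_coding` | inside an exon and inside the CDS span                        |
| 2    | `splice_site`   | intronic, within min(2, *w*) bases of an exon boundary        |
| 3    | `splice_region` | intronic, within *w* bases of an exon boundary                |
| 4    | `ncRNA_exonic`  | exon of a transcript with no CDS                              |
| 5    | `UTR5`          | exonic, 5′ of the CDS span (strand-aware)                     |
| 6    | `UTR3`          | exonic, 3′ of the CDS span (strand-aware)                     |
| 7    | `intronic`      | between exons, outside any splice window                      |
| 8    | `upstream`      | within *f* bases 5′ of the transcript span                    |
| 9    | `downstream`    | within *f* bases 3′ of the transcript span                    |
| 10   | `intergenic`    | none of the above for any transcript                          |

where *w* is `splice_window` (default 6) and *f* is `flank_window`
(default 1000). Lower rank means more severe. The `splice_site` term is
deliberately defined as `min(2, splice_window)`: the canonical donor and
acceptor dinucleotides are a biological constant, so widening
`splice_window` widens only `splice_region`, never `splice_site`.

The default *w* = 6 reflects the common convention that intronic bases
within a few positions of the junction can affect splicing; the default
*f* = 1000 is a deliberately narrow promoter/terminator-proximal window.
Both are parameters of `annotator_config()`, not constants, because tools
in this space genuinely disagree about them — that disagreement is
precisely what the concordance machinery is for (see `test-workflow.R`'s
flank-window experiment).

### Two reporting conventions

`annotate_variants()` supports two styles that mirror the two conventions
found in practice:

* **`exhaustive`** reports every (variant, transcript) consequence. A
  variant in an exon of one transcript and the intron of an overlapping
  transcript yields two rows.
* **`precedence`** collapses to a single most-severe call per variant,
  breaking rank ties by the lexicographically smallest `transcript_id` so
  the output is a deterministic function of the input.

A multi-base REF allele (a deletion) may straddle a boundary; the
annotator assigns the most severe term over the bases of the REF
interval, which is the conservative convention (a deletion touching one
coding base is coding).

### Two independent implementations

The package intentionally contains two annotation code paths:

1. `annotate_variants()` — an interval-index route
   (`GenomicRanges::findOverlaps` with `maxgap = flank_window - 1`,
   then a vectorised positional classifier per transcript).
2. `label_genome()` + `classify_from_track()` — a brute-force route
   that paints a per-base severity track for a whole contig and reads
   classifications off it.

They share no classification code, so agreement between them on random
variants is a genuine cross-check, used both in the test suite and in
`scripts/acceptance.R`. The generator builds on the painted track (route
2), which means "planted category is recovered by the annotator" is also
a route-1-vs-route-2 comparison, not a tautology.

## 2. Variant normalisation

VCF records are decomposed and normalised before annotation:

* **Multiallelic splitting** (`split_multiallelic()`): one record per ALT
  allele, with genotypes recoded per allele (the focal allele becomes 1,
  other ALTs become 0, missing stays missing). Symbolic and breakend
  alleles (`<DEL>`, `]p]N`, `*`) are counted and dropped — the package
  models short sequence-resolved variants only.
* **Allele trimming** (`normalize_alleles()`): shared suffix bases are
  removed, then shared prefix bases, each only while both alleles keep at
  least one base. This is the standard parsimony rule; it preserves the
  anchor base of indels. Left-alignment across repeat tracts requires the
  reference sequence, which VCF + GFF3 inputs do not provide, so two
  representations of the same indel inside a repeat run may remain
  distinct — a documented limitation, not a bug.
* **Variant keys**: `chrom:pos:ref:alt` after normalisation
  (`variant_key()`). All cross-strategy bookkeeping is keyed on these.

Variant types follow length rules: SNV (1 → 1, different), insertion
(len(ALT) > len(REF)), deletion (len(REF) > len(ALT)), MNP (equal
length > 1), other. Transitions are A↔G and C↔T; `summarize_variants()`
reports Ts/Tv as `NA` (never 0/0 = 0) when there are no transversions.

## 3. Harmonisation and concordance

Two annotation strategies rarely share a vocabulary, so fine terms are
mapped onto nine broad categories (`exonic`, `splicing`, `ncRNA_exonic`,
`UTR5`, `UTR3`, `intronic`, `upstream`, `downstream`, `intergenic`)
before comparison. The default map collapses `exonic_coding → exonic`
and `splice_site`/`splice_region → splicing`; custom maps are loaded with
`load_harmonization_map()`, which validates totality (every fine term
mapped, every target a known category).

For each category `c`, `compare_assignments()` computes over the union of
variant keys:

* `n_A`, `n_S` — keys assigned `c` by each strategy;
* `n_shared` — keys assigned `c` by both;
* `n_union = n_A + n_S − n_shared` (maintained as an identity);
* `match_rate_A = n_shared / n_A`, `match_rate_S = n_shared / n_S`,
  `union_share = n_shared / n_union`.

Rates with a zero denominator are `NA`, never 0: "no variants in this
category" and "complete disagreement" must not be conflated. A key
annotated by only one strategy counts toward that strategy's totals and
toward the union — private annotations are disagreements, not data to be
discarded. The `total` row aggregates key-level agreement across all
categories.

Two closed-form facts anchor the test suite: comparing an assignment
with itself gives `union_share = 1` everywhere, and independently
re-drawing both assignments uniformly over the nine categories gives
expected agreement 1/9 (verified to within 3 binomial standard errors at
n = 10,000).

## 4. Population subsetting and summaries

`subset_population()` restricts a multi-sample VCF to a sample subset,
drops sites with no remaining non-missing ALT allele, and recomputes
`AC`, `AN`, and `AF` from the retained genotypes (FORMAT is reduced to
`GT`). It is validated against a brute-force genotype recount, checked to
be idempotent, and checked to be monotone (sites kept for a subset are
kept for the full panel).

`snp_density()` bins variants into fixed windows with
`bin_index = (pos − 1) %/% bin_size` (default 1 Mb), so position 1 falls
in bin 0 and bin boundaries are independent of the data. Bin counts are
conserved: they always sum to the number of variants.
`known_sites_annotate()` flags membership in external site lists, by
exact `chrom:pos:ref:alt` key when `allele_aware = TRUE` (default) or by
position otherwise.

## 5. The synthetic-data generator

`generate_layout()` and `generate_variants()` produce a fully synthetic
study: a genome, transcript models, a multi-sample VCF, and a
ground-truth table mapping every variant key to its *planted* broad
category.

**What it emulates.** The generator reproduces the structural features
the pipeline is sensitive to: multi-exon transcripts on both strands,
coding and non-coding transcripts, occasional overlapping transcripts,
a configurable category mix (defaults dominated by intronic and
intergenic variants, as in real call sets), a tunable SNV/indel split
(default 0.9), a target Ts/Tv ratio implemented by drawing each SNV as a
transition with probability `tstv / (1 + tstv)` (default target 2.0, the
genome-wide human value; uniform substitution choice gives 0.5), an
allele-frequency spectrum (default Beta(0.3, 3), a rare-skewed shape),
and Hardy–Weinberg genotypes for a configurable sample panel.

**How planting works.** Each base of the genome is labelled by the
painted severity track, bases are grouped by broad category, and variant
positions are sampled within the requested category's positions (with
per-category counts from the configured mix by largest-remainder
rounding, so counts sum exactly to `n_variants`). Deletions are
rejection-sampled onto runs of constant category so the planted label is
unambiguous. Because categories partition the genome, every planted
label is correct by construction — and recovering 100% of them through
the file-level pipeline (GFF3 and VCF round-trips included) is the
package's primary end-to-end check.

**What it does not emulate.** There are no sequence-context effects
(mutational signatures, CpG), no linkage disequilibrium between sites,
no population structure among samples, no genotyping error or missing
calls, and reference/alternate bases are random letters — the genome has
no actual sequence. The generator validates annotation and accounting
logic, not population-genetic inference.

**Determinism.** Every generator function takes a seed through its
config object and is a pure function of (config, seed); fixtures written
twice are byte-identical. The pipeline itself writes no timestamps, and
its `manifest.json` records an md5 checksum per output, so whole runs can
be compared byte for byte.

## 6. Default problem sizes

The package's standard validation scale — chosen as a balance between
statistical power and test-suite runtime — is a 2 × 5 Mb genome, 50
transcripts, 20,000 variants across 96 samples. At this scale the
category mix leaves hundreds of variants in even the rarest category,
Ts/Tv estimates at n = 50,000 SNVs have binomial standard errors near
0.002, and the full test suite (over 10,000 assertions, most of them
property-based comparisons against independent oracles) runs in about
two minutes.

## 7. Limitations

* No codon-level consequences (missense/synonymous/stop): the model
  stops at the exonic/CDS level because no reference sequence is
  modelled.
* Parsimony trimming without left-alignment (see §2).
* Symbolic/structural alleles are dropped, not annotated.
* The severity precedence is a single fixed ranking; real tools embed
  subtler, sometimes context-dependent orderings. The ranking is a
  parameter (`annotator_config(precedence = ...)`) for exactly that
  reason.
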