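---
title: "Detecting nuclease-induced double-strand breaks from tag-integration sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nuclease-induced double-strand breaks from tag-integration sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbtrace)
library(dplyr)
```

## The experimental readout

Tag-integration sequencing (the GUIDE-seq family of assays) marks
double-strand breaks (DSBs) in living cells by supplying a short
double-stranded oligodeoxynucleotide donor — the *Tag* — that is captured at
break sites by end-joining repair. Nested PCR with Tag-specific primers then
amplifies the junctions between the Tag and the genome, and paired-end
sequencing reads them out: Read 1 begins with a unique molecular index (UMI)
and a sample barcode, Read 2 begins with a Tag-primer remnant followed by
genomic sequence that starts exactly at the Tag–genome junction. For
nuclease experiments two libraries are made per sample, one with the forward
and one with the reverse Tag primer, so every break can be observed from
both sides; for transposon integration-site mapping a single
arm-specific-primer library is used instead.

`dsbtrace` implements the downstream computation: read filtering, UMI
consolidation, junction-track construction, peak calling with a
bidirectional support rule, guide matching for on/off-target classification,
cleavage-geometry profiling, a transposon mode with dinucleotide motif
enrichment, and amplicon validation metrics. A built-in simulator generates
read sets with planted ground truth so every stage is testable without
external sequencing data.

## Coordinates and the junction convention

All coordinates are 0-based, half-open. A cut at coordinate $c$ means the
top strand is nicked between bases $c-1$ and $c$. The fragment to the right
of the cut yields reads that map to the + strand and start at $c$; the
fragment to the left yields reads mapping to the − strand whose junction is
the rightmost aligned base + 1. Using the raw alignment start for both
strands would shift − observations by the read length, so
`add_junctions()` reports the alignment *end* for − strand records.

A staggered cut with a 5′ overhang of $k$ nt nicks the bottom strand at
$c + k$; after end repair fills in the overhang, the left fragment's
junction moves to $c + k$. The signed offset between the modal − and +
junctions therefore recovers the overhang directly: 0 for blunt Cas9-like
cuts, +1 for the 1-nt overhangs seen at many SpCas9 sites, and a
two-component mixture such as {+4, +5} for Cpf1/Cas12a-like staggered
cutting. This quantitative modal-offset rule is a formalisation of what is
usually judged visually from overlapping read pileups; the thresholds
(an offset must carry ≥ 20% of the mass to count as modal; a modal
|offset| ≥ 2 or two modal offsets label a site "staggered-multi") are
package choices, not experimental constants.

## The calling model

Junction positions vary by a few bases because of end resection and repair,
so positions are first pooled across strands and libraries per chromosome
and grouped greedily into *hotspot regions*: adjacent positions strictly
closer than `max_gap` (default 10 bp) share a region. Pooling is deliberate
— the two sides of one break must land in the same region to be
co-evaluated. Within each region, sliding windows of width `window`
(default 10 bp, step 1) are counted per (strand × library) class, and peaks
of the summed count vector are taken as candidate sites. A peak is a strict
local maximum; a plateau yields one peak at its leftmost window, and peaks
closer than `min_peak_separation` (default = window, to avoid calling one
break twice) keep only the higher one, ties resolved leftmost.

A candidate becomes a DSB site when at least `min_support` consolidated
molecules (default 6, i.e. "more than five") support it **on both the + and
− strands**, or on one strand **from both the forward- and reverse-primer
libraries**. We read the threshold as applying to each evidence class
separately, which is the stricter interpretation; `support_rule = "total"`
switches to the pooled reading. The consensus cut position is the modal
junction inside the peak window (ties leftmost). No background model or
FDR is applied — the assay's specificity comes from the fixed
molecule-count rule, as in the field's standard pipelines.

Support counts *molecules*, not reads: reads with the same mapping
position, strand, library and UMI are consolidated to one observation
(`consolidate_umi()`; exact UMI match by default, with optional directional
1-edit clustering).

## Guide matching

Each called site's ±25 bp flank is scanned with the guide spacer on both
strands. With unit match/mismatch scores and gap penalties high enough to
forbid gaps, the best Smith–Waterman local alignment of the full spacer is
simply the placement minimising substitutions, with spacer bases hanging
off the window counted as mismatches and `N` always a mismatch; ties break
to the leftmost genomic start, then the + strand. Sites with 0 mismatches
are on-target, 1–6 (`max_mismatches`) off-target, anything else unmatched.
Gapped ("bulged") placements are deliberately not counted as off-targets —
mismatch counting is defined for substitutions only; the PAM-side adjacent
bases are reported as an annotation, and a strict mode additionally
requires them to match the PAM pattern (NGG 3′ for SpCas9, TTTV 5′ for
Cpf1). The default matches the spacer alone, because the printed decision
rule of this assay family is spacer-only.

## Transposon mode and motif enrichment

Sleeping-Beauty-style integration is mapped from a single
arm-specific-primer library, so the bidirectional rule cannot use two
libraries: a site is kept when its total support is at least
`min_support_transposon` (default 5, "at least five reads") with both
strands represented. The ±5 bp flank windows of the called sites are
stacked into a position frequency matrix, and the dinucleotide at the
central step — the insertion point — is tested for enrichment against a
background dinucleotide distribution with a one-sided exact binomial test
per dinucleotide (`stats::binom.test`), results sorted by p-value. Both a
genome-frequency background and a within-flank shuffle background are
provided, since the appropriate null depends on how sites were ascertained;
the genome background is the default in the pipeline. This targeted
PFM-plus-binomial design replaces de-novo motif discovery on purpose: the
hypothesis (TA preference at the insertion step) is specific, and an exact
test against an explicit background is easier to calibrate than a
general-purpose motif finder.

## Amplicon validation metrics

For targeted deep sequencing of an edited locus, each read is aligned to
the amplicon reference (read-global/reference-local dynamic programming via
`Biostrings::pairwiseAlignment`; the reference must be ≤ 10 kb — whole
genomes belong to an external aligner). Inserted and deleted segments are
extracted with 0-based boundaries, and reads are classified wildtype,
indel, donor-containing, or unaligned. A read counts as unaligned when its
alignment score falls below 20% of a perfect full-length match — unrelated
reads score near zero while reads carrying even a full-length Tag insertion
stay well above. An insertion is a *Tag (donor) insertion* when a local
alignment against the Tag spans at least 16 bp at ≥ 50% identity; the
original e-value criterion of short-sequence aligners is replaced by this
self-contained length/identity rule, which is the decision rule the assay
actually states. Indel frequency is indel reads / total reads and the
integration rate donor reads / total reads, as exact ratios; whether
unaligned reads enter the denominator is a flag (off by default).

## The simulator

`simulate_genome()` draws a uniform-composition background genome at a
configurable GC fraction and plants, at each requested cut position, a
protospacer carrying exactly the requested number of substitutions against
the guide plus a PAM realising the IUPAC pattern (Cas9-like geometry: cut
3 bp from the PAM-proximal boundary; Cpf1-like: 18 bp). A collision check
guarantees no second guide-like match (≤ 6 mismatches) within 100 bp of a
planted site, redrawing background if needed, so recovery tests are
unambiguous. `simulate_reads()` emits one read pair per molecule with the
junction geometry described above, a random Tag orientation (hence a 50/50
split between forward- and reverse-primer libraries), random UMIs, optional
PCR duplicates (same UMI and coordinates, independent errors), flat-rate
substitution errors, and uniform-random single-read background
integrations as the false-positive null. Truth tables record every read's
origin. The simulator writes FASTA/FASTQ and a truth-based SAM, so the
pipeline's pre-aligned mode runs without an external aligner.

What the simulator does *not* emulate — and hence what passing recovery
tests do not show about real data: indels at the junction beyond the
overhang geometry, position-dependent quality profiles, chimeric reads,
chromatin-dependent capture efficiency, and mappability structure of a real
genome. Defaults were chosen once to mirror a typical experiment at desk
scale: 100-bp reads, 8-nt UMIs, a 10-nt Tag-primer remnant on Read 2,
41% genomic GC, 100 read pairs per planted site, and editing efficiency 1
for tag-read simulation (efficiency matters for the amplicon simulator,
where it sets the planted indel/integration fractions). The bundled default
Tag is a synthetic 35-mer constructed to the GC-balance property of such
donors (16/35 = 45.7% GC); it is not a deposited oligonucleotide.

## Numerical and design choices

* **Boundary semantics.** "Less than 10 bp" gaps share a hotspot (a gap of
  exactly 10 splits); "more than five reads" means ≥ 6; "at least five"
  means ≥ 5; reads shorter than 50 bp after trimming are discarded (a 50-bp
  mate survives). These are asserted at their exact boundaries in the test
  suite.
* **Tie-breaks.** Peak plateaus → leftmost window; equal-support modal
  junction → leftmost position; equal-mismatch guide placements → leftmost
  start, then + strand; equal read counts in reports → (chromosome,
  position) order. All deterministic, so identical inputs reproduce
  identical outputs byte for byte.
* **Tag-prefix tolerance.** Read 2 must start with the Tag remnant within
  1 substitution (no indels) by default; the tolerance is a parameter since
  the assay description only requires the Tag "at the beginning" of Read 2.
* **Quality trimming** removes terminal bases below Phred 20 from both
  ends; the threshold is a package default, not an assay constant.
* **Degenerate inputs.** Empty read sets flow through every stage and yield
  empty tables; sites too close to a chromosome end are annotated "edge"
  rather than matched; single-strand sites get an "undetermined" geometry.
* **Problem sizes.** The shipped tests and the acceptance script run a 1-Mb
  genome with 10 planted sites at 100 reads/site plus 500 background
  integrations for recovery, 3 sites at 80 reads for geometry, 100 TA
  insertions at 10 reads for the transposon mode with 100 null trials, and
  1000 amplicon reads — sizes chosen so the full battery completes on a
  laptop in minutes while keeping every threshold away from its noise
  floor.

## Limitations

Alignment to a full genome is out of scope: the package consumes SAM/BAM
from an external aligner (or the simulator) and only aligns amplicon-scale
references itself. Off-target *scoring* models (CFD/MIT), background
modelling from control samples, error-correcting barcode designs, and
repair-outcome prediction are non-goals. Indel-containing junction reads
shift individual junction observations; the modal statistics tolerate this
but per-read offsets at very low coverage (< ~20 molecules per strand) can
mislabel geometry, which is why `infer_cut_profile()` reports the full
offset distribution alongside the label.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  genome_length = 200000,
  planted_sites = planted_site(cut_position = c(50000L, 120000L),
                               mismatches = c(0L, 3L)),
  reads_per_site = 60, background_integrations = 50, seed = 1
)
sg <- simulate_genome(cfg)
sr <- simulate_reads(sg)
sam <- tempfile(fileext = ".sam")
write_sam(sr, sg$genome, sam)

run <- run_rgn_mode(sg$genome, cfg$grna, sam = sam)
run$hits |> select(chrom, cut_position, mismatches, classification,
                   read_count)
glance(run$sites)
autoplot(run$sites)
```
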