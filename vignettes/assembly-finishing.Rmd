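---
title: "Finishing telomere-to-telomere assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finishing telomere-to-telomere assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2tfinish)
```

`t2tfinish` implements the computational finishing stages that turn a
chromosome-scale draft assembly into a gap-free, telomere-to-telomere (T2T)
one, in the form they are applied to plant genomes such as allotetraploid
rapeseed (*Brassica napus*, AACC, 19 chromosome pairs): long-read
filtering, tiered flank-anchored gap filling, telomere detection and
chromosome-end patching, centromere delimitation, k-mer quality control,
structural-variant (SV) screening against gene sets with ecotype
frequencies, and Ks-based divergence dating. Every stage can be exercised
on synthetic genomes with planted ground truth, so the whole pipeline is
testable on a laptop without any sequencing data.

This vignette explains the models and procedures, the tunable parameters
and their defaults, and the design decisions taken where the methods
literature leaves choices open.

## The synthetic genome model

`make_genome()` builds chromosomes with the architecture the pipeline is
designed to resolve:

* exact tandem telomeric arrays at both termini — the plant telomeric
  7-mer `CCCTAAA` on the 5' (left) end and its reverse complement
  `TTTAGGG` on the right, 100 copies per end by default;
* one centromeric satellite array per chromosome: a random monomer of 176
  bp (a typical plant satellite scale; the monomer length is configurable)
  repeated to a configurable array length and placed mid-chromosome;
* non-overlapping genes, a configurable fraction flagged as
  flowering-related, placed outside the centromere and the telomeric
  arrays;
* i.i.d. background sequence with configurable GC content — the simplest
  null that still exercises alignment anchoring.

All truth tables use 0-based half-open coordinates, the package-wide
convention. Generators are pure functions of `(config, seed)`:
`degrade_to_draft()` masks chosen intervals with `N` (recording the masked
sequence for oracle comparisons), `simulate_reads()` emits error-free
substrings with filterable metadata (ONT ultra-long and HiFi profiles;
a uniform substitution mode exists for robustness tests),
`simulate_end_reads()` emits reads clamped to the chromosome termini as
sequenced molecules running off a physical chromosome end would be, and
`make_variant_accession()` applies typed SVs (INS/DEL/DUP/INV) with full
coordinate lift-over so that every edit is exactly reversible.

What the generator does **not** emulate: platform-specific error profiles,
heterozygosity, satellite monomer divergence, segmental duplication, or
Hi-C data. Tests passing on these fixtures therefore demonstrate
algorithmic correctness on clean signals, not robustness to every artefact
of real data; the structural layout (arrays, genes, gaps, planted SVs) is
what carries over.

## Read filtering

Two ONT stages mirror a pass filter followed by an assembly-input filter:
`pass` keeps mean Phred quality >= 7 and length >= 10 kb; `assembly`
additionally requires length >= 30 kb and a Filtlong-style percent score
strictly > 90. HiFi subreads keep `passes >= 3` and `SNR >= 2.5`.
Boundary semantics are literal: thresholds phrased as "below X filtered"
drop strictly, so equality is kept, while the "> 90%" score is a strict
keep. The mean Phred quality and the Filtlong percent score are distinct
scales and are carried as separate metadata fields. Reads with missing
metadata are neither kept nor counted as failures; they are reported
separately as unscorable.

## k-mer statistics

All k-mer work uses canonical k-mers (the lexicographic minimum of a
k-mer and its reverse complement) with `k = 19` by default, skipping any
window containing `N`. Counting is done in C++ over 2-bit-encoded 64-bit
codes (`k <= 31`).

**Genome size.** Depths below `error_depth_cutoff` (default 3) are
discarded and the size is `sum(depth * count) / peak`. The peak is
located as the mode of a lightly smoothed histogram and refined to the
count-weighted mean depth of bins below twice that mode, rather than
taken as the raw integer mode: depth along a genome is correlated over a
read length, so the realized histogram at, say, 30x from 15-kb reads is
lumpy and the integer mode alone is biased by several percent. The
twice-the-mode ceiling keeps the peak local to the single-copy
component — repeat k-mers sit at multiples of the coverage and must add
instances to the numerator without dragging the peak upward, which is
what lets the estimator count a satellite array by its copy number. For
an idealized single-bin histogram the refinement is skipped and
`{depth 50: 1e6 k-mers}` gives exactly 1 Mb at peak 50. The estimator
assumes a single coverage component above the cutoff; it does not model a
heterozygous half-depth peak (a full mixture model is out of scope).

**Assembly QV.** With `m` of `t` assembly k-mer instances missing from
the read set, the per-base error probability is
`E = 1 - (1 - m/t)^(1/k)` and `QV = -10 log10(E)` — the Merqury
formulation. A single interior substitution makes exactly `k` instances
missing. When nothing is missing the QV is reported at a cap (default 99,
since `-10 log10(0)` is undefined) and flagged.

**Assembly statistics.** N50 is the length of the smallest contig in the
minimal set of largest contigs covering half the assembly — always a
member of the input multiset. Mapping rate and per-target covered
fractions come from interval unions of alignment records.

## Tiered gap filling

Gaps are maximal runs of at least `min_n = 10` consecutive `N` (no
standard exists for how many Ns make a gap; 10 avoids counting isolated
ambiguous bases). For each gap the donor sets are tried in fixed priority:
tier 1, alternative assemblies; tier 2, ONT reads; tier 3, HiFi reads.
Donors are aligned to the gap plus flanks; flanks start at 5 kb and
escalate through 10/15/20 kb while no donor spans (5–20 kb being the
range such procedures use). A donor qualifies when one donor sequence has
aligned coverage reaching at least `conf = 500` bp into both flanks
beyond the gap edges — an anchor-confidence default of this package, not
an external standard. Among qualifying donors of the best tier, the
longest aligned block wins; ties break on match count, then donor name.
The chromosome between the innermost flank anchors is replaced by the
donor sequence between the corresponding donor anchors, so filled output
differs from the draft only inside those anchor windows. Unfillable gaps
are reported `unfilled`, never thrown.

The built-in aligner finds k-mers (`k = 31`) unique in both sequences and
chains them colinearly (longest increasing subsequence on the query
side). On error-free fixtures it is exact; for real data a PAF from an
external long-read aligner can drive `select_patch()` instead.

One identifiability limit is worth stating plainly: inside a *perfect*
tandem array every flank k-mer recurs in every repeat unit, so no
flank-anchored method — whatever the aligner — can uniquely place a donor
for a gap buried deeper than the permitted flank range inside the array.
`random_gap_spec()` therefore keeps its demo gaps (plus the widest flank)
out of the planted satellite array; a deliberately planted in-array gap is
reported `unfilled`. Real satellite monomers diverge by a few percent,
which is precisely what makes such gaps fillable in practice.

`verify_fills()` checks each junction of a filled gap for at least one
read alignment covering `junction +- 1 kb` (default), labelling fills
`spanned`/`unspanned`.

## Telomeres

`count_motif()` counts non-overlapping occurrences of `CCCTAAA` or its
reverse complement, whichever strand gives more (the 7-mer cannot overlap
itself; degenerate motifs resolve left-greedy). `call_telomeres()` counts
in a terminal window of 20 kb and calls an end present at >= 100 motif
copies; a chromosome with both ends present is T2T. Neither the window
nor the threshold has a published standard; both are explicit, logged
parameters, and the synthetic truth (100 planted copies) sits exactly at
the default threshold.

End patching follows the highest-evidence-read rule: among reads assigned
to an end (alignment terminus within 50 bp of the chromosome end; a read
qualifying for both ends of a tiny sequence goes to the left end by a
fixed tie rule), the read with the most motif copies is the template. Its
exact overlap with the terminal 1 kb anchor of the chromosome defines the
junction; only the distal overhang is appended, so bases proximal to the
junction are never modified, and the patch is a no-op unless it adds at
least `min_gain = 100` bp of telomeric array. On error-free fixtures the
template is used verbatim; consensus polishing of the patch is delegated
to external tools via the returned report.

## Centromeres

Candidate centromeres are continuous clusters of high tandem-repeat
density co-located with low gene density. Tandem density comes from a
single-pass periodicity scan: a position is flagged when its 13-mer
recurred at a lag within the satellite period range (2–2000 bp); window
profiles average the flags. This detects tandemness directly without
re-implementing a full tandem-repeat finder; where Tandem Repeats Finder
output is available, `read_trf_dat()` and `trf_density()` build the same
window profile from it so external evidence drives
`delimit_centromeres()` unchanged. Defaults — window 100 kb,
step 10 kb, `tandem_min` 0.5, `gene_max` 1 gene/Mb, `min_cluster` 300 kb,
`merge_gap` 2 steps — are package decisions (no published values exist
for them) and are all configurable. Qualifying windows are merged, and
cluster boundaries are refined to the extent of 1-kb bins with flagged
density >= 0.5, so a half-overlapping boundary window neither inflates
nor truncates the call; on planted arrays both boundaries land within
one window step of truth. The largest cluster per chromosome is primary,
the rest secondary. `centromere_composition()` reports per-repeat-class
covered fractions by interval union, so overlapping same-class features
never push a fraction above 1.

## Structural variants and ecotype screening

The internal caller pairs chromosomes by name, chains unique-31-mer
anchors (subsampled at a 50 bp stride), and inspects inter-anchor
segments after trimming their common prefix/suffix: query surplus is an
insertion, reference surplus a deletion, an equal-length reverse
complement an inversion, anything else `OTHER`. Breakpoints are
left-normalized (VCF-style) before classification — without this, an
anchor k-mer crossing the end of a duplicated unit yields a rotated
insertion that defeats the adjacency test — and an insertion equal to the
reference segment immediately up- or downstream is reported as a tandem
duplication covering its source span. Anchors can overlap across a
junction by a few coincidentally matching bases; the gap start is shifted
back by the overlap, which the previous anchor's match guarantees to be
safe. On error-free fixtures types and lengths are exact and positions
are recovered to within the anchor stride (inversion lengths can shrink
by a base or two where boundary bases coincide with their reverse
complement context — genuine representational ambiguity). The caller is a
desk-scale stand-in: real comparisons import syri output verbatim via
`read_syri()`/`svs_from_syri()`.

The gene screen flags a gene when an SV intersects
`[gene_start - 5000, gene_end + 5000)` — one closed-open window, a point
anchor for insertions, all SV types weighted equally. Ecotype frequencies
are affected-accessions / accessions per ecotype, and a gene is
ecotype-diagnostic only at strict 1.0 vs 0.0 fixation between the two
configured groups (default spring vs semi-winter + winter, matching the
vernalization split of rapeseed panels).

`novel_regions()` reports the complement of the aligned-interval union of
a focal assembly against another, filtered to a minimum length, with
fully contained genes flagged novel.

## Ks dating and consistency arithmetic

`ks_peak()` takes a Gaussian-kernel density (Silverman's bandwidth by
default) over `[0, 3)` — values above the saturation cutoff are excluded
— and returns the global mode with all local maxima listed.
`divergence_time()` applies the molecular clock `T = Ks / (2r)` with
`r = 1.4e-8` synonymous substitutions per site per year; the factor 2
counts both diverging lineages. A Ks peak of 0.30 dates the Brassica
whole-genome triplication near 10.7 Mya and 0.40 dates the split from
*Arabidopsis thaliana* near 14.3 Mya. `consistency_report()` is pure
numerator/denominator arithmetic rounded half-up at the printed precision
(2 decimals for ratios and percentages, 1 for fold-changes), so printed
values such as 2.66 genes per family (124 774 / 46 851) or a 4.4-fold N50
gain (50.70 / 11.47 Mb) are reproducible to the digit.

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open internally; GFF3 and syri input
  (1-based inclusive) are converted on read, writers convert back.
* Minus-strand PAF records keep query coordinates in forward-query space;
  nothing is silently flipped.
* `ks_peak()` on identical samples returns that value directly (a kernel
  bandwidth cannot be estimated from zero variance).
* Empty inputs: an empty FASTA yields an empty set with a warning; a
  draft without gaps fills to itself with an empty report; an empty SV
  spec returns the reference unchanged.
* Rounding for printed numbers is half-up, not banker's.

## Problem sizes used in tests

The shipped test-and-acceptance fixtures use 4 chromosomes of 0.5 Mb with
13 gaps for gap filling, 8 ends for telomere recovery, 20 random
centromere arrays of 0.3–2 Mb, an 8-accession ecotype panel on a 0.5 Mb
chromosome, and a 1 Mb genome at 30x for k-mer QC — sizes chosen so the
full suite exercises every code path in about two minutes on one core
while leaving every detection margin (coverage, array length, SV spacing)
at realistic ratios rather than inflated ones.
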