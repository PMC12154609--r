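---
title: "Dissecting sex-chromosome sequence architecture with parscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting sex-chromosome sequence architecture with parscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parscope)
```

## The problem

Mammalian Y chromosomes are mosaics of a few characteristic sequence
classes. A terminal **pseudoautosomal region (PAR)** still crosses over with
the X every male meiosis and is therefore held essentially identical to its
X counterpart. **X-transposed regions (XTR)** arose by recent X-to-Y
duplication and sit near 99.5% identity. **Ancestral gametologs** survive
from the original autosome pair and are deeply diverged. **Ampliconic**
sequence consists of euchromatic intrachromosomal repeats above 99% identity
over more than 10 kb, often arranged in head-to-tail tandem arrays, and
**heterochromatic** satellite blocks occupy centromere- and telomere-adjacent
territory. parscope implements the computational steps by which such a
mosaic is measured and annotated from assembled sequence — windowed
exact-match dot plots, collinear X–Y identity profiling, pseudoautosomal
boundary (PAB) detection, amplicon and tandem-array calling, five-class
segmentation, GC statistics, Hi-C flank-link contig ordering, and
male/female k-mer subtraction — together with a synthetic genome generator
that reproduces the architecture, so every stage can be validated against
known truth.

## The synthetic generator and its presets

`simulate_pair()` turns a declarative `blueprint` (an ordered list of
segment specs per chromosome, plus homology links) into sequences and exact
truth annotations. Homologous blocks share an ancestor: one chromosome
carries the ancestral copy, the other a copy with independent per-site
substitutions at the segment's divergence, so the pairwise mismatch count is
exactly Binomial(length, divergence). Tandem-array copies each diverge from
a unit ancestor at half the nominal inter-copy rate, giving pairwise
inter-copy divergence of the nominal rate to first order. Satellite
segments are exact head-to-tail repeats of a packaged synthetic 234-bp
monomer. Base composition is i.i.d. at each segment's GC target (0.40
background; 0.46 for XTR segments, emulating the elevated GC of recently
recombining sequence).

The shipped presets encode the study conditions the package is validated
against:

* `PAR`: an 18-kb + 282-kb terminal homologous block at divergence
  5/282000 (five expected differences over 282 kb), inside a 300-kb
  functional PAR, on 400-kb scaffolds whose remainder diverges at 2%.
* `XTR`: a 207-kb homologous block at divergence 0.005 (99.5% identity) on
  a 515-kb scaffold, with asymmetric satellite blocks.
* `MED14`: a 5-kb retrogene pair at divergence 0.07 (93% identity).
* `SSTY_ARRAY`: 24 copies of an 85-kb unit (2.04 Mb) at inter-copy
  divergence 0.005. The copy number follows from the 2-Mb span divided by
  the 85-kb unit.
* `LARGEST_AMPLICON`: 3.5 Mb of tandem repeats at 99.5% inter-copy
  identity. The unit length (50 kb x 70 copies) is a free choice — only the
  span and identity are constrained — and is recorded as such.
* `HET_ASYMMETRY`: X and Y scaffolds whose satellite content differs
  exactly 4-fold (160 kb vs 40 kb), aligned to 10-kb window boundaries.
  The scaffold sizes themselves are arbitrary.
* `FULL_ARCHITECTURE`: a 520-kb collinear X/Y pair carrying every class at
  once (XTR, ancestral, tandem array, satellite, terminal PAR, interleaved
  unrelated sequence), used for end-to-end classification recovery. All
  segment lengths are multiples of 10 kb so that window boundaries align
  with class boundaries; the array's inter-copy divergence is 0.002 so that
  250-bp dot windows chain into contiguous diagonals.

What the generator does *not* emulate matters for interpreting green tests:
there are no indels or rearrangements (all homology is gap-free and
collinear), no interspersed repeats (only satellite tandem repeats), no read
quality profile, and i.i.d. base composition rather than real k-mer
statistics. Passing tests demonstrate that the algorithms recover the
architecture they are specified against, not that they are robust to
alignment gaps, segmental deletions, or real repeat landscapes.

## Dot plots

`self_dotplot()` and `pair_dotplot()` report every pair of w-bp windows
(default step = w, matching the "100% identity in a w-bp window" figure
convention) that match exactly, on either strand, using canonical-key
hashing; windows containing non-ACGT characters are skipped. The output is
a match table, checked against a brute-force all-pairs oracle in the test
suite; rendering (`plot()` method) is a thin layer. Reverse-complement
matches in self mode are reported with i < j; palindromic window pairs
appear on both strands, as the brute-force definition implies.

```{r dotplot-example}
g <- simulate_pair(build_blueprint("SSTY_ARRAY", list(
  seed = 1, "y.2.length_bp" = 170000L, "y.2.copies" = 2L)))
d <- self_dotplot(g$sequences["chrY"], w = 250)
print(d)
```

## Identity profiles, the PAB, and the recombination rate

`sliding_identity()` compares collinear, gap-free sequences in fixed
windows (default 1 kb); windows with no comparable bases are *missing*, not
zero. `detect_pab()` scans from the telomeric end and reports the first
window of the first run of at least `k_consecutive = 5` windows below
`threshold = 99.9%`. Neither value is dictated by the biology alone: 99.9%
at 1-kb windows cleanly separates a PAR-like stratum (a handful of
differences per hundreds of kb, so nearly all windows at 100%) from the
99.5% XTR stratum, whose windows fall below 99.9% about 96% of the time;
five consecutive windows make a spurious boundary call vanishingly unlikely
in either direction. `homology_arcs()` merges windows above a threshold
(default 95%) into arcs carrying their weighted mean identity.

`par_recombination_rate()` encodes the obligatory-crossover argument: one
crossover (50 cM) per male meiosis over the PAR gives `50 / (L / 1e6)`
cM/Mb — about 166.7 for a 300-kb PAR, printed in the field as "approximately
166".

```{r pab-example}
gp <- simulate_pair(build_blueprint("PAR", list(seed = 1)))
prof <- sliding_identity(gp$sequences["chrY"], gp$sequences["chrX"])
detect_pab(prof)
par_recombination_rate(300000)
```

## Amplicons and tandem arrays

`diagonal_runs()` chains forward dot matches whose offsets agree within
500 bp and whose along-diagonal gaps stay below 2 kb; `call_amplicons()`
then recomputes ungapped base-level identity over each chained interval
pair and applies the >99% / >10 kb definition. Identity is recomputed
rather than inferred from match density because the chained span includes
the windows that failed to match. Heterochromatic intervals can be
excluded, honouring the *euchromatic* qualifier of the amplicon definition
(satellite arrays are self-similar at every offset and would otherwise
flood the calls). `tandem_periodicity()` takes the modal 1-kb offset bin —
in a c-copy array the unit offset carries c-1 diagonals, every multiple
fewer — and `array_span()` measures the anchor-side interval of unit-offset
matches, extended by one unit because the last copy only pairs leftward.
The gap (2 kb), offset tolerance (500 bp) and bin width (1 kb) defaults are
package conventions; at the study's inter-copy identities (99.5%) a 250-bp
window matches with probability ~0.29, so consecutive matched windows on a
diagonal sit ~875 bp apart on average and a 2-kb gap limit keeps unit
diagonals chained while separating unrelated repeats.

## Five-class segmentation

`classify()` labels every base by precedence heterochromatic > PAR > XTR >
ancestral > ampliconic > other. Identity arcs computed at the ancestral
floor (70%) are assigned to strata by their mean identity: >= 99.9% and
telomere-anchored is PAR (unanchored near-identity falls back to XTR);
[95, 99.9) is XTR; [70, 95) is ancestral. The 70% floor and the 99.9%
ceiling are package conventions chosen to separate strata that sit near
99.99%, 99.5% and 85-93%; only the 95% arc threshold is field-standard.
The ancestral band is a nucleotide-identity proxy for what is really a
gene-homology concept, and blended adjacent strata (e.g. an XTR arc
physically contiguous with a PAR arc) would average into a single arc —
in the architectures modelled here the strata are separated by diverged
sequence, as on the real chromosome. Heterochromatin comes from
`satellite_profile()` (k = 21 monomer k-mer coverage, 10-kb windows,
>= 50% fraction — conventions again), and the ampliconic footprint from
`call_amplicons()`. The output tiles the sequence exactly; on ten
`FULL_ARCHITECTURE` replicates the per-base agreement with truth exceeds
99%, with errors confined to window-quantised boundaries.

## GC statistics

`windowed_gc()` drops windows straddling region boundaries (a conservative
choice: no window mixes classes). `gc_elevation_test()` is a label
permutation test on window GC values with an add-one p-value, so p is never
zero and the test is exact under exchangeability; the permutation scheme is
canonicalised (sorted pool, smaller group resampled) so relabelling the two
classes changes only the sign of the statistic, not the p-value. Window GC
values within a class are i.i.d. under the generator, so the nominal size
holds; on real chromosomes autocorrelation of GC along the sequence would
make window-level permutation anticonservative — block permutation would be
the extension.

## Hi-C flank linkage

`unique_kmers()` indexes genome-wide-unique canonical 32-mers;
`filter_pairs()` keeps mate pairs whose 100-bp end footprints overlap a
unique position — on *both* ends by default, the stricter of the two
readings of "overlapping these positions" (`either_end = TRUE` gives the
other). `flank_link_matrix()` counts links between 50-kb contig end
windows, and `order_and_orient()` joins flank pairs greedily by count
(lexicographic tie-break) under a simple-path constraint. Contigs shorter
than twice the flank become a single ambiguous flank that can join two
neighbours but cannot be oriented. Mate pairs are simulated with the
locus-pair contact model — uniform anchor, contact probability decaying as
d^-1 — under which adjacent-flank counts dominate; no deduplication is
performed. Recovery is meaningful up to whole-scaffold reversal, and at
10,000 pairs over five 100-kb contigs succeeds in >= 9/10 seeds.

## Electronic subtraction

`build_kmer_set()` collects canonical k-mers (k = 31, odd so no k-mer is
its own reverse complement; multiplicity >= 2 to suppress singleton error
k-mers) from female reads; `classify_reads()` computes, per male read, the
fraction of its k-mers absent from that set, and calls reads at >= 0.5
Y-candidates. All three parameters are package conventions. Reads from
X-shared Y sequence (PAR, XTR) are deliberately *not-Y*: the target is
male-specific sequence. At 20x error-free coverage of a three-component
(autosome + X + Y) genome, precision and recall both exceed 0.95.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open everywhere; BED on disk. Window starts
are multiples of the step; trailing partial windows are dropped, so
profiles and GC tables only ever aggregate full windows. `count_differences`
ignores any position where either base is not ACGT. `detect_pab` treats
missing-identity windows as divergent (absence of evidence of identity).
`tandem_periodicity` errors on aperiodic input rather than guessing;
`array_span` errors when no match sits at the requested unit. Permutation
and bootstrap routines accept a seed and restore the caller's RNG state.

## Problem sizes

The validation suite runs the full presets exactly as specified (282-kb PAR
block over 200 replicates for the difference-count mean; 20 replicates for
the XTR and Med14 identities; single 2.04-Mb and 3.5-Mb arrays for the
dot-plot geometry) and scales the property experiments to sizes where their
statistics are already decisive: five 100-kb contigs for scaffold recovery,
~120-kb genomes at 20x for subtraction, 520-kb chromosomes for
classification, 500 replicates for the permutation-test size. These sizes
are the package's validation conditions; the algorithms themselves carry no
size assumptions beyond memory.

## Known limitations

Collinear, substitution-only homology is assumed throughout: none of the
identity machinery tolerates indels, so real X/Y comparisons need a
collinear projection first. Amplicon identity is ungapped. The ancestral
stratum is an identity band, not an orthology call. Satellite detection
requires the monomer library; diverged satellites below exact 21-mer
matching escape it. The Hi-C step consumes pre-mapped pair tables and does
no contact-map normalisation or misassembly detection.
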