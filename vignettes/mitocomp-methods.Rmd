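---
title: "Methods: comparative mitochondrial genome analysis with mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitochondrial genome analysis with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

`mitocomp` implements the comparative-genomics workflow used in insect
mitochondrial (mt) genomics: composition and skew statistics, codon usage,
conserved intergenic spacer consensus, tRNA stem substitution patterns,
alignment conservation, control-region structural elements, and
codon-partitioned supermatrix assembly. This vignette documents the models
and procedures, the tunable parameters and their defaults, the numerical
choices made where the design was genuinely open, and what the synthetic
data generator does and does not emulate.

## Coordinates and data model

Internally every interval is zero-based, half-open, on the J-strand (the
deposited strand of the circular molecule); all printed and interchange
formats (GenBank, feature tables) use 1-based inclusive coordinates.
Features that wrap the origin of a circular genome are stored as an ordered
span pair rather than by rotating the sequence, so deposited coordinates are
preserved exactly. Gene names are normalized through a packaged, editable
synonym table (`inst/extdata/gene_synonyms.tsv`); the Leu and Ser tRNAs
carry isoacceptor suffixes (L1 = CUN, L2 = UUR, S1 = AGN, S2 = UCN). A
record lacking a control-region feature gets one inferred as the region
between srRNA and tRNA-Ile, flagged `inferred` so downstream reports can
state its provenance.

## Composition and skews

Strand asymmetry is measured as AT-skew = (A − T)/(A + T) and
GC-skew = (G − C)/(G + C), computed at full precision and rounded only at
presentation (three decimals; percentages to one decimal). Ambiguity codes
are excluded from counts. A zero denominator flags the corresponding skew
as undefined rather than coercing it to zero. Whole-genome skews are
computed on the deposited J-strand. Codon-position composition drops
trailing incomplete codons and is invariant to whether genes are profiled
separately or concatenated.

Start/stop tabulation reports the literal first codon (the canonical set in
these genomes includes ATN, TTG, GTG and TCG; no filtering is applied) and
the trailing codon when the CDS length is a multiple of three. Otherwise
the trailing one or two nucleotides must be `T` or `TA` — the incomplete
stops completed to TAA by polyadenylation; both are accepted and flagged
distinctly, and any other remainder is reported as an annotation
inconsistency naming the gene.

RSCU uses the invertebrate mitochondrial genetic code with stop codons
excluded: RSCU(c) = n(c)·|F|/Σn(F) within each synonymous family F. Codons
of a family with zero usage are reported as absent (`NA`) rather than zero,
so RSCU = 0 identifies an unused codon in a used family.

## Spacer consensus

Named intergenic spacers are the literal sequence strictly between two
annotated features. Orientation: when both flanking genes lie on the
N-strand the spacer is reported reverse-complemented; mixed-strand flanks
are reported J-strand. Panels are aligned with a small deterministic
progressive aligner (profile vs next sequence, in input order) scoring
match +1, mismatch 0, gap −2, with terminal gaps free. Ties prefer the
diagonal, then consuming a profile column. Under this scoring an alignment
that shifts a shorter sequence into a free terminal gap can beat one with
an internal gap — the alignment of `ACGT` with `AGT`, for example,
optimally places the `A` of `AGT` opposite the `C` region via a leading
terminal gap (score 2) rather than an internal gap opposite the `C`
(score 1). The aligner's tests are frozen against an exhaustive
enumeration oracle under exactly this scoring. Sets whose length ratio
exceeds 2 are refused and referred to manual review.

The consensus is a presence-set IUPAC code per column: the set of distinct
non-gap residues (input ambiguity letters expanded) maps to the code that
denotes exactly that set (W = {A,T}, M = {A,C}, H = {A,C,T}, B = {C,G,T},
N = all four). Frequency thresholds are deliberately not used: a single
taxon carrying T among four A's yields W, which is what makes the printed
motifs reproducible from a five-genome panel. Columns that are gaps in at
least half of the rows are trimmed, so terminal extensions present in only
one or two taxa (handled by the free terminal gaps) do not inflate the
conserved core.

## tRNA stems and the five substitution patterns

Cloverleaves are parsed from a sequence, a dot-bracket structure and an
arm-boundary map; stems are defined by the arm map's expected extents (the
k-th pair joins `stem_start5 + k − 1` with `stem_end3 − k + 1`), and
positions left unpaired by the structure remain mismatch candidates.
tRNA-Ser(AGN) is represented with an empty DHU stem. The canonical pair set
is {A–U, U–A, G–C, C–G, G–U, U–G}; G–U must be canonical for the classical
hemi-compensatory example G–U → A–U to be a canonical-to-canonical change.

Pair changes are classified undirected, comparing stems position-by-position
from each stem's 5′ end (no sequence alignment inside stems; surplus
positions of a deeper stem are reported as unaligned rather than
force-aligned):

* equal pairs → `identity`;
* both canonical, one base changed → `hemi_cbc`;
* both canonical, both bases changed, one pair the reversal of the other →
  `mbc` (the mirror test precedes the compensatory one, since the
  intermediate state of a mirrored change is non-canonical);
* both canonical, both changed otherwise → `cbc`;
* exactly one canonical → `rbc`;
* neither canonical → `nrbc`.

Reparative changes are defined in the literature against a majority
background; in an undirected pairwise comparison that direction is not
recoverable, so `rbc` covers canonical ↔ non-canonical in either direction
and the output annotates which taxon holds the canonical state, preserving
both readings. The classifier is verified against an independent oracle
over all 256 ordered pair comparisons; the six categories partition that
space and the function is symmetric in its arguments.

## Conservation profiling

%INUC is the percentage of alignment columns in which every row carries the
same unambiguous non-gap residue. Gap-containing columns count as variable
*and stay in the denominator* — this is the convention under which 974
identical columns out of 1350 give 72.1%. Because the alternative
denominator (excluding gap-only columns) is also defensible, profiles
report both (`percent_INUC` and `percent_INUC_nogap`). Identity is
case-insensitive; ambiguity codes never count as identical. A+T is computed
over non-gap residues. rRNA structural domains are consumed as column-range
tables (no structure inference) and yield per-domain sub-profiles whose
identical-column counts sum to the total when the domains tile the
alignment. The %INUC ~ A+T association across gene panels is the Pearson
coefficient; zero variance in either variable is flagged undefined.
Group summaries flag groups represented by fewer than three genomes.

## Control-region elements

Four element classes are detected with these defaults:

| element | definition | default threshold |
|---|---|---|
| poly-T / poly-A | maximal single-base run | ≥ 10 nt |
| (TA)n stretch | maximal exact (TA)n/(AT)n run, whole units | ≥ 3 units |
| macro repeat | flank-maximal exact repeated substring, ≥ 2 non-overlapping copies separated by ≥ 1 nt | ≥ 30 bp |
| stem-loop | perfect inverted repeat, Watson–Crick + G·T pairs | stem ≥ 6 bp, loop 3–20 nt |

"Non-tandem" is operationalized as an occurrence gap of at least 1 nt;
abutting copies are a different phenomenon (tandem arrays) and are reported
in a separate list. Repeats are exact matches only — the reported copies in
real control regions are identical, and a mismatch-tolerant mode is out of
scope. Maximality means no single-character extension left or right
preserves *all* occurrences; sub-repeats whose occurrences all lie within a
longer reported repeat are suppressed. The finder does a level-wise
duplicated-substring scan (a repeated (L+1)-mer implies a repeated L-mer,
so the occupied lengths are contiguous) and is tested for exact agreement
with a brute-force all-substrings oracle on seeded random sequences.

Stem-loops allow zero mismatches; a candidate loop whose innermost flanking
bases could still pair (with the shrunken loop staying in range) is
subsumed by the longer-stem hairpin rather than double-reported. Results
are ranked by stem length, ties broken by 3′ proximity, because the
biologically salient hairpin sits at the 3′ end of the control region. The
insect consensus flanks (5′ `TATA`, 3′ `G(A)nT`) are checked per hairpin
and reported as two flags. In AT-rich sequence many short perfect hairpins
exist by chance; the ranking, not the count, is the useful signal.

## Supermatrix assembly

Aligned per-gene blocks (alignment construction for real data is upstream,
in external aligners) are concatenated into four datasets: P123 (13 PCGs,
all codon positions), P123R (plus 2 rRNAs and the tRNAs), and P12/P12R
(third codon positions excluded from PCG blocks). Codon-position partitions
are interleaved column classes encoded with stride notation
(`from-to\3`, or `\2` after third-position exclusion), matching standard
phylogenetics partition dialects; partitions tile each matrix exactly.
Three tRNAs absent from some taxa in typical dipteran samplings (Ile, Gln,
Met) are excluded by default (configurable). Third-position exclusion
renumbers the surviving columns (frame reset to 1), so applying it twice
removes phase-3 columns of the new numbering — it is documented as
non-idempotent rather than silently guarded. Taxa missing a gene should be
supplied as all-gap rows. Writers emit relaxed sequential PHYLIP, NEXUS
with a sets block, RAxML partition files and a PartitionFinder-style
configuration; the PHYLIP writer round-trips through the package reader and
is cross-checked against an independent reader in the tests.

## The synthetic data generator

The generator emits a circular annotated genome in the ancestral insect
gene order (23 J / 14 N genes), with every output fully determined by the
seed. Its defaults are the study conditions of the comparative setting it
emulates:

* overall A+T 76.9%, J-strand AT-skew −0.009, GC-skew −0.174 (used for
  background sampling);
* PCG codon-position A+T of 67.8 / 66.0 / 90.0% with the corresponding
  position skews. Codon probabilities are a per-position product profile
  with stop codons removed; because that removal distorts the position
  marginals, an iterative proportional fit re-calibrates the stop-free
  codon distribution to the targets, and the emitted genes recover them to
  within binomial sampling error;
* canonical starts per gene, TAA/TAG stops, and an incomplete `T` stop on
  CO1;
* the three conserved spacers realized from their IUPAC motifs
  (18, 15 and 18 bp); taxon t takes residue ((t−1) mod k)+1 of each
  column's k-residue set, so a panel of ≥ 4 genomes covers each set exactly
  and the consensus regenerates each motif letter for letter;
* 22 template cloverleaf tRNAs (packaged data, editable) with planted
  reference mismatches (a U–U acceptor pair in tRNA-Arg, an A–A anticodon
  pair in tRNA-Leu(CUN)); panel generators plant stem changes of each of
  the five categories, verified at construction time, with the default
  histogram cbc 3, hemi-cbc 2, rbc 1, mbc 1, nrbc 1;
* a 1541 bp control region with a planted 11 nt poly-T, (TA)5, 16 nt
  poly-A, a 3′ stem-loop (stem 10, loop 6) and the two macro repeats (72
  and 36 bp, two copies each ~385 nt apart).

Two construction details make planted elements exactly recoverable.
Background sampling refuses homopolymer runs ≥ 6 and A/T alternations ≥ 6,
so no background feature reaches the detection thresholds; and each planted
repeat's flanking characters are forced to differ between copies, so the
planted unit — not an extension of it — is the flank-maximal repeat.
The A+T target is met by solving for the background base frequency after
the fixed-composition parts (PCGs, tRNAs, spacers, planted elements) are
built; infeasible targets error before emission. Realized whole-genome A+T
lands within one percentage point of the target.

Counts that downstream assertions need exactly (identical alignment
columns, stem-change categories, repeat copies) are planted as exact
counts; sampling is used only for composition targets with a stated
tolerance. Alignment panels plant exact identical-column counts; the
%INUC ~ A+T panel imposes its correlation by construction (Gram–Schmidt on
a deterministic base vector), so the target pairs carry a sample
correlation of exactly 0.2 and the realized profiles deviate only by
column quantization.

The default supermatrix block widths are post-filtering gene lengths
calibrated so that the four assembled datasets have 10,977 / 13,903 /
7,318 / 10,244 columns — the sizes of the corresponding published matrices
— which makes the assembly arithmetic checkable against printed values.

### What the generator does not emulate

No evolution along a tree: panel genomes differ only where differences are
planted, so recovery tests validate detectors, not robustness to divergence.
rRNA genes are composition-matched random sequence without secondary
structure. Whole-genome GC-skew is applied to background sampling only; the
genome-wide value emerges from the codon profile and is weaker than in real
genomes, where replication asymmetry drives it. No sequencing error,
annotation noise, gene rearrangement or length variation between panel
members. Passing the recovery suite therefore demonstrates correctness of
the statistics and detectors on well-formed input, not tolerance of noisy
annotation.

## Numerical and degenerate-input conventions

Skews are undefined (flagged) at zero denominators; empty spacers (abutting
features) are legal zero-length results, not errors; alignments must be
rectangular; comparisons of different tRNA identities are errors; a
duplicated canonical gene is an error. Percentages print to one decimal,
skews to three, correlations to two; all computation is full precision.
Random number use is confined to the generators, which derive a substream
seed per component from the master seed (kept below 2^31).

## Problem sizes used in the tests

The suites run entirely on generated data at desk scale: 16.5 kb genomes,
five-taxon panels, 1.5 kb random sequences for the repeat-finder oracle
(minimum repeat length 10, where chance repeats exist), 600 nt for the
stem-loop oracle (minimum stem 5), and full-width supermatrix blocks. The
complete test suite runs in well under a minute.
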