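---
title: "Methods: comparative plastome analysis with plastomics"
author: "plastomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

# Scope and model

`plastomics` implements the pairwise comparative analysis that plastid
genomicists run on newly assembled chloroplast genomes: quadripartite
structure metrics, repeat censuses, a sequence-variability screen for
mutational hotspots, pairwise dN/dS by codon counting, and IR/SSC
junction profiling with the three-way (A/B/C) ndh-based plastome
typology. Every stage is also exercisable on synthetic plastomes with a
complete planted-truth ledger, so the whole stack is testable without
any sequence download. This vignette records the models, conventions
and numerical choices; it states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Coordinates and the quadripartite partition

Coordinates are 1-based closed throughout, the IRanges/Biostrings
convention; GenBank locations are consumed as-is and a `join` across
the origin of a circular record is stored "unwrapped" as a single
segment whose end exceeds the genome length, which keeps all rotation
arithmetic modular. A `RegionPartition` orders the canonical
linearization LSC, IRb, SSC, IRa with the LSC starting at base 1. The
junction J_SB is identified with the first SSC base and J_SA with the
last, so both junctions coincide with the SSC's endpoints; "the
boundary" in prose always means the bond following/preceding those
bases.

## IR detection and boundary pinning

The inverted repeat is found by hashing exact 31-mers of the doubled
(circularized) sequence against their reverse complements and
extending merged seeds along antidiagonals under a mismatch budget of
`maxMismatchRate` (default 0.001, i.e. copies at >= 99.9% identity).
A budgeted maximal window systematically overshoots a sharp biological
boundary -- with a budget of b mismatches the window happily absorbs b
junk positions beyond the junction -- so detected windows are refined
base-by-base: while a mismatch lies within the terminal 8 bp of the
window, the window is cut back past it. The reported IR therefore ends
on an 8 bp exact-match run at both boundaries, which pins the junction
to the base on genomes whose IR copies are locally exact near the
boundary (true of real plastomes at this identity level, and enforced
by the simulator). The shorter inter-IR segment is labelled SSC.
Equally long candidate pairs are resolved toward the smaller start
coordinate. Canonical SSC orientation places ndhF nearer J_SB,
matching the conventional junction figures; genomes without any ndh
gene fall back to the lexicographically smaller SSC string, so output
is deterministic either way.

## SSR census

A simple sequence repeat is a maximal perfect tandem run of a
primitive 1-6 bp motif. Thresholds follow the usual plastome census
settings, read inclusively: >= 8 units (mononucleotide), >= 5
(dinucleotide), >= 3 (tri- through hexanucleotide). The published
phrase "greater than 8, 5, and 3 units" is ambiguous between the
inclusive and strict readings; the census tool this mirrors treats its
minimum as inclusive, so that is the default, and
`ssrThresholds(strict = TRUE)` selects the other reading for
comparison. Conventions: the reported span covers whole unit copies
from the run's first base (a trailing partial unit extends the run but
never the span, so span length = motif length x unit count); a run
reportable under several unit sizes appears only under its primitive
unit; `N` breaks runs; on circular sequences an origin-spanning run is
counted once, stored unwrapped. IR-duplicated SSRs are counted per
occurrence by default because that is what a census of the genome
sequence sees; `collapseIRDuplicates = TRUE` drops the IRa copies.

## Dispersed repeats

Dispersed repeats come in three kinds -- forward (copy2 = copy1),
palindromic (copy2 = reverse complement) and reverse (copy2 = plain
reversal) -- under joint criteria: copy length >= 30 bp, hamming
distance <= 3, identity >= 90%. The finder reports every *maximal*
window (extending one base on either side would exceed the budget or
the sequence) exactly once per unordered pair, with `start1 < start2`.
Two deliberate exclusions: pairs whose copies overlap (tandem arrays
and fold-back palindromes belong to the SSR/secondary-structure
domain, not to dispersed repeats), and hits whose two copies are the
genome's own IR pair (reciprocal overlap >= 90% with IRb and IRa).
No further de-duplication of overlapping maximal windows is applied:
published repeat counts depend on tool-specific post-processing that
is not reproducible from their methods, so the package reports the
well-defined maximal set and leaves aggregation to the caller. The
scan is exact-seed (7-mer) with banded extension in C++; since any
qualifying pair contains an exact run of at least
ceil((30 - 3) / 4) = 7 bp, the seeding is lossless, and a brute-force
all-pairs oracle over every diagonal confirms exact agreement in the
test suite. The scan works on the given linearization; origin-spanning
dispersed repeats are out of scope.

## Syntenic loci, alignment and SV%

For a genome pair, loci are paired by name: protein-coding genes
intact in both; intergenic spacers whose flanking feature names match
(`"psbK-trnS"`); introns of shared multi-exon genes (`"ndhA intron"`,
`"clpP intron 1"`). IR-resident loci are taken from IRb only.
Non-coding loci shorter than 150 bp in either genome are dropped.
Pairwise global alignment uses affine gaps (match +1, mismatch -1,
open 4, extend 1); coding loci are aligned codon-aware by aligning the
translated products (BLOSUM62, open 10, extend 0.5) and threading the
codons back, so coding gaps are frame-preserving. Terminal stop codons
are set aside before translation and re-appended as aligned columns.
An out-of-frame or internally stop-containing locus falls back to the
nucleotide path with a warning and is flagged.

After terminal-gap trimming, the event counts are: conserved = columns
with identical non-gap bases; substitutions = columns with differing
non-gap bases; indel events = maximal runs of gap columns (a k-base
gap is one event); `N` columns are ignored entirely. A substitution
adjacent to a gap column counts as a substitution. The statistic is

SV% = (substitutions + indel events) /
(conserved + substitutions + indel events) x 100.

Hotspot candidacy is restricted to non-coding loci, ranked by SV%
descending with alphabetical tie-breaks. Accompanying statistics are
Spearman correlations (SV-GC, indels-substitutions, indels-GC,
substitutions-GC) and two-sided Mann-Whitney tests (coding vs
non-coding SV; single-copy vs IR SV), reported as raw two-sided
p-values without multiplicity correction, matching how such screens
are conventionally presented.

## dN/dS by NG86

The pairwise estimator is Nei-Gojobori (1986) counting with
Jukes-Cantor correction, substituting for ML codon models, which are
out of scope. Synonymous site fractions per codon position count
changes to stop codons as non-synonymous, so synonymous plus
non-synonymous sites always total three per codon; site counts are
averaged over the two sequences. Codons differing at 2-3 positions are
resolved by averaging over all minimal mutational pathways, excluding
pathways through stop codons (if every pathway is blocked, all are
used -- a documented, rarely exercised fallback). Rates are
d = -(3/4) ln(1 - (4/3) p); p >= 3/4 flags saturation and leaves the
rate undefined rather than numeric nonsense; omega is undefined when
ds = 0. Counts (nd, sd, sites) are additive, so the concatenated
estimate equals NG86 on the pooled codons. Because the estimator
differs from ML, absolute published dN/dS values from codeml are not
reproduction targets; the package's claims are property-based
(symmetry, additivity, exact pathway counting against brute-force
enumeration, and recovery of the ordering and approximate magnitude of
omega in forward simulations).

## Junction profiling and the typology

The ycf1-to-J_SA distance is measured along the gene from the 5' end,
signed positive when the junction lies inside the gene body (ycf1
overhanging into the IR); in stable type-A architectures this distance
sits near 1 kb, and the package default of 991 bp is also the
reference point for the "IR shift" response. The ndh inventory distinguishes
intact genes, pseudogene remnants (the record's pseudogene qualifier,
or a CDS failing the frame/internal-stop completeness check) and
absences. Types: A = all 11 ndh genes intact; B = the complement lost
entirely; C = anything in between. The published B-vs-C boundary is
verbally fuzzy (zero *intact* genes versus zero *remnants*); the
default "remnant" rule requires type B to have no annotated ndh
sequence at all, because the type-C diagnostic is precisely the
retained remnant length, and a one-remnant genome belongs on that
regression. The alternative "intact" rule is selectable rather than
guessed. `retainedNdhLength` sums annotated ndh exon sequence,
including pseudogene remnants, counting IR-duplicated genes once.

The IR-shift-vs-retained-length relation is fitted through the origin:
slope = sum(xy)/sum(x^2), with R^2 = 1 - RSS/sum(y^2) against the
origin-constrained fit. Phylogenetically corrected correlation is
replaced by this ordinary origin fit plus a fixed-seed permutation
p-value (999 permutations of y, p = (1 + #{R^2_perm >= R^2_obs}) /
1000); this is a deliberate deviation, since tree-aware correction
needs a phylogeny the package does not infer.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions for every recovery claim.

**Architecture.** A circular genome LSC + IRb + SSC + revcomp(IRb)
with default targets 12,600 / 5,400 / 8,400 bp (genome 31,800 bp) --
a deliberately scaled-down plastome that keeps the full architecture:
34 genes including all 11 ndh genes in their native regions (ndhC/J/K
in the LSC, intron-bearing ndhB in the IR, the rest in the SSC),
rRNA genes in the IR, intron-bearing rps16/clpP/trnL/ndhA, ndhF
adjacent to J_SB, and ycf1 spanning the SSC/IRa junction with a 991 bp
overhang whose reverse complement appears as the canonical ycf1
pseudogene fragment at the IRb end. Spacer lengths are drawn to meet
the region targets exactly; a gene set that overflows its region is a
configuration error. Protein-coding sequence is random sense codons
(ATG ... TAA, no internal stops); every exon length is a codon
multiple so frames never straddle intron boundaries, except in ycf1
where the junction overhang makes a straddling codon unavoidable and
the mutation machinery handles the frame offset explicitly.

**Planted elements.** The default plan plants 12 SSRs (spanning all
six motif classes, several sitting exactly on their class threshold so
the inclusive-vs-strict reading is observable) and 6 dispersed repeats
(lengths 32-50 bp across all three kinds). Planting is engineered for
*exact* recovery: each dispersed-repeat pair carries exactly three
clustered central mismatches and two enforced mismatching flank bases
at every copy boundary. With the full budget spent in the middle, every
alternative maximal window around the planted pair falls below the
30 bp minimum, so the finder's output collapses to precisely the
planted coordinates -- an exact planted copy, by contrast, would
legitimately generate a family of overlapping maximal windows under a
nonzero mismatch budget, which is why the generator never plants exact
copies. The same reasoning pins the IR: two mismatching bases are
enforced just outside each IR boundary, which the boundary-refinement
rule then respects exactly. After assembly the genome is verified with
the package's own finders and any segment producing an unplanned hit
is resampled (random sequence of this size typically contains a
handful of chance SSRs); repeat copies are redrawn at planting time if
they contain an SSR internally, since their interiors are protected
from resampling.

**Mutation process.** `evolvePair` applies two independent draws of
the mutation process to the ancestor (star genealogy, so expected
pairwise divergence is additive). Substitutions are per-site Bernoulli
at half the pairwise rate per descendant with a uniform alternative
base; CDS start/stop codons are protected and substitutions creating
internal stops are redrawn, so gene pairing downstream is not eroded
by nonsense mutations. Indel events per locus are Poisson at half the
pairwise rate with geometric lengths (mean 3); coding indels are
codon-aligned multiples of three; indels never overlap planted
elements (and substitutions also skip them, so the planted truth
survives into the descendants). IR-resident loci mutate in concert --
the mutation appears in both copies, as plastid IRs do -- at 0.25x the
single-copy rate, and IR indels are disabled so junctions stay put.

**Rates.** The default pairwise rates are calibrated analytically to
the divergence regime reported for congeneric plastome pairs: coding
p_sub = 0.0085 with 0.1 indels/locus puts the expected mean coding SV
near 0.86%, and non-coding p_sub = 0.011 with 0.5 indels/locus --
after accounting for the planted hotspot multipliers (2.4-6x on ten
named spacers/introns) -- puts mean non-coding SV near 2.6-fold the
coding value. These are generator properties derived from the SV
expectation formula, not values fitted to any test outcome; the
acceptance script measures them fresh on every run.

**Scenarios.** Scenario B deletes all ndh genes and expands the IR by
a configured amount; scenario C deletes/pseudogenizes a configured ndh
subset and shifts J_SA by slope x retained-ndh-length (default slope
0.136, optional gaussian noise). Shifts are realized by transferring
ycf1 body sequence into the IR overhang, so the planted shift is exact
to the base and a noiseless type-C cohort recovers the slope with
R^2 = 1 up to integer rounding of the shift.

**What the simulator does not emulate**, and hence what passing tests
do not show about real data: context-dependent mutation and
codon-usage bias (coding sequence is uniform over sense codons, which
also leaves the synthetic genome near 53% AT instead of the ~64% of
real plastomes -- spacers are AT-rich but coding is not);
recombination and gene conversion beyond perfect IR concerting;
annotation error, which in real GenBank records is a major source of
census discrepancies; assembly artifacts; and tool-specific
de-duplication conventions behind published repeat counts. Published
absolute values that depend on ML estimation over many genomes or on
phylogenetic correction are likewise outside what the synthetic
recovery demonstrates.

# Problem sizes and determinism

The test suite runs the full recovery battery on 100 simulated genomes
(about 32 kb each, all three scenario types), four SV-recovery
parameter combinations with >= 200 replicate loci each, exhaustive
NG86 pathway checks over all 2-3-difference sense codon pairs, and
brute-force repeat-oracle comparisons on ~2 kb sequences; these sizes
were chosen as the smallest that make the recovery claims sharp.
All randomness flows from explicit integer seeds through a private
RNG scope that never perturbs the caller's `.Random.seed`; the same
configuration always yields byte-identical genomes, reports and
pipeline outputs.

# Known limitations

Dispersed-repeat scanning does not cross the origin of the
linearization; IR detection assumes a single IR pair (genomes with
degenerate or absent IRs are reported as IR-lacking rather than
partitioned); the NG86 estimator saturates above p = 3/4 and is not a
substitute for ML rate estimation; junction typology on real records
is only as good as their pseudogene annotations, which is why the
completeness check can be disabled; and the hotspot ranking of a
single genome pair is noisy at low divergence -- averaging SV across
replicate pairs (as the acceptance script does) stabilizes it.
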