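---
title: "Methods: comparative tandem repeat length variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative tandem repeat length variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trvar)
```

## The problem

Tandem repeats (TRs) — tracts where a unit of two or more base pairs is
repeated head-to-tail — mutate by gaining or losing whole unit copies,
orders of magnitude faster than point substitution. When such a tract
sits inside a coding sequence and its unit length is a multiple of
three, copy-number mutations lengthen or shorten the encoded protein
without shifting the reading frame, making TRs a source of rapid,
potentially adaptive protein variation. `trvar` implements the full
comparative workflow for quantifying this between two related genomes
with an outgroup: detect TRs in a focal assembly, locate each locus in
a second genome by its unique flanking sequence, call length-variable
loci, trace variants through CDS annotation to confirmed protein-length
changes, polarize changes against the outgroup, classify per-individual
allele panels, and compute functional-category enrichment folds.

Because full insect assemblies are too large for routine testing, the
package is built around a synthetic genome-trio generator with exact
ground truth; every stage is validated against what was planted.

## Tandem repeat detection

### Scoring model

A candidate is a triple (start, end, period *p*). Its score is the best
global alignment of the candidate segment against cyclic repetitions of
the unit *u* — defined as the segment's leading *p* bases — computed by
wraparound dynamic programming with +2 per matching base, −7 per
mismatch and −7 per inserted or deleted base, free entry and exit phase
within the unit. `N` always scores as a mismatch. A perfect array
therefore scores 2 points per base.

Reported loci must have a tandem alignment score of at least 50, span
at least 30 bp, cover at least two unit copies at the enumerated
period, contain at most 10% `N`, and — after the consensus is reduced
to its primitive period — have a unit of at least 2 bp. The primitive
reduction is what removes homopolymer runs: a poly-A tract enumerated
at period 2 has consensus "AA", which reduces to a 1 bp unit and is
discarded. These filters deliberately discard the abundant chance
mononucleotide and near-mononucleotide tracts of an AT-rich genome
(the default background is 63% AT).

The consensus of a candidate is the per-phase majority base over the
ungapped reading of the segment (ties toward the alphabetically first
base); the reported `unit` is the lexicographically minimal rotation of
the primitive consensus, and units are counted on the given strand with
no reverse-complement merging. `percent_matches` is the fraction of
segment positions matching the consensus in the same ungapped reading.

Among overlapping candidates the detector keeps the highest score;
ties are broken toward the longer array, then the shorter primitive
unit, then the leftmost start, then the smaller enumerated period.
Accepted arrays never overlap; the separate redundancy-elimination
step matters when catalogs are merged or imported.

### Search strategy and the brute-force reference

`detectTandemRepeats()` seeds candidate periods from runs of lag-*p*
self-matches (runs of at least 4 for *p* ≤ 6, at least 8 above),
merges nearby runs, requires enough matched bases in a cluster to make
the score threshold reachable (for *p* > 6 a score-50 array must place
at least (5*p* + 50)/9 matches beyond its first copy at lag *p*), and
skips clusters whose span is already ≥95% periodic at a proper divisor
of *p* — the divisor lag finds the identical loci and wins the
unit-length tie-break. Within each admitted window, all (start, end)
pairs are scored exhaustively by the wraparound DP in C++.

`bruteForceTandemRepeats()` is a pure-R implementation of the same
scoring definition that enumerates *every* triple with period up to 6
with no seeding, no windows and no pruning. The equivalence suite
generates random sequences with planted, mutated arrays and requires
the two implementations to produce identical loci, spans, units and
scores. Because the reference is exhaustive it is quadratic in sequence
length and is only run on sequences of a few hundred bp. The
divisor-skip and the stronger run threshold only apply above period 6,
so the exhaustively verified domain is searched with the guaranteed
thresholds (any array reaching score 50 must contain a lag-match run
of length 4).

### Redundancy elimination

When two loci overlap by more than half the length of the *shorter*
array, the longer array is kept; ties go to the shorter unit, then the
leftmost locus. The shorter-array denominator is the conservative
choice: it removes contained duplicates. Processing in that fixed order
makes the operation order-independent and idempotent.

## Flank-anchored ortholog matching

Each retained locus is extracted with 100 bp of upstream and
downstream flanking sequence from the soft-masked assembly. A locus is
excluded when either flank contains a lowercase (soft-masked) run
longer than 10 bp — the signature of an adjacent interspersed repeat
that would make the flank non-unique — or when it lies within 100 bp
of a sequence end (uniform full-length flanks keep the coverage rule
meaningful; truncated flanks are not used).

The query (flank + array + flank) is searched against the target
genome by exact 18-mer seeds taken every 8 bp along both flanks;
seed diagonals are clustered and each candidate window is aligned
locally with +2/−7 substitution weights and BLAST-like affine gaps
(opening 10, extension 1). Two properties of the gap model matter and
were chosen after observing concrete failure modes against simulator
truth:

* with *linear* per-base gap costs an optimal-alignment engine is free
  to scatter tie-equivalent gap columns through the flank region,
  which corrupts any column-based projection of the array span;
* with *expensive* contiguous gaps (7 per base), spanning a
  copy-number change of more than ~28 bp costs more than the ~200
  points the distal flank contributes, so the optimal local alignment
  truncates at the indel and the hit loses a flank entirely. Cheap
  affine extension keeps changes of up to two 50 bp units affordable.

Hits are ranked by a Karlin–Altschul e-value estimate with λ computed
for the +2/−7 scheme under uniform base frequencies and a fixed
K = 0.1; for near-identical queries of ~300 bp the thresholds are
generous, so the e-value serves as a ranking and sanity statistic, not
a BLAST replication, and acceptance additionally requires 80% identity
over the aligned span to reject low-complexity accidents. Only the
best hit is evaluated (ties: higher raw score, then lowest target
coordinate). The ingroup mode requires more than 95 bp of both flanks
aligned at e ≤ 1e-10; the outgroup mode relaxes this to more than
90 bp at e ≤ 1e-5.

The target array span is delimited by the innermost aligned flank
columns: everything between the last aligned left-flank column and the
first aligned right-flank column belongs to the array. This is robust
to the aligner's placement of a whole-unit indel at the array/flank
boundary, where a projection based strictly on array columns would
silently drop the indel. A locus is called length-variable exactly
when the projected target span differs in length from the query array;
indels confined to flank columns never produce a call.

## Coding impact

A variable locus qualifies for coding analysis only when its array is
fully contained in a single CDS feature — partial overlaps would make
the reading frame ambiguous, and repeats in untranslated exon regions
are excluded by construction. The query gene's protein is matched to
the target proteome by best local-alignment score (BLOSUM62, affine
gaps); in synthetic mode the hit must be reciprocal, while real-proteome
runs may keep the one-way best hit. The protein pair is aligned
globally and the locus is confirmed when a net nonzero indel falls
within the repeat-encoded residue window, widened by one unit of
residues on each side because aligners may slide gaps within a repeat
run. For in-frame units the gained or lost residues are reported as
the codon-aligned translated unit repeated once per copy changed. The
strict consistency check `aa_length_delta * 3 == array_length_delta`
is exact on noise-free simulations and is asserted for every confirmed
record.

## Polarization and classification

With a single outgroup the parsimony rule is: if the two ingroup
lengths differ and one equals the outgroup length, that lineage is
ancestral and the other derived (gain if longer than the outgroup,
loss if shorter); if both differ from the outgroup the locus is
unpolarized. Lengths are compared in base pairs, not copy counts,
because the outgroup's unit consensus may drift; differences that are
not exact unit multiples are flagged non-integral rather than rounded.
The three-way comparison is assembled from two pairwise anchorings
(focal→congener, focal→outgroup) rather than a joint multiple
alignment.

Allele panels across individuals are classified on *observed length
sets*: `invariant` when every individual agrees, `not_fixed` when the
two species share at least one observed length, and for disjoint sets
`within_species_variation` if any species is polymorphic, otherwise
`fixed_between`. With panels of three to five individuals, judging
overlap by ranges instead of shared values would overstate overlap,
which is why set intersection was chosen; the range alternative is a
genuine open choice. The fourth class (`invariant`) is an addition
needed for synthetic panels, which unlike a PCR panel are not
pre-selected for variability.

Enrichment folds are plain contingency arithmetic,
fold = (k/n)/(K/N), with an optional hypergeometric upper-tail
probability that is off by default because the fold alone is the
headline statistic.

## The synthetic genome trio

`simulateGenomeTrio()` draws an i.i.d. ancestor at 63% AT, plants TR
cassettes, and evolves three lineages independently. Defaults, chosen
once to mirror the study system and left fixed:

| parameter | default | meaning |
|---|---|---|
| `n_chromosomes`, `chrom_length` | 2 × 250 kb | desk-scale genome |
| `at_fraction` | 0.63 | AT-rich background |
| `n_tr_loci` | 500 | planted loci |
| `genic_fraction` | 0.667 | share of loci inside genes |
| `coding_fraction_of_genic` | 0.5 | genic loci placed in CDS |
| `unit_length_weights` | ∝ len^−1.2 over 2–50 | short units dominate |
| `copy_number_range` | 4–12 | ancestral copies (raised so all lineages keep ≥30 bp and ≥2 copies) |
| `p_variable` | 0.3 | per-lineage chance of a unit-number change |
| `step_probs` | ±1 (0.3 each), ±2 (0.2 each) | signed unit steps |
| `point_divergence_ingroup` | 0.005/site/lineage | ~1% between ingroups |
| `point_divergence_outgroup` | 0.03/site | a clearly diverged outgroup |
| `masked_repeat_density` | 0.1 | loci given a 15 bp soft-masked flank run |

Coding cassettes use in-frame, codon-aligned units drawn from non-stop
codons inside a single-CDS forward-strand gene (a configuration flag
adds reverse-strand genes); genic non-coding cassettes place the array
in untranslated gene territory. Point substitutions are applied to
intergenic and untranslated sequence only, never inside planted arrays
or CDS, and divergence is substitution-only. These choices keep ground
truth exact — the focal span of every planted locus is a verbatim pure
array — which is what makes the 100% frame-consistency and
zero-false-call assertions meaningful. A per-array substitution rate
(`array_noise`) exists for robustness experiments but is off by
default, and the within-species allele perturbation of
`simulatePopulationAlleles()` is a rounded-normal stand-in, not an
inference about any real species' allele distribution.

What passing tests on this universe do **not** show: tolerance to
assembly gaps and collapsed repeats, indel divergence in flanks,
sequencing error, inversions or rearrangements across a locus,
multi-exon frame bookkeeping beyond the flag-enabled cases, and the
behaviour of the e-value estimate in genuinely repetitive genomes.
Full-scale runs on real assemblies go through the same
`runTRPipeline()` configuration with paths instead of a simulation
block; every workflow threshold (100 bp flanks, >10 bp mask run,
>95 bp/1e-10 ingroup, >90 bp/1e-5 outgroup) is a named default.

## Numerical and implementation choices

* All coordinates at interfaces are 1-based inclusive; the BED export
  is the only 0-based half-open surface.
* The detector's tie-breaks (score, array length, unit length, start,
  period) are total, so detection is deterministic; the simulator
  consumes one seeded RNG stream in fixed order, so identical seed and
  configuration give byte-identical FASTA/GFF3/TSV outputs.
* Problem sizes used by the shipped checks: oracle equivalence on
  1000 planted sequences of ≤150 bp at periods ≤6; parameter recovery
  on the 500-locus default trio; both chosen to exercise every code
  path at desk scale.
* The period scan of the pipeline is capped at 120 bp (the generator
  plants units of at most 50 bp); the detector itself scans to
  2000 bp by default.
* Degenerate inputs: empty sequences and empty catalogs flow through
  as empty results; chromosomes without annotated genes yield missing
  distances with a warning; a zero-length background between cassettes
  is a configuration error, reported with the chromosome index.

## Known limitations

The detector's completeness guarantees above period 6 are heuristic
(seed runs of 8, periodicity-scaled admission); near-threshold arrays
with heavy internal mutation may be missed there, which is acceptable
for the noise-free planted universe but untested on real decayed
repeats. The e-value model is ungapped theory applied to a gapped
search. Polarization assumes the outgroup state is ancestral at
single-locus resolution and will mis-polarize hemiplasy. None of the
enrichment machinery performs functional annotation itself — category
counts come from the user.
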