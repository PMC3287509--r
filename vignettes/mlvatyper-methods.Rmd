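---
title: "Tandem repeat discovery and MLVA typing: models and methods"
author: "mlvatyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem repeat discovery and MLVA typing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlvatyper)
```

## The problem

Endosymbiotic bacteria such as *Wolbachia pipientis* are often typed by
multi-locus sequence typing (MLST) of conserved housekeeping genes.
Closely related strains — for instance the *w*Mel-like strains of
*Drosophila* — are frequently indistinguishable at MLST resolution.
Their genomes do, however, carry loci that evolve much faster: tandem
repeats.  Two classes matter here:

* **Intergenic VNTRs** (variable number tandem repeat loci) with long
  periods (on the order of 105 and 141 bp), whose copy number expands
  and contracts between strains.  Amplifying a VNTR with primers in its
  conserved single-copy flanks yields strain-specific product sizes, so
  a handful of loci gives an MLVA (multiple locus VNTR analysis)
  fingerprint readable on an agarose gel.
* **ANK genes**, coding for ankyrin repeat domain proteins built from
  tandem ~33-aa units (99 bp of coding sequence per unit).  Unit counts
  differ between strains, so size differences come in multiples of
  99 bp; premature stops, transmembrane-segment loss and mobile-element
  insertions add further diagnostic events.

`mlvatyper` implements the full computational side of this marker
system: genome-wide tandem repeat discovery, VNTR locus structure
analysis, in-silico PCR typing, and ANK architecture analysis, plus a
deterministic generator of ground-truthed synthetic data that every
analysis is validated against.

## Tandem repeat discovery

### Model

A tandem array is modelled as a window of sequence aligned against an
unbounded head-to-tail concatenation of a single consensus period.  The
alignment is computed by *wraparound dynamic programming*: the DP state
is (sequence position, position within the period), and the alignment
path may wrap from the period's last column back to its first.  The
reported score is

\[ S = m\cdot\#\{\text{matches}\} - x\cdot\#\{\text{mismatches}\}
     - i\cdot\#\{\text{indels}\} \]

with the weights `scoringParams()` defaults to: match +2, mismatch 7,
indel 7, a minimum reporting score of 50, a maximum period of 500 bp,
and a reportable copy-number floor of 1.8 copies.  These are the
standard parameter settings for endosymbiont genome scans of this kind,
and the perfect-array closed form \(S = 2cp\) for \(c\) exact copies of
period \(p\) follows directly.

### Search strategy

Sequences up to 300 bp are scanned by exhaustive period enumeration
(every candidate period against the whole sequence), which makes the
finder directly comparable against a brute-force oracle.  Longer
sequences are seeded: every pair of identical 5-mers at distance
\(d \le 500\) votes for candidate period \(d\); votes are clustered
along the sequence, and a cluster is promoted only when its support is
commensurate with \(d\) (at least \(d/8\) matching k-mer pairs — a
genuine array of period \(d\) produces a matching pair at almost every
clean position of its span, chance k-mer pairs do not).  Each promoted
(window, period) candidate is refined by local wraparound alignment
with up to three rounds of majority-vote consensus re-estimation (ties
go to the earliest copy), then recursion into the unmatched remainder
of the window catches multiple arrays of the same period.

Two post-processing rules resolve redundancy:

* **Minimal period.**  A consensus that is itself an exact tandem of a
  sub-period is re-refined at the sub-period.  Additionally, when two
  reports cover essentially the same span (overlap above 70% of the
  smaller) at near-harmonic periods (\(p\) and \(\approx kp\), with
  \(k \ge 2\)), the smaller period wins whenever it scores at least 85%
  of the larger.  The margin exists because a harmonic consensus can
  absorb copy-specific SNPs and thereby overfit the raw score; the true
  period loses by at most a few mismatch penalties, never by 15%.
* **Span dedup.**  Among the remaining reports, heavily overlapping
  spans keep only the best score (ties towards the smaller period).
  Reports with distinct spans always coexist.

Only the forward strand is scanned: a tandem array is its own
reverse-complement's mirror, so a reverse scan would duplicate every
report.  Windows with more than 10% N are skipped.

`summarizeRepeats()` aggregates a scan into the genome-level summary
(count, total repeat extent, percent of genome, means and ranges of
period size, copy number and internal match).  Overlapping arrays are
collapsed to their union before the total is computed; the unweighted
arithmetic mean is used throughout.  An empty scan reports zero counts
and `NA` means, never zeros pretending to be measurements.

## VNTR locus structure

### Period decomposition

`decomposePeriods()` aligns a locus (or a whole amplicon including its
flanks) against a consensus period and cuts the alignment path at
consensus coordinate zero.  Each resulting period instance is
classified:

* **full** — no internal deletion of 20 bp or more, and at least 90% of
  the period aligned; counts 1.0 copies;
* **half** — an internal deletion of at least 20 bp; counts 0.5 copies.
  The threshold sits well below the 25 and 32 bp deletions that real
  half-copies of the 105 bp locus carry, and well above the small
  indels a full copy tolerates;
* **partial** — a truncated copy at an array end; counts its aligned
  fraction rounded to one decimal (round-half-even, matching the
  one-decimal copy numbers the markers are reported with).

The total copy number is the sum of the contributions, and the copy
string records the composition (`"7+0.3"`, `"4+2x0.5"`, `"3x0.5"`,
`"0.8"`).

Decomposition deliberately uses a different gap model from the finder:
match +2, mismatch 7, and *affine* gaps (open 7, extend 1).  With the
finder's linear indel cost, a 25 bp structured deletion costs 175 and a
terminal half-copy becomes unprofitable to align — the alignment would
silently trim exactly the features the locus structure consists of.
With cheap linear gaps instead, alignment drifts profitably into
AT-rich random flanks (an LCS effect).  Affine costs give both
properties at once: one structured deletion costs 7 + L, while drift
through unrelated sequence requires many gap openings and stays
strongly negative.  A locus without any alignment above `minScore`
(default 50) yields a "no repeat structure" result with `NA` copy
number — an expected outcome, not an exception.

Two honest limitations: when flank bases coincide with the period edge,
equal-scoring alignments make the matched region's boundary ambiguous
by a base or two; and a terminal half-copy whose post-deletion remnant
is shorter than ~15 bp cannot be anchored and is reported as a partial
instead.  The validation suite therefore asserts exact copy structure,
and region coordinates only to ±3 bp.

### Internal motifs

`findDirectRepeats()` reports maximal exactly-repeated units (default
5–20 bp, at least two greedy non-overlapping occurrences): a unit is
maximal when no one-base extension repeats as often.  Units with
mononucleotide Shannon entropy of at most 1 bit are suppressed, so
homopolymers and other trivial low-complexity motifs are never
reported.  An inverted mode additionally pairs a unit with its reverse
complement.  The field's descriptions of such 15 bp units vary between
"direct" and "inverted" repeats; the toolkit detects and labels both
kinds explicitly rather than adjudicating.

`findDyads()` enumerates hairpin-forming palindromic repeats: a stem
arm followed, after a loop of bounded length, by its reverse
complement, maximal under both outward and inward (loop-consuming) stem
extension.  A stem of 9 with a loop of 5 spans \(2\cdot9+5 = 23\) bp —
the hairpin geometry of both VNTR periods.  Both finders are verified
against literal brute-force enumerations on random sequence.

## In-silico PCR and MLVA profiles

Primer sites are located by exact or bounded-mismatch substring
matching (IUPAC codes in a primer match their expansion sets; no
indels).  The default mismatch tolerance is 0: the markers are designed
against a reference genome, and amplification failure under divergence
is itself diagnostic, so mismatch tolerance is an explicit flag rather
than a silent default.  Every forward site paired with every downstream
reverse-complement site within the product cap (default 5000 bp) yields
an amplicon; the length runs from the 5' end of the forward footprint
to the 5' end of the reverse footprint on the template, so both primer
sequences are included — the standard PCR product-size convention.

`callAllele()` decomposes the amplicon against the locus consensus;
when no repeat structure is present the allele is still emitted with
its length (size-only typing, as on a gel).  `buildProfile()` assembles
per-locus allele lists over all template sequences in an extract, so a
mixed infection appears as multiple distinct lengths at one locus and
raises the `multipleInfection` flag.  The packaged *wsp* primer pair
acts as the DNA quality control: a profile whose QC locus fails to
amplify is flagged rather than reported as "no infection".
`profileDistance()` and `copyNumberDistance()` provide Manhattan
distances over copy-number characters for cladistic comparison, with
missing loci excluded as explicit `NA` — never counted as zero copies.
The gel-style report merges bands within ±5 bp (an agarose resolution
surrogate) in the human-readable output only; the data model always
keeps exact lengths.

## ANK architecture

* **Translation** uses the bacterial genetic code; ATG and GTG starts
  both read as methionine, codons containing N read as X.  A stop
  before 90% of the CDS length is flagged premature; every
  protein-level feature (units, TM segments, mass) is computed from the
  translation up to the first stop, so a premature stop ablates all
  downstream features — the behaviour real truncated orthologs show.
* **Unit detection** scans with a 33-column log-odds profile (log2
  odds against Robinson–Robinson background frequencies, pseudocount
  2) built from the packaged seed alignment of canonical ankyrin-unit
  variants (`inst/extdata/ank_seed_units.fasta`, a curated synthetic
  seed set written from the published ankyrin consensus).  Selection is
  greedy left-to-right with a small look-ahead, so adjacent units may
  abut.  The detection threshold of 25 bits is the packaged calibration
  constant: on this profile, random proteins of background composition
  stay below −15 bits per window, while planted units — including
  variable-position-randomized and strain-diverged ones — score 45–70
  bits.  The suite re-verifies both sides of this calibration
  empirically.
* **Transmembrane segments** use Kyte–Doolittle hydropathy with a
  19-residue window and a mean cutoff of 1.6; a segment is the union of
  passing windows, segments closer than 5 aa merge, and segments
  shorter than 15 aa are dropped.  This is a deliberate, documented
  stand-in for HMM-based TM prediction: adequate for the planted
  23-residue hydrophobic tails and for presence/absence calls, not for
  precise topology.
* **Mass** is the sum of average amino-acid residue masses plus one
  water, reported in kDa to one decimal, X counting as an average
  residue.
* **Insertions** (IS-element scale) are read from a global DNA
  alignment against a reference ortholog (match +2, mismatch −7, gap
  open −7, extend −1): every reference gap of at least 100 bp is
  reported with its exact length.  Identification is length- and
  alignment-based, not library-based.  Orthology is gated by ≥50%
  identity *and* a positive alignment score — unrelated DNA reaches
  two-thirds LCS-style identity under cheap gap extension, but only at
  a strongly negative score.  Single-base frameshifts against an
  in-frame reference can be patched with N (`correctFrameshifts()`).
* **Unit phylogenetics** aligns the near-equal-length units by
  center-star progressive alignment (BLOSUM62; the center is the unit
  with the highest total pairwise score; "once a gap, always a gap")
  and builds a neighbor-joining tree on p-distances with a
  deterministic tie-break towards input order.  NJ on p-distance
  replaces maximum-likelihood inference deliberately: at 33–36 aligned
  residues per unit, branch support is weak under any model, and the
  consumed output is the position-cluster structure, not branch
  support.  Column-resampling bootstrap is available as an option.
  `clusterPositions()` single-links units at an identity threshold
  (default 0.8) and reports the two event classes of interest:
  lineage-specific tandem duplication (one strain contributing adjacent
  indices to one cluster) and unit shuffling (two strains' shared
  clusters in inverted order).

## The synthetic generator

`makeVntrLocus()`, `makeAnkGene()` and `makeGenome()` produce the exact
structures the analyses assume, with a `truth` record and byte-identical
regeneration under a fixed seed (the caller's RNG stream is left
untouched).  Defaults mirror the real marker system: 141/105 bp
periods, 25 bp internal deletions placed mid-period, terminal partial
copies as prefix fractions (0.3 × 141 = 42 planted bases), conserved
flanks whose outermost 20 bp serve as primers, 35% GC AT-rich
background, ANK genes as M + 33-aa units + an optional tail coding two
23-residue hydrophobic stretches.  Base ANK units are a deterministic
function of (seed, position) — consensus mutated at the twelve
solvent-exposed positions of the unit, drawing from a polar/charged
alphabet, so units at different positions are distinguishable while
the structural core and solubility are preserved; strain-level noise is
layered on top so orthologous positions stay cognate across a panel.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: indel noise between copies
(only planted structured deletions), sequencing error, genome-scale
compositional heterogeneity, gene-conversion-style concerted evolution,
and real codon usage (back-translation uses one fixed codon per amino
acid).  Scan-level results on real genomes additionally depend on
heuristic internals that published tools do not fully specify, which is
why the genome-level summary comparison is a tolerance check, not an
exact one.

## Problem sizes and determinism

The validation suite runs entirely at desk scale: oracle equivalence on
strings up to 100 bp, motif oracles up to 64 bp, planted-array recovery
on 200 seeded loci spanning periods 10–500 and 2–12 copies with up to
5% SNP noise (the published copy-number range for these markers),
genomes of 10–30 kb, and ANK panels of 2–14 units.  Every stochastic
test fixes its seed; the acceptance script takes `--seed` and derives
all randomness from it.  Accession-based checks (reference genome
coordinates, published amplicon sizes and masses) run against local
FASTA exports of the public accessions when present under
`tests/testthat/accessions/`; they are the only parts of the suite
requiring external data.

## Known limitations

* Periods above 500 bp and interspersed (non-tandem) repeat families
  are out of scope, as is masking.
* No bit-compatibility with any particular published repeat finder's
  output is claimed; scoring and reporting rules are as stated above.
* Hairpins are detected combinatorially, not thermodynamically — no
  folding free energies.
* Amplicon-size arithmetic across strains assumes comparable flank
  lengths; where flanks differ between strains, only within-strain
  copy-number calls are meaningful.
* The ANK profile is a position-weight matrix, not a profile HMM; unit
  boundary offsets of a few residues against HMM-based annotations are
  expected.
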