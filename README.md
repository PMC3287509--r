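# mlvatyper

Tandem repeat discovery and MLVA (multiple locus VNTR analysis) strain
typing for endosymbiont genomes, with ankyrin (ANK) repeat-domain
architecture analysis.

## The problem

Closely related strains of endosymbionts such as *Wolbachia* are often
indistinguishable by multi-locus sequence typing of conserved genes.
Their genomes, however, carry fast-evolving tandem repeats: intergenic
VNTR loci whose long periods (~105 and ~141 bp) expand and contract in
copy number, and ANK genes built from tandem 33-amino-acid repeat units
(99 bp each).  Amplified with primers in conserved single-copy flanks,
these loci give strain-specific product sizes — an MLVA fingerprint
readable on a gel, resolving strains that sequence typing cannot.

`mlvatyper` implements the computational side of this marker system:

* **`findTandemRepeats()` / `summarizeRepeats()`** — genome-wide tandem
  repeat detection by k-mer-seeded wraparound dynamic programming.  The
  alignment score is `2·matches − 7·mismatches − 7·indels` with a
  minimum reporting score of 50, a maximum period of 500 bp and a
  copy-number floor of 1.8; for a perfect array of *c* copies of period
  *p* the score is exactly `2·c·p`.
* **`decomposePeriods()`, `findDyads()`, `findDirectRepeats()`** — VNTR
  locus structure: the locus is cut into period instances classified
  full / half (internal deletion ≥ 20 bp, counted 0.5) / partial
  (terminal fraction, one decimal), yielding copy numbers like `7.3`
  and copy strings like `"4+2x0.5"`; internal direct repeats and
  palindromic hairpins (e.g. a 9 bp stem + 5 bp loop = 23 bp dyad) are
  annotated.
* **`inSilicoPCR()`, `callAllele()`, `buildProfile()`** — in-silico PCR
  typing with the packaged marker primers (VNTR-141, VNTR-105, WD0550,
  WD0766, and *wsp* as DNA quality control), amplicon sizing including
  both primer footprints, per-locus allele calling, multi-locus
  profiles with multiple-infection flags, and Manhattan profile
  distances.
* **`ankArchitecture()`, `repeatUnitTree()`, `clusterPositions()`** —
  ANK gene analysis: translation with premature-stop detection,
  repeat-unit detection by a packaged 33-column log-odds profile,
  Kyte–Doolittle transmembrane prediction, protein mass (1-dp kDa),
  IS-element-scale insertion detection against a reference ortholog,
  center-star unit alignment, neighbor-joining unit trees, and
  duplication/shuffling event calls across orthologs.
* **`makeVntrLocus()`, `makeAnkGene()`, `makeGenome()`** — a
  deterministic, seeded synthetic-data generator with ground truth for
  every planted structure.

## Worked example

Two strains differing by one 141 bp period at a VNTR locus:

```r
library(mlvatyper)

simA <- makeVntrLocus(periodLen = 141, nFull = 7, terminalFraction = 0.3,
                      flankF = 150, flankR = 150, seed = 42, locusId = "strainA")
simB <- makeVntrLocus(periodLen = 141, nFull = 6, terminalFraction = 0.3,
                      flankF = 150, flankR = 150, seed = 42, locusId = "strainB")
pp <- primerPair("VNTR-141-like", simA$truth$primerF, simA$truth$primerR)

ampA <- inSilicoPCR(simA$seq, pp)
ampA
#>   template_id      locus_id start  end length
#> 1     strainA VNTR-141-like     1 1329   1329

callAllele(substr(as.character(simA$seq[[1]]), ampA$start, ampA$end),
           simA$truth$periodSeq, "VNTR-141-like")
#> MlvaAllele VNTR-141-like: 1329 bp [7+0.3]

ampB <- inSilicoPCR(simB$seq, pp)
callAllele(substr(as.character(simB$seq[[1]]), ampB$start, ampB$end),
           simB$truth$periodSeq, "VNTR-141-like")
#> MlvaAllele VNTR-141-like: 1188 bp [6+0.3]
```

The two amplicons differ by exactly one period (1329 − 1188 = 141 bp)
and the copy numbers by 1.0 (7.3 vs 6.3): amplicon size alone types the
strains, and decomposition explains the size.

Genome-wide scan of a synthetic genome with two planted loci:

```r
g <- makeGenome(2, 20000,
                list(list(periodLen = 141, nFull = 4, snpRate = 0.02),
                     list(periodLen = 105, nFull = 4, nHalf = 2,
                          halfDeletionLen = 25)),
                seed = 6)
r <- findTandemRepeats(g$seq)
as.data.frame(r)[, c("start", "end", "period_size", "copy_number", "score")]
#>   start   end period_size copy_number score
#> 1 11266 11825         141         4.0  1030
#> 2 12181 12640         105         4.4   920
#> 3 12560 12760          80         2.5   402
```

Rows 1–2 are the planted arrays (the 105 bp locus counts its two
deleted copies fractionally); row 3 is the 80 bp sub-array that the two
deletion-carrying copies themselves form — a distinct span, so it is
reported alongside rather than suppressed.  And an ANK gene:

```r
gA <- makeAnkGene(nUnits = 8, tmTail = TRUE, seed = 14)
ankArchitecture(as.character(gA$seq[[1]]), "synthetic_ank")
#> AnkArchitecture 'synthetic_ank': 8 ANK unit(s), 2 TM segment(s), 35.7 kDa
```

A command-line front end over the same functions (subcommands `scan`,
`summarize`, `structure`, `type`, `ank`, `simulate`) is installed at
`inst/scripts/mlva-tools.R`.

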