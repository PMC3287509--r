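test_that("fractional copies round as printed copy numbers", {
  expect_equal(fractionalCopy(108, 141), 0.8)
  expect_equal(fractionalCopy(141, 141), 1.0)
  expect_equal(fractionalCopy(70, 141), 0.5)
  expect_equal(fractionalCopy(42, 141), 0.3)
  expect_error(fractionalCopy(10, 0), "period")
  expect_error(fractionalCopy(0, 141), "alignedLen")
  expect_error(fractionalCopy(150, 141), "alignedLen")
})

test_that("decomposition classifies full, half and partial periods", {
  set.seed(71)
  p141 <- rand_dna(141)
  # identity
  d0 <- decomposePeriods(p141, p141)
  expect_equal(copyNumber(d0), 1.0)
  expect_equal(copyString(d0), "1")
  expect_equal(nrow(periodInstances(d0)), 1L)
  # seven exact copies plus a 42 bp terminal prefix -> 7.3
  d1 <- decomposePeriods(paste0(strrep(p141, 7), substr(p141, 1, 42)), p141)
  expect_equal(copyNumber(d1), 7.3)
  expect_equal(copyString(d1), "7+0.3")
  expect_equal(sum(periodInstances(d1)$class == "full"), 7L)
  # four full + two 25 bp internal deletions on a 105 bp period
  sim <- makeVntrLocus(periodLen = 105, nFull = 4, nHalf = 2,
                       halfDeletionLen = 25, flankF = 120, flankR = 120,
                       seed = 72)
  d2 <- decomposePeriods(as.character(sim$seq[[1]]), sim$truth$periodSeq)
  expect_equal(copyString(d2), "4+2x0.5")
  expect_equal(copyNumber(d2), 5.0)
  half <- periodInstances(d2)[periodInstances(d2)$class == "half", ]
  expect_equal(nrow(half), 2L)
  for (k in seq_len(nrow(half)))
    expect_true(any(half$deletions[[k]][, "length"] == 25))
  # halves only, as in the smallest published 105 bp allele class
  sim3 <- makeVntrLocus(periodLen = 105, nFull = 0, nHalf = 3,
                        halfDeletionLen = 32, flankF = 100, flankR = 100,
                        seed = 73)
  d3 <- decomposePeriods(as.character(sim3$seq[[1]]), sim3$truth$periodSeq)
  expect_equal(copyString(d3), "3x0.5")
  expect_equal(copyNumber(d3), 1.5)
  # single core period (no insertion, one missing 15 bp unit) -> 0.8
  d4 <- decomposePeriods(substr(p141, 1, 108), p141)
  expect_equal(copyNumber(d4), 0.8)
  # unrelated sequence -> "no repeat structure", not an exception
  d5 <- decomposePeriods(rand_dna(300, gc = 0.65), p141)
  expect_true(is.na(copyNumber(d5)))
  expect_equal(nrow(periodInstances(d5)), 0L)
  expect_error(decomposePeriods("ACGTACGT", "ACGTACGT"), ">= 10")
})

test_that("decomposition tiles the matched region and is validity-checked", {
  set.seed(81)
  for (i in 1:5) {
    # periods >= 50 so that a half copy retains enough flanking match on
    # each side of its deletion to be anchored by the aligner
    p <- sample(50:141, 1)
    sim <- makeVntrLocus(periodLen = p, nFull = sample(2:6, 1),
                         nHalf = sample(0:2, 1),
                         halfDeletionLen = 25L,
                         terminalFraction = sample(c(0, 0.3, 0.6), 1),
                         flankF = 80, flankR = 80, seed = 800 + i)
    d <- decomposePeriods(as.character(sim$seq[[1]]), sim$truth$periodSeq)
    ins <- periodInstances(d)
    expect_true(methods::validObject(d))
    expect_equal(ins$start[1], IRanges::start(d@region))
    expect_equal(ins$end[nrow(ins)], IRanges::end(d@region))
    if (nrow(ins) > 1)
      expect_equal(ins$start[-1], ins$end[-nrow(ins)] + 1L)
    # round-trip against generator truth in noise-free loci
    expect_equal(copyNumber(d), sim$truth$copyNumber)
    expect_equal(copyString(d), sim$truth$copyString)
  }
})

test_that("copy number is invariant to which identical copy seeds the consensus", {
  set.seed(91)
  p <- rand_dna(60)
  locus <- strrep(p, 4)
  rotations <- vapply(c(1, 21, 41), function(s)
    substr(paste0(p, p), s, s + 59), character(1))
  for (cons in rotations)
    expect_equal(copyNumber(decomposePeriods(locus, cons)), 4.0)
})

test_that("direct repeat finder matches brute-force enumeration", {
  set.seed(101)
  for (i in 1:12) {
    s <- rand_dna(sample(40:64, 1), gc = 0.5)
    got <- findDirectRepeats(s, minUnit = 5, maxUnit = 12)
    want <- oracle_direct_repeats(s, 5L, 12L)
    expect_setequal(got$unit, vapply(want, `[[`, character(1), "unit"))
    for (k in seq_len(nrow(got)))
      expect_equal(got$positions[[k]], want[[got$unit[k]]]$positions)
  }
  # planted 15 bp unit at both ends of a 141 bp period
  sim <- makeVntrLocus(periodLen = 141, nFull = 1,
                       plantDirectRepeat = list(unitLen = 15,
                                                offsets = c(1, 127)),
                       seed = 102)
  dr <- findDirectRepeats(sim$truth$periodSeq, minUnit = 5, maxUnit = 20)
  hit <- dr[dr$unit == sim$truth$motifs$directRepeat$unit, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unitLength, 15L)
  expect_equal(hit$nOccurrences, 2L)
  expect_equal(hit$positions[[1]], c(1L, 127L))
  # homopolymers are suppressed by the entropy filter
  expect_equal(nrow(findDirectRepeats(strrep("A", 50))), 0L)
})

test_that("inverted-repeat mode reports unit/reverse-complement pairs", {
  unit <- "GATTCCGTAACGGAT"
  s <- paste0("TTTTT", unit, "AAACCCAAA", revcomp(unit), "TTTTT")
  got <- findDirectRepeats(s, minUnit = 10, maxUnit = 16,
                           allowInverted = TRUE)
  inv <- got[got$kind == "inverted_repeat" & got$unitLength >= 15, ]
  expect_gte(nrow(inv), 1L)
  expect_true(any(inv$unit == unit | inv$unit == revcomp(unit)))
})

test_that("dyad finder matches brute-force enumeration and geometry", {
  # constructed hairpin: stem 9, loop 5, span 23 = the published geometry
  arm <- "GGATCCGTC"
  s <- paste0("AAATT", arm, "AAAAA", revcomp(arm), "TTAAA")
  dy <- findDyads(s, minStem = 6, maxLoop = 8)
  expect_equal(nrow(dy), 1L)
  expect_equal(dy$stemLen, 9L)
  expect_equal(dy$loopLen, 5L)
  expect_equal(dy$span, 23L)
  expect_equal(nrow(findDyads(strrep("A", 30))), 0L)
  set.seed(111)
  for (i in 1:10) {
    s <- rand_dna(sample(40:60, 1), gc = 0.5)
    got <- findDyads(s, minStem = 4, maxLoop = 6)
    want <- oracle_dyads(s, 4L, 6L)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_setequal(paste(got$start, got$end, got$stemLen),
                      paste(want[, "start"], want[, "end"], want[, "stemLen"]))
    }
  }
})

test_that("planted hairpin inside a generated period is recovered exactly", {
  sim <- makeVntrLocus(periodLen = 141, nFull = 1,
                       plantHairpin = c(stem = 9, loop = 5), seed = 121)
  hp <- sim$truth$motifs$hairpin
  dy <- findDyads(sim$truth$periodSeq, minStem = 6, maxLoop = 8)
  expect_true(any(dy$start == hp$start & dy$stemLen >= 9 & dy$span >= 23))
})

test_that("copy-number characters form a cladistic matrix with explicit NA", {
  byStrain <- list(
    wMelLike = list(`VNTR-141` = 7.3, `VNTR-105` = 5.0),
    wMelCSLike = list(`VNTR-141` = 6.3, `VNTR-105` = 4.0),
    wWilLike = list(`VNTR-141` = 0.8))
  m <- copyNumberCharacters(byStrain)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["wMelLike", "VNTR-141"], 7.3)
  expect_true(is.na(m["wWilLike", "VNTR-105"]))
  d <- copyNumberDistance(m)
  # printed copy numbers one period apart differ by exactly 1.0
  expect_equal(d["wMelLike", "wMelCSLike"], 2.0)
  expect_equal(attr(d, "nLoci")["wMelLike", "wWilLike"], 1L)
  expect_equal(d["wMelLike", "wWilLike"], 6.5)
  expect_equal(d["wMelLike", "wMelLike"], 0)
})

test_that("generated decompositions populate the character matrix exactly", {
  set.seed(131)
  specs <- list(a = 3L, b = 5L, c = 7L)
  decs <- lapply(specs, function(n) {
    sim <- makeVntrLocus(periodLen = 60, nFull = n, flankF = 50,
                         flankR = 50, seed = 130 + n)
    list(L1 = decomposePeriods(as.character(sim$seq[[1]]),
                               sim$truth$periodSeq))
  })
  m <- copyNumberCharacters(decs)
  expect_equal(unname(m[, "L1"]), c(3, 5, 7))
})
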