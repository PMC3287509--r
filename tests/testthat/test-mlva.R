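test_that("primer site search matches a naive sliding-window scan", {
  set.seed(141)
  primer <- "GGAGTATTATTGATATGCG"
  tmpl <- paste0(rand_dna(60), primer, rand_dna(80), revcomp(primer),
                 rand_dna(40))
  sites <- findPrimerSites(tmpl, primer)
  expect_equal(sites$strand, c("+", "-"))
  expect_equal(sites$start[1], 61L)
  for (mm in 0:2) {
    for (i in 1:4) {
      t2 <- rand_dna(300, gc = 0.5)
      p2 <- substr(t2, 101, 118)  # a real 18-mer site
      got <- findPrimerSites(t2, p2, maxMismatch = mm)
      want <- oracle_primer_sites(t2, p2, mm)
      expect_equal(got$start[got$strand == "+"], want$fwd)
      expect_equal(got$start[got$strand == "-"], want$rev)
    }
  }
  # IUPAC degeneracy in the primer matches its expansion set
  expect_equal(nrow(findPrimerSites("AAACGTAAACGTAAACGTAA",
                                    "AAACGTAAACGTAAR")), 1L)
})

test_that("in-silico PCR sizes amplicons with both primer footprints", {
  sim <- makeVntrLocus(periodLen = 141, nFull = 3, flankF = 100,
                       flankR = 100, primerLen = 20, seed = 151)
  tr <- sim$truth
  pp <- primerPair("vntr", tr$primerF, tr$primerR)
  amp <- inSilicoPCR(sim$seq, pp)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 100L + 3L * 141L + 100L)  # 623
  expect_equal(amp$length, tr$ampliconLength)
  # no reverse site -> empty, distinguished from a QC failure
  noRev <- substr(as.character(sim$seq[[1]]), 1, 500)
  expect_equal(nrow(inSilicoPCR(noRev, pp)), 0L)
  # product cap
  ppShort <- primerPair("vntr", tr$primerF, tr$primerR, maxProduct = 500)
  expect_equal(nrow(inSilicoPCR(sim$seq, ppShort)), 0L)
})

test_that("packaged primer set carries the published marker pairs", {
  pr <- mlvaPrimers()
  expect_setequal(names(pr),
                  c("VNTR-141", "VNTR-105", "WD0550", "WD0766", "wsp"))
  expect_equal(pr[["VNTR-141"]]@forward, "GGAGTATTATTGATATGCG")
  expect_equal(pr[["VNTR-105"]]@reverse, "ATGACACCTTACTTAACCGTC")
  for (p in pr) expect_gte(nchar(p@forward), 15L)
  expect_error(primerPair("x", "ACGT", "ACGTACGTACGTACGT"), ">= 15")
})

test_that("allele calling decomposes amplicon interiors", {
  sim <- makeVntrLocus(periodLen = 105, nFull = 2, nHalf = 1,
                       halfDeletionLen = 25, flankF = 90, flankR = 90,
                       seed = 161)
  al <- callAllele(sim$seq[[1]], sim$truth$periodSeq, "VNTR-105-like")
  expect_s4_class(al, "MlvaAllele")
  expect_equal(copyString(al), "2+1x0.5")
  expect_equal(ampliconLength(al), sim$truth$ampliconLength)
  # flanks only: size-only typing remains possible
  flanksOnly <- paste0(rand_dna(90), rand_dna(90))
  al0 <- callAllele(flanksOnly, sim$truth$periodSeq, "x")
  expect_true(is.na(copyNumber(al0)))
  expect_equal(ampliconLength(al0), 180L)
  al1 <- callAllele(flanksOnly, NULL, "x")
  expect_true(is.na(copyNumber(al1)))
})

test_that("adding one full period shifts the amplicon by exactly one period", {
  for (p in c(105L, 141L)) {
    s4 <- makeVntrLocus(periodLen = p, nFull = 4, flankF = 120,
                        flankR = 120, seed = 171)
    s5 <- makeVntrLocus(periodLen = p, nFull = 5, flankF = 120,
                        flankR = 120, seed = 171)
    pp <- primerPair("x", s4$truth$primerF, s4$truth$primerR)
    a4 <- inSilicoPCR(s4$seq, pp); a5 <- inSilicoPCR(s5$seq, pp)
    expect_equal(a5$length - a4$length, p)
    c4 <- callAllele(substr(as.character(s4$seq[[1]]), a4$start, a4$end),
                     s4$truth$periodSeq)
    c5 <- callAllele(substr(as.character(s5$seq[[1]]), a5$start, a5$end),
                     s5$truth$periodSeq)
    expect_equal(copyNumber(c5) - copyNumber(c4), 1.0)
  }
})

test_that("profiles flag multiple infections and failed QC", {
  # two co-infecting strains differing by 2 periods at one locus
  sA <- makeVntrLocus(periodLen = 141, nFull = 3, flankF = 100,
                      flankR = 100, seed = 181)
  sB <- makeVntrLocus(periodLen = 141, nFull = 5, flankF = 100,
                      flankR = 100, seed = 181)
  pp <- primerPair("V141", sA$truth$primerF, sA$truth$primerR)
  wsp <- mlvaPrimers()[["wsp"]]
  set.seed(182)
  wspTemplate <- paste0(wsp@forward, rand_dna(300), revcomp(wsp@reverse))
  mix <- c(a = as.character(sA$seq[[1]]), b = as.character(sB$seq[[1]]),
           w = wspTemplate)
  prof <- buildProfile("mixed", mix, list(pp, wsp),
                       consensi = list(V141 = sA$truth$periodSeq))
  expect_true(prof@multipleInfection[["V141"]])
  expect_true(qcPassed(prof))
  lens <- sort(vapply(alleles(prof)[["V141"]], ampliconLength, integer(1)))
  expect_equal(diff(lens), 282L)  # 2 periods apart
  # single strain: no flags
  single <- buildProfile("single", c(a = as.character(sA$seq[[1]]),
                                     w = wspTemplate),
                         list(pp, wsp),
                         consensi = list(V141 = sA$truth$periodSeq))
  expect_false(single@multipleInfection[["V141"]])
  # QC locus absent from the extract
  noQc <- buildProfile("noqc", c(a = as.character(sA$seq[[1]])),
                       list(pp, wsp),
                       consensi = list(V141 = sA$truth$periodSeq))
  expect_false(qcPassed(noQc))
  # mixture completeness: k strains -> k distinct lengths
  sC <- makeVntrLocus(periodLen = 141, nFull = 7, flankF = 100,
                      flankR = 100, seed = 181)
  mix3 <- c(mix, c3 = as.character(sC$seq[[1]]))
  p3 <- buildProfile("mix3", mix3, list(pp, wsp),
                     consensi = list(V141 = sA$truth$periodSeq))
  expect_equal(length(unique(vapply(alleles(p3)[["V141"]], ampliconLength,
                                    integer(1)))), 3L)

  tsv <- tempfile(fileext = ".tsv")
  df <- writeProfileTsv(list(prof, single, noQc), tsv)
  expect_true(file.exists(tsv))
  expect_true("multiple_infection" %in%
                df$flags[df$strain == "mixed"])
  gel <- gelReport(list(prof))
  expect_true(any(grepl("multiple|\\|", gel)) || length(gel) >= 2)
})

test_that("profile distance is Manhattan over shared loci", {
  mk <- function(id, n141, n105) {
    s1 <- makeVntrLocus(periodLen = 141, nFull = n141, flankF = 100,
                        flankR = 100, seed = 191)
    s2 <- makeVntrLocus(periodLen = 105, nFull = n105, flankF = 100,
                        flankR = 100, seed = 192)
    p1 <- primerPair("V141", s1$truth$primerF, s1$truth$primerR)
    p2 <- primerPair("V105", s2$truth$primerF, s2$truth$primerR)
    buildProfile(id, c(a = as.character(s1$seq[[1]]),
                       b = as.character(s2$seq[[1]])),
                 list(p1, p2), qcLocus = NA,
                 consensi = list(V141 = s1$truth$periodSeq,
                                 V105 = s2$truth$periodSeq))
  }
  pa <- mk("A", 4, 3); pb <- mk("B", 5, 3)
  expect_equal(as.numeric(profileDistance(pa, pa)), 0)
  d <- profileDistance(pa, pb)
  expect_equal(as.numeric(d), 1.0)
  expect_equal(attr(d, "nLoci"), 2L)
  expect_equal(as.numeric(profileDistance(pa, mk("C", 6, 5))), 4.0)
})
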