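test_that("translation handles starts, fuzzy codons and premature stops", {
  tr <- translateCds("ATGAAATAA")
  expect_equal(tr$protein, "MK")
  expect_equal(tr$stopCodon, 3L)
  expect_true(is.na(tr$prematureStop))  # stop at the end is not premature
  # GTG start reads as M
  expect_equal(substr(translateCds("GTGAAATAA")$protein, 1, 1), "M")
  # internal N -> X
  expect_true(grepl("X", translateCds("ATGANGAAATAA")$protein))
  # 300-codon CDS with a stop planted at codon 150
  g <- makeAnkGene(nUnits = 12, tmTail = FALSE, prematureStopCodon = 150,
                   seed = 201)
  tr2 <- translateCds(as.character(g$seq[[1]]))
  expect_equal(tr2$prematureStop, 150L)
  expect_equal(nchar(tr2$protein), 149L)
  expect_error(translateCds("AT"), "codon")
  # planted unit codons translate back to the planted peptides
  g3 <- makeAnkGene(nUnits = 3, tmTail = FALSE, seed = 202)
  tr3 <- translateCds(as.character(g3$seq[[1]]))
  expect_equal(substr(tr3$protein, 2, 34), g3$truth$units[1])
})

test_that("ANK profile scanner is calibrated: consensus in, random out", {
  prof <- ankProfile()
  expect_equal(nchar(prof$consensus), 33L)
  # three exact concatenated consensus copies -> exactly 3 units
  p3 <- strrep(prof$consensus, 3)
  r3 <- findAnkRepeats(p3)
  expect_equal(nrow(r3), 3L)
  expect_equal(r3$aaStart, c(1L, 34L, 67L))
  # empirical null: random-composition proteins yield no units
  set.seed(211)
  aas <- rownames(prof$pssm)
  bg <- c(0.0780, 0.0512, 0.0448, 0.0536, 0.0192, 0.0426, 0.0629, 0.0738,
          0.0219, 0.0514, 0.0901, 0.0574, 0.0224, 0.0385, 0.0520, 0.0711,
          0.0584, 0.0132, 0.0321, 0.0644)
  for (i in 1:10) {
    rp <- paste(sample(aas, 500, TRUE, prob = bg), collapse = "")
    expect_equal(nrow(findAnkRepeats(rp)), 0L)
  }
  expect_equal(nrow(findAnkRepeats("MKLV")), 0L)  # < 30 aa
})

test_that("planted units are recovered exactly across the published range", {
  for (u in c(2L, 5L, 8L, 11L, 14L)) {
    g <- makeAnkGene(nUnits = u, tmTail = (u %% 2 == 0), seed = 220 + u)
    tr <- translateCds(as.character(g$seq[[1]]))
    r <- findAnkRepeats(tr$protein)
    expect_equal(nrow(r), u)
    expect_equal(r$aaStart, g$truth$unitAaStarts)
  }
  # units survive strain-level divergence
  g2 <- makeAnkGene(nUnits = 8, strainNoiseRate = 0.05,
                    strainId = "diverged", seed = 231)
  tr2 <- translateCds(as.character(g2$seq[[1]]))
  expect_equal(nrow(findAnkRepeats(tr2$protein)), 8L)
})

test_that("hydropathy TM prediction finds planted tails and nothing else", {
  expect_equal(length(predictTm(strrep("L", 30))), 1L)
  expect_equal(length(predictTm(strrep("D", 30))), 0L)
  expect_equal(length(predictTm("MKL")), 0L)  # shorter than the window
  g <- makeAnkGene(nUnits = 8, tmTail = TRUE, seed = 241)
  tr <- translateCds(as.character(g$seq[[1]]))
  tm <- predictTm(tr$protein)
  expect_equal(length(tm), 2L)
  # both segments near the C-terminus (window union may reach a few
  # residues into the last repeat)
  expect_true(all(BiocGenerics::start(tm) > 8 * 33 - 15))
  expect_equal(length(predictTm(translateCds(
    as.character(makeAnkGene(nUnits = 8, tmTail = FALSE,
                             seed = 241)$seq[[1]]))$protein)), 0L)
})

test_that("protein mass is additive average mass in kDa", {
  expect_equal(proteinMass("GG"), 0.1)  # 132.1 Da
  expect_error(proteinMass(""), "empty")
  set.seed(251)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (i in 1:5) {
    p1 <- paste(sample(aas, 40, TRUE), collapse = "")
    p2 <- paste(sample(aas, 60, TRUE), collapse = "")
    # mass(P1 + P2) = mass(P1) + mass(P2) - water, up to kDa rounding
    m12 <- proteinMass(paste0(p1, p2))
    expect_lt(abs(m12 - (proteinMass(p1) + proteinMass(p2) - 0.0180153)),
              0.11)
  }
})

test_that("large insertions are detected with exact lengths and positions", {
  ref <- as.character(makeAnkGene(nUnits = 10, tmTail = FALSE,
                                  seed = 261)$seq[[1]])
  # a 918 bp element planted mid-gene (inside the 10th unit region)
  at <- 700L
  ins <- as.character(makeAnkGene(nUnits = 10, tmTail = FALSE,
                                  insertion = list(position = at,
                                                   length = 918L),
                                  seed = 261)$seq[[1]])
  got <- detectInsertion(ins, ref)
  expect_equal(nrow(got), 1L)
  expect_equal(got$length, 918L)
  expect_equal(got$position, at)
  expect_equal(nrow(detectInsertion(ref, ref)), 0L)
  # two planted insertions recovered with exact lengths
  two <- paste0(substr(ins, 1, 200),
                paste(rep("GACTT", 30), collapse = ""),
                substr(ins, 201, nchar(ins)))
  got2 <- detectInsertion(two, ref)
  expect_setequal(got2$length, c(150L, 918L))
  set.seed(262)
  expect_error(detectInsertion(rand_dna(900), ref), "not orthologous")
})

test_that("frameshift correction restores the reading frame", {
  ref <- as.character(makeAnkGene(nUnits = 6, tmTail = FALSE,
                                  seed = 271)$seq[[1]])
  shifted <- paste0(substr(ref, 1, 300), substr(ref, 302, nchar(ref)))
  fixed <- correctFrameshifts(shifted, ref)
  expect_equal(nrow(fixed$corrections), 1L)
  expect_equal(nchar(fixed$gene) %% 3L, 0L)
  trRef <- translateCds(ref); trFix <- translateCds(fixed$gene)
  expect_true(is.na(trFix$prematureStop))
})

test_that("center-star alignment keeps all residues at bounded width", {
  u33 <- "DKDGNTPLHLAASNGHLEIVEVLLKAGADVNAK"
  u34 <- "DKDGNTPLHLAASNGGHLEIVEVLLKAGADVNAK"
  al <- alignRepeatUnits(c(a = u33, b = u34))
  expect_equal(unique(nchar(al)), 34L)
  expect_lte(unique(nchar(al)), 40L)
  expect_equal(sum(strsplit(al[["a"]], "")[[1]] == "-"), 1L)
  expect_identical(unname(gsub("-", "", al)), c(u33, u34))
  # identical units align without gaps
  al2 <- alignRepeatUnits(c(x = u33, y = u33, z = u33))
  expect_false(any(grepl("-", al2)))
  # degapping restores inputs on generated unit sets
  g <- makeAnkGene(nUnits = 6, seed = 281)
  units <- setNames(g$truth$units, paste0("u", seq_along(g$truth$units)))
  al3 <- alignRepeatUnits(units)
  expect_identical(gsub("-", "", al3), setNames(unname(units), names(units)))
  expect_lte(unique(nchar(al3))[1], 40L)
  expect_error(alignRepeatUnits(c(a = u33)), ">= 2")
})

test_that("neighbor joining recovers additive trees and matches ape", {
  set.seed(291)
  for (i in 1:25) {
    nt <- sample(4:8, 1)
    t0 <- ape::rtree(nt, rooted = FALSE)
    t0$edge.length <- stats::runif(nrow(t0$edge), 0.1, 1)
    D <- stats::cophenetic(t0)
    D <- D[order(rownames(D)), order(colnames(D))]
    mine <- njTree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(t0)), 0)
    expect_equal(phangorn::RF.dist(ape::unroot(mine),
                                   ape::unroot(ape::nj(stats::as.dist(D)))), 0)
    # NJ reproduces additive distances
    expect_lt(max(abs(stats::cophenetic(mine)[rownames(D), colnames(D)] - D)),
              1e-6)
  }
})

test_that("repeat-unit trees pair identical units and are deterministic", {
  u <- c(A = "DKDGNTPLHLAASNGHLEIVEVLLKAGADVNAK",
         A2 = "DKDGNTPLHLAASNGHLEIVEVLLKAGADVNAK",
         B = "DRQGETPLHLAASNGHLEIVEVLLKAGADVNAH",
         B2 = "DRQGETPLHLAASNGHLEIVEVLLKAGADVNAH")
  tr <- repeatUnitTree(u)
  nwk <- ape::write.tree(tr)
  expect_identical(nwk, ape::write.tree(repeatUnitTree(u)))  # deterministic
  # A/A2 and B/B2 must be cherries
  cp <- stats::cophenetic(tr)
  expect_equal(cp["A", "A2"], 0)
  expect_equal(cp["B", "B2"], 0)
  expect_gt(cp["A", "B"], 0)
  # all-identical units: star tree with zero branch lengths
  star <- repeatUnitTree(c(x = u[["A"]], y = u[["A"]], z = u[["A"]]))
  expect_equal(sum(star$edge.length), 0)
  expect_error(repeatUnitTree(u[1:2]), ">= 3")
})

test_that("duplicated units sit as siblings in the unit tree", {
  g <- makeAnkGene(nUnits = 6, duplicateIndices = 3, seed = 301)
  units <- setNames(g$truth$units,
                    paste0("u", seq_along(g$truth$units)))
  tr <- repeatUnitTree(units)
  cp <- stats::cophenetic(tr)
  # the duplicated pair (positions 3 and 4 after insertion) is closest
  expect_equal(cp["u3", "u4"], min(cp[upper.tri(cp)]))
})

test_that("position clustering flags planted duplications and shuffles only", {
  pull <- function(g, nm) {
    tr <- translateCds(as.character(g$seq[[1]]))
    r <- findAnkRepeats(tr$protein)
    data.frame(unit = r$unit, strain = nm, index = r$index)
  }
  ref <- pull(makeAnkGene(nUnits = 10, seed = 311, strainId = "ref",
                          strainNoiseRate = 0.03), "ref")
  dup <- pull(makeAnkGene(nUnits = 10, duplicateIndices = 3, seed = 311,
                          strainId = "dup", strainNoiseRate = 0.03), "dup")
  swp <- pull(makeAnkGene(nUnits = 10, swapIndices = c(8, 9), seed = 311,
                          strainId = "swp", strainNoiseRate = 0.03), "swp")
  all3 <- rbind(ref, dup, swp)
  res <- clusterPositions(all3$unit, all3$strain, all3$index)
  expect_equal(res$duplications$strain, "dup")
  expect_match(res$duplications$indices, "3,4")
  expect_true(all(c("swp") %in% c(res$shufflings$strainA,
                                  res$shufflings$strainB)))
  # ref and dup agree in order: no shuffling between them
  expect_false(any(res$shufflings$strainA == "ref" &
                     res$shufflings$strainB == "dup"))
  # identical architectures -> no events at all
  res0 <- clusterPositions(c(ref$unit, ref$unit),
                           c(ref$strain, rep("copy", nrow(ref))),
                           c(ref$index, ref$index))
  expect_equal(nrow(res0$duplications), 0L)
  expect_equal(nrow(res0$shufflings), 0L)
})

test_that("architecture assembly mirrors planted events end to end", {
  g <- makeAnkGene(nUnits = 8, tmTail = TRUE, seed = 321)
  a <- ankArchitecture(as.character(g$seq[[1]]), "full")
  expect_equal(nrow(ankRepeats(a)), 8L)
  expect_equal(length(tmSegments(a)), 2L)
  expect_true(is.na(prematureStop(a)))
  # premature stop before the tail ablates the TM segments
  gs <- makeAnkGene(nUnits = 8, tmTail = TRUE, prematureStopCodon = 200,
                    seed = 321)
  as_ <- ankArchitecture(as.character(gs$seq[[1]]), "stopped")
  expect_equal(prematureStop(as_), 200L)
  expect_equal(length(tmSegments(as_)), 0L)
  expect_lt(nrow(ankRepeats(as_)), 8L)
  expect_lt(massKda(as_), massKda(a))
})
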