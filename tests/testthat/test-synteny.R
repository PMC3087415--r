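test_that("rotation to the first feature is the identity", {
  sim <- simulateGenomePair(SimParams(nGenes = 10L, seed = 14L))
  g <- sim$A
  first <- S4Vectors::mcols(features(g))$locus_tag[1]
  r <- rotateOrigin(g, first)
  # first feature of a simulated genome does not start at 1 (leading spacer),
  # so rotate once more to verify idempotence at the destination
  r2 <- rotateOrigin(r, first)
  expect_equal(start(features(r))[1] , 1L)
  expect_identical(as.character(genomeSeq(r2)), as.character(genomeSeq(r)))
  expect_identical(start(features(r2)), start(features(r)))
})

test_that("successive rotations compose like a group action", {
  sim <- simulateGenomePair(SimParams(nGenes = 8L, seed = 15L))
  g <- sim$A
  tags <- S4Vectors::mcols(features(g))$locus_tag
  once <- rotateOrigin(g, tags[5])
  twice <- rotateOrigin(rotateOrigin(g, tags[3]), tags[5])
  expect_identical(as.character(genomeSeq(twice)), as.character(genomeSeq(once)))
  expect_identical(start(features(twice)), start(features(once)))
  expect_identical(as.character(strand(features(twice))),
                   as.character(strand(features(once))))
})

test_that("rotation refuses absent anchors and linear genomes", {
  sim <- simulateGenomePair(SimParams(nGenes = 5L, seed = 16L))
  expect_error(rotateOrigin(sim$A, "NOPE_1"), "not found")
  lin <- newGenomeRecord("lin", circular = FALSE, seq = "ATGCATGCATGC",
                         features = features(sim$A)[0])
  expect_error(rotateOrigin(lin, "x"), "circular")
})

test_that("identical genomes give colinear points on the diagonal", {
  sim <- simulateGenomePair(SimParams(nGenes = 12L, substPerSite = 0,
                                      pDup = 0, pDel = 0, pSplit = 0,
                                      pHgt = 0, nInversions = 0L, seed = 3L))
  om <- truthOrthologs(sim$truth)
  part <- partitionGenomes(sim$A, sim$B,
                           data.frame(id_a = om$locus_a[om$ftype == "CDS"],
                                      id_b = om$locus_b[om$ftype == "CDS"]),
                           data.frame(id_a = om$locus_a[om$ftype != "CDS"],
                                      id_b = om$locus_b[om$ftype != "CDS"]))
  pts <- dotPoints(part, sim$A, sim$B)
  expect_equal(nrow(pts), nrow(om))
  expect_true(all(pts$orientation == "colinear"))
  expect_equal(pts$x, pts$y)
  # empty partition, empty points
  empty <- partitionGenomes(sim$A, sim$B,
                            data.frame(id_a = character(),
                                       id_b = character()))
  expect_equal(nrow(dotPoints(empty, sim$A, sim$B)), 0L)
})

test_that("an inverted block shows up as exactly its antiparallel members", {
  sim <- simulateGenomePair(SimParams(nGenes = 60L, substPerSite = 0.05,
                                      pDup = 0, pDel = 0, pSplit = 0,
                                      pHgt = 0, nInversions = 1L, seed = 44L))
  om <- truthOrthologs(sim$truth)
  part <- partitionGenomes(sim$A, sim$B,
                           data.frame(id_a = om$locus_a[om$ftype == "CDS"],
                                      id_b = om$locus_b[om$ftype == "CDS"]),
                           data.frame(id_a = om$locus_a[om$ftype != "CDS"],
                                      id_b = om$locus_b[om$ftype != "CDS"]))
  pts <- dotPoints(part, sim$A, sim$B)
  ev <- truthEvents(sim$truth)
  members <- ev$locus_tag[ev$event == "inversion_member"]
  expect_gt(length(members), 0)
  expect_setequal(pts$id_b[pts$orientation == "antiparallel"], members)
  expect_equal(nrow(pts), nrow(om))
})

test_that("orientation is invariant under reverse-complementing both genomes", {
  run <- sharedRun()
  part <- run$res$partition
  pts <- dotPoints(part, run$sim$A, run$sim$B)
  rcPts <- dotPoints(part, revCompGenome(run$sim$A), revCompGenome(run$sim$B))
  o1 <- setNames(pts$orientation, pairKeys(pts))
  o2 <- setNames(rcPts$orientation, pairKeys(rcPts))
  expect_identical(o1, o2[names(o1)])
})

test_that("planted unique-CDS clusters are recovered exactly", {
  # 40 CDS of 300 bp spaced 700 bp; two clusters of 8 consecutive unique CDS
  n <- 40L
  st <- 1L + (seq_len(n) - 1L) * 1000L
  seqLen <- max(st) + 1000L
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(st, st + 299L),
                               strand = "+",
                               locus_tag = sprintf("C_%02d", seq_len(n)),
                               ftype = "CDS",
                               translation = "MKVLHEDQIRNFSTYCPAIM")
  g <- newGenomeRecord("c", seq = strrep("ACGT", ceiling(seqLen / 4)),
                       features = gr)
  uniq <- sprintf("C_%02d", c(3:10, 25:32))
  reg <- uniqueRegions(g, uniq, windowBp = 3000, minCount = 5)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$n_unique, c(8L, 8L))
  expect_equal(reg$start, st[c(3, 25)])
  # scattered uniques below the density threshold give no region
  sparse <- sprintf("C_%02d", seq(2, 38, by = 6))
  expect_equal(nrow(uniqueRegions(g, sparse, windowBp = 3000, minCount = 5)),
               0L)
  expect_equal(nrow(uniqueRegions(g, character(), 3000, 5)), 0L)
})

test_that("hotspot counts are unchanged by origin rotation", {
  n <- 30L
  st <- 1L + (seq_len(n) - 1L) * 1000L
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(st, st + 299L),
                               strand = "+",
                               locus_tag = sprintf("C_%02d", seq_len(n)),
                               ftype = "CDS", translation = "MK")
  g <- newGenomeRecord("c", seq = strrep("ACGT", 10000L), features = gr)
  uniq <- sprintf("C_%02d", 10:17)
  before <- uniqueRegions(g, uniq, 3000, 5)
  rot <- rotateOrigin(g, "C_05")
  after <- uniqueRegions(rot, uniq, 3000, 5)
  expect_equal(after$n_unique, before$n_unique)
  expect_equal(after$end - after$start, before$end - before$start)
})
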