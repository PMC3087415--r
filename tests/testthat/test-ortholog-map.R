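test_that("identical proteomes match one-to-one with no reuse", {
  sim <- simulateGenomePair(SimParams(nGenes = 15L, substPerSite = 0,
                                      pDup = 0, pDel = 0, pSplit = 0,
                                      pHgt = 0, nInversions = 0L, seed = 6L))
  p <- proteinSet(sim$A); q <- proteinSet(sim$B)
  h <- allVsAll(p, q, proteinScoring(), 1e-4)
  m <- oneToOneMatch(h, orthopair:::.transposeHits(h), 1e-8)
  expect_equal(nrow(m), 15L)
  expect_false(anyDuplicated(m$id_a) > 0)
  expect_false(anyDuplicated(m$id_b) > 0)
  expect_equal(sub("SGA", "SGB", sort(m$id_a)), sort(m$id_b))
})

test_that("greedy matching honours the uniqueness rule on a 3-vs-3 score table", {
  # a1's best hit is b1, but b1's best partner is a2 with a lower E-value:
  # b1 must go to a2 and a1 falls back to its next admissible partner b2
  hitsAB <- data.frame(
    qid = c("a1", "a1", "a2", "a3"),
    sid = c("b1", "b2", "b1", "b3"),
    evalue = c(1e-30, 1e-20, 1e-40, 1e-10),
    bitscore = c(120, 90, 150, 60))
  hitsBA <- data.frame(qid = hitsAB$sid, sid = hitsAB$qid,
                       evalue = hitsAB$evalue, bitscore = hitsAB$bitscore)
  m <- oneToOneMatch(hitsAB, hitsBA, 1e-8)
  key <- setNames(m$id_b, m$id_a)
  expect_equal(key[["a2"]], "b1")
  expect_equal(key[["a1"]], "b2")
  expect_equal(key[["a3"]], "b3")
  # under a tighter cutoff only (a2,b1) at 1e-40 and (a1,b1) at 1e-30 remain
  # admissible; b1 is consumed by a2, so a1 is left unmatched
  m25 <- oneToOneMatch(hitsAB, hitsBA, 1e-25)
  expect_equal(sort(m25$id_a), "a2")
  expect_identical(oneToOneMatch(hitsAB[0, ], hitsBA[0, ], 1e-8)$id_a,
                   character(0))
})

test_that("reciprocal-best-hit mode only keeps mutual best hits", {
  hitsAB <- data.frame(
    qid = c("a1", "a1", "a2"), sid = c("b1", "b2", "b1"),
    evalue = c(1e-30, 1e-20, 1e-40), bitscore = c(120, 90, 150))
  hitsBA <- data.frame(qid = hitsAB$sid, sid = hitsAB$qid,
                       evalue = hitsAB$evalue, bitscore = hitsAB$bitscore)
  m <- oneToOneMatch(hitsAB, hitsBA, 1e-8, method = "rbh")
  # a2<->b1 is mutual; a1's best (b1) is taken and a1-b2 is not mutual-best
  expect_equal(nrow(m), 1L)
  expect_equal(m$id_a, "a2")
})

test_that("global validation computes identity/similarity over full columns", {
  s <- "MKVLHEDQIRNFSTYCPAIM"
  v <- validatePairs(data.frame(id_a = "x", id_b = "y",
                                evalue = 1e-30, bitscore = 100),
                     setNames(s, "x"), setNames(s, "y"))
  expect_equal(v$global_identity, 100)
  expect_equal(v$global_similarity, 100)
  expect_equal(v$aln_len, nchar(s))
  expect_error(validatePairs(data.frame(id_a = "x", id_b = "zz",
                                        evalue = 1, bitscore = 1),
                             setNames(s, "x"), setNames(s, "y")),
               "missing sequence")
})

test_that("global scores agree with an exhaustive DP reference on small instances", {
  set.seed(33)
  sc <- proteinScoring()
  for (i in 1:15) {
    a <- randomProtein(sample(5:30, 1)); b <- randomProtein(sample(5:30, 1))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(a), Biostrings::AAStringSet(b), type = "global",
      substitutionMatrix = sc$matrix, gapOpening = sc$gapOpen,
      gapExtension = sc$gapExt)
    expect_equal(Biostrings::score(pa),
                 oracleGlobalScore(a, b, sc$matrix, sc$gapOpen, sc$gapExt))
  }
})

test_that("unrelated proteins fall below 10% identity and are dropped", {
  # compositionally disjoint sequences: no column can be identical
  set.seed(101)
  a <- paste(sample(c("A", "V", "L", "I"), 100, TRUE), collapse = "")
  b <- paste(sample(c("D", "E", "K", "R"), 100, TRUE), collapse = "")
  expect_message(
    v <- validatePairs(data.frame(id_a = "ra", id_b = "rb",
                                  evalue = 1e-9, bitscore = 40),
                       setNames(a, "ra"), setNames(b, "rb"),
                       minIdentity = 10),
    "dropped")
  expect_equal(nrow(v), 0L)
})

test_that("E-value bands shift towards weaker bins with divergence", {
  run <- function(subst, seed) {
    sim <- simulateGenomePair(SimParams(nGenes = 40L, substPerSite = subst,
                                        pDup = 0, pDel = 0, pSplit = 0,
                                        pHgt = 0, nInversions = 0L,
                                        seed = seed))
    p <- proteinSet(sim$A); q <- proteinSet(sim$B)
    h <- allVsAll(p, q, proteinScoring(), 1e-4)
    m <- oneToOneMatch(h, orthopair:::.transposeHits(h), 1e-8)
    binPairs(validatePairs(m, p, q))
  }
  lo <- run(0.05, 51L); hi <- run(0.5, 51L)
  fLo <- setNames(lo$bands$fraction, lo$bands$band)
  fHi <- setNames(hi$bands$fraction, hi$bands$band)
  expect_gt(fLo[["<=1e-100"]], fHi[["<=1e-100"]])
  expect_lt(fLo[["(1e-50,1e-25]"]] + fLo[["(1e-25,1e-8]"]],
            fHi[["(1e-50,1e-25]"]] + fHi[["(1e-25,1e-8]"]])
  # identical full-length genes (long enough that self-scores clear the
  # strongest band) concentrate at similarity 100
  sim0 <- simulateGenomePair(SimParams(nGenes = 10L, substPerSite = 0,
                                       geneLenMean = 300, geneLenSd = 0,
                                       pDup = 0, pDel = 0, pSplit = 0,
                                       pHgt = 0, nInversions = 0L, seed = 1L))
  p <- proteinSet(sim0$A); q <- proteinSet(sim0$B)
  h <- allVsAll(p, q, proteinScoring(), 1e-4)
  b0 <- binPairs(validatePairs(oneToOneMatch(h, orthopair:::.transposeHits(h),
                                             1e-8), p, q))
  expect_equal(b0$fraction_similarity_100, 100)
  expect_equal(setNames(b0$bands$fraction, b0$bands$band)[["<=1e-100"]], 100)
})

test_that("partition fields are disjoint, exhaustive, and truth-exact without splits", {
  p <- SimParams(nGenes = 60L, pSplit = 0, seed = 71L)
  sim <- simulateGenomePair(p)
  res <- suppressMessages(runPipeline(sim$A, sim$B, runConfig()))
  part <- res$partition
  expect_equal(nrow(orthologPairs(part)) + length(uniqueLoci(part, "A")),
               countFeatures(sim$A, "CDS"))
  expect_equal(nrow(orthologPairs(part)) + length(uniqueLoci(part, "B")),
               countFeatures(sim$B, "CDS"))
  om <- truthOrthologs(sim$truth)
  omCds <- om[om$ftype == "CDS", ]
  expect_setequal(pairKeys(orthologPairs(part)), pairKeys(omCds))
  tagsA <- S4Vectors::mcols(features(sim$A))
  cdsA <- tagsA$locus_tag[tagsA$ftype == "CDS"]
  expect_setequal(uniqueLoci(part, "A"), setdiff(cdsA, omCds$locus_a))
  # RNA genes partition separately
  expect_setequal(pairKeys(part@rnaPairs),
                  pairKeys(om[om$ftype != "CDS", ]))
  expect_error(partitionGenomes(sim$A, sim$B,
                                data.frame(id_a = "nope", id_b = "nada")),
               "unknown")
})

test_that("identical genomes leave both unique sets empty", {
  sim <- simulateGenomePair(SimParams(nGenes = 12L, substPerSite = 0,
                                      pDup = 0, pDel = 0, pSplit = 0,
                                      pHgt = 0, nInversions = 0L, seed = 2L))
  res <- suppressMessages(runPipeline(sim$A, sim$B, runConfig()))
  expect_length(uniqueLoci(res$partition, "A"), 0L)
  expect_length(uniqueLoci(res$partition, "B"), 0L)
  expect_equal(nrow(res$partition@rnaPairs), 10L)
})

test_that("no locus tag is reused and the pair set transposes under genome swap", {
  run <- sharedRun()
  pairs <- run$res$pairs
  expect_false(anyDuplicated(pairs$id_a) > 0)
  expect_false(anyDuplicated(pairs$id_b) > 0)
  swapped <- oneToOneMatch(run$res$hitsBA, run$res$hitsAB,
                           runConfig()$eCutoff)
  expect_setequal(paste(swapped$id_b, swapped$id_a),
                  pairKeys(run$res$matches))
})

test_that("tightening the cutoff strictly shrinks the pair set on a diverged pair", {
  sim <- simulateGenomePair(SimParams(nGenes = 120L, substPerSite = 0.45,
                                      geneLenMean = 120, geneLenSd = 60,
                                      pDup = 0, pDel = 0, pSplit = 0,
                                      pHgt = 0, nInversions = 0L, seed = 91L))
  p <- proteinSet(sim$A); q <- proteinSet(sim$B)
  h <- allVsAll(p, q, proteinScoring(), 1)
  ht <- orthopair:::.transposeHits(h)
  n8 <- nrow(oneToOneMatch(h, ht, 1e-8))
  n25 <- nrow(oneToOneMatch(h, ht, 1e-25))
  n50 <- nrow(oneToOneMatch(h, ht, 1e-50))
  expect_lt(n25, n8)
  expect_lte(n50, n25)
})
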