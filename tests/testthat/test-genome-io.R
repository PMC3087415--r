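test_that("GFF3+FASTA reading gives 1-based coordinates and table-11 translations", {
  gff <- system.file("extdata", "toy.gff3", package = "orthopair")
  fa <- system.file("extdata", "toy.fasta", package = "orthopair")
  g <- readGenome(gff, format = "gff3", fasta = fa)
  ft <- features(g)
  expect_s4_class(g, "GenomeRecord")
  expect_true(isCircularGenome(g))
  expect_equal(start(ft)[1], 1L)       # GFF start column carried through
  expect_equal(end(ft)[1], 9L)
  # ATGAAATAG translates to MK with the trailing stop stripped
  expect_equal(S4Vectors::mcols(ft)$translation[1], "MK")
  expect_true(is.na(S4Vectors::mcols(ft)$translation[2]))
  expect_equal(countFeatures(g, "CDS"), 1L)
  expect_equal(countFeatures(g, "tRNA"), 1L)
})

test_that("GenBank flat files parse: locations, strands, stored translations", {
  gb <- file.path(tempdir(), "mini.gbk")
  writeLines(c(
    "LOCUS       TESTREC00              60 bp    DNA     circular BCT 01-JAN-2000",
    "DEFINITION  synthetic test record.",
    "  ORGANISM  Testus fictus",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..9",
    "                     /locus_tag=\"T_0001\"",
    "                     /product=\"toy protein\"",
    "                     /translation=\"MK\"",
    "     CDS             complement(13..24)",
    "                     /locus_tag=\"T_0002\"",
    "     tRNA            join(31..40,45..54)",
    "                     /locus_tag=\"T_t1\"",
    "                     /product=\"tRNA-Gly\"",
    "ORIGIN",
    "        1 atgaaatagc cgcatggcgg cctagctaac ggattatcgc atgcatcgat cggctagcta",
    "//"), gb)
  g <- readGenome(gb, format = "genbank")
  ft <- features(g)
  expect_equal(recordId(g), "TESTREC00")
  expect_equal(organismName(g), "Testus fictus")
  expect_true(isCircularGenome(g))
  expect_equal(length(genomeSeq(g)), 60L)
  m <- S4Vectors::mcols(ft)
  expect_equal(m$locus_tag, c("T_0001", "T_0002", "T_t1"))
  # translation taken from the file when present
  expect_equal(m$translation[m$locus_tag == "T_0001"], "MK")
  expect_equal(as.character(strand(ft))[m$locus_tag == "T_0002"], "-")
  # ascending join (intron-carrying tRNA) collapsed to its span
  expect_equal(start(ft)[m$locus_tag == "T_t1"], 31L)
  expect_equal(end(ft)[m$locus_tag == "T_t1"], 54L)
})

test_that("malformed inputs are rejected with parse/validation errors", {
  fa <- file.path(tempdir(), "empty.fasta")
  writeLines(character(), fa)
  gff <- system.file("extdata", "toy.gff3", package = "orthopair")
  expect_error(readGenome(gff, format = "gff3", fasta = fa), "empty FASTA")

  gb <- file.path(tempdir(), "wrap.gbk")
  writeLines(c(
    "LOCUS       WRAP                   30 bp    DNA     circular BCT 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(25..30,1..6)",
    "                     /locus_tag=\"W_1\"",
    "ORIGIN",
    "        1 atgaaatagc cgttacggat cgttagcatg",
    "//"), gb)
  expect_error(readGenome(gb, format = "genbank"), "origin-spanning")

  expect_error(
    newGenomeRecord("x", seq = "ATGC",
                    features = GenomicRanges::GRanges(
                      "x", IRanges::IRanges(2, 12), strand = "+",
                      locus_tag = "f1", ftype = "CDS")),
    "outside sequence bounds")
  expect_error(readGenome("/no/such/file.gbk"), "no such file")
})

test_that("CDS with internal stops are flagged and excluded from proteins", {
  # TAA at codon 2 of a 4-codon CDS
  seqs <- paste0("ATG", "TAA", "AAA", "TAG", strrep("C", 18))
  gr <- GenomicRanges::GRanges("x", IRanges::IRanges(1, 12), strand = "+",
                               locus_tag = "bad1", ftype = "CDS")
  expect_message(g <- newGenomeRecord("x", seq = seqs, features = gr),
                 "internal stop")
  expect_true(is.na(S4Vectors::mcols(features(g))$translation[1]))
  expect_equal(length(proteinSet(g)), 0L)
})

test_that("write + re-read round trip preserves coordinates, strands, sequence", {
  sim <- simulateGenomePair(SimParams(nGenes = 12L, seed = 5L))
  g <- sim$A
  gff <- file.path(tempdir(), "rt.gff3")
  fa <- file.path(tempdir(), "rt.fasta")
  writeGenome(g, gff, fa)
  g2 <- readGenome(gff, format = "gff3", fasta = fa)
  expect_equal(as.character(genomeSeq(g2)), as.character(genomeSeq(g)))
  expect_equal(start(features(g2)), start(features(g)))
  expect_equal(end(features(g2)), end(features(g)))
  expect_equal(as.character(strand(features(g2))),
               as.character(strand(features(g))))
  expect_equal(S4Vectors::mcols(features(g2))$locus_tag,
               S4Vectors::mcols(features(g))$locus_tag)
  expect_true(isCircularGenome(g2))
  # re-derived translations equal the simulator's proteins
  expect_equal(as.character(proteinSet(g2)), as.character(proteinSet(g)))
})

test_that("gcContent follows its definition and is reverse-complement invariant", {
  expect_equal(gcContent("GGCC"), 100)
  expect_equal(gcContent("ATGC"), 50)
  expect_equal(gcContent("ATGCN"), 50)  # N excluded from the denominator
  expect_error(gcContent("NNNN"), "undefined")
  set.seed(9)
  for (i in 1:15) {
    s <- randomDna(sample(50:400, 1))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(gcContent(s), gcContent(rc))
  }
})

test_that("feature counts match the simulator's planted RNA complement", {
  sim <- simulateGenomePair(SimParams(nGenes = 15L, nTrna = 6L, nRrna = 3L,
                                      seed = 2L))
  expect_equal(countFeatures(sim$A, "tRNA"), 6L)
  expect_equal(countFeatures(sim$A, "rRNA"), 3L)
  expect_equal(countFeatures(sim$B, "tRNA"), 6L)
  sumr <- genomeSummary(sim$A, sim$B)
  expect_equal(sumr$n_trna, c(6L, 6L))
  expect_equal(sumr$length_bp, c(length(genomeSeq(sim$A)),
                                 length(genomeSeq(sim$B))))
  tsv <- file.path(tempdir(), "summary.tsv")
  genomeSummary(sim$A, file = tsv)
  expect_equal(read.delim(tsv)$n_cds, countFeatures(sim$A, "CDS"))
})
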