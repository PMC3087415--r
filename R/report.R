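#' Pipeline configuration
#'
#' Collects every tunable of the two-genome comparison with the defaults
#' used throughout: strict match cutoff `E <= 1e-8`, global-identity
#' validation at `>= 10%`, relaxed homology cutoff `1e-4` for origin
#' tracing, BLOSUM62 11/1 protein scoring and +2/-3 5/2 nucleotide scoring,
#' synteny hotspot window 10 kb / minimum 5, and the origin-classifier
#' thresholds.
#'
#' @param eCutoff strict expectation cutoff for ortholog matching.
#' @param minIdentity minimum global percent identity for a valid pair.
#' @param relaxedE relaxed cutoff used by the origin classifier.
#' @param protScoring,nucScoring scoring systems.
#' @param windowBp,minCount unique-region parameters.
#' @param gapMax,covMin,zMin,olapMax origin-classifier thresholds.
#' @param anchorLocus optional locus tag: rotate genome B there before
#'   synteny analysis.
#' @param seed RNG seed recorded with the run.
#' @return a list of class `"opConfig"`.
#' @export
runConfig <- function(eCutoff = 1e-8, minIdentity = 10, relaxedE = 1e-4,
                      protScoring = proteinScoring(),
                      nucScoring = nucleotideScoring(),
                      windowBp = 10000, minCount = 5,
                      gapMax = 300, covMin = 0.6, zMin = 2.5, olapMax = 0.2,
                      anchorLocus = NULL, seed = 1L) {
  stopifnot(eCutoff > 0, relaxedE > 0, minIdentity >= 0, minIdentity <= 100)
  structure(list(eCutoff = eCutoff, minIdentity = minIdentity,
                 relaxedE = relaxedE, protScoring = protScoring,
                 nucScoring = nucScoring, windowBp = windowBp,
                 minCount = minCount, gapMax = gapMax, covMin = covMin,
                 zMin = zMin, olapMax = olapMax, anchorLocus = anchorLocus,
                 seed = as.integer(seed)), class = "opConfig")
}

## mirror a hit table: with effective lengths equal to the raw pairwise
## lengths and a symmetric matrix, scores and E-values are direction
## symmetric, so the reverse search is the transpose
.transposeHits <- function(hits) {
  data.frame(qid = hits$sid, sid = hits$qid,
             pident_local = hits$pident_local, length = hits$length,
             mismatches = hits$mismatches, gapopens = hits$gapopens,
             qstart = hits$sstart, qend = hits$send,
             sstart = hits$qstart, send = hits$qend,
             evalue = hits$evalue, bitscore = hits$bitscore,
             raw_score = hits$raw_score)
}

#' Genome-comparison summary report
#'
#' Per-genome rows of the headline statistics: replicon size, G+C, CDS
#' totals, CDS in common / not in common, RNA gene counts and RNA genes in
#' common — the computed analogue of a published genome-comparison table.
#'
#' @param A,B [GenomeRecord-class] objects.
#' @param partition a [GenomePartition-class].
#' @return data.frame with columns `metric`, `value_a`, `value_b`.
#' @export
summaryReport <- function(A, B, partition) {
  nP <- nrow(orthologPairs(partition))
  nR <- nrow(partition@rnaPairs)
  rnaCount <- function(g) countFeatures(g, "tRNA") + countFeatures(g, "rRNA") +
    countFeatures(g, "other_RNA")
  data.frame(
    metric = c("record_id", "chromosome_size_bp", "gc_molpct", "cds",
               "cds_in_common", "cds_not_in_common", "trna", "rrna",
               "other_rna", "rna_in_common", "rna_not_in_common"),
    value_a = c(recordId(A), length(genomeSeq(A)), gcContent(A),
                countFeatures(A, "CDS"), nP, length(uniqueLoci(partition, "A")),
                countFeatures(A, "tRNA"), countFeatures(A, "rRNA"),
                countFeatures(A, "other_RNA"), nR,
                rnaCount(A) - nR),
    value_b = c(recordId(B), length(genomeSeq(B)), gcContent(B),
                countFeatures(B, "CDS"), nP, length(uniqueLoci(partition, "B")),
                countFeatures(B, "tRNA"), countFeatures(B, "rRNA"),
                countFeatures(B, "other_RNA"), nR,
                rnaCount(B) - nR))
}

#' Audit a curated gene catalogue against the computed ortholog map
#'
#' For each catalogue entry (a functional gene with its locus tag in each
#' genome) reports whether the tags exist in the annotations, whether the
#' two tags form a computed ortholog pair, and a status flag:
#' `paired`, `other_partner` (both present but paired elsewhere),
#' `unpaired` (both present, neither paired), `missing_locus`, or
#' `one_sided` (the catalogue itself lists only one genome).
#'
#' @param entries data.frame with columns `locus_a`, `locus_b` (NA allowed)
#'   and any annotation columns (e.g. `category`, `complex`).
#' @param partition a [GenomePartition-class].
#' @param A,B the [GenomeRecord-class] objects.
#' @return `entries` with added columns `present_a`, `present_b`, `paired`,
#'   `status`.
#' @export
auditCatalogue <- function(entries, partition, A, B) {
  tagsA <- mcols(features(A))$locus_tag
  tagsB <- mcols(features(B))$locus_tag
  pairKey <- paste(orthologPairs(partition)$id_a,
                   orthologPairs(partition)$id_b)
  entries$present_a <- !is.na(entries$locus_a) & entries$locus_a %in% tagsA
  entries$present_b <- !is.na(entries$locus_b) & entries$locus_b %in% tagsB
  entries$paired <- paste(entries$locus_a, entries$locus_b) %in% pairKey
  entries$status <- ifelse(
    is.na(entries$locus_a) | is.na(entries$locus_b), "one_sided",
    ifelse(!entries$present_a | !entries$present_b, "missing_locus",
    ifelse(entries$paired, "paired",
    ifelse(entries$locus_a %in% orthologPairs(partition)$id_a |
             entries$locus_b %in% orthologPairs(partition)$id_b,
           "other_partner", "unpaired"))))
  entries
}

#' Read the packaged methanogenesis gene catalogue
#'
#' A transcription of the published inventory of the ~200 genes for methane
#' formation and energy conservation in the two *Methanothermobacter*
#' genomes, expanded to individual locus-tag pairs where the published
#' ranges correspond element-wise; entries with ambiguous alternatives are
#' flagged (`ambiguous == TRUE`) and not expanded.
#'
#' @param file path to a catalogue TSV; defaults to the packaged one.
#' @return data.frame with columns `category`, `complex`, `locus_a`,
#'   `locus_b`, `ambiguous`, `note`.
#' @export
readCatalogue <- function(file = system.file("extdata",
                                             "methanogenesis_catalogue.tsv",
                                             package = "orthopair")) {
  read.delim(file, comment.char = "#", na.strings = c("NA", ""))
}

#' Run the full two-genome comparison pipeline
#'
#' Executes, in order: protein and RNA extraction, all-vs-all local search
#' at the relaxed cutoff, one-to-one matching at the strict cutoff,
#' full-length global validation, shared/unique partitioning, synteny dot
#' points and unique-CDS hotspot detection, origin classification of both
#' unique sets, and the summary report. Deterministic given the inputs and
#' configuration.
#'
#' @param A,B [GenomeRecord-class] objects (or paths readable by
#'   [readGenome()] when `format` is given).
#' @param config a [runConfig()] list.
#' @param outDir optional directory; when given, all tables are written as
#'   TSV (`pairs.tsv`, `unique_a.tsv`, `unique_b.tsv`, `bins.tsv`,
#'   `hits_ab.tsv`, `synteny_points.tsv`, `unique_regions_[ab].tsv`,
#'   `origins_[ab].tsv`, `origin_summary.tsv`, `report.tsv`).
#' @return list with elements `hitsAB`, `hitsBA`, `matches`, `pairs`,
#'   `rnaPairs`, `partition`, `points`, `regionsA`, `regionsB`, `originsA`,
#'   `originsB`, `originSummaryA`, `originSummaryB`, `bins`, `report`,
#'   `config`.
#' @export
runPipeline <- function(A, B, config = runConfig(), outDir = NULL) {
  stopifnot(is(A, "GenomeRecord"), is(B, "GenomeRecord"))
  set.seed(config$seed)
  if (!is.null(config$anchorLocus)) B <- rotateOrigin(B, config$anchorLocus)
  protA <- proteinSet(A); protB <- proteinSet(B)
  rnaA <- rnaSet(A); rnaB <- rnaSet(B)

  message("searching: ", length(protA), " x ", length(protB), " proteins")
  hitsAB <- allVsAll(protA, protB, config$protScoring, config$relaxedE)
  hitsBA <- .transposeHits(hitsAB)
  matches <- oneToOneMatch(hitsAB, hitsBA, config$eCutoff)
  pairs <- validatePairs(matches, protA, protB, config$protScoring,
                         config$minIdentity)
  message("matched: ", nrow(pairs), " validated CDS pairs")

  rnaPairs <- data.frame(id_a = character(), id_b = character(),
                         evalue = numeric(), bitscore = numeric(),
                         global_identity = numeric(),
                         global_similarity = numeric(), aln_len = integer())
  if (length(rnaA) && length(rnaB)) {
    rnaHits <- allVsAll(rnaA, rnaB, config$nucScoring, config$relaxedE)
    rnaMatches <- oneToOneMatch(rnaHits, .transposeHits(rnaHits),
                                config$eCutoff)
    rnaPairs <- validatePairs(rnaMatches, rnaA, rnaB, config$nucScoring,
                              config$minIdentity)
  }

  partition <- partitionGenomes(A, B, pairs, rnaPairs)
  points <- dotPoints(partition, A, B)
  regionsA <- uniqueRegions(A, uniqueLoci(partition, "A"),
                            config$windowBp, config$minCount)
  regionsB <- uniqueRegions(B, uniqueLoci(partition, "B"),
                            config$windowBp, config$minCount)

  selfHitsFor <- function(prot, uniq) {
    if (!length(uniq)) return(.emptyHits())
    allVsAll(prot[uniq], prot, config$protScoring, config$eCutoff)
  }
  originsA <- classifyUnique(A, B, uniqueLoci(partition, "A"), hitsAB,
                             selfHitsFor(protA, uniqueLoci(partition, "A")),
                             pairs, side = "A", gapMax = config$gapMax,
                             covMin = config$covMin, zMin = config$zMin,
                             strictE = config$eCutoff,
                             olapMax = config$olapMax)
  originsB <- classifyUnique(B, A, uniqueLoci(partition, "B"), hitsBA,
                             selfHitsFor(protB, uniqueLoci(partition, "B")),
                             pairs, side = "B", gapMax = config$gapMax,
                             covMin = config$covMin, zMin = config$zMin,
                             strictE = config$eCutoff,
                             olapMax = config$olapMax)
  message("origins (A): ", paste(names(summarizeOrigins(originsA)$counts),
                                 summarizeOrigins(originsA)$counts,
                                 collapse = ", "))

  res <- list(hitsAB = hitsAB, hitsBA = hitsBA, matches = matches,
              pairs = pairs, rnaPairs = rnaPairs, partition = partition,
              points = points, regionsA = regionsA, regionsB = regionsB,
              originsA = originsA, originsB = originsB,
              originSummaryA = summarizeOrigins(originsA),
              originSummaryB = summarizeOrigins(originsB),
              bins = binPairs(pairs),
              report = summaryReport(A, B, partition),
              config = config)
  if (!is.null(outDir)) .writePipeline(res, partition, outDir)
  res
}

.writePipeline <- function(res, partition, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) write.table(x, file.path(outDir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  w(res$pairs, "pairs.tsv")
  w(data.frame(locus_tag = uniqueLoci(partition, "A")), "unique_a.tsv")
  w(data.frame(locus_tag = uniqueLoci(partition, "B")), "unique_b.tsv")
  w(res$bins$bands, "bins.tsv")
  w(res$hitsAB, "hits_ab.tsv")
  w(res$points, "synteny_points.tsv")
  w(res$regionsA, "unique_regions_a.tsv")
  w(res$regionsB, "unique_regions_b.tsv")
  w(res$originsA, "origins_a.tsv")
  w(res$originsB, "origins_b.tsv")
  su <- rbind(data.frame(genome = "A", label = names(res$originSummaryA$counts),
                         count = res$originSummaryA$counts,
                         fraction = res$originSummaryA$fractions),
              data.frame(genome = "B", label = names(res$originSummaryB$counts),
                         count = res$originSummaryB$counts,
                         fraction = res$originSummaryB$fractions))
  w(su, "origin_summary.tsv")
  w(res$report, "report.tsv")
  invisible(outDir)
}
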