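.FTYPES <- c("CDS", "tRNA", "rRNA", "other_RNA")

#' GenomeRecord: an annotated replicon
#'
#' Holds one replicon: its nucleotide sequence, whether it is circular, and
#' an ordered set of typed gene features (CDS, tRNA, rRNA, other_RNA) as a
#' [GenomicRanges::GRanges] with metadata columns `locus_tag`, `ftype`,
#' `product` and, for CDS, `translation` (amino acids, stop stripped).
#' Coordinates follow the GRanges/GFF3 convention (1-based, inclusive).
#'
#' @slot recordId accession-like identifier of the replicon.
#' @slot organism organism name.
#' @slot circular logical; `TRUE` for a circular replicon.
#' @slot seq a [Biostrings::DNAString] over `{A,C,G,T,N}`.
#' @slot features a `GRanges` sorted by start with the metadata columns
#'   described above; locus tags are unique within a record.
#'
#' @aliases GenomeRecord-class
#' @export GenomeRecord
#' @exportClass GenomeRecord
GenomeRecord <- setClass("GenomeRecord",
  slots = c(
    recordId = "character",
    organism = "character",
    circular = "logical",
    seq = "DNAString",
    features = "GRanges"
  )
)

setValidity("GenomeRecord", function(object) {
  msgs <- character()
  if (length(object@seq) < 1L)
    msgs <- c(msgs, "sequence must be non-empty")
  ft <- object@features
  if (length(ft)) {
    need <- c("locus_tag", "ftype")
    miss <- setdiff(need, colnames(mcols(ft)))
    if (length(miss))
      msgs <- c(msgs, paste("features lack mcols:", paste(miss, collapse = ", ")))
    else {
      if (anyDuplicated(mcols(ft)$locus_tag))
        msgs <- c(msgs, "locus_tag values must be unique within a record")
      bad <- !(mcols(ft)$ftype %in% .FTYPES)
      if (any(bad))
        msgs <- c(msgs, paste("unknown ftype:", paste(unique(mcols(ft)$ftype[bad]), collapse = ", ")))
      if (is.unsorted(start(ft)))
        msgs <- c(msgs, "features must be sorted by start")
      if (any(start(ft) < 1L) || any(end(ft) > length(object@seq)))
        msgs <- c(msgs, "feature coordinates outside sequence bounds")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GenomeRecord", function(object) {
  n <- table(factor(mcols(object@features)$ftype, levels = .FTYPES))
  cat("GenomeRecord", object@recordId,
      sprintf("(%s, %s, %d bp)\n", object@organism,
              if (object@circular) "circular" else "linear", length(object@seq)))
  cat(sprintf("  features: %d CDS, %d tRNA, %d rRNA, %d other_RNA\n",
              n[["CDS"]], n[["tRNA"]], n[["rRNA"]], n[["other_RNA"]]))
})

#' SimParams: parameters of the divergent genome-pair simulator
#'
#' Describes one simulation of two genomes diverged from a common ancestor:
#' gene complement size and length distribution, substitution divergence per
#' lineage, per-gene structural event probabilities (tandem duplication,
#' deletion, frameshift gene split, lateral insertion), number of inversion
#' blocks, composition shift of laterally acquired genes, and the RNA-gene
#' complement. See [simulateGenomePair()].
#'
#' @slot nGenes number of ancestral protein-coding genes.
#' @slot geneLenMean,geneLenSd protein length distribution (amino acids).
#' @slot substPerSite expected amino-acid substitutions per site per lineage.
#' @slot pDup,pDel,pSplit,pHgt per-gene structural event probabilities per
#'   lineage; at most one structural event is drawn per gene and lineage.
#' @slot dupExtraSubst additional divergence applied to a duplicate copy.
#' @slot nInversions number of contiguous blocks reverse-complemented in
#'   lineage B.
#' @slot gcTarget codon-model GC parameter used in back-translation.
#' @slot hgtGcShift offset added to `gcTarget` for laterally inserted genes.
#' @slot spacerLenMean mean intergenic spacer length (nt).
#' @slot nTrna,nRrna RNA genes planted per genome (slow-evolving nucleotide
#'   genes; no structural events).
#' @slot rnaSubstPerSite nucleotide substitutions per site per lineage for
#'   RNA genes.
#' @slot seed integer seed; identical parameters give identical output.
#'
#' @aliases SimParams-class
#' @export SimParams
#' @exportClass SimParams
SimParams <- setClass("SimParams",
  slots = c(
    nGenes = "integer", geneLenMean = "numeric", geneLenSd = "numeric",
    substPerSite = "numeric",
    pDup = "numeric", pDel = "numeric", pSplit = "numeric", pHgt = "numeric",
    dupExtraSubst = "numeric",
    nInversions = "integer",
    gcTarget = "numeric", hgtGcShift = "numeric",
    spacerLenMean = "numeric",
    nTrna = "integer", nRrna = "integer", rnaSubstPerSite = "numeric",
    seed = "integer"
  ),
  prototype = list(
    nGenes = 300L, geneLenMean = 200, geneLenSd = 60,
    substPerSite = 0.2,
    pDup = 0.05, pDel = 0.05, pSplit = 0.02, pHgt = 0.04,
    dupExtraSubst = 0.1,
    nInversions = 2L,
    gcTarget = 0.49, hgtGcShift = 0.10,
    spacerLenMean = 120,
    nTrna = 8L, nRrna = 2L, rnaSubstPerSite = 0.02,
    seed = 1L
  )
)

setValidity("SimParams", function(object) {
  msgs <- character()
  p <- c(object@pDup, object@pDel, object@pSplit, object@pHgt)
  if (any(p < 0) || any(p > 1))
    msgs <- c(msgs, "event probabilities must lie in [0, 1]")
  if (sum(p) > 1)
    msgs <- c(msgs, "pDup + pDel + pSplit + pHgt must not exceed 1")
  if (object@nGenes < 1L) msgs <- c(msgs, "nGenes must be >= 1")
  if (object@substPerSite < 0) msgs <- c(msgs, "substPerSite must be >= 0")
  if (object@geneLenMean <= 0) msgs <- c(msgs, "geneLenMean must be positive")
  if (object@nInversions < 0L) msgs <- c(msgs, "nInversions must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' TruthTable: simulator ground truth
#'
#' Records, for one simulated genome pair, the true one-to-one ortholog map,
#' the per-gene structural event log, and the ancestor of every extant gene.
#'
#' @slot orthologMap data.frame with columns `locus_a`, `locus_b`; one-to-one
#'   (no tag appears twice). Includes RNA gene pairs (column `ftype`). A gene
#'   split in one lineage is represented by its majority fragment
#'   (majority-overlap convention); twin duplications pair their extra
#'   copies; ancestors split in both lineages or deleted in either leave no
#'   pair.
#' @slot events data.frame with columns `lineage` (`"A"`/`"B"`),
#'   `locus_tag`, `event` (split, deletion, duplication, lateral_transfer,
#'   inversion_member) and `ancestor`. For deletions `locus_tag` is the tag
#'   retained in the *other* lineage.
#' @slot ancestors data.frame mapping every extant gene (`lineage`,
#'   `locus_tag`) to its ancestral gene id (`NA` for lateral insertions).
#'
#' @aliases TruthTable-class
#' @export TruthTable
#' @exportClass TruthTable
TruthTable <- setClass("TruthTable",
  slots = c(orthologMap = "data.frame", events = "data.frame",
            ancestors = "data.frame")
)

setValidity("TruthTable", function(object) {
  om <- object@orthologMap
  if (nrow(om) &&
      (anyDuplicated(om$locus_a) || anyDuplicated(om$locus_b)))
    return("orthologMap must be one-to-one")
  TRUE
})

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable:", nrow(object@orthologMap), "ortholog pairs,",
      nrow(object@events), "events\n")
})

#' GenomePartition: shared and unique gene complements
#'
#' The result of partitioning two genomes with [partitionGenomes()]:
#' validated ortholog pairs, per-genome unique CDS, and the same for RNA
#' genes matched in nucleotide mode.
#'
#' @slot pairs data.frame of validated CDS pairs (`id_a`, `id_b`, `evalue`,
#'   `bitscore`, `global_identity`, `global_similarity`, `aln_len`).
#' @slot uniqueA,uniqueB locus tags of CDS without a validated partner.
#' @slot rnaPairs data.frame of RNA gene pairs (same columns).
#' @slot rnaUniqueA,rnaUniqueB locus tags of unpaired RNA genes.
#'
#' @aliases GenomePartition-class
#' @export GenomePartition
#' @exportClass GenomePartition
GenomePartition <- setClass("GenomePartition",
  slots = c(pairs = "data.frame",
            uniqueA = "character", uniqueB = "character",
            rnaPairs = "data.frame",
            rnaUniqueA = "character", rnaUniqueB = "character")
)

setValidity("GenomePartition", function(object) {
  msgs <- character()
  a <- c(object@pairs$id_a, object@uniqueA)
  b <- c(object@pairs$id_b, object@uniqueB)
  if (anyDuplicated(a) || anyDuplicated(b))
    msgs <- c(msgs, "a locus tag occurs in two fields of the partition")
  ra <- c(object@rnaPairs$id_a, object@rnaUniqueA)
  rb <- c(object@rnaPairs$id_b, object@rnaUniqueB)
  if (anyDuplicated(ra) || anyDuplicated(rb))
    msgs <- c(msgs, "an RNA locus tag occurs in two fields of the partition")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GenomePartition", function(object) {
  cat("GenomePartition:", nrow(object@pairs), "CDS pairs;",
      length(object@uniqueA), "unique in A;",
      length(object@uniqueB), "unique in B;",
      nrow(object@rnaPairs), "RNA pairs (",
      length(object@rnaUniqueA), "/", length(object@rnaUniqueB),
      "RNA unique )\n")
})
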