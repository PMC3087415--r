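#' Rotate a circular genome so an anchor CDS starts at position 1
#'
#' Re-linearizes a circular replicon at the start of the anchor feature:
#' the sequence is rotated and every feature coordinate shifted modulo the
#' genome length, strands preserved. Mirrors the convention of starting a
#' synteny dot plot at a shared anchor gene (e.g. the replication initiator
#' Cdc6). Features that would span the new origin are rejected.
#'
#' @param g a circular [GenomeRecord-class].
#' @param anchorLocus locus tag of the anchor feature.
#' @return the rotated [GenomeRecord-class].
#' @export
rotateOrigin <- function(g, anchorLocus) {
  if (!isCircularGenome(g)) stop("rotateOrigin requires a circular genome")
  ft <- features(g)
  i <- match(anchorLocus, mcols(ft)$locus_tag)
  if (is.na(i)) stop("anchor locus not found: ", anchorLocus)
  off <- start(ft)[i] - 1L
  if (off == 0L) return(g)
  L <- length(genomeSeq(g))
  seq <- genomeSeq(g)
  newSeq <- Biostrings::xscat(subseq(seq, off + 1L, L), subseq(seq, 1L, off))
  ns <- (start(ft) - 1L - off) %% L + 1L
  ne <- ns + width(ft) - 1L
  if (any(ne > L))
    stop("feature(s) would span the rotated origin: ",
         paste(mcols(ft)$locus_tag[ne > L], collapse = ", "))
  gr <- GRanges(recordId(g), IRanges(ns, ne), strand = strand(ft))
  mcols(gr) <- mcols(ft)
  newGenomeRecord(recordId(g), organismName(g), TRUE, newSeq, gr)
}

#' Synteny dot-plot points from an ortholog partition
#'
#' One point per ortholog pair: x/y are the midpoints (bp) of the paired
#' features on genomes A and B; orientation is `colinear` when the two
#' features lie on the same strand and `antiparallel` otherwise (the
#' signature of an inverted segment).
#'
#' @param partition a [GenomePartition-class] (CDS and RNA pairs are used).
#' @param A,B the two [GenomeRecord-class] objects.
#' @return data.frame: `id_a`, `id_b`, `x`, `y`, `orientation`.
#' @export
dotPoints <- function(partition, A, B) {
  pr <- rbind(orthologPairs(partition)[, c("id_a", "id_b")],
              partition@rnaPairs[, c("id_a", "id_b"), drop = FALSE])
  if (!nrow(pr))
    return(data.frame(id_a = character(), id_b = character(),
                      x = numeric(), y = numeric(),
                      orientation = character()))
  fa <- features(A); fb <- features(B)
  ia <- match(pr$id_a, mcols(fa)$locus_tag)
  ib <- match(pr$id_b, mcols(fb)$locus_tag)
  if (anyNA(ia) || anyNA(ib))
    stop("pair id does not resolve to a feature")
  data.frame(
    id_a = pr$id_a, id_b = pr$id_b,
    x = (start(fa)[ia] + end(fa)[ia]) / 2,
    y = (start(fb)[ib] + end(fb)[ib]) / 2,
    orientation = ifelse(as.character(strand(fa))[ia] ==
                           as.character(strand(fb))[ib],
                         "colinear", "antiparallel"))
}

#' Detect genome regions enriched in unique CDS
#'
#' Scans the unique features of one genome in coordinate order and merges
#' consecutive unique CDS whose midpoints lie within `windowBp` of the
#' previous one into runs; runs with at least `minCount` members are
#' reported. This is the hotspot notion behind "unique genes concentrated
#' in a few genome areas".
#'
#' @param g a [GenomeRecord-class].
#' @param uniqueTags locus tags of the unique CDS of `g`.
#' @param windowBp maximum midpoint gap (bp) joining two unique CDS.
#' @param minCount minimum run size reported.
#' @return data.frame: `start`, `end` (bp span of the run), `n_unique`.
#' @export
uniqueRegions <- function(g, uniqueTags, windowBp = 10000, minCount = 5) {
  stopifnot(windowBp > 0)
  empty <- data.frame(start = integer(), end = integer(),
                      n_unique = integer())
  if (!length(uniqueTags)) return(empty)
  ft <- features(g)
  idx <- match(uniqueTags, mcols(ft)$locus_tag)
  if (anyNA(idx)) stop("unknown unique locus tags")
  ft <- ft[idx]
  o <- order(start(ft))
  mid <- (start(ft)[o] + end(ft)[o]) / 2
  run <- cumsum(c(1, diff(mid) > windowBp))
  out <- do.call(rbind, lapply(split(seq_along(mid), run), function(i)
    data.frame(start = min(start(ft)[o][i]), end = max(end(ft)[o][i]),
               n_unique = length(i))))
  out <- out[out$n_unique >= minCount, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot a synteny dot plot
#'
#' Renders [dotPoints()] output with colinear points in red and
#' antiparallel points in blue (requires ggplot2). The tables, not the
#' image, are the analysis surface.
#'
#' @param points data.frame from [dotPoints()].
#' @param A,B optional [GenomeRecord-class] objects used for axis labels.
#' @return a ggplot object.
#' @export
plotSynteny <- function(points, A = NULL, B = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotSynteny requires the ggplot2 package")
  ggplot2::ggplot(points, ggplot2::aes(x = x, y = y, colour = orientation)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(colinear = "red",
                                            antiparallel = "blue")) +
    ggplot2::labs(x = if (is.null(A)) "genome A (bp)" else recordId(A),
                  y = if (is.null(B)) "genome B (bp)" else recordId(B)) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("x", "y", "orientation"))
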