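## gene-wise GC and GC3 (third codon position GC) for the CDS of a genome
.geneComposition <- function(g) {
  ft <- features(g)
  sel <- mcols(ft)$ftype == "CDS"
  tags <- mcols(ft)$locus_tag[sel]
  nt <- .featureSeqs(g, tags)
  gc <- as.numeric(letterFrequency(nt, "GC", as.prob = TRUE))
  gc3 <- vapply(seq_along(nt), function(i) {
    v <- strsplit(as.character(nt[[i]]), "")[[1]]
    p3 <- v[seq(3, length(v) - length(v) %% 3, by = 3)]
    mean(p3 %in% c("G", "C"))
  }, 1)
  data.frame(locus_tag = tags, gc = gc, gc3 = gc3)
}

## robust z-scores (median / MAD) so a handful of outliers does not
## contaminate the genome-wide baseline
.robustZ <- function(x) (x - median(x)) / max(mad(x), 1e-6)

#' Classify unique CDS by evolutionary origin
#'
#' Assigns each CDS of genome `g` that lacks a validated ortholog to one of
#' four origins, applying rules in fixed precedence:
#'
#' 1. **split** - the CDS and an adjacent same-strand CDS (intergenic gap
#'    at most `gapMax` bp) both hit the same single partner CDS on
#'    essentially non-overlapping subject segments (overlap at most
#'    `olapMax` of the shorter segment) whose union covers at least
#'    `covMin` of the partner; the neighbour must itself be unique or be
#'    the validated partner of that same CDS. This is the signature of a
#'    frameshift dividing one ancestral gene into two.
#' 2. **duplication** - the CDS has an intra-genome homolog at
#'    `E <= strictE` that either has its own ortholog pair (this CDS is the
#'    extra copy) or is an earlier unpaired member of the same family (a
#'    duplicated family wholly absent from the partner: by parsimony one
#'    member - the first in coordinate order - is the loss survivor and the
#'    rest are duplication copies).
#' 3. **lateral_transfer** - no partner-genome homolog at the relaxed
#'    cutoff and the gene is a composition outlier: robust |z| >= `zMin`
#'    for gene G+C or third-position G+C against the genome's gene-wise
#'    distribution.
#' 4. **deletion** - no partner-genome homolog at the relaxed cutoff and
#'    typical composition; interpreted as loss in the partner lineage.
#' 5. **unclassified** otherwise.
#'
#' @param g the genome whose unique CDS are classified.
#' @param partner the other genome.
#' @param uniqueTags unique CDS tags of `g` (from the partition).
#' @param hitsRelaxed cross-genome hit table (queries from `g`, subjects
#'   from `partner`) computed at the relaxed cutoff.
#' @param selfHits intra-genome hit table of `g` (self-matches ignored).
#' @param pairs validated ortholog pairs ([validatePairs()] output).
#' @param side `"A"` if `g`'s tags are `id_a` in `pairs`, else `"B"`.
#' @param gapMax,covMin,zMin,strictE,olapMax rule thresholds (see above).
#' @return data.frame: `locus_tag`, `label`, `evidence`.
#' @export
classifyUnique <- function(g, partner, uniqueTags, hitsRelaxed, selfHits,
                           pairs, side = c("A", "B"), gapMax = 300,
                           covMin = 0.6, zMin = 2.5, strictE = 1e-8,
                           olapMax = 0.2) {
  side <- match.arg(side)
  empty <- data.frame(locus_tag = character(), label = character(),
                      evidence = character())
  if (!length(uniqueTags)) return(empty)
  selfCol <- if (side == "A") "id_a" else "id_b"
  partnerCol <- if (side == "A") "id_b" else "id_a"
  pairedSelf <- pairs[[selfCol]]
  pairedPartner <- setNames(pairs[[partnerCol]], pairs[[selfCol]])

  comp <- .geneComposition(g)
  comp$z_gc <- .robustZ(comp$gc)
  comp$z_gc3 <- .robustZ(comp$gc3)

  partnerLen <- setNames(width(proteinSet(partner)), names(proteinSet(partner)))

  ft <- features(g)
  cds <- ft[mcols(ft)$ftype == "CDS"]
  cds <- cds[order(start(cds))]
  tags <- mcols(cds)$locus_tag
  strd <- as.character(strand(cds))

  hitsByQ <- split(hitsRelaxed, hitsRelaxed$qid)
  selfByQ <- if (nrow(selfHits)) split(selfHits, selfHits$qid) else list()

  classify1 <- function(u) {
    i <- match(u, tags)
    hu <- hitsByQ[[u]]
    ## rule 1: split
    for (j in c(i - 1L, i + 1L)) {
      if (j < 1L || j > length(tags)) next
      if (strd[j] != strd[i]) next
      gap <- max(start(cds)[max(i, j)] - end(cds)[min(i, j)] - 1L, 0L)
      if (gap > gapMax) next
      v <- tags[j]
      hv <- hitsByQ[[v]]
      if (is.null(hu) || is.null(hv)) next
      shared <- intersect(hu$sid, hv$sid)
      for (w in shared) {
        okNeighbour <- (v %in% uniqueTags) ||
          (!is.na(pairedPartner[v]) && identical(unname(pairedPartner[v]), w))
        if (!okNeighbour) next
        su <- hu[hu$sid == w, ][1, ]
        sv <- hv[hv$sid == w, ][1, ]
        lo <- max(su$sstart, sv$sstart); hi <- min(su$send, sv$send)
        olap <- max(0, hi - lo + 1)
        shorter <- min(su$send - su$sstart + 1, sv$send - sv$sstart + 1)
        covered <- (su$send - su$sstart + 1) + (sv$send - sv$sstart + 1) - olap
        if (olap <= olapMax * shorter && covered / partnerLen[[w]] >= covMin)
          return(c("split", sprintf(
            "adjacent CDS %s; partner %s; segments %d-%d/%d-%d; coverage %.2f",
            v, w, su$sstart, su$send, sv$sstart, sv$send,
            covered / partnerLen[[w]])))
      }
    }
    ## rule 2: duplication - an intra-genome paralog that is either paired
    ## (this CDS is the extra copy) or an earlier unpaired family member
    ## (parsimony: one loss survivor per unpaired family, the rest are
    ## duplication copies; the survivor is the first in coordinate order)
    sh <- selfByQ[[u]]
    if (!is.null(sh)) {
      sh <- sh[sh$sid != u & sh$evalue <= strictE, ]
      anch <- sh[sh$sid %in% pairedSelf, ]
      if (nrow(anch))
        return(c("duplication", sprintf(
          "intra-genome paralog %s (E=%.2e) with ortholog %s",
          anch$sid[1], anch$evalue[1], pairedPartner[anch$sid[1]])))
      fam <- sh[sh$sid %in% uniqueTags &
                  match(sh$sid, tags) < i, , drop = FALSE]
      if (nrow(fam))
        return(c("duplication", sprintf(
          "intra-genome paralog %s (E=%.2e); family absent from partner, upstream member treated as loss survivor",
          fam$sid[1], fam$evalue[1])))
    }
    ## rules 3/4: no partner homolog at the relaxed cutoff
    if (is.null(hu) || !nrow(hu)) {
      z <- comp[comp$locus_tag == u, ]
      if (abs(z$z_gc) >= zMin || abs(z$z_gc3) >= zMin)
        return(c("lateral_transfer", sprintf(
          "no partner homolog; composition outlier z_gc=%.2f z_gc3=%.2f",
          z$z_gc, z$z_gc3)))
      return(c("deletion", sprintf(
        "no partner homolog at relaxed cutoff; typical composition (z_gc=%.2f)",
        z$z_gc)))
    }
    c("unclassified", "")
  }

  res <- t(vapply(sort(uniqueTags), classify1, c("", "")))
  data.frame(locus_tag = rownames(res), label = res[, 1],
             evidence = res[, 2], row.names = NULL)
}

#' Summarize origin labels
#'
#' Counts and percentages of unique CDS per origin category.
#'
#' @param labels data.frame from [classifyUnique()].
#' @return list with `counts` and `fractions` (percent, named by label,
#'   over split, deletion, duplication, lateral_transfer, unclassified).
#' @export
summarizeOrigins <- function(labels) {
  lv <- c("split", "deletion", "duplication", "lateral_transfer",
          "unclassified")
  counts <- table(factor(labels$label, levels = lv))
  n <- sum(counts)
  list(counts = setNames(as.integer(counts), lv),
       fractions = setNames(if (n) round(100 * as.numeric(counts) / n, 2)
                            else rep(0, length(lv)), lv))
}
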