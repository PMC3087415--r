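## Amino-acid background frequencies (BLOSUM62 marginals) used both to draw
## ancestral proteins and to build the substitution exchange process.
.AA <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
.AA_FREQ <- c(0.074, 0.052, 0.045, 0.054, 0.025, 0.034, 0.054, 0.074,
              0.026, 0.068, 0.099, 0.058, 0.025, 0.047, 0.039, 0.057,
              0.051, 0.013, 0.032, 0.073)

## Conditional substitution distribution q(b | a) derived from the BLOSUM62
## implied target frequencies: q(b|a) proportional to p_b * exp(lambda_u *
## s(a, b)) for b != a, with the ungapped lambda for BLOSUM62 (0.3176).
.substKernel <- function() {
  sc <- proteinScoring()$matrix[.AA, .AA]
  q <- sweep(exp(0.3176 * sc), 2, .AA_FREQ, "*")
  diag(q) <- 0
  q / rowSums(q)
}

## codon table (translation table 11), stops separated
.codonTables <- function() {
  gc <- getGeneticCode("11")
  stops <- names(gc)[gc == "*"]
  sense <- gc[gc != "*"]
  byAA <- split(names(sense), sense)
  gcCount <- vapply(names(gc), function(cdn)
    sum(strsplit(cdn, "")[[1]] %in% c("G", "C")), integer(1))
  list(byAA = byAA, stops = stops, gcCount = gcCount)
}

## expected per-residue GC fraction of coding sequence under the codon
## weight model, as a function of the weight parameter t
.expectedCodingGC <- function(t, tables, aaProb) {
  perAA <- vapply(names(tables$byAA), function(a) {
    cds <- tables$byAA[[a]]
    g <- tables$gcCount[cds]
    w <- t^g * (1 - t)^(3 - g)
    sum(w * g) / sum(w) / 3
  }, 1)
  common <- intersect(names(perAA), names(aaProb))
  sum(aaProb[common] * perAA[common]) / sum(aaProb[common])
}

## invert the weight model so that the realized coding GC equals the target
## (the GC parameters of SimParams are actual GC fractions, not raw weights)
.solveCodonParam <- function(targetGC, tables, aaProb) {
  lo <- .expectedCodingGC(0.001, tables, aaProb)
  hi <- .expectedCodingGC(0.999, tables, aaProb)
  if (targetGC <= lo) return(0.001)
  if (targetGC >= hi) return(0.999)
  stats::uniroot(function(t) .expectedCodingGC(t, tables, aaProb) - targetGC,
                 c(0.001, 0.999), tol = 1e-6)$root
}

## sample one codon per amino acid, weighted towards a GC parameter t:
## weight proportional to t^g * (1-t)^(3-g) with g = GC bases in the codon
.sampleCodons <- function(aa, t, tables) {
  vapply(aa, function(x) {
    cds <- tables$byAA[[x]]
    g <- tables$gcCount[cds]
    w <- t^g * (1 - t)^(3 - g)
    if (length(cds) == 1L) cds else sample(cds, 1L, prob = w)
  }, "", USE.NAMES = FALSE)
}

.sampleStop <- function(t, tables) {
  g <- tables$gcCount[tables$stops]
  sample(tables$stops, 1L, prob = t^g * (1 - t)^(3 - g))
}

.randomSpacer <- function(len, t) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - t) / 2, t / 2, t / 2, (1 - t) / 2)),
        collapse = "")
}

## mutate a protein (character vector of residues) at `rate` expected
## substitutions per site: Poisson jumps through the exchange kernel
.mutateResidues <- function(res, rate, kernel) {
  if (rate <= 0) return(res)
  nm <- rpois(length(res), rate)
  for (i in which(nm > 0L)) {
    x <- res[i]
    for (k in seq_len(nm[i])) x <- sample(.AA, 1L, prob = kernel[x, ])
    res[i] <- x
  }
  res
}

.mutateNt <- function(nt, rate) {
  if (rate <= 0) return(nt)
  v <- strsplit(nt, "")[[1]]
  hit <- which(runif(length(v)) < 1 - exp(-rate))
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

#' Simulate a divergent genome pair with known ground truth
#'
#' Generates an ancestor of `nGenes` protein-coding genes (residues i.i.d.
#' from the BLOSUM62 background, Met start) plus a planted RNA-gene
#' complement, then evolves two lineages independently: amino-acid
#' substitutions through a BLOSUM62-derived exchange process at
#' `substPerSite` expected substitutions per site, followed by at most one
#' structural event per gene and lineage, drawn mutually exclusively with
#' probabilities `pDup` (tandem duplicate with `dupExtraSubst` extra
#' divergence), `pDel` (gene removed), `pSplit` (the gene is divided at a
#' point uniform in its middle 60% into two adjacent CDS, emulating a
#' frameshift), and `pHgt` (a de-novo gene with codon GC shifted by
#' `hgtGcShift` inserted downstream). Finally `nInversions` random
#' contiguous blocks of lineage B are inverted (order reversed, strands
#' flipped). Genomes are assembled by back-translating codons (synonymous
#' positions inherited from the ancestor, so zero divergence yields
#' byte-identical genomes) separated by neutral spacers.
#'
#' @param params a [SimParams-class].
#' @return list with elements `A`, `B` ([GenomeRecord-class]) and `truth`
#'   ([TruthTable-class]).
#' @examples
#' sim <- simulateGenomePair(SimParams(nGenes = 20L, seed = 42L))
#' sim$A
#' nrow(truthOrthologs(sim$truth))
#' @export
simulateGenomePair <- function(params = SimParams()) {
  validObject(params)
  set.seed(params@seed)
  kernel <- .substKernel()
  tables <- .codonTables()
  n <- params@nGenes
  t0 <- params@gcTarget
  aaProb <- setNames(.AA_FREQ, .AA)
  ## codon weight parameters solved so realized coding GC hits the targets
  tC <- .solveCodonParam(t0, tables, aaProb)
  tH <- .solveCodonParam(min(0.95, max(0.05, t0 + params@hgtGcShift)),
                         tables, aaProb)

  ## ---- ancestor -----------------------------------------------------------
  lens <- pmax(50L, as.integer(round(rnorm(n, params@geneLenMean,
                                           params@geneLenSd))))
  anc <- vector("list", n)
  for (i in seq_len(n)) {
    prot <- c("M", sample(.AA, lens[i] - 1L, replace = TRUE, prob = .AA_FREQ))
    anc[[i]] <- list(id = sprintf("anc%04d", i), type = "CDS", prot = prot,
                     codons = .sampleCodons(prot, tC, tables),
                     stop = .sampleStop(tC, tables))
  }
  nRna <- params@nTrna + params@nRrna
  rna <- vector("list", nRna)
  if (nRna > 0) for (i in seq_len(nRna)) {
    isT <- i <= params@nTrna
    rna[[i]] <- list(id = sprintf("ancRNA%02d", i),
                     type = if (isT) "tRNA" else "rRNA",
                     nt = .randomSpacer(if (isT) 76L else 1500L, t0))
  }
  ## interleave RNA genes at random ancestral positions
  slots <- sort(sample(n + nRna, nRna))
  order_ <- vector("list", n + nRna)
  ci <- ri <- 1L
  for (i in seq_len(n + nRna)) {
    if (i %in% slots) { order_[[i]] <- rna[[ri]]; ri <- ri + 1L }
    else { order_[[i]] <- anc[[ci]]; ci <- ci + 1L }
  }
  strands <- sample(c("+", "-"), n + nRna, replace = TRUE)
  spacers <- pmax(20L, rpois(n + nRna + 1L, params@spacerLenMean))
  ancSpacer <- vapply(spacers, .randomSpacer, "", t = t0)

  ## ---- lineages -----------------------------------------------------------
  pcut <- cumsum(c(params@pDup, params@pDel, params@pSplit, params@pHgt))
  evolve <- function(lineage) {
    pre <- if (lineage == "A") "SGA_" else "SGB_"
    genes <- list()
    events <- list()
    cnt <- 0L
    newTag <- function() { cnt <<- cnt + 1L; sprintf("%s%04d", pre, cnt) }
    for (i in seq_along(order_)) {
      el <- order_[[i]]
      strnd <- strands[i]
      if (el$type != "CDS") {
        genes[[length(genes) + 1L]] <- list(
          tag = newTag(), anc = el$id, type = el$type, strand = strnd,
          role = "primary",
          nt = .mutateNt(el$nt, params@rnaSubstPerSite), prot = NA)
        next
      }
      prot <- .mutateResidues(el$prot, params@substPerSite, kernel)
      chg <- prot != el$prot
      codons <- el$codons
      if (any(chg)) codons[chg] <- .sampleCodons(prot[chg], tC, tables)
      u <- runif(1)
      ev <- if (u < pcut[1]) "duplication" else if (u < pcut[2]) "deletion"
        else if (u < pcut[3]) "split" else if (u < pcut[4]) "lateral_transfer"
        else "none"
      if (ev == "deletion") {
        events[[length(events) + 1L]] <- data.frame(
          lineage = lineage, locus_tag = NA_character_, event = "deletion",
          ancestor = el$id)
        next
      }
      tag <- NULL
      if (ev == "split") {
        L <- length(prot)
        k <- sample(seq(max(2L, floor(0.2 * L)), min(L - 2L, ceiling(0.8 * L))), 1L)
        t1 <- newTag(); t2 <- newTag()
        genes[[length(genes) + 1L]] <- list(
          tag = t1, anc = el$id, type = "CDS", strand = strnd,
          role = "frag",
          nt = paste0(paste(codons[1:k], collapse = ""),
                      .sampleStop(tC, tables)),
          prot = paste(prot[1:k], collapse = ""))
        genes[[length(genes) + 1L]] <- list(
          tag = t2, anc = el$id, type = "CDS", strand = strnd,
          role = "frag",
          nt = paste0(paste(codons[(k + 1L):L], collapse = ""), el$stop),
          prot = paste(prot[(k + 1L):L], collapse = ""))
        events[[length(events) + 1L]] <- data.frame(
          lineage = lineage, locus_tag = c(t1, t2), event = "split",
          ancestor = el$id)
        next
      }
      tag <- newTag()
      genes[[length(genes) + 1L]] <- list(
        tag = tag, anc = el$id, type = "CDS", strand = strnd,
        role = "primary",
        nt = paste0(paste(codons, collapse = ""), el$stop),
        prot = paste(prot, collapse = ""))
      if (ev == "duplication") {
        dprot <- .mutateResidues(prot, params@dupExtraSubst, kernel)
        dchg <- dprot != prot
        dcod <- codons
        if (any(dchg)) dcod[dchg] <- .sampleCodons(dprot[dchg], tC, tables)
        dtag <- newTag()
        genes[[length(genes) + 1L]] <- list(
          tag = dtag, anc = el$id, type = "CDS", strand = strnd,
          role = "copy",
          nt = paste0(paste(dcod, collapse = ""), .sampleStop(tC, tables)),
          prot = paste(dprot, collapse = ""))
        events[[length(events) + 1L]] <- data.frame(
          lineage = lineage, locus_tag = dtag, event = "duplication",
          ancestor = el$id)
      } else if (ev == "lateral_transfer") {
        hl <- max(50L, as.integer(round(rnorm(1, params@geneLenMean,
                                              params@geneLenSd))))
        hprot <- c("M", sample(.AA, hl - 1L, replace = TRUE, prob = .AA_FREQ))
        htag <- newTag()
        genes[[length(genes) + 1L]] <- list(
          tag = htag, anc = NA_character_, type = "CDS",
          role = "hgt", strand = sample(c("+", "-"), 1L),
          nt = paste0(paste(.sampleCodons(hprot, tH, tables), collapse = ""),
                      .sampleStop(tH, tables)),
          prot = paste(hprot, collapse = ""))
        events[[length(events) + 1L]] <- data.frame(
          lineage = lineage, locus_tag = htag, event = "lateral_transfer",
          ancestor = NA_character_)
      }
    }
    list(genes = genes, events = events)
  }

  linA <- evolve("A")
  linB <- evolve("B")

  ## ---- inversions in lineage B -------------------------------------------
  gB <- linB$genes
  invEvents <- list()
  if (params@nInversions > 0L && length(gB) > 6L) {
    taken <- rep(FALSE, length(gB))
    for (k in seq_len(params@nInversions)) {
      for (try in 1:50) {
        len <- sample(5:15, 1L)
        if (len >= length(gB)) next
        s <- sample(length(gB) - len + 1L, 1L)
        if (any(taken[s:(s + len - 1L)])) next
        idx <- s:(s + len - 1L)
        block <- rev(gB[idx])
        block <- lapply(block, function(g) {
          g$strand <- if (g$strand == "+") "-" else "+"; g })
        gB[idx] <- block
        taken[idx] <- TRUE
        invEvents[[length(invEvents) + 1L]] <- data.frame(
          lineage = "B", locus_tag = vapply(block, `[[`, "", "tag"),
          event = "inversion_member",
          ancestor = vapply(block, `[[`, "", "anc"))
        break
      }
    }
  }
  linB$genes <- gB

  ## ---- assembly -----------------------------------------------------------
  assemble <- function(lin, recId, orgName) {
    genes <- lin$genes
    segs <- character(2L * length(genes) + 1L)
    st <- en <- integer(length(genes))
    pos <- 0L
    for (i in seq_along(genes)) {
      sp <- .mutateNt(ancSpacer[min(i, length(ancSpacer))], params@substPerSite / 3)
      segs[2L * i - 1L] <- sp
      nt <- genes[[i]]$nt
      if (genes[[i]]$strand == "-")
        nt <- as.character(reverseComplement(DNAString(nt)))
      segs[2L * i] <- nt
      st[i] <- pos + nchar(sp) + 1L
      en[i] <- st[i] + nchar(nt) - 1L
      pos <- en[i]
    }
    segs[2L * length(genes) + 1L] <- .mutateNt(ancSpacer[length(ancSpacer)],
                                               params@substPerSite / 3)
    seq <- paste(segs, collapse = "")
    gr <- GRanges(recId, IRanges(st, en),
                  strand = vapply(genes, `[[`, "", "strand"))
    mcols(gr)$locus_tag <- vapply(genes, `[[`, "", "tag")
    mcols(gr)$ftype <- vapply(genes, `[[`, "", "type")
    mcols(gr)$product <- ifelse(mcols(gr)$ftype == "CDS",
                                "simulated protein", "simulated RNA")
    mcols(gr)$translation <- vapply(genes, function(g)
      if (identical(g$prot, NA)) NA_character_ else g$prot, "")
    newGenomeRecord(recId, orgName, circular = TRUE, seq = seq, features = gr)
  }
  A <- assemble(linA, "simA", "synthetic lineage A")
  B <- assemble(linB, "simB", "synthetic lineage B")

  ## ---- truth --------------------------------------------------------------
  tagOf <- function(lin) {
    g <- lin$genes
    data.frame(ancestor = vapply(g, `[[`, "", "anc"),
               locus_tag = vapply(g, `[[`, "", "tag"),
               ftype = vapply(g, `[[`, "", "type"),
               role = vapply(g, `[[`, "", "role"),
               aa_len = vapply(g, function(x)
                 if (identical(x$prot, NA)) 0L else nchar(x$prot), 0L))
  }
  ta <- tagOf(linA); tb <- tagOf(linB)
  evA <- if (length(linA$events)) do.call(rbind, linA$events) else NULL
  evB <- if (length(linB$events)) do.call(rbind, linB$events) else NULL
  ev <- rbind(evA, evB,
              if (length(invEvents)) do.call(rbind, invEvents) else NULL)
  if (is.null(ev))
    ev <- data.frame(lineage = character(), locus_tag = character(),
                     event = character(), ancestor = character())
  ## one-to-one truth map. Per ancestral gene: pair the surviving primary
  ## copies; a gene split in one lineage is represented by its majority
  ## fragment (the one carrying more ancestral residues) on that side; twin
  ## duplications (same ancestor duplicated in both lineages) also pair
  ## their extra copies. Ancestors deleted or split in both lineages leave
  ## no pair.
  pickSide <- function(tt, a) {
    rows <- tt[!is.na(tt$ancestor) & tt$ancestor == a, , drop = FALSE]
    pri <- rows[rows$role == "primary", , drop = FALSE]
    if (nrow(pri)) return(pri$locus_tag[1])
    fr <- rows[rows$role == "frag", , drop = FALSE]
    if (nrow(fr)) return(fr$locus_tag[which.max(fr$aa_len)])
    NA_character_
  }
  ancIds <- unique(c(ta$ancestor, tb$ancestor))
  ancIds <- sort(ancIds[!is.na(ancIds)])
  splitBoth <- intersect(ev$ancestor[ev$event == "split" & ev$lineage == "A"],
                         ev$ancestor[ev$event == "split" & ev$lineage == "B"])
  omA <- vapply(ancIds, pickSide, "", tt = ta)
  omB <- vapply(ancIds, pickSide, "", tt = tb)
  keep <- !is.na(omA) & !is.na(omB) & !(ancIds %in% splitBoth)
  om <- data.frame(locus_a = omA[keep], locus_b = omB[keep],
                   ftype = ta$ftype[match(omA[keep], ta$locus_tag)])
  dupBoth <- intersect(ev$ancestor[ev$event == "duplication" &
                                     ev$lineage == "A"],
                       ev$ancestor[ev$event == "duplication" &
                                     ev$lineage == "B"])
  for (a in dupBoth) {
    ca <- ta$locus_tag[!is.na(ta$ancestor) & ta$ancestor == a &
                         ta$role == "copy"]
    cb <- tb$locus_tag[!is.na(tb$ancestor) & tb$ancestor == a &
                         tb$role == "copy"]
    om <- rbind(om, data.frame(locus_a = ca[1], locus_b = cb[1],
                               ftype = "CDS"))
  }
  om <- om[order(om$locus_a), ]
  rownames(om) <- NULL
  ## fill deletion event tags with the tag retained in the other lineage
  del <- ev$event == "deletion"
  if (any(del)) {
    other <- ifelse(ev$lineage[del] == "A", "B", "A")
    look <- rbind(cbind(ta, lineage = "A"), cbind(tb, lineage = "B"))
    key <- paste(look$lineage, look$ancestor)
    ev$locus_tag[del] <- look$locus_tag[match(paste(other, ev$ancestor[del]),
                                              key)]
  }
  ancestors <- rbind(cbind(ta, lineage = "A"), cbind(tb, lineage = "B"))
  truth <- new("TruthTable", orthologMap = om,
               events = ev[, c("lineage", "locus_tag", "event", "ancestor")],
               ancestors = ancestors[, c("lineage", "locus_tag", "ancestor")])
  list(A = A, B = B, truth = truth)
}

#' Write simulator truth as TSV
#'
#' Writes `ortholog_map.tsv` and `events.tsv` into a directory.
#'
#' @param truth a [TruthTable-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(truthOrthologs(truth), file.path(dir, "ortholog_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truthEvents(truth), file.path(dir, "events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
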