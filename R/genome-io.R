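#' Construct a GenomeRecord from parts
#'
#' Low-level constructor used by the readers and the simulator. Features are
#' sorted by start; CDS translations are taken from `translation` when
#' present, otherwise derived from the genome sequence with the bacterial /
#' archaeal genetic code (translation table 11), trailing stop stripped.
#' CDS whose in-frame translation contains an internal stop are flagged
#' (`translation` set to `NA`) and excluded from protein comparison by the
#' downstream pipeline.
#'
#' @param recordId,organism,circular,seq see [GenomeRecord-class].
#' @param features a `GRanges` with mcols `locus_tag`, `ftype` and
#'   optionally `product`, `translation`.
#' @return a validated [GenomeRecord-class].
#' @export
newGenomeRecord <- function(recordId, organism = "synthetic organism",
                            circular = TRUE, seq, features) {
  if (is.character(seq)) seq <- DNAString(seq)
  if (length(seq) < 1L) stop("empty genome sequence for record ", recordId)
  if (length(features)) {
    if (any(start(features) < 1L) || any(end(features) > length(seq)))
      stop("feature outside sequence bounds in record ", recordId, ": ",
           paste(mcols(features)$locus_tag[start(features) < 1L |
                                           end(features) > length(seq)],
                 collapse = ", "))
    if (is.null(mcols(features)$product))
      mcols(features)$product <- NA_character_
    if (is.null(mcols(features)$translation))
      mcols(features)$translation <- NA_character_
    features <- features[order(start(features), end(features))]
    cds <- which(mcols(features)$ftype == "CDS")
    need <- cds[is.na(mcols(features)$translation[cds])]
    if (length(need)) {
      tr <- .translateFeature(seq, features[need])
      mcols(features)$translation[need] <- tr
      bad <- need[is.na(tr)]
      if (length(bad))
        message(length(bad), " CDS with internal stop codons flagged and ",
                "excluded from protein comparison: ",
                paste(utils::head(mcols(features)$locus_tag[bad], 5),
                      collapse = ", "),
                if (length(bad) > 5) ", ...")
    }
  }
  new("GenomeRecord", recordId = as.character(recordId),
      organism = as.character(organism), circular = isTRUE(circular),
      seq = seq, features = features)
}

## translate CDS features off the genome; NA for internal stops
.translateFeature <- function(seq, feats) {
  if (!length(feats)) return(character())
  nt <- DNAStringSet(seq, start = start(feats), end = end(feats))
  rev <- as.character(strand(feats)) == "-"
  if (any(rev)) nt[rev] <- reverseComplement(nt[rev])
  w <- width(nt) - width(nt) %% 3L
  nt <- subseq(nt, 1L, w)
  aa <- as.character(translate(nt, genetic.code = getGeneticCode("11"),
                               if.fuzzy.codon = "solve", no.init.codon = TRUE))
  aa <- sub("\\*$", "", aa)
  ifelse(grepl("\\*", aa), NA_character_, aa)
}

#' Read an annotated genome
#'
#' Reads a GenBank flat file, or a GFF3 annotation plus genomic FASTA, into
#' a [GenomeRecord-class]. Feature types are mapped to `CDS`, `tRNA`,
#' `rRNA`, `other_RNA`; all other GFF3/GenBank feature keys are ignored.
#' Features spanning the origin of a circular replicon are rejected.
#'
#' @param path GenBank file, or GFF3 file when `format = "gff3"`.
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta genomic FASTA path (required for `format = "gff3"`).
#' @return a [GenomeRecord-class].
#' @examples
#' gff <- system.file("extdata", "toy.gff3", package = "orthopair")
#' fa  <- system.file("extdata", "toy.fasta", package = "orthopair")
#' readGenome(gff, format = "gff3", fasta = fa)
#' @export
readGenome <- function(path, format = c("genbank", "gff3"), fasta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "genbank") .readGenBank(path) else {
    if (is.null(fasta)) stop("format='gff3' requires a fasta= path")
    .readGff3(path, fasta)
  }
}

.readGff3 <- function(gff, fasta) {
  seqs <- readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("parse error: empty FASTA file ", fasta)
  gr <- rtracklayer::import(gff)
  if (length(seqs) > 1L)
    warning("multiple FASTA records; using the first (", names(seqs)[1], ")")
  sid <- sub("\\s.*", "", names(seqs)[1])
  type <- as.character(gr$type)
  map <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
           ncRNA = "other_RNA", tmRNA = "other_RNA", RNase_P_RNA = "other_RNA",
           SRP_RNA = "other_RNA", misc_RNA = "other_RNA")
  keep <- type %in% names(map)
  gr <- gr[keep]
  ftype <- unname(map[type[keep]])
  lt <- if (!is.null(gr$locus_tag)) gr$locus_tag else gr$ID
  if (is.null(lt) || anyNA(lt))
    stop("parse error: GFF3 features without locus_tag/ID in ", gff)
  feats <- GRanges(sid, IRanges(start(gr), end(gr)), strand = strand(gr))
  mcols(feats)$locus_tag <- as.character(lt)
  mcols(feats)$ftype <- ftype
  mcols(feats)$product <- if (!is.null(gr$product))
    as.character(gr$product) else NA_character_
  mcols(feats)$translation <- NA_character_
  circ <- grepl("circular", readLines(gff, n = 5L), ignore.case = TRUE)
  newGenomeRecord(sid, organism = sid, circular = any(circ),
                  seq = seqs[[1]], features = feats)
}

## Minimal GenBank flat-file parser: LOCUS / ORGANISM / FEATURES / ORIGIN.
## Handles 'a..b', 'complement(a..b)' and ascending 'join(...)' (collapsed to
## its span, as for tRNA introns); origin-spanning joins are rejected.
.readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("parse error: not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  recId <- toks[2]
  circular <- any(toks == "circular")
  org <- NA_character_
  oline <- grep("^\\s{2}ORGANISM", lines)
  if (length(oline)) org <- trimws(sub("^\\s+ORGANISM\\s+", "", lines[oline[1]]))

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("parse error: no ORIGIN section in ", path)
  seqlines <- lines[(ostart[1] + 1L):length(lines)]
  seqlines <- seqlines[!grepl("^//", seqlines)]
  seqchr <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nchar(seqchr)) stop("parse error: empty sequence in ", path)
  seq <- DNAString(seqchr)

  keep <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
            ncRNA = "other_RNA", tmRNA = "other_RNA", misc_RNA = "other_RNA")
  st <- en <- integer(); strd <- lt <- prod_ <- tra <- character()
  ftp <- character()
  if (length(fstart)) {
    flines <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    ishead <- grepl("^\\s{5}\\S", flines)
    idx <- which(ishead)
    for (k in seq_along(idx)) {
      i <- idx[k]
      key <- sub("^\\s+(\\S+).*", "\\1", flines[i])
      if (!key %in% names(keep)) next
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(flines)
      block <- flines[i:to]
      loc <- sub("^\\s+\\S+\\s+", "", block[1])
      j <- 2L
      while (j <= length(block) && !grepl("^\\s+/", block[j])) {
        loc <- paste0(loc, trimws(block[j])); j <- j + 1L
      }
      pl <- .parseGbLocation(loc, path)
      quals <- paste(trimws(block[j:length(block)]), collapse = "\n")
      getq <- function(name) {
        m <- regmatches(quals, regexpr(
          paste0("/", name, "=\"[^\"]*\""), quals))
        if (!length(m)) return(NA_character_)
        gsub("\n", "", sub(paste0("/", name, "=\""), "",
                           sub("\"$", "", m[1]), fixed = TRUE))
      }
      st <- c(st, pl$start); en <- c(en, pl$end); strd <- c(strd, pl$strand)
      ftp <- c(ftp, unname(keep[key]))
      tag <- getq("locus_tag")
      lt <- c(lt, if (is.na(tag)) paste0(recId, "_f", k) else tag)
      prod_ <- c(prod_, getq("product"))
      tra <- c(tra, if (key == "CDS") gsub("\\s", "", getq("translation"))
               else NA_character_)
    }
  }
  feats <- GRanges(recId, IRanges(st, en), strand = strd)
  mcols(feats)$locus_tag <- lt
  mcols(feats)$ftype <- ftp
  mcols(feats)$product <- prod_
  mcols(feats)$translation <- tra
  newGenomeRecord(recId, organism = org, circular = circular,
                  seq = seq, features = feats)
}

.parseGbLocation <- function(loc, path) {
  loc <- gsub("[<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    nums <- lapply(parts, function(p)
      as.integer(strsplit(p, "\\.\\.")[[1]]))
    flat <- unlist(nums)
    if (is.unsorted(flat))
      stop("validation error: origin-spanning or non-ascending join() ",
           "location '", loc, "' in ", path)
    return(list(start = min(flat), end = max(flat), strand = strand))
  }
  nums <- as.integer(strsplit(loc, "\\.\\.")[[1]])
  if (anyNA(nums)) stop("parse error: unsupported location '", loc,
                        "' in ", path)
  if (length(nums) == 1L) nums <- c(nums, nums)
  list(start = nums[1], end = nums[2], strand = strand)
}

#' Write a GenomeRecord as GFF3 + FASTA
#'
#' Coordinates are emitted 1-based inclusive (GFF3). Feature types map back
#' to `CDS`, `tRNA`, `rRNA`, `ncRNA`.
#'
#' @param g a [GenomeRecord-class].
#' @param gffPath,fastaPath output paths.
#' @return invisibly, the two paths.
#' @export
writeGenome <- function(g, gffPath, fastaPath) {
  ft <- features(g)
  gr <- GRanges(recordId(g), IRanges(start(ft), end(ft)), strand = strand(ft))
  revmap <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", other_RNA = "ncRNA")
  mcols(gr)$type <- unname(revmap[mcols(ft)$ftype])
  mcols(gr)$phase <- ifelse(mcols(gr)$type == "CDS", 0L, NA_integer_)
  mcols(gr)$ID <- mcols(ft)$locus_tag
  mcols(gr)$locus_tag <- mcols(ft)$locus_tag
  prodOk <- !is.na(mcols(ft)$product)
  mcols(gr)$product <- mcols(ft)$product
  rtracklayer::export(gr, gffPath, format = "gff3")
  ## annotate circularity for the round trip
  hdr <- readLines(gffPath)
  hdr <- append(hdr, paste0("# sequence-region ", recordId(g), " ",
                            if (isCircularGenome(g)) "circular" else "linear"),
                after = 1L)
  writeLines(hdr, gffPath)
  s <- DNAStringSet(list(genomeSeq(g)))
  names(s) <- recordId(g)
  writeXStringSet(s, fastaPath)
  invisible(c(gffPath, fastaPath))
}

#' G+C content of a genome (mol%)
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` is excluded from the denominator.
#' Reported to two decimals, matching the convention of published genome
#' tables.
#'
#' @param x a [GenomeRecord-class], [Biostrings::DNAString] or character.
#' @return numeric percentage, rounded to 2 decimals.
#' @examples gcContent("ATGC")
#' @export
setGeneric("gcContent", function(x) standardGeneric("gcContent"))

#' @rdname gcContent
#' @export
setMethod("gcContent", "GenomeRecord", function(x) gcContent(genomeSeq(x)))

#' @rdname gcContent
#' @export
setMethod("gcContent", "DNAString", function(x) {
  f <- letterFrequency(x, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) stop("undefined G+C content: no unambiguous bases")
  round(100 * (f[["G"]] + f[["C"]]) / denom, 2)
})

#' @rdname gcContent
#' @export
setMethod("gcContent", "character", function(x) gcContent(DNAString(x)))

#' Count features of a given type
#'
#' @param g a [GenomeRecord-class].
#' @param ftype one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"other_RNA"`.
#' @return integer count.
#' @export
countFeatures <- function(g, ftype = c("CDS", "tRNA", "rRNA", "other_RNA")) {
  ftype <- match.arg(ftype)
  sum(mcols(features(g))$ftype == ftype)
}

#' Per-replicon summary statistics
#'
#' One row per genome: length, G+C (mol%), and feature counts by type — the
#' per-replicon half of a genome-comparison table.
#'
#' @param ... one or more [GenomeRecord-class] objects.
#' @param file optional path; when given, the table is also written as TSV.
#' @return data.frame with columns `record_id`, `length_bp`, `gc_molpct`,
#'   `n_cds`, `n_trna`, `n_rrna`, `n_other_rna`.
#' @export
genomeSummary <- function(..., file = NULL) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !is(gs[[1]], "GenomeRecord"))
    gs <- gs[[1]]
  out <- do.call(rbind, lapply(gs, function(g) data.frame(
    record_id = recordId(g),
    length_bp = length(genomeSeq(g)),
    gc_molpct = gcContent(g),
    n_cds = countFeatures(g, "CDS"),
    n_trna = countFeatures(g, "tRNA"),
    n_rrna = countFeatures(g, "rRNA"),
    n_other_rna = countFeatures(g, "other_RNA"))))
  rownames(out) <- NULL
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Reverse complement of a whole GenomeRecord
#'
#' Complements the sequence and mirrors all feature coordinates and strands.
#' Useful for orientation-invariance checks.
#'
#' @param g a [GenomeRecord-class].
#' @return a [GenomeRecord-class].
#' @export
revCompGenome <- function(g) {
  L <- length(genomeSeq(g))
  ft <- features(g)
  ns <- L - end(ft) + 1L
  ne <- L - start(ft) + 1L
  gr <- GRanges(recordId(g), IRanges(ns, ne),
                strand = ifelse(as.character(strand(ft)) == "+", "-", "+"))
  mcols(gr) <- mcols(ft)
  newGenomeRecord(recordId(g), organismName(g), isCircularGenome(g),
                  reverseComplement(genomeSeq(g)), gr)
}

## nucleotide sequence of each feature (on the coding strand)
.featureSeqs <- function(g, tags) {
  ft <- features(g)
  idx <- match(tags, mcols(ft)$locus_tag)
  if (anyNA(idx)) stop("unknown locus tags: ",
                       paste(tags[is.na(idx)], collapse = ", "))
  ft <- ft[idx]
  nt <- DNAStringSet(genomeSeq(g), start = start(ft), end = end(ft))
  rev <- as.character(strand(ft)) == "-"
  if (any(rev)) nt[rev] <- reverseComplement(nt[rev])
  names(nt) <- tags
  nt
}

#' Protein and RNA sequence sets of a genome
#'
#' `proteinSet()` returns the translations of all CDS with a clean reading
#' frame (internal-stop CDS are dropped) as an `AAStringSet`;
#' `rnaSet()` returns the coding-strand nucleotide sequences of all RNA
#' genes as a `DNAStringSet`. Both are named by locus tag.
#'
#' @param g a [GenomeRecord-class].
#' @return an `AAStringSet` / `DNAStringSet` named by locus tag.
#' @export
proteinSet <- function(g) {
  ft <- features(g)
  sel <- mcols(ft)$ftype == "CDS" & !is.na(mcols(ft)$translation)
  aa <- AAStringSet(mcols(ft)$translation[sel])
  names(aa) <- mcols(ft)$locus_tag[sel]
  aa
}

#' @rdname proteinSet
#' @export
rnaSet <- function(g) {
  ft <- features(g)
  sel <- mcols(ft)$ftype %in% c("tRNA", "rRNA", "other_RNA")
  .featureSeqs(g, mcols(ft)$locus_tag[sel])
}
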