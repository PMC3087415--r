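## ---- scoring systems -------------------------------------------------------

#' Scoring systems for local and global alignment
#'
#' A scoring system bundles a substitution matrix, affine gap penalties
#' (a gap of length L costs `gapOpen + L * gapExt`, the NCBI convention) and
#' fixed Karlin-Altschul parameters `lambda` (nats per score unit) and `K`
#' used to convert raw local-alignment scores into bit scores and E-values.
#'
#' `proteinScoring()` defaults to BLOSUM62 with gap open 11 / extend 1 and
#' the published gapped-statistics constants lambda = 0.267, K = 0.041.
#' `nucleotideScoring()` defaults to match +2 / mismatch -3 with gap open 5 /
#' extend 2 and lambda = 0.625, K = 0.41. Both mirror common BLAST defaults;
#' every component is configurable.
#'
#' @param matrix substitution matrix (integer-valued, symmetric, with row and
#'   column names over the alphabet).
#' @param gapOpen,gapExt affine gap parameters (positive costs).
#' @param lambda,k Karlin-Altschul parameters.
#' @param match,mismatch nucleotide match reward / mismatch penalty.
#' @return a `list` of class `"opScoring"` with elements `matrix`, `gapOpen`,
#'   `gapExt`, `lambda`, `k`, `alphabet`.
#' @examples
#' sc <- proteinScoring()
#' sc$matrix["M", "M"]
#' @export
proteinScoring <- function(matrix = NULL, gapOpen = 11, gapExt = 1,
                           lambda = 0.267, k = 0.041) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  structure(list(matrix = matrix, gapOpen = gapOpen, gapExt = gapExt,
                 lambda = lambda, k = k, alphabet = "protein"),
            class = "opScoring")
}

#' @rdname proteinScoring
#' @export
nucleotideScoring <- function(match = 2, mismatch = -3, gapOpen = 5,
                              gapExt = 2, lambda = 0.625, k = 0.41) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0L; m[, "N"] <- 0L
  structure(list(matrix = m, gapOpen = gapOpen, gapExt = gapExt,
                 lambda = lambda, k = k, alphabet = "nucleotide"),
            class = "opScoring")
}

#' @export
print.opScoring <- function(x, ...) {
  cat(sprintf("%s scoring: %dx%d matrix, gap %g/%g, lambda=%g K=%g\n",
              x$alphabet, nrow(x$matrix), ncol(x$matrix),
              x$gapOpen, x$gapExt, x$lambda, x$k))
  invisible(x)
}

## encode sequences as 0-based indices into the scoring matrix alphabet
.encodeSeqs <- function(seqs, scoring) {
  ab <- rownames(scoring$matrix)
  lut <- setNames(seq_along(ab) - 1L, ab)
  chs <- strsplit(as.character(seqs), "")
  lapply(chs, function(ch) {
    v <- lut[ch]
    if (anyNA(v))
      stop("alphabet mismatch: residue(s) ",
           paste(unique(ch[is.na(v)]), collapse = ","),
           " not in the ", scoring$alphabet, " scoring alphabet")
    unname(v)
  })
}

#' Karlin-Altschul statistics
#'
#' Converts raw local-alignment scores to bit scores,
#' `bit = (lambda * S - ln K) / ln 2`, and expectations
#' `E = m * n * 2^(-bit)` with effective lengths equal to the raw sequence
#' lengths (no edge correction).
#'
#' @param rawScore raw score(s) in substitution-matrix units.
#' @param m,n effective query and subject lengths (residues).
#' @param scoring an [proteinScoring()] / [nucleotideScoring()] object.
#' @return data.frame with columns `bitscore`, `evalue`.
#' @export
kaStatistics <- function(rawScore, m, n, scoring) {
  bit <- (scoring$lambda * rawScore - log(scoring$k)) / log(2)
  data.frame(bitscore = bit, evalue = as.numeric(m) * as.numeric(n) * 2^(-bit))
}

#' Empirical recalibration of E-value statistics
#'
#' Optional alternative to the fixed constants: aligns shuffled sequence
#' pairs, fits the score distribution to a Gumbel law by the method of
#' moments (`lambda = pi / (sd * sqrt(6))`,
#' `K = exp(lambda * mode) / (m * n)`), and returns the scoring object with
#' `lambda` and `k` replaced.
#'
#' @param scoring scoring system to recalibrate.
#' @param seqs an `XStringSet` providing residue composition.
#' @param nPairs number of shuffled pairs to align.
#' @param len length of the shuffled sequences.
#' @param seed RNG seed.
#' @return the recalibrated scoring object.
#' @export
calibrateScoring <- function(scoring, seqs, nPairs = 200, len = 150,
                             seed = 1) {
  set.seed(seed)
  pool <- strsplit(paste(as.character(seqs), collapse = ""), "")[[1]]
  mk <- function() paste(sample(pool, len, replace = TRUE), collapse = "")
  a <- vapply(seq_len(nPairs), function(i) mk(), "")
  b <- vapply(seq_len(nPairs), function(i) mk(), "")
  sc <- .sw_score_matrix(.encodeSeqs(a[1], scoring), .encodeSeqs(b, scoring),
                         scoring$matrix, scoring$gapOpen, scoring$gapExt)
  sc <- vapply(seq_len(nPairs), function(i)
    .sw_score_matrix(.encodeSeqs(a[i], scoring), .encodeSeqs(b[i], scoring),
                     scoring$matrix, scoring$gapOpen, scoring$gapExt)[1, 1],
    numeric(1))
  lambda <- pi / (stats::sd(sc) * sqrt(6))
  mode_ <- mean(sc) - 0.5772 / lambda
  k <- exp(lambda * mode_) / (len * len)
  scoring$lambda <- lambda
  scoring$k <- k
  scoring
}

## ---- local alignment -------------------------------------------------------

## detailed local alignments of query set vs one subject via Biostrings
.localDetails <- function(qs, subj, scoring) {
  pa <- pairwiseAlignment(qs, subj, type = "local",
                          substitutionMatrix = scoring$matrix,
                          gapOpening = scoring$gapOpen,
                          gapExtension = scoring$gapExt)
  ind <- Biostrings::nindel(pa)
  data.frame(
    pident_local = round(100 * Biostrings::nmatch(pa) /
                           Biostrings::nchar(pa), 2),
    length = Biostrings::nchar(pa),
    mismatches = Biostrings::nmismatch(pa),
    gapopens = Biostrings::insertion(ind)[, "Length"] +
      Biostrings::deletion(ind)[, "Length"],
    qstart = start(pattern(pa)), qend = end(pattern(pa)),
    sstart = start(subject(pa)), send = end(subject(pa)),
    raw_score = score(pa))
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman with affine gaps under the given scoring system, with
#' Karlin-Altschul bit score and E-value (effective lengths = raw lengths).
#' Returns a one-row hit table, or a zero-row table when the optimal score
#' is 0 (no positively scoring local alignment exists).
#'
#' @param a,b sequences (character, or `AAString`/`DNAString`); names (or
#'   `qid`/`sid`) label the hit.
#' @param scoring scoring system; its alphabet must match the sequences.
#' @param qid,sid identifiers for the hit table.
#' @return data.frame in 12-column blast-tab layout (`qid`, `sid`,
#'   `pident_local`, `length`, `mismatches`, `gapopens`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`), 1-based inclusive coordinates,
#'   plus `raw_score`.
#' @examples
#' localAlign("MKVLA", "MKVLA", proteinScoring())
#' @export
localAlign <- function(a, b, scoring = proteinScoring(),
                       qid = "query", sid = "subject") {
  a <- as.character(a); b <- as.character(b)
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  raw <- .sw_score_matrix(.encodeSeqs(a, scoring), .encodeSeqs(b, scoring),
                          scoring$matrix, scoring$gapOpen, scoring$gapExt)[1, 1]
  if (raw <= 0) return(.emptyHits())
  qs <- if (scoring$alphabet == "protein") AAStringSet(a) else DNAStringSet(a)
  sb <- if (scoring$alphabet == "protein") AAString(b) else DNAString(b)
  det <- .localDetails(qs, sb, scoring)
  ka <- kaStatistics(raw, nchar(a), nchar(b), scoring)
  cbind(data.frame(qid = qid, sid = sid), det[, 1:8],
        data.frame(evalue = ka$evalue, bitscore = ka$bitscore,
                   raw_score = raw))
}

.emptyHits <- function() {
  data.frame(qid = character(), sid = character(), pident_local = numeric(),
             length = integer(), mismatches = integer(), gapopens = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             raw_score = numeric())
}

#' All-vs-all local alignment between two sequence sets
#'
#' Computes optimal Smith-Waterman scores for every query/subject pair
#' (exact, no heuristic seeding), converts them to E-values, and reports
#' every hit with `evalue <= eReport` with full alignment details. Within
#' each query, hits are sorted by ascending E-value, then descending bit
#' score, then subject id.
#'
#' @param A,B named `AAStringSet`/`DNAStringSet` (or named character
#'   vectors); names are the locus tags and must be unique within each set.
#' @param scoring scoring system matching the alphabet.
#' @param eReport expectation cutoff for reporting.
#' @return hit table as in [localAlign()].
#' @export
allVsAll <- function(A, B, scoring = proteinScoring(), eReport = 1e-4) {
  A <- setNames(as.character(A), names(A))
  B <- setNames(as.character(B), names(B))
  if (is.null(names(A)) || is.null(names(B)))
    stop("A and B must be named by locus tag")
  if (anyDuplicated(names(A)) || anyDuplicated(names(B)))
    stop("duplicate ids within a sequence set")
  if (!length(A) || !length(B) || eReport <= 0) return(.emptyHits())
  raw <- .sw_score_matrix(.encodeSeqs(A, scoring), .encodeSeqs(B, scoring),
                          scoring$matrix, scoring$gapOpen, scoring$gapExt)
  mlen <- nchar(A); nlen <- nchar(B)
  bit <- (scoring$lambda * raw - log(scoring$k)) / log(2)
  ev <- outer(as.numeric(mlen), as.numeric(nlen)) * 2^(-bit)
  keep <- which(ev <= eReport & raw > 0, arr.ind = TRUE)
  if (!nrow(keep)) return(.emptyHits())
  qsCls <- if (scoring$alphabet == "protein") AAStringSet else DNAStringSet
  sbCls <- if (scoring$alphabet == "protein") AAString else DNAString
  parts <- lapply(split(keep[, 1], keep[, 2]), identity)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    sj <- as.integer(names(parts)[i])
    qi <- parts[[i]]
    det <- .localDetails(qsCls(A[qi]), sbCls(B[[sj]]), scoring)
    out[[i]] <- cbind(
      data.frame(qid = names(A)[qi], sid = names(B)[sj]), det[, 1:8],
      data.frame(evalue = ev[cbind(qi, sj)], bitscore = bit[cbind(qi, sj)],
                 raw_score = raw[cbind(qi, sj)]))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$qid, out$evalue, -out$bitscore, out$sid), ]
  rownames(out) <- NULL
  out
}

#' Write / read a hit table as blast-tab-like TSV
#'
#' @param hits hit table from [allVsAll()].
#' @param file path.
#' @return `readHits` returns the hit table.
#' @export
writeHits <- function(hits, file) {
  write.table(hits, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeHits
#' @export
readHits <- function(file) read.delim(file)
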