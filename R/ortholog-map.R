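#' One-to-one matching of bidirectional hits
#'
#' Implements the uniqueness rule of the two-step comparison: every sequence
#' may be used only once. Candidate pairs are the union of the two
#' directional hit tables; they are ranked by ascending E-value (ties:
#' descending bit score, then lexicographic id pair) and accepted greedily
#' when neither member is already matched and the E-value passes the cutoff.
#' Second- or third-best hits never create a pair once a partner is
#' consumed. A strict reciprocal-best-hit mode (`method = "rbh"`), which
#' only accepts pairs that are each other's best hit, is available for
#' sensitivity analysis.
#'
#' @param hitsAB hit table with queries from genome A, subjects from B.
#' @param hitsBA hit table with queries from genome B, subjects from A.
#' @param eCutoff expectation cutoff (pairs above it are never accepted).
#' @param method `"greedy"` (default) or `"rbh"`.
#' @return data.frame with columns `id_a`, `id_b`, `evalue`, `bitscore`.
#' @export
oneToOneMatch <- function(hitsAB, hitsBA, eCutoff = 1e-8,
                          method = c("greedy", "rbh")) {
  method <- match.arg(method)
  cand <- rbind(
    if (nrow(hitsAB)) data.frame(id_a = hitsAB$qid, id_b = hitsAB$sid,
                                 evalue = hitsAB$evalue,
                                 bitscore = hitsAB$bitscore),
    if (nrow(hitsBA)) data.frame(id_a = hitsBA$sid, id_b = hitsBA$qid,
                                 evalue = hitsBA$evalue,
                                 bitscore = hitsBA$bitscore))
  if (is.null(cand) || !nrow(cand))
    return(data.frame(id_a = character(), id_b = character(),
                      evalue = numeric(), bitscore = numeric()))
  ## union over directions: keep the best statistics per ordered pair
  cand <- cand[order(cand$evalue, -cand$bitscore, cand$id_a, cand$id_b), ]
  cand <- cand[!duplicated(paste(cand$id_a, cand$id_b)), ]
  cand <- cand[cand$evalue <= eCutoff, ]
  if (method == "rbh") {
    bestA <- cand[!duplicated(cand$id_a), ]
    bestB <- cand[!duplicated(cand$id_b), ]
    key <- paste(bestA$id_a, bestA$id_b)
    cand <- bestA[key %in% paste(bestB$id_a, bestB$id_b), ]
    rownames(cand) <- NULL
    return(cand)
  }
  takenA <- new.env(hash = TRUE); takenB <- new.env(hash = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand$id_a[i]; b <- cand$id_b[i]
    if (is.null(takenA[[a]]) && is.null(takenB[[b]])) {
      keep[i] <- TRUE
      takenA[[a]] <- TRUE; takenB[[b]] <- TRUE
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

## per-column identity / positive-score stats of one global alignment
.globalColumnStats <- function(pa, scoring) {
  p <- strsplit(as.character(alignedPattern(pa)), "")
  s <- strsplit(as.character(alignedSubject(pa)), "")
  mat <- scoring$matrix
  t(vapply(seq_along(p), function(i) {
    pi_ <- p[[i]]; si <- s[[i]]
    ng <- pi_ != "-" & si != "-"
    ident <- sum(pi_ == si & ng)
    pos <- sum(mat[cbind(pi_[ng], si[ng])] > 0)
    c(aln_len = length(pi_), identical = ident, positive = pos)
  }, c(aln_len = 0, identical = 0, positive = 0)))
}

#' Validate candidate pairs by full-length global alignment
#'
#' Needleman-Wunsch over the full sequence lengths (affine gaps, end gaps
#' penalized). Identity is the percentage of alignment columns (gaps
#' included in the denominator) with identical residues; similarity is the
#' percentage of columns whose substitution-matrix score is positive. Pairs
#' below `minIdentity` percent identity are dropped (reported via message).
#'
#' @param matches data.frame from [oneToOneMatch()].
#' @param seqsA,seqsB named sequence sets resolving every id.
#' @param scoring scoring system (also defines "positive" columns).
#' @param minIdentity minimum percent identity to keep a pair.
#' @return data.frame of validated pairs: `id_a`, `id_b`, `evalue`,
#'   `bitscore`, `global_identity`, `global_similarity`, `aln_len`.
#' @export
validatePairs <- function(matches, seqsA, seqsB, scoring = proteinScoring(),
                          minIdentity = 10) {
  empty <- data.frame(id_a = character(), id_b = character(),
                      evalue = numeric(), bitscore = numeric(),
                      global_identity = numeric(),
                      global_similarity = numeric(), aln_len = integer())
  if (!nrow(matches)) return(empty)
  ia <- match(matches$id_a, names(seqsA))
  ib <- match(matches$id_b, names(seqsB))
  if (anyNA(ia)) stop("missing sequence for id: ",
                      paste(matches$id_a[is.na(ia)], collapse = ", "))
  if (anyNA(ib)) stop("missing sequence for id: ",
                      paste(matches$id_b[is.na(ib)], collapse = ", "))
  cls <- if (scoring$alphabet == "protein") AAStringSet else DNAStringSet
  pa <- pairwiseAlignment(cls(as.character(seqsA)[ia]),
                          cls(as.character(seqsB)[ib]), type = "global",
                          substitutionMatrix = scoring$matrix,
                          gapOpening = scoring$gapOpen,
                          gapExtension = scoring$gapExt)
  st <- .globalColumnStats(pa, scoring)
  out <- data.frame(id_a = matches$id_a, id_b = matches$id_b,
                    evalue = matches$evalue, bitscore = matches$bitscore,
                    global_identity = round(100 * st[, "identical"] /
                                              st[, "aln_len"], 2),
                    global_similarity = round(100 * st[, "positive"] /
                                                st[, "aln_len"], 2),
                    aln_len = as.integer(st[, "aln_len"]))
  drop <- out$global_identity < minIdentity
  if (any(drop))
    message(sum(drop), " candidate pair(s) dropped below ", minIdentity,
            "% global identity: ",
            paste(utils::head(paste(out$id_a[drop], out$id_b[drop], sep = "/"),
                              5), collapse = ", "))
  out <- out[!drop, ]
  rownames(out) <- NULL
  out
}

#' Bin validated pairs by E-value
#'
#' Reports the fraction of pairs in the disjoint expectation bands
#' `(0, 1e-100]`, `(1e-100, 1e-50]`, `(1e-50, 1e-25]`, `(1e-25, 1e-8]` and
#' `(1e-8, Inf)`, with the similarity range observed in each band, plus the
#' fraction of pairs with a similarity score of exactly 100.
#'
#' @param pairs validated pairs from [validatePairs()].
#' @return list with elements `bands` (data.frame: `band`, `n`, `fraction`,
#'   `min_similarity`, `max_similarity`) and `fraction_similarity_100`.
#' @export
binPairs <- function(pairs) {
  edges <- c(0, 1e-100, 1e-50, 1e-25, 1e-8, Inf)
  labs <- c("<=1e-100", "(1e-100,1e-50]", "(1e-50,1e-25]", "(1e-25,1e-8]",
            ">1e-8")
  band <- cut(pairs$evalue, edges, labels = labs, include.lowest = TRUE)
  n <- as.integer(table(band))
  bands <- data.frame(
    band = labs, n = n,
    fraction = if (nrow(pairs)) round(100 * n / nrow(pairs), 2) else 0,
    min_similarity = vapply(labs, function(l) {
      v <- pairs$global_similarity[band == l]
      if (length(v)) min(v) else NA_real_ }, 1),
    max_similarity = vapply(labs, function(l) {
      v <- pairs$global_similarity[band == l]
      if (length(v)) max(v) else NA_real_ }, 1))
  rownames(bands) <- NULL
  list(bands = bands,
       fraction_similarity_100 = if (nrow(pairs))
         round(100 * mean(pairs$global_similarity == 100), 2) else 0)
}

#' Partition two gene complements into shared and unique sets
#'
#' CDS (and, separately, RNA genes matched in nucleotide mode) without a
#' validated partner form the unique sets. Every comparable feature of each
#' genome lands in exactly one field.
#'
#' @param A,B [GenomeRecord-class] objects.
#' @param pairs validated CDS pairs.
#' @param rnaPairs validated RNA pairs (nucleotide mode); may be empty.
#' @return a [GenomePartition-class].
#' @export
partitionGenomes <- function(A, B, pairs,
                             rnaPairs = data.frame(id_a = character(),
                                                   id_b = character())) {
  fa <- mcols(features(A)); fb <- mcols(features(B))
  cdsA <- fa$locus_tag[fa$ftype == "CDS"]
  cdsB <- fb$locus_tag[fb$ftype == "CDS"]
  rnaA <- fa$locus_tag[fa$ftype != "CDS"]
  rnaB <- fb$locus_tag[fb$ftype != "CDS"]
  bad <- c(setdiff(pairs$id_a, cdsA), setdiff(pairs$id_b, cdsB),
           setdiff(rnaPairs$id_a, rnaA), setdiff(rnaPairs$id_b, rnaB))
  if (length(bad))
    stop("pair references unknown or mistyped id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  new("GenomePartition",
      pairs = pairs,
      uniqueA = setdiff(cdsA, pairs$id_a),
      uniqueB = setdiff(cdsB, pairs$id_b),
      rnaPairs = rnaPairs,
      rnaUniqueA = setdiff(rnaA, rnaPairs$id_a),
      rnaUniqueB = setdiff(rnaB, rnaPairs$id_b))
}
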