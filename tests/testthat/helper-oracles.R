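# Independent plain-R dynamic-programming references for the aligners, plus
# small shared fixtures. The oracles share no code with the package kernels.

# Smith-Waterman, affine gaps (gap of length L costs go + L * ge), score only
oracleLocalScore <- function(a, b, mat, go, ge) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  F <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(E[i, j + 1] - ge, H[i, j + 1] - go - ge)
      F[i + 1, j + 1] <- max(F[i + 1, j] - ge, H[i + 1, j] - go - ge)
      H[i + 1, j + 1] <- max(0, H[i, j] + mat[a[i], b[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Needleman-Wunsch, affine gaps, end gaps penalized, score only
oracleGlobalScore <- function(a, b, mat, go, ge) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  for (i in seq_len(n)) {
    E[i + 1, 1] <- -go - i * ge
    H[i + 1, 1] <- E[i + 1, 1]
  }
  for (j in seq_len(m)) {
    F[1, j + 1] <- -go - j * ge
    H[1, j + 1] <- F[1, j + 1]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(E[i, j + 1] - ge, H[i, j + 1] - go - ge)
      F[i + 1, j + 1] <- max(F[i + 1, j] - ge, H[i + 1, j] - go - ge)
      H[i + 1, j + 1] <- max(H[i, j] + mat[a[i], b[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  H[n + 1, m + 1]
}

randomProtein <- function(len) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

randomDna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# truth origin label of each unique CDS of one lineage, from the event log
truthOriginLabels <- function(truth, tags, lineage) {
  ev <- truthEvents(truth)
  s <- ev$locus_tag[ev$lineage == lineage & ev$event == "split"]
  d <- ev$locus_tag[ev$lineage == lineage & ev$event == "duplication"]
  h <- ev$locus_tag[ev$lineage == lineage & ev$event == "lateral_transfer"]
  del <- ev$locus_tag[ev$lineage != lineage & ev$event == "deletion"]
  ifelse(tags %in% s, "split",
  ifelse(tags %in% d, "duplication",
  ifelse(tags %in% h, "lateral_transfer",
  ifelse(tags %in% del, "deletion", "other"))))
}

pairKeys <- function(df, ca = 1, cb = 2) paste(df[[ca]], df[[cb]])

# one moderate simulated pair + full pipeline run, computed once and shared
# across test files
.sharedEnv <- new.env()
sharedRun <- function() {
  if (is.null(.sharedEnv$run)) {
    sim <- simulateGenomePair(SimParams(nGenes = 120L, seed = 301L))
    res <- suppressMessages(runPipeline(sim$A, sim$B, runConfig()))
    .sharedEnv$run <- list(sim = sim, res = res)
  }
  .sharedEnv$run
}
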