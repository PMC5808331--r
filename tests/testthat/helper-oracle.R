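# Independent Smith-Waterman oracle: plain-R dynamic program, score only.
# Linear gap penalty; N mismatches everything. Kept deliberately separate
# from the package's aligner so tests compare two implementations.
sw_oracle_score <- function(q, s, match = 1, mismatch = -2, gap = -2.5) {
  qc <- strsplit(q, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  n <- length(qc); m <- length(sc)
  prev <- numeric(m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    sub <- ifelse(sc == qc[i] & qc[i] != "N", match, mismatch)
    for (j in seq_len(m)) {
      h <- max(0, prev[j] + sub[j], prev[j + 1L] + gap, cur[j] + gap)
      cur[j + 1L] <- h
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

# Cross-check oracle via Biostrings (C implementation, also independent of
# the package's DP). Local alignment, linear gap via zero opening cost.
biostrings_best_score <- function(q, s, match = 1, mismatch = -2,
                                  gap = 2.5) {
  mat <- matrix(mismatch, 5, 5,
                dimnames = list(c("A", "C", "G", "T", "N"),
                                c("A", "C", "G", "T", "N")))
  diag(mat)[1:4] <- match
  as.numeric(Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = gap, scoreOnly = TRUE))
}

best_oracle_score_both_strands <- function(q, s, ...) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  max(biostrings_best_score(q, s, ...), biostrings_best_score(q, rc, ...))
}
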