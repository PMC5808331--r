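#' Alignment parameters
#'
#' Scoring and significance settings for the built-in seed-and-extend
#' nucleotide aligner. Defaults mirror megablast-style scoring: match +1,
#' mismatch -2, linear gap penalty -2.5 per gapped column, word size 11.
#' Significance uses Karlin-Altschul statistics,
#' \eqn{E = K m n e^{-\lambda S}}, with the effective search space taken as
#' query length times total target length; \eqn{\lambda} is solved from the
#' scoring scheme under uniform base composition and \eqn{K} is fixed at
#' the conventional ungapped value for this scheme.
#'
#' @param match match score (positive).
#' @param mismatch mismatch score (negative).
#' @param gap linear gap penalty per gap column (negative).
#' @param seed_k exact-match word size used to seed candidate pairs.
#' @param max_evalue report alignments with E-value at or below this.
#' @param K Karlin-Altschul K constant.
#' @param max_hits_per_pair cap on non-overlapping alignments reported per
#'   query/target/strand combination.
#' @return a list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -2, gap = -2.5, seed_k = 11L,
                         max_evalue = 1e-6, K = 0.621,
                         max_hits_per_pair = 10L) {
  stopifnot(match > 0, mismatch < 0, gap < 0, seed_k >= 1, max_evalue > 0)
  lambda <- karlin_lambda(match, mismatch)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 seed_k = as.integer(seed_k), max_evalue = max_evalue,
                 K = K, lambda = lambda,
                 max_hits_per_pair = as.integer(max_hits_per_pair)),
            class = "align_params")
}

# Solve sum_ij p_i p_j exp(lambda * s_ij) = 1 for uniform base frequencies:
# (1/4) exp(lambda * match) + (3/4) exp(lambda * mismatch) = 1.
karlin_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 50 / match), tol = 1e-12)$root
}

#' Karlin-Altschul expectation of a local alignment score
#'
#' @param score raw alignment score.
#' @param m query length (nt).
#' @param n total target length (nt).
#' @param params an [align_params()] object.
#' @return the E-value.
#' @export
alignment_evalue <- function(score, m, n, params) {
  params$K * as.numeric(m) * as.numeric(n) * exp(-params$lambda * score)
}

as_sequence_set <- function(x, what) {
  if (inherits(x, "locus_catalog")) {
    tx <- x$transcripts
    list(seqs = stats::setNames(unname(x$sequences[tx$transcript_id]),
                                tx$transcript_id),
         locus = stats::setNames(tx$locus_id, tx$transcript_id))
  } else if (is.character(x) && (length(x) == 0L || !is.null(names(x)))) {
    list(seqs = x, locus = stats::setNames(names(x), names(x)))
  } else stop(what, " must be a locus_catalog or a named character vector")
}

empty_matches <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             query_locus = character(0), subject_locus = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             aligned_length = integer(0), percent_identity = numeric(0),
             score = numeric(0), evalue = numeric(0),
             subject_strand = character(0), subject_class = character(0),
             stringsAsFactors = FALSE)
}


#' All-vs-all local nucleotide alignment
#'
#' Seed-and-extend homology search: query/target pairs with two exact
#' `seed_k`-mer word hits on nearby diagonals (the classic two-hit trigger,
#' checked on both target strands; any alignment containing an exact run of
#' `seed_k + 1` nt seeds) are aligned with a full
#' Smith-Waterman dynamic program; all non-overlapping local alignments
#' whose E-value is at or below `params$max_evalue` are reported.
#' Within a pair, overlapping alternative alignments are resolved greedily
#' by score. Exact self matches (`query_id == subject_id`) are emitted here
#' and flagged for removal by the downstream filter cascade.
#'
#' Coordinates in the result are 0-based half-open on the transcript; for
#' minus-strand hits `s_start`/`s_end` refer to the forward strand of the
#' subject. `N` bases mismatch everything, including `N`.
#'
#' @param queries a `locus_catalog` or named character vector of sequences.
#' @param targets a `locus_catalog` or named character vector of sequences.
#' @param params an [align_params()] object.
#' @return a data.frame of homology matches with columns `query_id`,
#'   `subject_id`, `query_locus`, `subject_locus`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `aligned_length`, `percent_identity` (fraction in
#'   \[0,1\]), `score`, `evalue`, `subject_strand`, `subject_class`
#'   (initialised to `"unclassified"`).
#' @export
align_all <- function(queries, targets, params = align_params()) {
  qs <- as_sequence_set(queries, "queries")
  ts <- as_sequence_set(targets, "targets")
  if (length(qs$seqs) == 0L || length(ts$seqs) == 0L) return(empty_matches())
  if (any(nchar(qs$seqs) == 0L) || any(nchar(ts$seqs) == 0L))
    stop("sequences must be non-empty")
  k <- params$seed_k
  if (k > min(nchar(qs$seqs)))
    stop("configuration error: seed_k (", k,
         ") exceeds the shortest query length")
  n_total <- sum(nchar(ts$seqs))
  # minimum raw score implied by the E-value threshold (depends on m)
  min_score_for <- function(m)
    (log(params$K * m * n_total) - log(params$max_evalue)) / params$lambda

  target_ids <- names(ts$seqs)
  qseq_vec <- unname(qs$seqs)
  rows <- list()
  for (ti in seq_along(ts$seqs)) {
    fwd <- ts$seqs[[ti]]
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") fwd else revcomp(fwd)
      cand <- which(seed_candidates(qseq_vec, sseq, k, 16L))
      for (qi in cand) {
        qseq <- qs$seqs[[qi]]
        ms <- min_score_for(nchar(qseq))
        hits <- sw_align_pair(qseq, sseq, params$match, params$mismatch,
                              params$gap, ms, params$max_hits_per_pair)
        if (nrow(hits) == 0L) next
        ev <- alignment_evalue(hits[, "score"], nchar(qseq), n_total, params)
        keep <- ev <= params$max_evalue & hits[, "length"] >= k
        if (!any(keep)) next
        hits <- hits[keep, , drop = FALSE]
        ev <- ev[keep]
        s_len <- nchar(fwd)
        s_start <- if (strand == "+") hits[, "s_start"] else s_len - hits[, "s_end"]
        s_end <- if (strand == "+") hits[, "s_end"] else s_len - hits[, "s_start"]
        qid <- names(qs$seqs)[qi]
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid, subject_id = target_ids[ti],
          query_locus = unname(qs$locus[[qid]]),
          subject_locus = unname(ts$locus[[target_ids[ti]]]),
          q_start = as.integer(hits[, "q_start"]),
          q_end = as.integer(hits[, "q_end"]),
          s_start = as.integer(s_start), s_end = as.integer(s_end),
          aligned_length = as.integer(hits[, "length"]),
          percent_identity = hits[, "identities"] / hits[, "length"],
          score = hits[, "score"], evalue = ev,
          subject_strand = strand, subject_class = "unclassified",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty_matches())
  out <- do.call(rbind, rows)
  out <- out[order(out$query_id, out$subject_id, out$subject_strand,
                   out$q_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
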