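BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Import alignments from 12-column BLAST tabular output
#'
#' Reads the standard tabular dialect (`outfmt 6`: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) and
#' converts it to the package's match table: 1-based closed coordinates
#' become 0-based half-open, percent identity is rescaled to \[0,1\], and a
#' minus-strand subject is inferred from `sstart > send`. This lets users
#' substitute real external BLASTN results for the built-in aligner.
#'
#' @param path tabular alignment file.
#' @param catalog optional `locus_catalog` used to resolve transcript ids
#'   to locus ids for both queries and subjects; ids absent from the
#'   catalog map to themselves.
#' @return a homology match data.frame (see [align_all()]).
#' @export
import_blast_tabular <- function(path, catalog = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_matches())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L)
  if (length(bad) > 0L)
    stop("format error at line ", bad[1L], ": expected 12 tab-separated ",
         "columns, found ", nf[bad[1L]])
  m <- do.call(rbind, parts)
  colnames(m) <- BLAST6_COLS
  sstart <- as.integer(m[, "sstart"]); send <- as.integer(m[, "send"])
  minus <- sstart > send
  lookup <- function(ids) {
    if (is.null(catalog)) return(ids)
    map <- stats::setNames(catalog$transcripts$locus_id,
                           catalog$transcripts$transcript_id)
    out <- unname(map[ids])
    out[is.na(out)] <- ids[is.na(out)]
    out
  }
  data.frame(
    query_id = m[, "qseqid"], subject_id = m[, "sseqid"],
    query_locus = lookup(m[, "qseqid"]),
    subject_locus = lookup(m[, "sseqid"]),
    q_start = as.integer(m[, "qstart"]) - 1L,
    q_end = as.integer(m[, "qend"]),
    s_start = ifelse(minus, send, sstart) - 1L,
    s_end = ifelse(minus, sstart, send),
    aligned_length = as.integer(m[, "length"]),
    percent_identity = as.numeric(m[, "pident"]) / 100,
    score = as.numeric(m[, "bitscore"]),
    evalue = as.numeric(m[, "evalue"]),
    subject_strand = ifelse(minus, "-", "+"),
    subject_class = "unclassified",
    stringsAsFactors = FALSE)
}

#' Export a match table as 12-column BLAST tabular
#'
#' Inverse of [import_blast_tabular()]: coordinates go back to 1-based
#' closed (subject coordinates swapped for minus-strand hits), percent
#' identity back to a percentage, and the raw score fills the bitscore
#' column. Mismatch and gap-open columns are reported as
#' `aligned_length - identities` and 0 (the internal model does not keep
#' them separately).
#'
#' @param matches a homology match data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_blast_tabular <- function(matches, path) {
  minus <- matches$subject_strand == "-"
  identities <- round(matches$percent_identity * matches$aligned_length)
  lines <- paste(
    matches$query_id, matches$subject_id,
    format(matches$percent_identity * 100, digits = 12, trim = TRUE,
           scientific = FALSE),
    matches$aligned_length,
    matches$aligned_length - identities, 0L,
    matches$q_start + 1L, matches$q_end,
    ifelse(minus, matches$s_end, matches$s_start + 1L),
    ifelse(minus, matches$s_start + 1L, matches$s_end),
    format(matches$evalue, digits = 12, trim = TRUE),
    format(matches$score, digits = 12, trim = TRUE),
    sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write the enriched match table
#'
#' A richer TSV than the 12-column tabular format: includes locus ids,
#' subject strand and the subject classification.
#'
#' @param matches a homology match data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
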