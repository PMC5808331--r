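#' @useDynLib lncfam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

BIOTYPES <- c("lncRNA", "mRNA", "rRNA", "other_ncRNA")

#' Construct a locus catalog
#'
#' A locus catalog is the central container of the pipeline: a table of
#' annotated transcripts grouped by gene-level locus, together with their
#' spliced sequences and (optionally) their genomic exon spans.
#'
#' @param transcripts data.frame with columns `locus_id`, `transcript_id`,
#'   `biotype` (one of `"lncRNA"`, `"mRNA"`, `"rRNA"`, `"other_ncRNA"`),
#'   `exon_count`, `length_nt`, `chrom`, `strand` (`"+"` or `"-"`).
#' @param sequences named character vector of spliced transcript sequences
#'   over `A,C,G,T,N`, keyed by `transcript_id`.
#' @param exon_spans optional named list (keyed by `transcript_id`) of
#'   two-column integer matrices of genomic exon coordinates, 0-based
#'   half-open, sorted in ascending genomic order and non-overlapping.
#'   For minus-strand transcripts the spliced sequence is the reverse
#'   complement of the concatenated exon substrings.
#' @param provenance free-text description of the source.
#'
#' @return An object of class `locus_catalog`.
#' @export
locus_catalog <- function(transcripts, sequences, exon_spans = NULL,
                          provenance = "in-memory") {
  stopifnot(is.data.frame(transcripts))
  req <- c("locus_id", "transcript_id", "biotype", "exon_count",
           "length_nt", "chrom", "strand")
  missing_cols <- setdiff(req, names(transcripts))
  if (length(missing_cols) > 0L)
    stop("transcripts is missing column(s): ", paste(missing_cols, collapse = ", "))
  transcripts <- transcripts[, req]
  transcripts$locus_id <- as.character(transcripts$locus_id)
  transcripts$transcript_id <- as.character(transcripts$transcript_id)
  transcripts$biotype <- as.character(transcripts$biotype)
  transcripts$exon_count <- as.integer(transcripts$exon_count)
  transcripts$length_nt <- as.integer(transcripts$length_nt)
  rownames(transcripts) <- NULL
  obj <- structure(
    list(transcripts = transcripts,
         sequences = sequences,
         exon_spans = exon_spans,
         provenance = provenance),
    class = "locus_catalog")
  validate_catalog(obj)
  obj
}

#' Validate a locus catalog
#'
#' Checks the structural invariants: unique transcript ids, known biotypes,
#' sequence lengths equal to the recorded transcript lengths, and — when
#' exon spans are present — exon counts and summed span lengths matching,
#' spans sorted and non-overlapping.
#'
#' @param catalog a `locus_catalog`.
#' @return `catalog`, invisibly; errors on violation.
#' @export
validate_catalog <- function(catalog) {
  tx <- catalog$transcripts
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript_id in catalog")
  bad_bt <- setdiff(unique(tx$biotype), BIOTYPES)
  if (length(bad_bt) > 0L)
    stop("unknown biotype(s): ", paste(bad_bt, collapse = ", "))
  if (!all(tx$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (nrow(tx) > 0L) {
    missing_seq <- setdiff(tx$transcript_id, names(catalog$sequences))
    if (length(missing_seq) > 0L)
      stop("missing sequence for transcript(s): ",
           paste(utils::head(missing_seq, 3L), collapse = ", "))
    seq_len_nt <- nchar(catalog$sequences[tx$transcript_id])
    off <- which(seq_len_nt != tx$length_nt)
    if (length(off) > 0L)
      stop("length_nt disagrees with sequence length for ",
           tx$transcript_id[off[1L]])
    bad_chr <- grepl("[^ACGTN]", catalog$sequences[tx$transcript_id])
    if (any(bad_chr))
      stop("sequence contains characters outside {A,C,G,T,N}: ",
           tx$transcript_id[which(bad_chr)[1L]])
  }
  if (!is.null(catalog$exon_spans)) {
    for (i in seq_len(nrow(tx))) {
      id <- tx$transcript_id[i]
      sp <- catalog$exon_spans[[id]]
      if (is.null(sp)) next
      if (nrow(sp) != tx$exon_count[i])
        stop("exon_count disagrees with exon spans for ", id)
      if (sum(sp[, 2L] - sp[, 1L]) != tx$length_nt[i])
        stop("summed exon span length disagrees with length_nt for ", id)
      if (nrow(sp) > 1L &&
          any(sp[-1L, 1L] < sp[-nrow(sp), 2L]))
        stop("exon spans overlap or are unsorted for ", id)
    }
  }
  invisible(catalog)
}

#' @export
print.locus_catalog <- function(x, ...) {
  tx <- x$transcripts
  cat("locus_catalog:", length(unique(tx$locus_id)), "loci,",
      nrow(tx), "transcripts\n")
  if (nrow(tx) > 0L) {
    bt <- table(tx$biotype)
    cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  }
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
summary.locus_catalog <- function(object, ...) {
  tx <- object$transcripts
  per_locus <- table(tx$locus_id)
  out <- list(n_loci = length(per_locus),
              n_transcripts = nrow(tx),
              biotype_counts = table(tx$biotype),
              isoforms_per_locus = summary(as.integer(per_locus)),
              length_nt = summary(tx$length_nt))
  class(out) <- "summary.locus_catalog"
  out
}

#' @export
print.summary.locus_catalog <- function(x, ...) {
  cat("Loci:", x$n_loci, " Transcripts:", x$n_transcripts, "\n")
  print(x$biotype_counts)
  cat("Isoforms per locus:\n"); print(x$isoforms_per_locus)
  cat("Transcript length (nt):\n"); print(x$length_nt)
  invisible(x)
}

#' Number of loci in a catalog
#' @param catalog a `locus_catalog`.
#' @return integer count of distinct loci.
#' @export
n_loci <- function(catalog) length(unique(catalog$transcripts$locus_id))

#' Subset a catalog to a set of transcripts
#' @param catalog a `locus_catalog`.
#' @param transcript_ids character vector of transcript ids to keep.
#' @return a new `locus_catalog` (the input is not modified).
#' @export
subset_transcripts <- function(catalog, transcript_ids) {
  tx <- catalog$transcripts
  keep <- tx$transcript_id %in% transcript_ids
  locus_catalog(tx[keep, , drop = FALSE],
                catalog$sequences[tx$transcript_id[keep]],
                if (is.null(catalog$exon_spans)) NULL
                else catalog$exon_spans[tx$transcript_id[keep]],
                provenance = catalog$provenance)
}

#' Subset a catalog by biotype
#' @param catalog a `locus_catalog`.
#' @param biotype one of `"lncRNA"`, `"mRNA"`, `"rRNA"`, `"other_ncRNA"`.
#' @return a new `locus_catalog` containing only transcripts of that biotype.
#' @export
filter_biotype <- function(catalog, biotype) {
  biotype <- match.arg(biotype, BIOTYPES)
  tx <- catalog$transcripts
  subset_transcripts(catalog, tx$transcript_id[tx$biotype == biotype])
}

#' Select one representative isoform per locus
#'
#' Reduces a catalog to a single transcript per locus. `"longest"` and
#' `"shortest"` choose by spliced length; ties are broken by the
#' lexicographically smallest transcript id so that selection is a total
#' order and reproducible. `"by_locus_list"` first drops loci absent from
#' `locus_ids` (for example, loci never seen in a set of differential
#' splicing result tables), then keeps the longest isoform of each
#' remaining locus.
#'
#' @param catalog a `locus_catalog`.
#' @param mode `"longest"`, `"shortest"`, or `"by_locus_list"`.
#' @param locus_ids character vector of loci to retain
#'   (required for `mode = "by_locus_list"`).
#' @return a new `locus_catalog` with exactly one isoform per retained
#'   locus; a warning and an empty catalog if `by_locus_list` retains
#'   nothing.
#' @export
select_isoform <- function(catalog,
                           mode = c("longest", "shortest", "by_locus_list"),
                           locus_ids = NULL) {
  mode <- match.arg(mode)
  tx <- catalog$transcripts
  if (nrow(tx) == 0L) stop("catalog is empty")
  if (mode == "by_locus_list") {
    if (is.null(locus_ids))
      stop("mode 'by_locus_list' requires locus_ids")
    tx <- tx[tx$locus_id %in% locus_ids, , drop = FALSE]
    if (nrow(tx) == 0L) {
      warning("no catalog locus present in locus_ids; returning empty catalog")
      return(subset_transcripts(catalog, character(0)))
    }
    mode <- "longest"
  }
  ord <- order(tx$locus_id,
               if (mode == "longest") -tx$length_nt else tx$length_nt,
               tx$transcript_id)
  tx <- tx[ord, , drop = FALSE]
  keep <- tx$transcript_id[!duplicated(tx$locus_id)]
  subset_transcripts(catalog, keep)
}

#' Write a catalog summary table
#'
#' @param catalog a `locus_catalog`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  tx <- catalog$transcripts
  utils::write.table(
    tx[, c("locus_id", "transcript_id", "biotype", "exon_count",
           "length_nt", "chrom", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write transcript sequences as FASTA
#'
#' Headers have the form `>transcript_id locus=locus_id`.
#'
#' @param catalog a `locus_catalog`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(catalog, path) {
  tx <- catalog$transcripts
  seqs <- Biostrings::DNAStringSet(catalog$sequences[tx$transcript_id])
  names(seqs) <- paste0(tx$transcript_id, " locus=", tx$locus_id)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a catalog back from its TSV + FASTA representation
#'
#' Counterpart to [write_catalog_tsv()] and [write_transcript_fasta()].
#' Genomic exon spans are not serialised in this representation, so the
#' returned catalog carries `exon_spans = NULL` (exon counts are preserved
#' through the table).
#'
#' @param tsv_path catalog TSV path.
#' @param fasta_path transcript FASTA path.
#' @return a `locus_catalog`.
#' @export
read_catalog <- function(tsv_path, fasta_path) {
  tx <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                          colClasses = "character")
  tx$exon_count <- as.integer(tx$exon_count)
  tx$length_nt <- as.integer(tx$length_nt)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  sequences <- stats::setNames(as.character(seqs), ids)
  locus_catalog(tx, sequences, NULL,
                provenance = paste0("read_catalog(", tsv_path, ")"))
}
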