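TRANSCRIPT_GFF_TYPES <- c("lnc_RNA", "mRNA", "rRNA", "ncRNA", "snoRNA",
                          "snRNA", "tRNA", "miRNA", "transcript")

gff_type_to_biotype <- function(type, ncrna_class) {
  ifelse(type == "lnc_RNA", "lncRNA",
  ifelse(type == "mRNA", "mRNA",
  ifelse(type == "rRNA", "rRNA",
  ifelse(type == "ncRNA" & !is.na(ncrna_class) &
           ncrna_class %in% c("lncRNA", "lincRNA"), "lncRNA",
         "other_ncRNA"))))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Parse a genome annotation into a locus catalog
#'
#' Reads transcript features from an annotation and assembles their spliced
#' sequences. Two source formats are supported: GFF3 with an accompanying
#' genome FASTA (exons are concatenated in genomic order and
#' reverse-complemented for minus-strand transcripts), and the NCBI RNA
#' GenBank flat-file dialect (`rna.gbff`), in which each record already
#' carries the spliced transcript sequence.
#'
#' Biotype assignment: `lnc_RNA` features, and `ncRNA` features whose
#' `ncRNA_class` is `lncRNA`/`lincRNA`, become biotype `"lncRNA"`; `mRNA`
#' and `rRNA` keep their own biotypes (ribosomal features are retained so
#' downstream filtering can identify rRNA subjects); all remaining
#' non-coding classes (snoRNA, snRNA, tRNA, miRNA, unclassed ncRNA) become
#' `"other_ncRNA"` and are excluded from the family pipeline by default.
#'
#' Internal coordinates are 0-based half-open throughout the package; GFF3's
#' 1-based closed coordinates are converted at this boundary.
#'
#' @param source path to a GFF3 file or a GenBank flat file.
#' @param genome for GFF3 input, path to the genome FASTA (or a named
#'   character vector / `DNAStringSet` of chromosome sequences).
#' @param biotype_filter optional biotype; if given, only transcripts of
#'   that biotype are returned.
#' @param format `"auto"` (by file extension), `"gff3"`, or `"gbff"`.
#' @return a `locus_catalog`.
#' @export
parse_annotation <- function(source, genome = NULL, biotype_filter = NULL,
                             format = c("auto", "gff3", "gbff")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", source)))
    format <- if (ext %in% c("gbff", "gb", "gbk", "genbank")) "gbff" else "gff3"
  }
  catalog <- if (format == "gff3") {
    if (is.null(genome))
      stop("GFF3 input requires a genome FASTA for sequence extraction")
    parse_gff3_annotation(source, genome)
  } else {
    parse_gbff_annotation(source)
  }
  if (!is.null(biotype_filter)) catalog <- filter_biotype(catalog, biotype_filter)
  catalog
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    stats::setNames(as.character(seqs), names(seqs))
  } else if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    genome
  } else stop("genome must be a FASTA path or a named sequence set")
}

parse_gff3_annotation <- function(path, genome) {
  genome <- load_genome(genome)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("failed to parse GFF3 '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(mc))
    vapply(mc$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  else rep(NA_character_, length(gr))
  ncrna_class <- if ("ncRNA_class" %in% names(mc))
    as.character(mc$ncRNA_class) else rep(NA_character_, length(gr))

  is_tx <- type %in% TRANSCRIPT_GFF_TYPES & !is.na(id)
  tx_idx <- which(is_tx)
  if (length(tx_idx) == 0L)
    stop("no transcript features found in '", path, "'")
  exon_idx <- which(type == "exon" & !is.na(parent))
  exons_by_tx <- split(exon_idx, parent[exon_idx])

  rows <- vector("list", length(tx_idx))
  seqs <- character(length(tx_idx))
  spans <- vector("list", length(tx_idx))
  for (k in seq_along(tx_idx)) {
    i <- tx_idx[k]
    tid <- id[i]
    ex <- exons_by_tx[[tid]]
    chrom <- as.character(GenomicRanges::seqnames(gr[i]))
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (!strand %in% c("+", "-")) strand <- "+"
    if (is.null(ex) || length(ex) == 0L) {
      # transcript without exon children: treat its own span as one exon
      sp <- cbind(GenomicRanges::start(gr[i]) - 1L, GenomicRanges::end(gr[i]))
    } else {
      sp <- cbind(GenomicRanges::start(gr[ex]) - 1L, GenomicRanges::end(gr[ex]))
      sp <- sp[order(sp[, 1L]), , drop = FALSE]
    }
    chrom_seq <- genome[[chrom]]
    if (is.null(chrom_seq) || is.na(chrom_seq))
      stop("validation error: transcript ", tid,
           " references unknown sequence '", chrom, "'")
    if (any(sp[, 1L] < 0L) || any(sp[, 2L] > nchar(chrom_seq)))
      stop("validation error: exons of transcript ", tid,
           " exceed bounds of sequence '", chrom, "'")
    pieces <- substring(chrom_seq, sp[, 1L] + 1L, sp[, 2L])
    seq <- paste(pieces, collapse = "")
    if (strand == "-") seq <- revcomp(seq)
    locus <- parent[i]
    if (is.na(locus)) locus <- tid
    rows[[k]] <- data.frame(
      locus_id = locus, transcript_id = tid,
      biotype = gff_type_to_biotype(type[i], ncrna_class[i]),
      exon_count = nrow(sp), length_nt = nchar(seq),
      chrom = chrom, strand = strand, stringsAsFactors = FALSE)
    seqs[k] <- seq
    spans[[k]] <- sp
  }
  tx <- do.call(rbind, rows)
  names(seqs) <- tx$transcript_id
  names(spans) <- tx$transcript_id
  locus_catalog(tx, seqs, spans,
                provenance = paste0("gff3:", path))
}

#' Write a locus catalog as GFF3
#'
#' Emits gene, transcript and exon features in the same dialect that
#' [parse_annotation()] reads: transcript types `lnc_RNA`, `mRNA`, `rRNA`
#' or `ncRNA`, exon features with `Parent` attributes, 1-based closed
#' coordinates.
#'
#' @param catalog a `locus_catalog` with genomic `exon_spans`.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(catalog, path) {
  tx <- catalog$transcripts
  if (is.null(catalog$exon_spans))
    stop("catalog has no genomic exon spans; cannot write GFF3")
  bio_to_type <- c(lncRNA = "lnc_RNA", mRNA = "mRNA", rRNA = "rRNA",
                   other_ncRNA = "ncRNA")
  lines <- c("##gff-version 3")
  for (locus in unique(tx$locus_id)) {
    sub <- tx[tx$locus_id == locus, , drop = FALSE]
    sp_all <- do.call(rbind, catalog$exon_spans[sub$transcript_id])
    g_start <- min(sp_all[, 1L]) + 1L
    g_end <- max(sp_all[, 2L])
    lines <- c(lines, paste(sub$chrom[1L], "lncfam", "gene", g_start, g_end,
                            ".", sub$strand[1L], ".",
                            paste0("ID=", locus), sep = "\t"))
    for (i in seq_len(nrow(sub))) {
      tid <- sub$transcript_id[i]
      sp <- catalog$exon_spans[[tid]]
      lines <- c(lines,
        paste(sub$chrom[i], "lncfam", bio_to_type[[sub$biotype[i]]],
              min(sp[, 1L]) + 1L, max(sp[, 2L]), ".", sub$strand[i], ".",
              paste0("ID=", tid, ";Parent=", locus), sep = "\t"),
        paste(sub$chrom[i], "lncfam", "exon", sp[, 1L] + 1L, sp[, 2L],
              ".", sub$strand[i], ".",
              paste0("ID=", tid, ".e", seq_len(nrow(sp)), ";Parent=", tid),
              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# --- GenBank flat file (NCBI rna.gbff dialect) ------------------------------
# Each record is one transcript: LOCUS/VERSION give the accession, a gene
# qualifier gives the locus, the RNA feature key (ncRNA/mRNA/rRNA/...) gives
# the biotype, exon features (transcript coordinates) give the exon count,
# and ORIGIN gives the spliced sequence. No installed parser reads this
# format offline, so a minimal one lives here.

parse_gbff_annotation <- function(path) {
  raw <- readLines(path, warn = FALSE)
  rec_ends <- which(raw == "//")
  if (length(rec_ends) == 0L)
    stop("format error: no GenBank record terminator '//' found in '", path, "'")
  rec_starts <- c(1L, utils::head(rec_ends, -1L) + 1L)
  rows <- list(); seqs <- character(0); spans <- list()
  for (r in seq_along(rec_ends)) {
    rec <- raw[rec_starts[r]:(rec_ends[r] - 1L)]
    rec <- rec[nzchar(trimws(rec))]
    if (length(rec) == 0L) next
    locus_line <- grep("^LOCUS", rec, value = TRUE)
    if (length(locus_line) == 0L)
      stop("format error: record ", r, " in '", path, "' has no LOCUS line")
    rec_name <- strsplit(trimws(sub("^LOCUS", "", locus_line[1L])), "\\s+")[[1L]][1L]
    ver_line <- grep("^VERSION", rec, value = TRUE)
    accession <- if (length(ver_line) > 0L)
      strsplit(trimws(sub("^VERSION", "", ver_line[1L])), "\\s+")[[1L]][1L]
    else rec_name

    feat_start <- grep("^FEATURES", rec)
    origin_start <- grep("^ORIGIN", rec)
    if (length(origin_start) == 0L)
      stop("format error: record ", accession, " has no ORIGIN sequence")
    feat_lines <- if (length(feat_start) > 0L)
      rec[(feat_start[1L] + 1L):(origin_start[1L] - 1L)] else character(0)

    key_at <- which(grepl("^ {5}\\S", feat_lines))
    keys <- trimws(feat_lines[key_at])
    keys <- sub("\\s.*$", "", keys)
    quals <- feat_lines[grepl("^\\s+/", feat_lines)]
    gene_q <- grep('/gene="', quals, value = TRUE)
    locus_id <- if (length(gene_q) > 0L)
      sub('.*\\/gene="([^"]*)".*', "\\1", gene_q[1L]) else accession
    class_q <- grep('/ncRNA_class="', quals, value = TRUE)
    ncrna_class <- if (length(class_q) > 0L)
      sub('.*\\/ncRNA_class="([^"]*)".*', "\\1", class_q[1L]) else NA_character_

    biotype <-
      if ("ncRNA" %in% keys) {
        if (!is.na(ncrna_class) && ncrna_class %in% c("lncRNA", "lincRNA"))
          "lncRNA" else "other_ncRNA"
      } else if ("mRNA" %in% keys | "CDS" %in% keys) "mRNA"
      else if ("rRNA" %in% keys) "rRNA"
      else "other_ncRNA"

    # exon features carry transcript-space start..end locations
    exon_lines <- trimws(feat_lines[key_at][keys == "exon"])
    exon_locs <- sub("^exon\\s+", "", exon_lines)
    sp <- NULL
    ok <- grepl("^<?[0-9]+\\.\\.>?[0-9]+$", exon_locs)
    if (length(exon_locs) > 0L && all(ok)) {
      st <- as.integer(sub("^<?([0-9]+)\\.\\..*$", "\\1", exon_locs)) - 1L
      en <- as.integer(sub("^.*\\.\\.>?([0-9]+)$", "\\1", exon_locs))
      sp <- cbind(st, en)[order(st), , drop = FALSE]
    }

    seq_lines <- rec[(origin_start[1L] + 1L):length(rec)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    seq <- chartr("U", "T", seq)
    if (grepl("[^ACGTN]", seq))
      stop("format error: record ", accession,
           " contains non-ACGTN sequence characters")
    exon_count <- if (!is.null(sp)) nrow(sp) else max(1L, sum(keys == "exon"))
    if (!is.null(sp) && sum(sp[, 2L] - sp[, 1L]) != nchar(seq)) sp <- NULL
    if (is.null(sp)) sp <- cbind(0L, nchar(seq))

    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = locus_id, transcript_id = accession, biotype = biotype,
      exon_count = exon_count, length_nt = nchar(seq),
      chrom = ".", strand = "+", stringsAsFactors = FALSE)
    seqs[accession] <- seq
    if (nrow(sp) == exon_count) spans[[accession]] <- sp
  }
  tx <- do.call(rbind, rows)
  locus_catalog(tx, seqs,
                exon_spans = NULL,  # gbff spans are transcript-space, not genomic
                provenance = paste0("gbff:", path))
}
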