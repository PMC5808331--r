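#' Configuration for the synthetic genome generator
#'
#' Defaults describe a toy genome whose planted structure mirrors the
#' magnitudes the pipeline is meant to detect: family shared blocks of
#' 605, 382 and 208 nt mutated at a 3% per-base substitution rate (so
#' within-family identity is about 97%), family sizes spanning 3 to 35,
#' plus background loci, two-member pair groups (for the degree tallies),
#' TE-derived decoy families, ribosomal loci and coding genes, two of
#' which carry a copy of a lncRNA block (lncRNA-to-coding sequence
#' sharing).
#'
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @param n_background_lnc background lncRNA loci with no planted homology.
#' @param family_sizes integer vector of planted family sizes (each >= 3).
#' @param shared_block_lengths nt lengths of family shared blocks, recycled
#'   across families.
#' @param per_base_substitution_rate substitution rate applied to each
#'   copy of a shared block, in \[0, 0.5\].
#' @param indel_rate per-base indel rate applied to block copies
#'   (default 0; substitutions only).
#' @param n_pair_groups planted two-locus homology pairs (below family
#'   size; they populate the degree-1 tally).
#' @param n_te_decoy_families families whose shared block is a
#'   transposable-element fragment (should be flagged by the TE screen).
#' @param te_decoy_family_size members per TE decoy family.
#' @param n_rrna_loci ribosomal RNA loci; when positive, one background
#'   lncRNA also carries an rRNA fragment so the rRNA filter has work to
#'   do.
#' @param n_coding_genes protein-coding (mRNA) loci.
#' @param n_coding_genes_with_shared_region how many coding genes embed a
#'   copy of a family lncRNA block.
#' @param n_cross_species cross-species transcripts (not in the
#'   annotation) sharing a block with a family lncRNA; they get a
#'   non-target taxon in the accession table.
#' @param max_isoforms_per_locus isoform count per lncRNA locus is drawn
#'   uniformly from 1 to this (capped by what the exon structure allows;
#'   extra isoforms are skipped-exon and retained-intron variants).
#' @param locus_length_range nt range of primary transcript lengths.
#' @param gc background GC content (sequence is i.i.d. over ACGT).
#' @param taxon_of_interest species name written to the taxon tables for
#'   annotation transcripts.
#' @return a list of class `synthesis_config`.
#' @export
synthesis_config <- function(seed = 1L,
                             n_background_lnc = 20L,
                             family_sizes = c(3L, 3L, 4L, 5L, 7L, 35L),
                             shared_block_lengths = c(605L, 382L, 208L),
                             per_base_substitution_rate = 0.03,
                             indel_rate = 0,
                             n_pair_groups = 2L,
                             n_te_decoy_families = 2L,
                             te_decoy_family_size = 3L,
                             n_rrna_loci = 2L,
                             n_coding_genes = 5L,
                             n_coding_genes_with_shared_region = 2L,
                             n_cross_species = 2L,
                             max_isoforms_per_locus = 3L,
                             locus_length_range = c(800L, 1600L),
                             gc = 0.5,
                             taxon_of_interest = "Oryza sativa") {
  stopifnot(per_base_substitution_rate >= 0,
            per_base_substitution_rate <= 0.5,
            all(family_sizes >= 3L),
            all(shared_block_lengths >= 1L),
            n_background_lnc >= 0L, n_pair_groups >= 0L,
            n_te_decoy_families >= 0L, n_rrna_loci >= 0L,
            n_coding_genes >= 0L,
            n_coding_genes_with_shared_region <= n_coding_genes,
            gc > 0, gc < 1)
  if (max(shared_block_lengths) + 100L > locus_length_range[2L])
    stop("configuration error: shared block longer than the largest locus")
  structure(as.list(environment()), class = "synthesis_config")
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(seq, sub_rate, indel_rate = 0) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  hit <- which(stats::runif(n) < sub_rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  if (indel_rate > 0) {
    keep <- stats::runif(length(chars)) >= indel_rate / 2
    chars <- chars[keep]
    ins_at <- which(stats::runif(length(chars)) < indel_rate / 2)
    if (length(ins_at) > 0L) {
      ins <- sample(c("A", "C", "G", "T"), length(ins_at), replace = TRUE)
      out <- character(0)
      prev <- 1L
      for (k in seq_along(ins_at)) {
        out <- c(out, chars[prev:ins_at[k]], ins[k])
        prev <- ins_at[k] + 1L
      }
      if (prev <= length(chars)) out <- c(out, chars[prev:length(chars)])
      chars <- out
    }
  }
  paste(chars, collapse = "")
}

# split a transcript of length n into k exon lengths, each >= min_exon.
# forbidden_span (0-based half-open) marks a planted conserved block whose
# interior must stay inside one exon: conserved family blocks are modelled
# as exonic, so no isoform structure can fragment them.
split_exons <- function(n, k, min_exon = 50L, forbidden_span = NULL) {
  k <- max(1L, min(k, n %/% min_exon))
  if (k == 1L) return(n)
  allowed <- seq(min_exon, n - min_exon)
  if (!is.null(forbidden_span))
    allowed <- allowed[allowed <= forbidden_span[1L] |
                         allowed >= forbidden_span[2L]]
  while (k > 1L) {
    if (length(allowed) >= k - 1L) {
      for (attempt in 1:20) {
        cuts <- sort(allowed[sample.int(length(allowed), k - 1L)])
        lens <- diff(c(0L, cuts, n))
        if (all(lens >= min_exon)) return(lens)
      }
    }
    k <- k - 1L
  }
  n
}

#' Generate a synthetic annotated genome with planted structure
#'
#' Builds a toy genome and annotation in which the ground truth of every
#' downstream pipeline stage is known: lncRNA gene families sharing
#' mutated copies of a common block, two-locus pairs, background loci,
#' TE-fragment decoy families, ribosomal loci (plus one lncRNA carrying an
#' rRNA fragment), coding genes (some sharing a block with a family
#' lncRNA), and cross-species transcripts outside the annotation. Loci are
#' laid out on two chromosomes with introns and both strands; multi-isoform
#' loci carry skipped-exon and retained-intron variants. All output is a
#' deterministic function of `cfg$seed`.
#'
#' @param cfg a [synthesis_config()].
#' @param dir optional directory; when given, writes `genome.fasta`,
#'   `annotation.gff3`, `te_library.fasta`, `cross_species.fasta`,
#'   `accession2taxid.tsv`, `taxid_names.tsv` and `truth.tsv` there.
#' @return a list of class `synthetic_genome`: `genome` (named chromosome
#'   sequences), `catalog` (the full `locus_catalog`), `te_library` and
#'   `cross_species` (named sequence vectors), `taxa` (a `taxon_map`
#'   covering annotation and cross-species transcripts), `truth`
#'   (data.frame: `locus_id`, `role`, `group_id`, `block_length`), and
#'   `paths` when written.
#' @export
generate_genome <- function(cfg = synthesis_config(), dir = NULL) {
  set.seed(cfg$seed)
  gc <- cfg$gc

  te_library <- stats::setNames(
    vapply(seq_len(max(3L, cfg$n_te_decoy_families)), function(i)
      random_seq(sample(800:1200, 1L), gc), ""),
    sprintf("TE%04d", seq_len(max(3L, cfg$n_te_decoy_families))))

  plans <- list()   # one element per locus: sequence, biotype, role, group
  add_plan <- function(seq, biotype, role, group = NA_character_,
                       block_length = NA_integer_, block_span = NULL) {
    if (is.list(seq)) { block_span <- seq$span; seq <- seq$seq }
    plans[[length(plans) + 1L]] <<- list(seq = seq, biotype = biotype,
                                         role = role, group = group,
                                         block_length = block_length,
                                         block_span = block_span)
  }
  rand_len <- function(min_extra = 0L) {
    lo <- max(cfg$locus_length_range[1L], min_extra + 150L)
    hi <- max(cfg$locus_length_range[2L], lo + 1L)
    sample(lo:hi, 1L)
  }
  # returns the assembled sequence and the 0-based half-open block span, so
  # exon layout can keep the planted block inside a single exon
  embed_block <- function(block, total_len) {
    flank <- total_len - nchar(block)
    left <- sample(0:flank, 1L)
    list(seq = paste0(random_seq(left, gc), block,
                      random_seq(flank - left, gc)),
         span = c(left, left + nchar(block)))
  }

  # planted families
  fam_blocks <- list()
  block_lens <- rep_len(cfg$shared_block_lengths, length(cfg$family_sizes))
  for (fi in seq_along(cfg$family_sizes)) {
    bl <- block_lens[fi]
    block <- random_seq(bl, gc)
    fam_blocks[[fi]] <- block
    gid <- sprintf("TFAM%02d", fi)
    for (m in seq_len(cfg$family_sizes[fi])) {
      copy <- mutate_seq(block, cfg$per_base_substitution_rate,
                         cfg$indel_rate)
      add_plan(embed_block(copy, rand_len(nchar(copy))), "lncRNA",
               "family", gid, bl)
    }
  }
  # two-locus pairs
  for (pi in seq_len(cfg$n_pair_groups)) {
    bl <- sample(cfg$shared_block_lengths, 1L)
    block <- random_seq(bl, gc)
    gid <- sprintf("PAIR%02d", pi)
    for (m in 1:2) {
      copy <- mutate_seq(block, cfg$per_base_substitution_rate,
                         cfg$indel_rate)
      add_plan(embed_block(copy, rand_len(nchar(copy))), "lncRNA",
               "pair", gid, bl)
    }
  }
  # TE decoy families
  for (di in seq_len(cfg$n_te_decoy_families)) {
    te <- te_library[[((di - 1L) %% length(te_library)) + 1L]]
    bl <- min(500L, nchar(te))
    start <- sample(seq_len(nchar(te) - bl + 1L), 1L)
    frag <- substring(te, start, start + bl - 1L)
    gid <- sprintf("DFAM%02d", di)
    for (m in seq_len(cfg$te_decoy_family_size)) {
      copy <- mutate_seq(frag, cfg$per_base_substitution_rate,
                         cfg$indel_rate)
      add_plan(embed_block(copy, rand_len(nchar(copy))), "lncRNA",
               "te_decoy", gid, bl)
    }
  }
  # background lncRNAs
  n_bg <- cfg$n_background_lnc
  rrna_seqs <- character(0)
  if (cfg$n_rrna_loci > 0L) {
    rrna_seqs <- vapply(seq_len(cfg$n_rrna_loci), function(i)
      random_seq(sample(1200:1800, 1L), gc), "")
  }
  for (bi in seq_len(n_bg)) {
    if (bi == 1L && length(rrna_seqs) > 0L) {
      # one background lncRNA carries an rRNA fragment: its matches must
      # be removed by the rRNA filter, not clustered
      frag <- substring(rrna_seqs[1L], 1L, 400L)
      add_plan(embed_block(mutate_seq(frag, cfg$per_base_substitution_rate),
                           rand_len(400L)),
               "lncRNA", "background_rrna_block")
    } else {
      add_plan(random_seq(rand_len(), gc), "lncRNA", "background")
    }
  }
  # rRNA loci
  for (ri in seq_along(rrna_seqs))
    add_plan(rrna_seqs[ri], "rRNA", "rrna")
  # coding genes; some embed a copy of a family block
  for (ci in seq_len(cfg$n_coding_genes)) {
    if (ci <= cfg$n_coding_genes_with_shared_region &&
        length(fam_blocks) > 0L) {
      src <- ((ci - 1L) %% length(fam_blocks)) + 1L
      copy <- mutate_seq(fam_blocks[[src]], cfg$per_base_substitution_rate)
      add_plan(embed_block(copy, rand_len(nchar(copy))), "mRNA",
               "coding_shared", sprintf("TFAM%02d", src),
               nchar(fam_blocks[[src]]))
    } else {
      add_plan(random_seq(rand_len(), gc), "mRNA", "coding")
    }
  }

  # genomic layout and isoforms
  n_loci <- length(plans)
  chroms <- c("chr1", "chr2")
  chrom_parts <- stats::setNames(vector("list", length(chroms)), chroms)
  chrom_len <- stats::setNames(integer(length(chroms)), chroms)
  tx_rows <- list(); seqs <- character(0); spans <- list()
  truth_rows <- list()
  for (li in seq_len(n_loci)) {
    p <- plans[[li]]
    locus_id <- sprintf("SYNLOC%04d", li)
    chrom <- chroms[((li - 1L) %% length(chroms)) + 1L]
    strand <- if (stats::runif(1) < 0.3) "-" else "+"
    n <- nchar(p$seq)
    k <- if (p$biotype == "rRNA") 1L else sample(1:4, 1L)
    exon_lens <- split_exons(n, k, forbidden_span = p$block_span)
    k <- length(exon_lens)
    intron_lens <- if (k > 1L) sample(80:250, k - 1L, replace = TRUE)
    else integer(0)
    # segment in coding orientation
    seg_parts <- character(0)
    rel_spans <- matrix(0L, nrow = k, ncol = 2L)
    pos <- 0L
    tx_cut <- cumsum(c(0L, exon_lens))
    for (e in seq_len(k)) {
      exon_seq <- substring(p$seq, tx_cut[e] + 1L, tx_cut[e + 1L])
      seg_parts <- c(seg_parts, exon_seq)
      rel_spans[e, ] <- c(pos, pos + exon_lens[e])
      pos <- pos + exon_lens[e]
      if (e < k) {
        intr <- random_seq(intron_lens[e], gc)
        seg_parts <- c(seg_parts, intr)
        pos <- pos + intron_lens[e]
      }
    }
    segment <- paste(seg_parts, collapse = "")
    seg_len <- nchar(segment)
    if (strand == "-") {
      segment <- revcomp(segment)
      rel_spans <- cbind(seg_len - rel_spans[, 2L], seg_len - rel_spans[, 1L])
      rel_spans <- rel_spans[order(rel_spans[, 1L]), , drop = FALSE]
    }
    spacer <- random_seq(sample(100:300, 1L), gc)
    offset <- chrom_len[[chrom]] + nchar(spacer)
    chrom_parts[[chrom]] <- c(chrom_parts[[chrom]], spacer, segment)
    chrom_len[[chrom]] <- offset + seg_len
    abs_spans <- rel_spans + offset

    # isoform structures on the coding-orientation exon list
    iso_defs <- list(primary = seq_len(k))
    if (p$biotype == "lncRNA" && cfg$max_isoforms_per_locus > 1L) {
      n_iso <- sample(seq_len(cfg$max_isoforms_per_locus), 1L)
      if (n_iso >= 2L && k >= 3L)
        iso_defs$skip <- setdiff(seq_len(k), 2L)      # skipped exon
      if (length(iso_defs) < n_iso && k >= 2L)
        iso_defs$ri <- "retain1"                      # retained intron
    }
    iso_names <- names(iso_defs)
    for (ii in seq_along(iso_defs)) {
      tid <- sprintf("SYNT%04d.%d", li, ii)
      if (identical(iso_defs[[ii]], "retain1")) {
        # merge the two exons flanking intron 1 (coding orientation)
        keep <- seq_len(k)
        sp_cod <- rel_spans
        if (strand == "-") {
          # recover coding-orientation order: descending genomic
          sp_cod <- rel_spans[order(-rel_spans[, 1L]), , drop = FALSE]
          merged <- rbind(c(sp_cod[2L, 1L], sp_cod[1L, 2L]))
          sp <- rbind(merged,
                      if (k > 2L) sp_cod[3:k, , drop = FALSE])
        } else {
          merged <- rbind(c(sp_cod[1L, 1L], sp_cod[2L, 2L]))
          sp <- rbind(merged,
                      if (k > 2L) sp_cod[3:k, , drop = FALSE])
        }
        sp <- sp[order(sp[, 1L]), , drop = FALSE]
      } else {
        idx <- iso_defs[[ii]]
        sp_cod <- if (strand == "-")
          rel_spans[order(-rel_spans[, 1L]), , drop = FALSE] else rel_spans
        sp <- sp_cod[idx, , drop = FALSE]
        sp <- sp[order(sp[, 1L]), , drop = FALSE]
      }
      sp_abs <- sp + offset
      pieces <- substring(segment, sp[, 1L] + 1L, sp[, 2L])
      seq <- paste(pieces, collapse = "")
      if (strand == "-") seq <- revcomp(seq)
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        locus_id = locus_id, transcript_id = tid, biotype = p$biotype,
        exon_count = nrow(sp_abs), length_nt = nchar(seq),
        chrom = chrom, strand = strand, stringsAsFactors = FALSE)
      seqs[tid] <- seq
      spans[[tid]] <- sp_abs
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      locus_id = locus_id, role = p$role,
      group_id = if (is.na(p$group)) NA_character_ else p$group,
      block_length = p$block_length, stringsAsFactors = FALSE)
  }

  genome <- vapply(chrom_parts, paste, "", collapse = "")
  tx <- do.call(rbind, tx_rows)
  catalog <- locus_catalog(tx, seqs, spans,
                           provenance = sprintf("synthetic(seed=%d)",
                                                cfg$seed))
  truth <- do.call(rbind, truth_rows)

  # cross-species transcripts sharing a block with family 1
  cross <- character(0)
  if (cfg$n_cross_species > 0L && length(fam_blocks) > 0L) {
    for (xi in seq_len(cfg$n_cross_species)) {
      copy <- mutate_seq(fam_blocks[[1L]], cfg$per_base_substitution_rate)
      cross[sprintf("XSP%04d", xi)] <-
        embed_block(copy, rand_len(nchar(copy)))$seq
      truth <- rbind(truth, data.frame(
        locus_id = sprintf("XSP%04d", xi), role = "cross_species",
        group_id = "TFAM01", block_length = nchar(fam_blocks[[1L]]),
        stringsAsFactors = FALSE))
    }
  }

  taxa <- taxon_map(
    c(tx$transcript_id, names(cross)),
    c(rep(4530L, nrow(tx)), rep(4565L, length(cross))),
    c(rep(cfg$taxon_of_interest, nrow(tx)),
      rep("Triticum aestivum", length(cross))))

  out <- structure(list(genome = genome, catalog = catalog,
                        te_library = te_library, cross_species = cross,
                        taxa = taxa, truth = truth, config = cfg),
                   class = "synthetic_genome")
  if (!is.null(dir)) out$paths <- write_synthetic_genome(out, dir)
  out
}

write_synthetic_genome <- function(sg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- list(genome = file.path(dir, "genome.fasta"),
            annotation = file.path(dir, "annotation.gff3"),
            te_library = file.path(dir, "te_library.fasta"),
            cross_species = file.path(dir, "cross_species.fasta"),
            accession2taxid = file.path(dir, "accession2taxid.tsv"),
            taxid_names = file.path(dir, "taxid_names.tsv"),
            truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sg$genome), p$genome)
  write_annotation_gff3(sg$catalog, p$annotation)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sg$te_library),
                              p$te_library)
  if (length(sg$cross_species) > 0L)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sg$cross_species),
                                p$cross_species)
  utils::write.table(
    data.frame(accession = sub("\\..*$", "", sg$taxa$accession),
               accession.version = sg$taxa$accession,
               taxid = sg$taxa$taxid,
               gi = seq_len(nrow(sg$taxa))),
    p$accession2taxid, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    unique(data.frame(taxid = sg$taxa$taxid, species = sg$taxa$species)),
    p$taxid_names, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sg$truth, p$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome (seed", x$config$seed, "):",
      sum(nchar(x$genome)), "bp on", length(x$genome), "chromosome(s)\n")
  print(x$catalog)
  cat("  planted roles:",
      paste(names(table(x$truth$role)), table(x$truth$role),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Generate differential-splicing event tables with planted significance
#'
#' Emits per-type tables in the rMATS junction-count dialect in which a
#' known subset of rows passes the significance filter (p-value below
#' 0.005 and FDR below 0.05) and all remaining rows fail at least one
#' threshold. A configurable number of significant rows per type is
#' assigned to lncRNA loci. Default planted counts echo a
#' milk-seed-vs-mature-seed comparison: 217 SE, 247 RI, 85 A5SS and 131
#' A3SS significant events, of which 17/55/11/23 lie on lncRNA loci.
#'
#' @param seed integer RNG seed.
#' @param n_rows named integer vector of total rows per event type.
#' @param planted named integer vector of significant rows per type.
#' @param lnc_planted named integer vector (same names) of significant
#'   rows assigned to lncRNA loci; must not exceed `planted`.
#' @param lnc_loci character vector of lncRNA locus ids to draw from (a
#'   synthetic pool is invented if `NULL`).
#' @param locus_pool character vector of non-lncRNA locus ids for all
#'   other rows (invented if `NULL`).
#' @param required_loci loci guaranteed to appear among the significant
#'   rows (cycled over types); used to plant intersection cores across
#'   comparisons.
#' @param include_mxe also emit an MXE table (parsed downstream but
#'   excluded from the standard report).
#' @param dir optional directory to write `<type>.MATS.JC.txt` tables to.
#' @return a list: `records` (as from [read_events()]), `truth`
#'   (data.frame with `event_id`, `event_type`, `locus_id`, `significant`,
#'   `on_lncrna`), `paths` when written.
#' @export
generate_event_tables <- function(seed = 1L,
                                  n_rows = c(SE = 300L, RI = 350L,
                                             A5SS = 150L, A3SS = 200L),
                                  planted = c(SE = 217L, RI = 247L,
                                              A5SS = 85L, A3SS = 131L),
                                  lnc_planted = c(SE = 17L, RI = 55L,
                                                  A5SS = 11L, A3SS = 23L),
                                  lnc_loci = NULL, locus_pool = NULL,
                                  required_loci = NULL,
                                  include_mxe = FALSE, dir = NULL) {
  set.seed(seed)
  types <- names(n_rows)
  if (is.null(types)) stop("n_rows must be named by event type")
  planted <- planted[types]; planted[is.na(planted)] <- 0L
  lnc_planted <- lnc_planted[types]; lnc_planted[is.na(lnc_planted)] <- 0L
  if (any(planted > n_rows))
    stop("configuration error: planted significant rows exceed table rows")
  if (any(lnc_planted > planted))
    stop("configuration error: lncRNA significant rows exceed planted rows")
  if (is.null(lnc_loci))
    lnc_loci <- sprintf("EVLNC%04d", seq_len(max(200L, sum(lnc_planted))))
  if (is.null(locus_pool))
    locus_pool <- sprintf("EVLOC%04d", seq_len(2000L))
  if (include_mxe && !"MXE" %in% types) {
    n_rows <- c(n_rows, MXE = 50L)
    planted <- c(planted, MXE = 0L)
    lnc_planted <- c(lnc_planted, MXE = 0L)
    types <- names(n_rows)
  }
  req <- unique(required_loci)
  recs <- list(); truths <- list()
  for (ty in types) {
    n <- n_rows[[ty]]; n_sig <- planted[[ty]]; n_lnc <- lnc_planted[[ty]]
    sig <- c(rep(TRUE, n_sig), rep(FALSE, n - n_sig))
    p <- numeric(n); fdr <- numeric(n)
    p[sig] <- stats::runif(n_sig, 0, 0.00499)
    fdr[sig] <- stats::runif(n_sig, 0, 0.0499)
    fail_mode <- sample(1:3, n - n_sig, replace = TRUE)
    p[!sig] <- ifelse(fail_mode == 2L, stats::runif(n - n_sig, 0, 0.0049),
                      stats::runif(n - n_sig, 0.01, 1))
    fdr[!sig] <- ifelse(fail_mode == 1L, stats::runif(n - n_sig, 0, 0.049),
                        stats::runif(n - n_sig, 0.06, 1))
    loci <- character(n)
    # significant rows: lncRNA loci first, then required loci, then pool
    sig_loci <- character(n_sig)
    if (n_sig > 0L) {
      lnc_pick <- sample(lnc_loci, n_lnc)
      n_req_here <- min(length(req), n_sig - n_lnc)
      req_pick <- if (n_req_here > 0L) req[seq_len(n_req_here)] else character(0)
      rest <- n_sig - n_lnc - length(req_pick)
      pool_pick <- sample(setdiff(locus_pool, req), rest, replace = FALSE)
      sig_loci <- sample(c(lnc_pick, req_pick, pool_pick))
    }
    loci[sig] <- sig_loci
    loci[!sig] <- sample(setdiff(locus_pool, req), n - n_sig, replace = TRUE)
    inc1 <- round(stats::runif(n), 3)
    diffv <- round(stats::runif(n, -0.8, 0.8), 3)
    inc2 <- pmin(1, pmax(0, inc1 - diffv))
    recs[[ty]] <- data.frame(
      event_id = paste0(ty, ":", seq_len(n)), event_type = ty,
      locus_id = loci, chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      p_value = p, fdr = fdr, inclusion_difference = diffv,
      inc_level_1 = vapply(inc1, function(x) paste(
        round(pmin(1, pmax(0, x + stats::rnorm(3, 0, 0.02))), 3),
        collapse = ","), ""),
      inc_level_2 = vapply(inc2, function(x) paste(
        round(pmin(1, pmax(0, x + stats::rnorm(3, 0, 0.02))), 3),
        collapse = ","), ""),
      stringsAsFactors = FALSE)
    truths[[ty]] <- data.frame(
      event_id = recs[[ty]]$event_id, event_type = ty, locus_id = loci,
      significant = sig, on_lncrna = loci %in% lnc_loci,
      stringsAsFactors = FALSE)
    # required loci not yet placed are carried to the next type
    if (n_sig > 0L) req <- setdiff(req, loci[sig])
  }
  if (length(req) > 0L)
    warning(length(req), " required locus/loci could not be planted; ",
            "increase planted counts")
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  out <- list(records = records, truth = do.call(rbind, truths))
  if (!is.null(dir)) out$paths <- write_events(records, dir)
  out
}
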