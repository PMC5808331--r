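EVENT_TYPES <- c("SE", "RI", "A5SS", "A3SS", "MXE")
REPORTED_EVENT_TYPES <- c("SE", "RI", "A5SS", "A3SS")

infer_event_type <- function(path) {
  base <- basename(path)
  hit <- regmatches(base, regexpr("(SE|RI|A5SS|A3SS|MXE)", base))
  if (length(hit) == 0L)
    stop("cannot infer event type from file name '", base,
         "'; supply a named vector of paths")
  hit
}

#' Read differential-splicing event tables
#'
#' Ingests tab-separated event tables in the rMATS junction-count dialect
#' (`*.MATS.JC.txt` / `JCEC.txt`). Each file holds one event type; the
#' type is taken from the names of `paths` if present, otherwise inferred
#' from the file name. Required columns are `GeneID`, `PValue`, `FDR` and
#' `IncLevelDifference`; `ID`, `chr`, `strand`, `IncLevel1` and
#' `IncLevel2` are carried when present. `NA` statistics are tolerated and
#' simply fail every significance threshold. Gene ids are stripped of
#' surrounding quotes so they live in the annotation's locus namespace.
#'
#' @param paths character vector of file paths, optionally named by event
#'   type (`SE`, `RI`, `A5SS`, `A3SS`, `MXE`).
#' @return a data.frame of splice event records with columns `event_id`,
#'   `event_type`, `locus_id`, `chrom`, `strand`, `p_value`, `fdr`,
#'   `inclusion_difference`, `inc_level_1`, `inc_level_2` (the last two as
#'   comma-separated replicate strings).
#' @export
read_events <- function(paths) {
  types <- names(paths)
  if (is.null(types)) types <- unname(vapply(paths, infer_event_type, ""))
  bad <- setdiff(types, EVENT_TYPES)
  if (length(bad) > 0L)
    stop("unknown event type(s): ", paste(bad, collapse = ", "))
  out <- lapply(seq_along(paths), function(i) {
    tab <- utils::read.table(paths[i], sep = "\t", header = TRUE,
                             quote = "\"", na.strings = c("NA", ""),
                             row.names = NULL, stringsAsFactors = FALSE,
                             check.names = FALSE)
    req <- c("GeneID", "PValue", "FDR", "IncLevelDifference")
    missing_cols <- setdiff(req, names(tab))
    if (length(missing_cols) > 0L)
      stop("format error in '", paths[i], "': missing required column ",
           missing_cols[1L])
    grab <- function(col, default) if (col %in% names(tab)) tab[[col]] else default
    data.frame(
      event_id = paste0(types[i], ":",
                        grab("ID", seq_len(nrow(tab)))),
      event_type = types[i],
      locus_id = gsub('^"|"$', "", as.character(tab$GeneID)),
      chrom = as.character(grab("chr", ".")),
      strand = as.character(grab("strand", "+")),
      p_value = as.numeric(tab$PValue),
      fdr = as.numeric(tab$FDR),
      inclusion_difference = as.numeric(tab$IncLevelDifference),
      inc_level_1 = as.character(grab("IncLevel1", NA_character_)),
      inc_level_2 = as.character(grab("IncLevel2", NA_character_)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write splice event records back to per-type tables
#'
#' Inverse of [read_events()]: one rMATS-dialect table per event type
#' present, written as `<type>.MATS.JC.txt` under `dir`.
#'
#' @param records splice event records.
#' @param dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
write_events <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ty in unique(records$event_type)) {
    sub <- records[records$event_type == ty, , drop = FALSE]
    tab <- data.frame(
      ID = sub("^[^:]*:", "", sub$event_id),
      GeneID = sub$locus_id, geneSymbol = sub$locus_id,
      chr = sub$chrom, strand = sub$strand,
      PValue = sub$p_value, FDR = sub$fdr,
      IncLevel1 = sub$inc_level_1, IncLevel2 = sub$inc_level_2,
      IncLevelDifference = sub$inclusion_difference,
      stringsAsFactors = FALSE)
    p <- file.path(dir, paste0(ty, ".MATS.JC.txt"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[ty] <- p
  }
  invisible(paths)
}

#' Filter events for statistical significance
#'
#' Retains events with `p_value < p_max` and `fdr < fdr_max` — strict
#' inequalities by default, so an event at exactly the threshold is
#' dropped. Records with missing statistics fail every threshold. The
#' filter is idempotent and monotone in both thresholds.
#'
#' @param records splice event records from [read_events()].
#' @param p_max p-value threshold (default 0.005).
#' @param fdr_max FDR threshold (default 0.05).
#' @param strict use strict `<` (default); `FALSE` switches to `<=`.
#' @return the significant subset, with per-type counts available via
#'   [event_type_counts()].
#' @export
filter_significant <- function(records, p_max = 0.005, fdr_max = 0.05,
                               strict = TRUE) {
  stopifnot(p_max > 0, p_max <= 1, fdr_max > 0, fdr_max <= 1)
  keep <- if (strict)
    records$p_value < p_max & records$fdr < fdr_max
  else
    records$p_value <= p_max & records$fdr <= fdr_max
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count events per type
#'
#' @param records splice event records.
#' @param types event types to tally (default the four reported classes;
#'   MXE is parsed but excluded from the standard report).
#' @return named integer vector of per-type event counts.
#' @export
event_type_counts <- function(records, types = REPORTED_EVENT_TYPES) {
  vapply(types, function(ty) sum(records$event_type == ty), 0L)
}

#' Summarise one comparison's significant events
#'
#' @param records significant event records of one comparison.
#' @param label comparison label, e.g. `"milkseed_vs_mature"`.
#' @param lnc_catalog optional lncRNA-only `locus_catalog` used to mark
#'   the lncRNA subset.
#' @return a list of class `comparison_result`: `label`, `type_counts`
#'   (per-event), `locus_type_counts` (per-locus after deduplication),
#'   `loci` (significant locus set), `lnc_loci`.
#' @export
comparison_result <- function(records, label, lnc_catalog = NULL) {
  loci <- unique(records$locus_id)
  lnc <- if (is.null(lnc_catalog)) character(0)
  else intersect(loci, unique(lnc_catalog$transcripts$locus_id))
  per_locus <- vapply(REPORTED_EVENT_TYPES, function(ty)
    length(unique(records$locus_id[records$event_type == ty])), 0L)
  structure(list(label = label,
                 type_counts = event_type_counts(records),
                 locus_type_counts = per_locus,
                 loci = loci, lnc_loci = lnc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("comparison", x$label, "-", length(x$loci), "significant loci\n")
  cat("  events:",
      paste(names(x$type_counts), x$type_counts, sep = "=", collapse = " "),
      "\n")
  if (length(x$lnc_loci) > 0L)
    cat("  lncRNA loci:", length(x$lnc_loci), "\n")
  invisible(x)
}

#' Intersect significant locus sets across comparisons
#'
#' Builds the locus-by-comparison membership matrix and the counts of
#' every region of the intersection diagram (as a Venn/UpSet layout
#' would show them): each locus contributes to exactly one region, keyed
#' by the comparisons that contain it. Loci are deduplicated across event
#' types first, so a locus with both an exon-skipping and an
#' intron-retention event counts once.
#'
#' @param results list of two or more `comparison_result` objects (or
#'   plain character vectors of loci, in which case list names label
#'   them).
#' @return a list of class `comparison_intersection`: `membership`
#'   (logical matrix, loci x comparisons), `region_counts` (named integer
#'   vector keyed like `"a&b"`), `shared_by_all` (character vector of loci
#'   present in every comparison).
#' @export
intersect_comparisons <- function(results) {
  if (length(results) < 2L) stop("need at least two comparisons")
  sets <- lapply(results, function(r)
    if (inherits(r, "comparison_result")) r$loci else as.character(r))
  labels <- vapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (inherits(r, "comparison_result")) r$label
    else if (!is.null(names(results)) && nzchar(names(results)[i]))
      names(results)[i]
    else paste0("set", i)
  }, "")
  all_loci <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) all_loci %in% s,
                       logical(length(all_loci)))
  if (length(all_loci) == 1L) membership <- matrix(membership, nrow = 1L)
  dimnames(membership) <- list(all_loci, labels)
  pattern <- apply(membership, 1L, function(row)
    paste(labels[row], collapse = "&"))
  region_counts <- integer(0)
  # every non-empty region of the diagram, including empty intersections
  for (sz in seq_along(labels)) {
    combos <- utils::combn(labels, sz, paste, collapse = "&")
    region_counts[combos] <- vapply(combos, function(cb)
      sum(pattern == cb), 0L)
  }
  structure(list(membership = membership,
                 region_counts = region_counts,
                 shared_by_all = all_loci[rowSums(membership) ==
                                            length(labels)]),
            class = "comparison_intersection")
}

#' @export
print.comparison_intersection <- function(x, ...) {
  cat("comparison_intersection over", ncol(x$membership), "comparisons,",
      nrow(x$membership), "loci\n")
  for (nm in names(x$region_counts))
    cat(sprintf("  %-40s %d\n", nm, x$region_counts[[nm]]))
  cat("  shared by all:", length(x$shared_by_all), "loci\n")
  invisible(x)
}

#' Write the locus-by-comparison membership matrix
#'
#' @param intersection a `comparison_intersection`.
#' @param path output TSV path (UpSet-style 0/1 matrix with a locus
#'   column).
#' @return `path`, invisibly.
#' @export
write_membership_tsv <- function(intersection, path) {
  m <- intersection$membership
  tab <- data.frame(locus_id = rownames(m),
                    apply(m, 2L, as.integer),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Count significant events on lncRNA loci
#'
#' @param records significant splice event records.
#' @param lnc_catalog a `locus_catalog` restricted to lncRNA biotype
#'   (enforced here).
#' @param types event types to tally.
#' @return named integer vector of per-type counts of events whose locus
#'   is an annotated lncRNA.
#' @export
flag_lncrna_events <- function(records, lnc_catalog,
                               types = REPORTED_EVENT_TYPES) {
  tx <- lnc_catalog$transcripts
  lnc_loci <- unique(tx$locus_id[tx$biotype == "lncRNA"])
  on_lnc <- records[records$locus_id %in% lnc_loci, , drop = FALSE]
  event_type_counts(on_lnc, types)
}
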