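#' Run the full lncRNA gene-family discovery pipeline
#'
#' Convenience wrapper over the individual stages: select one
#' representative isoform per lncRNA locus, align all representatives
#' against a target transcript set (default: the whole catalog plus any
#' extra sequences, mimicking a search of an RNA database), apply the
#' filter cascade, classify the surviving matches, build the locus
#' homology graph from the same-species non-coding matches, extract gene
#' families and screen them against a transposable-element library.
#'
#' @param catalog a `locus_catalog` containing at least the lncRNA loci
#'   (other biotypes present are used as alignment targets and for
#'   rRNA/coding classification).
#' @param te_library named character vector of TE sequences (or `NULL` to
#'   skip the screen).
#' @param taxa optional `taxon_map` for species classification.
#' @param extra_targets optional named character vector of additional
#'   target sequences (for example cross-species transcripts).
#' @param isoform_mode isoform selection mode for queries
#'   (see [select_isoform()]).
#' @param align_cfg [align_params()].
#' @param filter_cfg [filter_config()].
#' @param min_family_size minimum family size (default 3).
#' @return a list of class `lncfam_result`: `representatives` (query
#'   catalog), `matches` (raw), `filtered`, `classified`, `families`
#'   (a `family_set` after TE screening), `params`.
#' @export
discover_families <- function(catalog, te_library = NULL, taxa = NULL,
                              extra_targets = NULL,
                              isoform_mode = "longest",
                              align_cfg = align_params(),
                              filter_cfg = filter_config(),
                              min_family_size = 3L) {
  reps_all <- select_isoform(catalog, isoform_mode)
  lnc <- filter_biotype(reps_all, "lncRNA")
  if (nrow(lnc$transcripts) == 0L) stop("no lncRNA loci in catalog")
  targets <- as_sequence_set(reps_all, "catalog")$seqs
  if (!is.null(extra_targets)) targets <- c(targets, extra_targets)
  target_locus <- stats::setNames(
    reps_all$transcripts$locus_id, reps_all$transcripts$transcript_id)
  matches <- align_all(lnc, stats::setNames(unname(targets), names(targets)),
                       align_cfg)
  # restore locus ids for catalog targets (extra targets map to themselves)
  hit <- match(matches$subject_id, names(target_locus))
  matches$subject_locus[!is.na(hit)] <-
    unname(target_locus[hit[!is.na(hit)]])
  filtered <- filter_matches(matches, filter_cfg, reps_all)
  classified <- classify_matches(filtered, reps_all, taxa, filter_cfg)
  graph <- build_family_graph(classified$same_species_ncrna)
  fams <- extract_families(graph, min_family_size)
  if (!is.null(te_library) && length(te_library) > 0L)
    fams <- screen_te(fams, te_library, reps_all, align_cfg,
                      min_match_length = filter_cfg$min_match_length)
  structure(list(representatives = reps_all, matches = matches,
                 filtered = filtered, classified = classified,
                 families = fams,
                 params = list(align = align_cfg, filter = filter_cfg,
                               min_family_size = min_family_size)),
            class = "lncfam_result")
}

#' @export
print.lncfam_result <- function(x, ...) {
  cat("lncfam_result\n")
  cat("  queries:", n_loci(filter_biotype(x$representatives, "lncRNA")),
      "lncRNA loci;", nrow(x$matches), "raw matches,",
      nrow(x$filtered), "after filtering\n")
  print(x$families)
  invisible(x)
}

#' Recovered family partition as a label vector
#'
#' Labels every locus of `loci` with its recovered family id, or
#' `"singleton"` if it is in no (unflagged) family. Useful for comparing a
#' run against a planted truth with [partition_rand_index()].
#'
#' @param family_set a `family_set`.
#' @param loci character vector of locus ids to label.
#' @param include_flagged also label members of TE-flagged families.
#' @return named character vector of labels.
#' @export
family_labels <- function(family_set, loci, include_flagged = FALSE) {
  labels <- stats::setNames(rep("singleton", length(loci)), loci)
  for (f in family_set$families) {
    if (!include_flagged && isTRUE(f$te_flagged)) next
    inside <- intersect(f$members, loci)
    labels[inside] <- f$family_id
  }
  labels
}
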