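#' Build the locus-level homology graph
#'
#' Nodes are loci that appear in at least one qualifying match; one
#' undirected edge joins each unordered locus pair regardless of how many
#' alignments (or reciprocal query/subject orientations) connect it. Each
#' edge is annotated with the best supporting alignment: largest aligned
#' length, ties broken by identity. The per-locus span of that best
#' alignment is kept on the edge so the TE screen can ask whether a
#' transposon hit covers the family-supporting region.
#'
#' @param nc_matches same-species non-coding matches that already passed
#'   the filter cascade (length, rRNA, self-locus).
#' @return an undirected `igraph` graph with edge attributes
#'   `aligned_length`, `percent_identity`, `span_a_start`, `span_a_end`,
#'   `span_b_start`, `span_b_end` (spans on the endpoint loci, sorted so
#'   endpoint `a` is the lexicographically smaller locus).
#' @export
build_family_graph <- function(nc_matches) {
  if (nrow(nc_matches) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  a <- pmin(nc_matches$query_locus, nc_matches$subject_locus)
  b <- pmax(nc_matches$query_locus, nc_matches$subject_locus)
  q_is_a <- nc_matches$query_locus == a
  edges <- data.frame(
    a = a, b = b,
    aligned_length = nc_matches$aligned_length,
    percent_identity = nc_matches$percent_identity,
    span_a_start = ifelse(q_is_a, nc_matches$q_start, nc_matches$s_start),
    span_a_end = ifelse(q_is_a, nc_matches$q_end, nc_matches$s_end),
    span_b_start = ifelse(q_is_a, nc_matches$s_start, nc_matches$q_start),
    span_b_end = ifelse(q_is_a, nc_matches$s_end, nc_matches$q_end),
    stringsAsFactors = FALSE)
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  if (nrow(edges) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  # keep the best alignment per unordered pair
  edges <- edges[order(edges$a, edges$b, -edges$aligned_length,
                       -edges$percent_identity), , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("a", "b")]), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Extract gene families from the homology graph
#'
#' A gene family is a connected component of at least `min_size` loci
#' (default three, the working definition of a family: three or more
#' lncRNAs sharing significant matches). Alongside the family list the
#' function reports the family-size spectrum and the degree tallies: the
#' number of loci that matched exactly one other locus and exactly two
#' other loci (distinct partners), computed on the full graph before any
#' size cut.
#'
#' @param graph output of [build_family_graph()].
#' @param min_size minimum family size; must be at least 2.
#' @return a list of class `family_set` with elements `families` (list of
#'   `gene_family` records: `family_id`, `members`, `edge_count`,
#'   `te_flagged`, `te_reason`, `representative_block`), `spectrum`
#'   (a `family_spectrum`), and `graph`.
#' @export
extract_families <- function(graph, min_size = 3L) {
  if (min_size < 2L) stop("configuration error: min_size must be >= 2")
  comp <- igraph::components(graph)
  deg <- igraph::degree(graph)
  families <- list()
  if (comp$no > 0L) {
    memb <- split(names(comp$membership), comp$membership)
    big <- memb[lengths(memb) >= min_size]
    # stable order: by decreasing size, then first member id
    if (length(big) > 0L) {
      ord <- order(-lengths(big),
                   vapply(big, function(m) sort(m)[1L], ""))
      big <- big[ord]
      families <- lapply(seq_along(big), function(i) {
        members <- sort(big[[i]])
        sub <- igraph::induced_subgraph(graph, members)
        ea <- igraph::edge_attr(sub)
        best <- which.max(ea$aligned_length)
        ends <- igraph::ends(sub, igraph::E(sub)[best])
        structure(list(
          family_id = sprintf("FAM%03d", i),
          members = members,
          edge_count = igraph::ecount(sub),
          te_flagged = FALSE,
          te_reason = NA_character_,
          representative_block = list(
            locus = ends[1L, 1L],
            span = c(ea$span_a_start[best], ea$span_a_end[best]),
            aligned_length = ea$aligned_length[best])),
          class = "gene_family")
      })
    }
  }
  out <- structure(list(families = families,
                        spectrum = family_spectrum(families, deg),
                        graph = graph),
                   class = "family_set")
  out
}

family_spectrum <- function(families, degrees) {
  sizes <- vapply(families, function(f) length(f$members), 0L)
  active <- vapply(families, function(f) !isTRUE(f$te_flagged), TRUE)
  sizes <- sizes[active]
  spec <- if (length(sizes) > 0L) table(sizes) else table(integer(0))
  structure(list(
    size_counts = stats::setNames(as.integer(spec),
                                  names(spec)),
    n_families = length(sizes),
    max_family_size = if (length(sizes) > 0L) max(sizes) else 0L,
    degree1_loci = sum(degrees == 1L),
    degree2_loci = sum(degrees == 2L)),
    class = "family_spectrum")
}

#' @export
print.family_spectrum <- function(x, ...) {
  cat("family spectrum:", x$n_families, "families, max size",
      x$max_family_size, "\n")
  if (length(x$size_counts) > 0L) {
    cat("  size:count ",
        paste(names(x$size_counts), x$size_counts, sep = ":",
              collapse = "  "), "\n")
  }
  cat("  loci matching exactly one partner:", x$degree1_loci, "\n")
  cat("  loci matching exactly two partners:", x$degree2_loci, "\n")
  invisible(x)
}

#' @export
print.family_set <- function(x, ...) {
  cat("family_set:", length(x$families), "families (",
      sum(vapply(x$families, function(f) isTRUE(f$te_flagged), TRUE)),
      "TE-flagged )\n")
  print(x$spectrum)
  invisible(x)
}

#' Screen gene families against a transposable-element library
#'
#' Each family member's representative transcript is aligned against the
#' TE library with the built-in aligner. A member is TE-supported when its
#' TE alignments of at least `min_match_length` nt together cover at
#' least `min_span_coverage` of the member's family-supporting matched
#' span (its best family edge); coverage is taken over the union of hits
#' because one TE insertion can be split into several alignments by a
#' member's intron structure. A family is flagged as spurious when at
#' least `min_member_fraction` of its members are TE-supported. Flagged
#' families stay in the output, with the reason recorded, but are excluded
#' from the reported spectrum. Degree tallies are computed on the
#' pre-screen graph and are unchanged by flagging.
#'
#' @param family_set output of [extract_families()].
#' @param te_library a named character vector or `locus_catalog` of TE
#'   sequences; an empty library is a no-op with a warning.
#' @param catalog the `locus_catalog` of representative isoforms the
#'   families were built from.
#' @param params [align_params()] for member-vs-TE alignment.
#' @param min_match_length minimum TE alignment length (nt).
#' @param min_span_coverage minimum fraction of the family-supporting span
#'   a TE hit must cover.
#' @param min_member_fraction fraction of TE-supported members at which a
#'   family is flagged.
#' @return the `family_set` with `te_flagged`/`te_reason` set and the
#'   spectrum recomputed over unflagged families only.
#' @export
screen_te <- function(family_set, te_library, catalog,
                      params = align_params(),
                      min_match_length = 100L,
                      min_span_coverage = 0.5,
                      min_member_fraction = 0.5) {
  te <- if (inherits(te_library, "locus_catalog"))
    as_sequence_set(te_library, "te_library")$seqs else te_library
  if (length(te) == 0L) {
    warning("empty TE library; screen is a no-op")
    return(family_set)
  }
  if (length(family_set$families) == 0L) return(family_set)
  tx <- catalog$transcripts
  locus_to_tx <- stats::setNames(tx$transcript_id, tx$locus_id)
  member_loci <- unique(unlist(lapply(family_set$families,
                                      function(f) f$members)))
  member_tx <- locus_to_tx[member_loci]
  if (anyNA(member_tx))
    stop("family member loci missing from catalog: ",
         paste(member_loci[is.na(member_tx)][1:3], collapse = ", "))
  seqs <- stats::setNames(unname(catalog$sequences[member_tx]), member_tx)
  te_hits <- align_all(seqs, te, params)
  te_hits <- te_hits[te_hits$aligned_length >= min_match_length, ,
                     drop = FALSE]
  hit_by_locus <- split(te_hits,
                        tx$locus_id[match(te_hits$query_id,
                                          tx$transcript_id)])

  # span of the best family edge, per member locus
  g <- family_set$graph
  fam_span <- function(locus) {
    es <- igraph::incident(g, locus)
    ea <- igraph::edge_attr(g, index = es)
    best <- which.max(ea$aligned_length)
    ends <- igraph::ends(g, es[best])
    if (ends[1L, 1L] == locus)
      c(ea$span_a_start[best], ea$span_a_end[best])
    else c(ea$span_b_start[best], ea$span_b_end[best])
  }

  member_supported <- function(locus) {
    hits <- hit_by_locus[[locus]]
    if (is.null(hits) || nrow(hits) == 0L) return(FALSE)
    span <- fam_span(locus)
    span_len <- span[2L] - span[1L]
    if (span_len <= 0L) return(FALSE)
    # union coverage of the span by all qualifying TE hits (a single TE
    # insertion can be split into several alignments by intron structure)
    st <- pmax(hits$q_start, span[1L]); en <- pmin(hits$q_end, span[2L])
    keep <- en > st
    if (!any(keep)) return(FALSE)
    iv <- IRanges::reduce(IRanges::IRanges(start = st[keep] + 1L,
                                           end = en[keep]))
    sum(IRanges::width(iv)) / span_len >= min_span_coverage
  }

  family_set$families <- lapply(family_set$families, function(f) {
    supported <- vapply(f$members, member_supported, TRUE)
    frac <- mean(supported)
    if (frac >= min_member_fraction) {
      f$te_flagged <- TRUE
      f$te_reason <- sprintf(
        "%d/%d members have TE-library matches >= %d nt covering >= %.0f%% of the family-supporting span",
        sum(supported), length(supported), min_match_length,
        100 * min_span_coverage)
    }
    f
  })
  family_set$spectrum <- family_spectrum(family_set$families,
                                         igraph::degree(g))
  family_set
}

#' Write families and spectrum as TSV
#'
#' @param family_set a `family_set`.
#' @param families_path TSV path for the family table (family_id, size,
#'   comma-separated members, te_flagged, reason).
#' @param spectrum_path optional TSV path for the two-column family-size
#'   spectrum (family size, number of families), TE-flagged families
#'   excluded.
#' @return `families_path`, invisibly.
#' @export
write_families_tsv <- function(family_set, families_path,
                               spectrum_path = NULL) {
  fams <- family_set$families
  tab <- data.frame(
    family_id = vapply(fams, `[[`, "", "family_id"),
    size = vapply(fams, function(f) length(f$members), 0L),
    members = vapply(fams, function(f) paste(f$members, collapse = ","), ""),
    te_flagged = vapply(fams, function(f) isTRUE(f$te_flagged), TRUE),
    reason = vapply(fams, function(f)
      if (is.na(f$te_reason)) "" else f$te_reason, ""),
    stringsAsFactors = FALSE)
  utils::write.table(tab, families_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(spectrum_path)) {
    sp <- family_set$spectrum$size_counts
    utils::write.table(
      data.frame(family_size = as.integer(names(sp)),
                 n_families = as.integer(sp)),
      spectrum_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(families_path)
}

#' Export the homology graph as GraphML
#'
#' @param graph the locus graph from [build_family_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Rand index between two partitions of loci
#'
#' Agreement between two partitions (for example, recovered families vs a
#' planted truth) as the fraction of locus pairs on which the partitions
#' agree about co-membership. 1 means identical partitions.
#'
#' @param labels_a named vector of group labels.
#' @param labels_b named vector of group labels over the same names.
#' @return the Rand index in \[0,1\].
#' @export
partition_rand_index <- function(labels_a, labels_b) {
  nm <- intersect(names(labels_a), names(labels_b))
  if (length(nm) < 2L) return(1)
  a <- as.character(labels_a[nm]); b <- as.character(labels_b[nm])
  pairs <- utils::combn(length(nm), 2L)
  same_a <- a[pairs[1L, ]] == a[pairs[2L, ]]
  same_b <- b[pairs[1L, ]] == b[pairs[2L, ]]
  mean(same_a == same_b)
}
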