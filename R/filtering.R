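#' Filter configuration for the match cascade
#'
#' @param min_match_length minimum significant match length in nt
#'   (alignment columns); the boundary is inclusive, so a 100 nt alignment
#'   passes the default.
#' @param drop_rrna drop matches whose subject is ribosomal RNA.
#' @param drop_self_locus drop matches within one locus (self hits and
#'   isoform-isoform hits).
#' @param taxon_of_interest species whose annotation the catalog describes;
#'   matches outside it are classified as other-species.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_match_length = 100L, drop_rrna = TRUE,
                          drop_self_locus = TRUE,
                          taxon_of_interest = "Oryza sativa") {
  stopifnot(min_match_length >= 1)
  structure(list(min_match_length = as.integer(min_match_length),
                 drop_rrna = drop_rrna, drop_self_locus = drop_self_locus,
                 taxon_of_interest = taxon_of_interest),
            class = "filter_config")
}

subject_biotype <- function(matches, catalog) {
  map <- stats::setNames(catalog$transcripts$biotype,
                         catalog$transcripts$transcript_id)
  bt <- unname(map[matches$subject_id])
  # fall back to locus-level lookup for subjects given by locus id
  lmap <- catalog$transcripts$biotype[!duplicated(catalog$transcripts$locus_id)]
  names(lmap) <- unique(catalog$transcripts$locus_id)
  miss <- is.na(bt)
  bt[miss] <- unname(lmap[matches$subject_locus[miss]])
  bt
}

is_rrna_subject <- function(matches, catalog, subject_descriptions = NULL) {
  bt <- subject_biotype(matches, catalog)
  rrna <- !is.na(bt) & bt == "rRNA"
  if (!is.null(subject_descriptions)) {
    desc <- subject_descriptions[matches$subject_id]
    kw <- !is.na(desc) & grepl("ribosomal RNA|\\brRNA\\b", desc,
                               ignore.case = TRUE)
    rrna <- rrna | (is.na(bt) & kw)
  }
  rrna
}

#' Apply the match filter cascade
#'
#' Removes, in any order (the cascade is order-independent):
#' ribosomal-RNA subjects (by catalog biotype, with an optional
#' product-description keyword fallback for subjects outside the catalog),
#' intra-locus matches (self hits and isoform-isoform hits of one locus),
#' and alignments shorter than the minimum significant match length
#' (inclusive boundary: an alignment of exactly `min_match_length` nt is
#' kept). Input order is preserved; empty input returns empty output.
#'
#' @param matches a homology match data.frame.
#' @param cfg a [filter_config()].
#' @param catalog the `locus_catalog` the queries came from (used for
#'   subject biotype lookup).
#' @param subject_descriptions optional named character vector of subject
#'   product descriptions, used to recognise rRNA subjects not in the
#'   catalog.
#' @return the retained subset of `matches`.
#' @export
filter_matches <- function(matches, cfg = filter_config(), catalog,
                           subject_descriptions = NULL) {
  if (nrow(matches) == 0L) return(matches)
  keep <- rep(TRUE, nrow(matches))
  if (cfg$drop_rrna)
    keep <- keep & !is_rrna_subject(matches, catalog, subject_descriptions)
  if (cfg$drop_self_locus)
    keep <- keep & matches$query_locus != matches$subject_locus
  keep <- keep & matches$aligned_length >= cfg$min_match_length
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a taxon map
#'
#' @param accession character vector of subject accessions.
#' @param taxid integer taxon ids.
#' @param species character species names (same length).
#' @return a data.frame of class `taxon_map`.
#' @export
taxon_map <- function(accession, taxid, species) {
  stopifnot(length(accession) == length(taxid),
            length(accession) == length(species))
  structure(data.frame(accession = as.character(accession),
                       taxid = as.integer(taxid),
                       species = as.character(species),
                       stringsAsFactors = FALSE),
            class = c("taxon_map", "data.frame"))
}

#' Read an accession-to-taxon mapping table
#'
#' Reads the four-column `accession2taxid` dialect (accession,
#' accession.version, taxid, gi; tab-separated, with header). Species names
#' are not part of that table, so they are attached from an optional
#' two-column taxid-to-name table; taxa without a name entry get species
#' `"unknown"`.
#'
#' @param path accession2taxid TSV.
#' @param names_path optional TSV with columns `taxid`, `species`.
#' @return a `taxon_map`.
#' @export
read_accession2taxid <- function(path, names_path = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("format error: accession2taxid table needs >= 3 columns")
  names(tab)[1:3] <- c("accession", "accession.version", "taxid")
  species <- rep("unknown", nrow(tab))
  if (!is.null(names_path)) {
    nm <- utils::read.table(names_path, sep = "\t", header = TRUE,
                            comment.char = "", stringsAsFactors = FALSE)
    names(nm)[1:2] <- c("taxid", "species")
    hit <- match(tab$taxid, nm$taxid)
    species[!is.na(hit)] <- nm$species[hit[!is.na(hit)]]
  }
  taxon_map(tab$accession.version, tab$taxid, species)
}

#' Classify filtered matches by subject category and species
#'
#' Splits matches three ways, mirroring the downstream reporting:
#' same-species non-coding subjects, same-species protein-coding subjects,
#' and subjects from other species (which carry the species name appended
#' from the taxon map). The partition is exhaustive and disjoint. Subjects
#' found in the catalog are classified by biotype; subjects outside the
#' catalog are looked up in the taxon map and any accession missing from it
#' is classified other-species with species `"unknown"` (with a warning).
#'
#' @param matches filtered homology matches.
#' @param catalog the same-species `locus_catalog`.
#' @param taxa a `taxon_map` (may be empty).
#' @param cfg a [filter_config()] supplying `taxon_of_interest`.
#' @return a list with elements `same_species_ncrna`,
#'   `same_species_coding`, `other_species` (the last with a `species`
#'   column); each a match data.frame with `subject_class` set to
#'   `self_ncRNA`, `self_coding`, or `cross_species`.
#' @export
classify_matches <- function(matches, catalog, taxa = NULL,
                             cfg = filter_config()) {
  n <- nrow(matches)
  bt <- subject_biotype(matches, catalog)
  in_catalog <- !is.na(bt)
  species <- rep(NA_character_, n)
  if (!is.null(taxa) && nrow(taxa) > 0L) {
    hit <- match(matches$subject_id, taxa$accession)
    species[!is.na(hit)] <- taxa$species[hit[!is.na(hit)]]
  }
  species[in_catalog] <- cfg$taxon_of_interest
  same <- in_catalog |
    (!is.na(species) & species == cfg$taxon_of_interest)
  unknown <- !same & is.na(species)
  if (any(unknown)) {
    warning(sum(unknown), " subject accession(s) missing from the taxon ",
            "map; classified as other-species 'unknown'")
    species[unknown] <- "unknown"
  }
  coding <- same & !is.na(bt) & bt == "mRNA"
  ncrna <- same & !coding
  other <- !same
  cls <- rep("cross_species", n)
  cls[ncrna] <- "self_ncRNA"
  cls[coding] <- "self_coding"
  matches$subject_class <- cls
  out_other <- matches[other, , drop = FALSE]
  out_other$species <- species[other]
  res <- list(same_species_ncrna = matches[ncrna, , drop = FALSE],
              same_species_coding = matches[coding, , drop = FALSE],
              other_species = out_other)
  res <- lapply(res, function(d) { rownames(d) <- NULL; d })
  res
}

#' Write the three-way classified match split
#'
#' @param classified output of [classify_matches()].
#' @param dir output directory; files `matches_ncrna.tsv`,
#'   `matches_coding.tsv`, `matches_other_species.tsv` are written there.
#' @return the directory, invisibly.
#' @export
write_classified_matches <- function(classified, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matches_tsv(classified$same_species_ncrna,
                    file.path(dir, "matches_ncrna.tsv"))
  write_matches_tsv(classified$same_species_coding,
                    file.path(dir, "matches_coding.tsv"))
  write_matches_tsv(classified$other_species,
                    file.path(dir, "matches_other_species.tsv"))
  invisible(dir)
}
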