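test_that("the locus graph deduplicates reciprocal and repeated matches", {
  m <- rbind(make_match("tA", "tB", "A", "B", aligned_length = 200L),
             make_match("tB", "tA", "B", "A", aligned_length = 200L),
             make_match("tA", "tB", "A", "B", aligned_length = 150L,
                        q_start = 300L, s_start = 300L))
  g <- build_family_graph(m)
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  # best supporting alignment annotated on the edge
  expect_equal(igraph::E(g)$aligned_length, 200L)
  # empty input: empty graph
  g0 <- build_family_graph(m[0, ])
  expect_equal(igraph::vcount(g0), 0L)
})

test_that("graph adjacency equals a brute-force pair enumeration", {
  set.seed(11)
  loci <- sprintf("L%02d", 1:50)
  n_m <- 120
  m <- do.call(rbind, lapply(seq_len(n_m), function(i) {
    ab <- sample(loci, 2)
    make_match(paste0(ab[1], ".t"), paste0(ab[2], ".t"), ab[1], ab[2],
               aligned_length = sample(100:400, 1))
  }))
  g <- build_family_graph(m)
  # oracle: enumerate all unordered locus pairs and ask whether any match
  # connects them
  oracle_pairs <- unique(t(apply(cbind(m$query_locus, m$subject_locus), 1,
                                 sort)))
  got_pairs <- igraph::as_edgelist(g)
  got_pairs <- unique(t(apply(got_pairs, 1, sort)))
  o <- paste(oracle_pairs[, 1], oracle_pairs[, 2])
  g2 <- paste(got_pairs[, 1], got_pairs[, 2])
  expect_setequal(g2, o)
})

test_that("families are connected components of size >= 3", {
  m <- rbind(make_match("a", "b", "A", "B"), make_match("b", "c", "B", "C"))
  fs <- extract_families(build_family_graph(m))
  expect_equal(length(fs$families), 1L)
  expect_setequal(fs$families[[1]]$members, c("A", "B", "C"))
  expect_equal(fs$spectrum$max_family_size, 3L)

  # a lone pair is no family; both loci count as matching a single partner
  m2 <- make_match("a", "b", "A", "B")
  fs2 <- extract_families(build_family_graph(m2))
  expect_equal(length(fs2$families), 0L)
  expect_equal(fs2$spectrum$degree1_loci, 2L)
  expect_equal(fs2$spectrum$degree2_loci, 0L)

  expect_error(extract_families(build_family_graph(m2), min_size = 1L),
               "min_size")
})

test_that("planted component structure is recovered exactly", {
  set.seed(12)
  sizes <- c(3L, 3L, 4L, 5L, 7L, 35L)
  edges <- list(); truth <- character(0)
  idx <- 0L
  for (fi in seq_along(sizes)) {
    members <- sprintf("F%02dM%02d", fi, seq_len(sizes[fi]))
    truth[members] <- sprintf("F%02d", fi)
    # random spanning tree plus a few extra edges
    for (k in 2:length(members)) {
      p <- sample(k - 1L, 1L)
      edges[[length(edges) + 1L]] <-
        make_match(paste0(members[k], ".t"), paste0(members[p], ".t"),
                   members[k], members[p])
    }
  }
  m <- do.call(rbind, edges)
  fs <- extract_families(build_family_graph(m))
  expect_equal(length(fs$families), length(sizes))
  got_sizes <- sort(vapply(fs$families, function(f) length(f$members), 0L))
  expect_equal(got_sizes, sort(sizes))
  labels <- family_labels(fs, names(truth))
  expect_equal(partition_rand_index(truth, labels), 1.0)
  # spectrum conservation: sum(size * count) equals loci in families
  sp <- fs$spectrum$size_counts
  expect_equal(sum(as.integer(names(sp)) * sp), sum(sizes))
})

test_that("raising the match-length threshold only splits families", {
  set.seed(13)
  m <- rbind(make_match("a", "b", "A", "B", aligned_length = 400L),
             make_match("b", "c", "B", "C", aligned_length = 150L),
             make_match("c", "d", "C", "D", aligned_length = 120L),
             make_match("d", "a", "D", "A", aligned_length = 350L))
  cat <- make_test_catalog()  # biotypes irrelevant: no rRNA subjects here
  fam_at <- function(len) {
    cfg <- filter_config(min_match_length = len, drop_rrna = FALSE,
                         drop_self_locus = FALSE)
    fs <- extract_families(build_family_graph(filter_matches(m, cfg, cat)),
                           min_size = 2L)
    lapply(fs$families, `[[`, "members")
  }
  low <- fam_at(100L); high <- fam_at(300L)
  # every high-threshold family is inside some low-threshold family
  for (h in high)
    expect_true(any(vapply(low, function(l) all(h %in% l), TRUE)))
  expect_gte(length(unlist(low)), length(unlist(high)))
})

test_that("TE screening flags decoy families and spares true ones", {
  set.seed(14)
  sg <- generate_genome(synthesis_config(
    seed = 201, family_sizes = c(3L, 4L), n_background_lnc = 6L,
    n_te_decoy_families = 2L, te_decoy_family_size = 3L,
    n_rrna_loci = 1L, n_coding_genes = 2L,
    n_coding_genes_with_shared_region = 1L, n_cross_species = 0L,
    shared_block_lengths = c(208L, 150L),
    locus_length_range = c(400L, 900L)))
  res <- discover_families(sg$catalog, te_library = sg$te_library,
                           taxa = sg$taxa)
  truth <- sg$truth
  decoy_groups <- unique(truth$group_id[truth$role == "te_decoy"])
  true_groups <- unique(truth$group_id[truth$role == "family"])
  for (f in res$families$families) {
    roles <- truth$role[match(f$members, truth$locus_id)]
    if (all(roles == "te_decoy")) {
      expect_true(f$te_flagged)
      expect_match(f$te_reason, "TE-library")
    } else {
      expect_false(f$te_flagged)
    }
  }
  # flagged families are excluded from the spectrum
  sp <- res$families$spectrum
  expect_equal(sp$n_families, length(true_groups))
  # empty TE library is a warning no-op
  fs <- extract_families(res$families$graph)
  expect_warning(out <- screen_te(fs, character(0), res$representatives),
                 "empty TE library")
  expect_identical(out$families, fs$families)
})

test_that("family tables and graph exports are written", {
  m <- rbind(make_match("a", "b", "A", "B"), make_match("b", "c", "B", "C"))
  fs <- extract_families(build_family_graph(m))
  fp <- tempfile(); sp <- tempfile(); gp <- tempfile(fileext = ".graphml")
  write_families_tsv(fs, fp, sp)
  tab <- read.delim(fp)
  expect_equal(tab$size, 3L)
  spec <- read.delim(sp)
  expect_equal(spec$family_size, 3L)
  expect_equal(spec$n_families, 1L)
  write_graphml(fs$graph, gp)
  expect_true(file.size(gp) > 0)
})
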