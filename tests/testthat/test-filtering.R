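make_filter_fixture <- function() {
  cat <- make_test_catalog()
  list(catalog = cat,
       matches = rbind(
         make_match("TA.1", "TB.1", "LOCA", "LOCB", aligned_length = 99L),
         make_match("TA.1", "TB.1", "LOCA", "LOCB", aligned_length = 100L),
         make_match("TA.1", "TB.1", "LOCA", "LOCB", aligned_length = 605L),
         make_match("TA.1", "TA.2", "LOCA", "LOCA", aligned_length = 500L),
         make_match("TA.1", "TA.1", "LOCA", "LOCA", aligned_length = 1406L),
         make_match("TB.1", "TR.1", "LOCB", "LOCR", aligned_length = 300L)))
}

test_that("length boundary is inclusive at the minimum match length", {
  fx <- make_filter_fixture()
  cfg <- filter_config(drop_rrna = FALSE, drop_self_locus = FALSE)
  out <- filter_matches(fx$matches[1:3, ], cfg, fx$catalog)
  expect_equal(sort(out$aligned_length), c(100L, 605L))
})

test_that("self-locus and rRNA-subject matches are removed", {
  fx <- make_filter_fixture()
  out <- filter_matches(fx$matches, filter_config(), fx$catalog)
  # isoform-isoform and exact self hits gone
  expect_false(any(out$query_locus == out$subject_locus))
  # rRNA subject gone
  expect_false(any(out$subject_id == "TR.1"))
  expect_equal(sort(out$aligned_length), c(100L, 605L))
  # empty input returns empty output
  expect_equal(nrow(filter_matches(fx$matches[0, ], filter_config(),
                                   fx$catalog)), 0L)
})

test_that("filter cascade is order-independent and monotone", {
  fx <- make_filter_fixture()
  cat <- fx$catalog
  m <- fx$matches
  full <- filter_matches(m, filter_config(), cat)
  # apply the three rules one at a time in two different orders
  step <- function(m, rrna, self, len) {
    cfg <- filter_config(min_match_length = len, drop_rrna = rrna,
                         drop_self_locus = self)
    filter_matches(m, cfg, cat)
  }
  o1 <- step(step(step(m, TRUE, FALSE, 1L), FALSE, TRUE, 1L),
             FALSE, FALSE, 100L)
  o2 <- step(step(step(m, FALSE, FALSE, 100L), FALSE, TRUE, 1L),
             TRUE, FALSE, 1L)
  expect_equal(o1, full, ignore_attr = TRUE)
  expect_equal(o2, full, ignore_attr = TRUE)
  # raising the threshold never gains matches
  counts <- vapply(c(1L, 50L, 100L, 200L, 700L), function(len)
    nrow(step(m, TRUE, TRUE, len)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("rRNA fixture counts match their construction", {
  cat <- make_test_catalog()
  set.seed(9)
  subj <- c(rep("TR.1", 5), rep("TB.1", 15))
  m <- do.call(rbind, lapply(seq_along(subj), function(i)
    make_match("TA.1", subj[i], "LOCA",
               ifelse(subj[i] == "TR.1", "LOCR", "LOCB"))))
  out <- filter_matches(m, filter_config(), cat)
  expect_equal(nrow(out), 15L)
})

test_that("classification partitions matches exhaustively", {
  cat <- make_test_catalog()
  taxa <- taxon_map(c("XOTHER.1", "XW.1"), c(4565L, 4565L),
                    c("Triticum aestivum", "Triticum aestivum"))
  m <- rbind(
    make_match("TA.1", "TB.1", "LOCA", "LOCB"),      # same-species lncRNA
    make_match("TA.1", "TC.1", "LOCA", "LOCC"),      # same-species coding
    make_match("TA.1", "XOTHER.1", "LOCA", "XOTHER.1"),  # cross-species
    make_match("TB.1", "XW.1", "LOCB", "XW.1"))
  cls <- classify_matches(m, cat, taxa)
  expect_equal(nrow(cls$same_species_ncrna), 1L)
  expect_equal(nrow(cls$same_species_coding), 1L)
  expect_equal(nrow(cls$other_species), 2L)
  expect_equal(nrow(cls$same_species_ncrna) + nrow(cls$same_species_coding) +
                 nrow(cls$other_species), nrow(m))
  expect_equal(cls$same_species_ncrna$subject_class, "self_ncRNA")
  expect_equal(cls$same_species_coding$subject_class, "self_coding")
  expect_setequal(cls$other_species$species, "Triticum aestivum")
  # unmapped accession: other-species "unknown" with a warning
  m2 <- make_match("TA.1", "MYSTERY.1", "LOCA", "MYSTERY.1")
  expect_warning(cls2 <- classify_matches(m2, cat, taxa), "missing")
  expect_equal(cls2$other_species$species, "unknown")
})

test_that("a planted three-way split is recovered exactly", {
  cat <- make_test_catalog()
  set.seed(10)
  taxa <- taxon_map("XS.1", 4565L, "Triticum aestivum")
  mk <- function(n, subject, subject_locus = subject)
    do.call(rbind, lapply(seq_len(n), function(i)
      make_match("TA.1", subject, "LOCA", subject_locus)))
  m <- rbind(mk(10, "TB.1", "LOCB"), mk(12, "TC.1", "LOCC"), mk(8, "XS.1"))
  m <- m[sample(nrow(m)), ]
  cls <- classify_matches(m, cat, taxa)
  expect_equal(c(nrow(cls$same_species_ncrna),
                 nrow(cls$same_species_coding),
                 nrow(cls$other_species)), c(10L, 12L, 8L))
})

test_that("the three-way split is written as three TSV files", {
  cat <- make_test_catalog()
  m <- rbind(make_match("TA.1", "TB.1", "LOCA", "LOCB"),
             make_match("TA.1", "TC.1", "LOCA", "LOCC"))
  cls <- suppressWarnings(classify_matches(m, cat, NULL))
  d <- tempfile("split")
  write_classified_matches(cls, d)
  expect_setequal(list.files(d), c("matches_ncrna.tsv", "matches_coding.tsv",
                                   "matches_other_species.tsv"))
  expect_equal(nrow(read.delim(file.path(d, "matches_ncrna.tsv"))), 1L)
  expect_equal(nrow(read.delim(file.path(d, "matches_coding.tsv"))), 1L)
})

test_that("accession2taxid tables read with species-name attachment", {
  acc <- tempfile(); nm <- tempfile()
  writeLines(c("accession\taccession.version\ttaxid\tgi",
               "AB1\tAB1.1\t4530\t1", "CD2\tCD2.1\t4565\t2",
               "EF3\tEF3.1\t99999\t3"), acc)
  writeLines(c("taxid\tspecies", "4530\tOryza sativa",
               "4565\tTriticum aestivum"), nm)
  tm <- read_accession2taxid(acc, nm)
  expect_equal(tm$species[tm$accession == "AB1.1"], "Oryza sativa")
  expect_equal(tm$species[tm$accession == "EF3.1"], "unknown")
})
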