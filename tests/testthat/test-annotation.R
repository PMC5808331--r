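test_that("GFF3 parsing builds the catalog with spliced sequences", {
  fx <- write_mini_gff3()
  cat_all <- parse_annotation(fx$gff, fx$fasta)
  expect_equal(n_loci(cat_all), 3L)
  expect_equal(nrow(cat_all$transcripts), 4L)

  lnc <- parse_annotation(fx$gff, fx$fasta, biotype_filter = "lncRNA")
  expect_equal(n_loci(lnc), 2L)
  expect_equal(nrow(lnc$transcripts), 3L)

  # plus strand, two exons: concatenation of exon substrings
  tx <- cat_all$transcripts
  t1 <- cat_all$sequences[["LNC1.t1"]]
  expect_equal(t1, paste0(substr(fx$genome, 51, 90),
                          substr(fx$genome, 121, 150)))
  expect_equal(tx$exon_count[tx$transcript_id == "LNC1.t1"], 2L)

  # minus strand with exons (10,20) and (30,40) 0-based half-open:
  # reverse complement of the concatenated exon substrings, length 20
  t2 <- cat_all$sequences[["LNC2.t1"]]
  concat <- paste0(substr(fx$genome, 11, 20), substr(fx$genome, 31, 40))
  expect_equal(nchar(t2), 20L)
  expect_equal(t2, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(concat))))
  # 1-based closed GFF coordinates stored as 0-based half-open spans
  expect_equal(cat_all$exon_spans[["LNC2.t1"]],
               cbind(c(10L, 30L), c(20L, 40L)), ignore_attr = TRUE)
})

test_that("out-of-bounds exons and missing genome raise validation errors", {
  fx <- write_mini_gff3()
  bad <- c(readLines(fx$gff),
           "chrZ\ttest\tgene\t1\t999999\t.\t+\t.\tID=BAD",
           "chrZ\ttest\tlnc_RNA\t1\t999999\t.\t+\t.\tID=BAD.t1;Parent=BAD",
           "chrZ\ttest\texon\t1\t999999\t.\t+\t.\tParent=BAD.t1")
  badgff <- tempfile(fileext = ".gff3")
  writeLines(bad, badgff)
  expect_error(parse_annotation(badgff, fx$fasta), "exceed bounds")
  expect_error(parse_annotation(fx$gff), "genome")
})

test_that("GenBank flat-file records parse with biotype and exon count", {
  gb <- c(
    "LOCUS       XR_0001             120 bp    RNA     linear   PLN",
    "DEFINITION  synthetic lncRNA record.",
    "VERSION     XR_0001.1",
    "FEATURES             Location/Qualifiers",
    "     gene            1..120",
    '                     /gene="LOCX1"',
    "     ncRNA           1..120",
    '                     /ncRNA_class="lncRNA"',
    '                     /gene="LOCX1"',
    "     exon            1..50",
    "     exon            51..120",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("ttggccaatt", 6), collapse = " ")),
    "//",
    "LOCUS       NM_0002              60 bp    mRNA    linear   PLN",
    "VERSION     NM_0002.1",
    "FEATURES             Location/Qualifiers",
    "     gene            1..60",
    '                     /gene="LOCX2"',
    "     mRNA            1..60",
    "     CDS             1..60",
    "ORIGIN",
    paste0("        1 ", paste(rep("gattacagat", 6), collapse = " ")),
    "//",
    "LOCUS       NR_0003              40 bp    rRNA    linear   PLN",
    "VERSION     NR_0003.1",
    "FEATURES             Location/Qualifiers",
    "     rRNA            1..40",
    "ORIGIN",
    paste0("        1 ", paste(rep("ccggaattcc", 4), collapse = " ")),
    "//")
  path <- tempfile(fileext = ".gbff")
  writeLines(gb, path)
  cat_gb <- parse_annotation(path)
  tx <- cat_gb$transcripts
  expect_equal(nrow(tx), 3L)
  expect_equal(tx$biotype[tx$transcript_id == "XR_0001.1"], "lncRNA")
  expect_equal(tx$biotype[tx$transcript_id == "NM_0002.1"], "mRNA")
  expect_equal(tx$biotype[tx$transcript_id == "NR_0003.1"], "rRNA")
  expect_equal(tx$exon_count[tx$transcript_id == "XR_0001.1"], 2L)
  expect_equal(tx$locus_id[tx$transcript_id == "XR_0001.1"], "LOCX1")
  expect_equal(tx$length_nt, c(120L, 60L, 40L))
  expect_equal(cat_gb$sequences[["NM_0002.1"]],
               toupper(paste(rep("gattacagat", 6), collapse = "")))
  # record without terminator is a format error
  expect_error(parse_annotation(textConnectionPath <- {
    p <- tempfile(); writeLines(gb[1:3], p); p
  }, format = "gbff"), "format error")
})

test_that("generated annotation round-trips through GFF3 + FASTA parsing", {
  sg <- generate_genome(synthesis_config(
    seed = 11, family_sizes = c(3L), n_background_lnc = 4L,
    n_te_decoy_families = 0L, n_rrna_loci = 1L, n_coding_genes = 2L,
    n_coding_genes_with_shared_region = 1L, n_cross_species = 0L,
    locus_length_range = c(400L, 800L),
    shared_block_lengths = 150L))
  dir <- tempfile("sg"); dir.create(dir)
  gff <- file.path(dir, "a.gff3"); fa <- file.path(dir, "g.fa")
  write_annotation_gff3(sg$catalog, gff)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sg$genome), fa)
  back <- parse_annotation(gff, fa)
  ord <- order(back$transcripts$transcript_id)
  orig_ord <- order(sg$catalog$transcripts$transcript_id)
  expect_equal(back$transcripts[ord, ],
               sg$catalog$transcripts[orig_ord, ],
               ignore_attr = TRUE)
  expect_equal(back$sequences[names(sg$catalog$sequences)],
               sg$catalog$sequences)
})
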