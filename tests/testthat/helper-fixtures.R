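random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_bases <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

# A small hand-built catalog: two lncRNA loci (3 + 1 isoforms), one mRNA,
# one rRNA locus. Sequences are arbitrary but length-consistent.
make_test_catalog <- function(seed = 42L) {
  set.seed(seed)
  lens <- c(1406L, 1080L, 1200L, 900L, 1000L, 1500L)
  tx <- data.frame(
    locus_id = c("LOCA", "LOCA", "LOCA", "LOCB", "LOCC", "LOCR"),
    transcript_id = c("TA.1", "TA.2", "TA.3", "TB.1", "TC.1", "TR.1"),
    biotype = c("lncRNA", "lncRNA", "lncRNA", "lncRNA", "mRNA", "rRNA"),
    exon_count = 1L, length_nt = lens,
    chrom = "chr1", strand = "+", stringsAsFactors = FALSE)
  seqs <- setNames(vapply(lens, random_dna, ""), tx$transcript_id)
  locus_catalog(tx, seqs, provenance = "test fixture")
}

# Build a homology-match data.frame row by row for filter tests.
make_match <- function(query_id, subject_id, query_locus = query_id,
                       subject_locus = subject_id, aligned_length = 200L,
                       percent_identity = 0.98, score = aligned_length * 0.9,
                       evalue = 1e-30, q_start = 0L, s_start = 0L,
                       subject_strand = "+") {
  data.frame(query_id = query_id, subject_id = subject_id,
             query_locus = query_locus, subject_locus = subject_locus,
             q_start = q_start, q_end = q_start + aligned_length,
             s_start = s_start, s_end = s_start + aligned_length,
             aligned_length = as.integer(aligned_length),
             percent_identity = percent_identity, score = score,
             evalue = evalue, subject_strand = subject_strand,
             subject_class = "unclassified", stringsAsFactors = FALSE)
}

# Minimal GFF3 + genome pair written to tempfiles; returns the two paths.
# Layout: locus LNC1 (+, isoforms of 2 and 1 exons), LNC2 (- strand,
# exons (10,20) and (30,40)), and one mRNA gene.
write_mini_gff3 <- function(dir = tempfile("anno")) {
  dir.create(dir)
  genome <- paste(rep(c("ACGTACGTGA", "TTGACCGTAA"), 30), collapse = "")
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chrZ = genome)), fa)
  lines <- c(
    "##gff-version 3",
    "chrZ\ttest\tgene\t51\t150\t.\t+\t.\tID=LNC1",
    "chrZ\ttest\tlnc_RNA\t51\t150\t.\t+\t.\tID=LNC1.t1;Parent=LNC1",
    "chrZ\ttest\texon\t51\t90\t.\t+\t.\tParent=LNC1.t1",
    "chrZ\ttest\texon\t121\t150\t.\t+\t.\tParent=LNC1.t1",
    "chrZ\ttest\tlnc_RNA\t51\t90\t.\t+\t.\tID=LNC1.t2;Parent=LNC1",
    "chrZ\ttest\texon\t51\t90\t.\t+\t.\tParent=LNC1.t2",
    "chrZ\ttest\tgene\t11\t40\t.\t-\t.\tID=LNC2",
    "chrZ\ttest\tlnc_RNA\t11\t40\t.\t-\t.\tID=LNC2.t1;Parent=LNC2",
    "chrZ\ttest\texon\t11\t20\t.\t-\t.\tParent=LNC2.t1",
    "chrZ\ttest\texon\t31\t40\t.\t-\t.\tParent=LNC2.t1",
    "chrZ\ttest\tgene\t201\t260\t.\t+\t.\tID=CODG",
    "chrZ\ttest\tmRNA\t201\t260\t.\t+\t.\tID=CODG.t1;Parent=CODG",
    "chrZ\ttest\texon\t201\t260\t.\t+\t.\tParent=CODG.t1")
  gff <- file.path(dir, "anno.gff3")
  writeLines(lines, gff)
  list(gff = gff, fasta = fa, genome = genome)
}
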