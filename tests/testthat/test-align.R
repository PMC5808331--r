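test_that("identical sequences yield one full-length perfect match", {
  set.seed(1)
  s <- random_dna(200)
  m <- align_all(c(q = s), c(t = s))
  plus <- m[m$subject_strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$aligned_length, 200L)
  expect_equal(plus$percent_identity, 1.0)
  expect_equal(plus$q_start, 0L)
  expect_equal(plus$q_end, 200L)
})

test_that("a conserved block mutated at 3% is found near full length", {
  set.seed(2)
  block <- random_dna(605)
  a <- paste0(random_dna(300), block, random_dna(200))
  b <- paste0(random_dna(150), substitute_bases(block, 0.03), random_dna(350))
  m <- align_all(c(qa = a), c(tb = b))
  expect_gte(nrow(m), 1L)
  best <- m[which.max(m$score), ]
  expect_gte(best$aligned_length, 0.95 * 605)
  expect_gt(best$percent_identity, 0.95)
})

test_that("best alignment scores match two independent oracles", {
  set.seed(3)
  # mixed set: random pairs (mostly insignificant) and planted homologies
  seqs <- vapply(sample(150:300, 10, replace = TRUE), random_dna, "")
  block <- random_dna(120)
  seqs <- c(seqs,
            paste0(random_dna(40), block, random_dna(60)),
            paste0(random_dna(90), substitute_bases(block, 0.02)))
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  params <- align_params()
  m <- align_all(seqs, seqs, params)
  n_total <- sum(nchar(seqs))
  min_score <- function(q) (log(params$K * nchar(q) * n_total) -
                              log(params$max_evalue)) / params$lambda
  checked <- 0L
  for (qi in names(seqs)) for (ti in names(seqs)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqs[[ti]])))
    oracle <- max(sw_oracle_score(seqs[[qi]], seqs[[ti]]),
                  sw_oracle_score(seqs[[qi]], rc))
    sub <- m[m$query_id == qi & m$subject_id == ti, ]
    got <- if (nrow(sub) > 0L) max(sub$score) else NA_real_
    if (oracle >= min_score(seqs[[qi]])) {
      expect_equal(got, oracle,
                   info = paste("pair", qi, ti))
      checked <- checked + 1L
    } else {
      expect_true(nrow(sub) == 0L || max(sub$score) <= oracle + 1e-9)
    }
    # Biostrings agrees with the hand-written DP oracle
    if (qi == "s01")
      expect_equal(best_oracle_score_both_strands(seqs[[qi]], seqs[[ti]]),
                   oracle)
  }
  expect_gte(checked, 3L)  # self hits + planted homology are non-vacuous
})

test_that("reverse-complementing the target flips strand only", {
  set.seed(4)
  block <- random_dna(250)
  q <- paste0(random_dna(100), block, random_dna(100))
  t_fwd <- paste0(random_dna(50), substitute_bases(block, 0.02),
                  random_dna(150))
  t_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(t_fwd)))
  m1 <- align_all(c(q = q), c(t = t_fwd))
  m2 <- align_all(c(q = q), c(t = t_rev))
  b1 <- m1[which.max(m1$score), ]
  b2 <- m2[which.max(m2$score), ]
  expect_equal(b1$subject_strand, "+")
  expect_equal(b2$subject_strand, "-")
  expect_equal(b1$aligned_length, b2$aligned_length)
  expect_equal(b1$percent_identity, b2$percent_identity)
  expect_equal(b1$score, b2$score)
  # span maps to the forward strand of the stored subject
  expect_equal(b2$s_start, nchar(t_fwd) - b1$s_end)
  expect_equal(b2$s_end, nchar(t_fwd) - b1$s_start)
})

test_that("locus-level symmetry: qualifying matches are reciprocal", {
  set.seed(5)
  block <- random_dna(300)
  seqs <- c(A = paste0(random_dna(120), block),
            B = paste0(substitute_bases(block, 0.02), random_dna(180)),
            C = random_dna(400))
  m <- align_all(seqs, seqs)
  pairs <- unique(m[m$query_id != m$subject_id,
                    c("query_id", "subject_id")])
  for (i in seq_len(nrow(pairs)))
    expect_true(any(m$query_id == pairs$subject_id[i] &
                      m$subject_id == pairs$query_id[i]))
})

test_that("configuration and degenerate inputs are rejected", {
  expect_error(align_all(c(q = "ACGT"), c(t = "ACGTACGTACGTACGT")),
               "seed_k")
  expect_error(align_params(match = -1), "match")
  set.seed(6)
  # empty input: empty match table
  expect_equal(nrow(align_all(character(0), c(t = random_dna(100)))), 0L)
})

test_that("E-values decrease monotonically with score", {
  p <- align_params()
  scores <- c(20, 40, 80, 160)
  ev <- alignment_evalue(scores, 1000, 1e6, p)
  expect_true(all(diff(ev) < 0))
  # lambda satisfies its defining equation
  expect_equal(0.25 * exp(p$lambda * p$match) +
                 0.75 * exp(p$lambda * p$mismatch), 1, tolerance = 1e-9)
})

test_that("N bases never count as identities", {
  set.seed(7)
  x <- random_dna(100); y <- random_dna(100)
  # identical sequences with a shared interior N run: the best local
  # alignment bridges the Ns (200 matches - 10 N mismatches) but its
  # identity must exclude the N columns
  q <- paste0(x, strrep("N", 10), y)
  m <- align_all(c(q = q), c(t = q))
  plus <- m[m$subject_strand == "+", ]
  best <- plus[which.max(plus$score), ]
  expect_equal(best$aligned_length, 210L)
  expect_equal(best$percent_identity, 200 / 210)
  expect_equal(best$score, 200 * 1 + 10 * -2)
})
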