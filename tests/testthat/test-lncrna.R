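test_that("longest ORF scanning follows the ATG/stop/tie rules", {
  orf <- longest_orf("ATGAAATAA")
  expect_equal(orf$length_aa, 2L)
  expect_equal(orf$peptide, "MK")
  expect_equal(orf$start, 0L)
  expect_true(orf$has_stop)
  # no ATG anywhere
  expect_equal(longest_orf("CCCCCCGGGTTT")$length_aa, 0L)
  # two equal-length ORFs: the 5'-most wins
  two <- paste0("ATGAAATAA", "G", "ATGCCCTAA")
  expect_equal(longest_orf(two)$start, 0L)
  # ORF without a stop runs to the transcript end
  open_orf <- longest_orf("CCATGAAAAAAAAA")
  expect_false(open_orf$has_stop)
  expect_equal(open_orf$length_aa, 4L)
  expect_equal(open_orf$peptide, "MKKK")
  # frames 1 and 2 are scanned
  expect_equal(longest_orf("GATGAAAAAATAA")$length_aa, 3L)
})

test_that("the Fickett statistic separates codon structure from shuffles", {
  sim <- simulate_coding_noncoding(n = 40L, seed = 9L)
  fc <- vapply(sim$coding, fickett_score, numeric(1))
  fn <- vapply(sim$noncoding, fickett_score, numeric(1))
  expect_gt(mean(fc), mean(fn))
  expect_gt(score_auc(fc, fn), 0.8)
})

test_that("coding potential is monotone in ORF size and case-invariant", {
  sim <- simulate_coding_noncoding(n = 1L, len_range = c(303L, 303L),
                                   seed = 2L)
  full <- sim$coding[[1L]]
  expect_gt(coding_potential(full), 0.5)
  # same backbone with the ORF destroyed scores lower
  shuf <- sim$noncoding[[1L]]
  expect_gt(coding_potential(full), coding_potential(shuf))
  expect_equal(coding_potential(tolower(full)), coding_potential(full))
  expect_true(coding_potential(shuf) >= 0 && coding_potential(shuf) <= 1)
})

make_lnc_world <- function() {
  # reference coding gene with two exons and one intron on chr1
  ref <- list(tx("cod1", c(1000, 1600, 2600, 3400), gene = "gc1"))
  set.seed(40)
  g <- random_genome(20000, seed = 40)
  list(ref = ref, genome = c(chr1 = g))
}

test_that("lncRNA filters reject short and ORF-bearing transcripts", {
  w <- make_lnc_world()
  short <- tx("short", c(5000, 5150))          # 150 nt < 200
  long_nc <- tx("lnc1", c(5000, 5500))         # intergenic, random seq
  cands <- list(short, long_nc)
  rec <- identify_lncrnas(cands, w$genome, w$ref)
  expect_false("short" %in% rec$transcript_id)
  expect_true("lnc1" %in% rec$transcript_id)
  expect_equal(rec$class[rec$transcript_id == "lnc1"], "lincRNA")
  # a transcript whose longest ORF exceeds 100 aa is rejected
  sim <- simulate_coding_noncoding(1L, c(600L, 600L), seed = 3L)
  gg <- w$genome
  substr(gg[["chr1"]], 8001, 8600) <- sim$coding[[1L]]
  coding_tx <- tx("orfy", c(8000, 8600))
  rec2 <- identify_lncrnas(list(coding_tx), gg, w$ref)
  expect_false("orfy" %in% rec2$transcript_id)
})

test_that("every emitted record satisfies all three filter predicates", {
  w <- make_lnc_world()
  set.seed(50)
  cands <- lapply(1:30, function(i) {
    s <- 4000 + 450 * i
    tx(paste0("c", i), c(s, s + sample(c(150, 300, 600), 1L)))
  })
  rec <- identify_lncrnas(cands, w$genome, w$ref, score_cutoff = 0.5)
  if (nrow(rec)) {
    expect_true(all(rec$length_nt >= 200L))
    expect_true(all(rec$orf_aa <= 100L))
    expect_true(all(rec$coding_score < 0.5))
  }
  expect_true(all(rec$class %in%
                    c("lincRNA", "lncNAT", "intronic", "sense_overlapping")))
})

test_that("positional classes are assigned by precedence and are exclusive", {
  w <- make_lnc_world()
  sense <- tx("s1", c(1200, 1500))                  # overlaps exon, sense
  nat <- tx("n1", c(1200, 1500), "-")               # antisense overlap
  intr <- tx("i1", c(1800, 2200))                   # inside the intron
  linc <- tx("l1", c(9000, 9400))                   # intergenic
  rec <- identify_lncrnas(list(sense, nat, intr, linc), w$genome, w$ref)
  got <- setNames(rec$class, rec$transcript_id)
  expect_equal(unname(got["s1"]), "sense_overlapping")
  expect_equal(unname(got["n1"]), "lncNAT")
  expect_equal(unname(got["i1"]), "intronic")
  expect_equal(unname(got["l1"]), "lincRNA")
})

test_that("target pairing uses distance/antisense rules and PCC classes", {
  lnc <- data.frame(transcript_id = c("l1", "n1"),
                    length_nt = 400L, n_exons = 1L, orf_aa = 10L,
                    coding_score = 0.1,
                    class = c("lincRNA", "lncNAT"),
                    stringsAsFactors = FALSE)
  txs <- list(tx("l1", c(9000, 9400)), tx("n1", c(1200, 1500), "-"))
  coding <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                       strand = "+", start = c(1000L, 20000L),
                       end = c(3400L, 21000L), stringsAsFactors = FALSE)
  expr <- rbind(l1 = c(1, 2, 3, 4, 5),
                n1 = c(5, 4, 3, 2, 1),
                gA = c(5.1, 4, 3, 2, 0.9),
                gB = c(2, 4, 1, 5, 3))
  pairs <- lnc_target_pairs(lnc, txs, coding, expr, max_dist_nt = 1e5)
  l1 <- pairs[pairs$lnc_id == "l1", ]
  expect_equal(l1$target_gene, "gA")   # nearest gene
  expect_equal(l1$pair_class, "negative")
  n1 <- pairs[pairs$lnc_id == "n1", ]
  expect_equal(n1$target_gene, "gA")   # antisense overlapping gene
  expect_gt(n1$pcc, 0.99)
  expect_equal(n1$pair_class, "positive")
  # |r| at the threshold is class 'none'
  expr2 <- expr
  expr2["gA", ] <- c(1, 4, 3, 2, 5)    # r = 0.6 with l1, not above it
  p2 <- lnc_target_pairs(lnc, txs, coding, expr2)
  expect_equal(p2$pair_class[p2$lnc_id == "l1"], "none")
  # zero-variance profiles are skipped and logged
  expr3 <- expr
  expr3["gA", ] <- 2
  p3 <- lnc_target_pairs(lnc["l1" == lnc$transcript_id, , drop = FALSE],
                         txs, coding, expr3)
  expect_equal(nrow(p3), 0L)
  expect_match(attr(p3, "skipped"), "l1", all = FALSE)
})
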