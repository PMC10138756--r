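test_that("end clustering flags alternative starts at the tolerance", {
  txs <- list(tx("a", c(100, 500)), tx("b", c(103, 510)),
              tx("c", c(250, 520)))
  ce <- cluster_ends(txs, "TSS", 50L)
  expect_equal(nrow(ce$clusters), 2L)
  expect_true(ce$alternative)
  ce2 <- cluster_ends(txs[1:2], "TSS", 50L)
  expect_equal(nrow(ce2$clusters), 1L)
  expect_false(ce2$alternative)
  # minus strand: the TSS is the genomic right end
  minus <- list(tx("a", c(100, 500), "-"), tx("b", c(100, 900), "-"))
  expect_true(cluster_ends(minus, "TSS", 50L)$alternative)
  expect_false(cluster_ends(minus, "TTS", 50L)$alternative)
})

test_that("the number of end clusters is non-increasing in tolerance", {
  set.seed(71)
  for (i in 1:8) {
    txs <- random_locus(n_tx = 5L)
    n_prev <- Inf
    for (tol in c(5L, 20L, 80L, 320L)) {
      n <- nrow(cluster_ends(txs, "TSS", tol)$clusters)
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("poly(A) calls follow the windowed A-content rule exactly", {
  mk <- function(tail) call_polya(paste0(strrep("G", 40), tail), 40L)
  expect_true(mk(strrep("A", 30))$tail_detected)
  # 28 A + 2 non-A in 30: violates 'fewer than two non-A'
  expect_false(mk(paste0(strrep("A", 28), "GG"))$tail_detected)
  # 7 A: violates 'at least eight adenines'
  expect_false(mk(strrep("A", 7))$tail_detected)
  # 29 A + 1 non-A passes
  expect_true(mk(paste0(strrep("A", 29), "C"))$tail_detected)
  # 8 A in an 8-nt terminal segment passes (short segment evaluated as-is)
  expect_true(mk(strrep("A", 8))$tail_detected)
  # sliding window finds a clean stretch after a dirty prefix
  dirty <- paste0("CGCGCGCG", strrep("A", 30))
  expect_true(mk(dirty)$tail_detected)
  # anchored mode only examines the window at the clip start
  r <- call_polya(paste0(strrep("G", 40), dirty), 40L, mode = "anchored")
  expect_false(r$tail_detected)
})

test_that("poly(A) calls agree with the brute-force rule on random tails", {
  set.seed(31)
  for (i in 1:300) {
    len <- sample(1:60, 1L)
    t <- paste(sample(c("A", "A", "A", "C", "G", "T"), len,
                      replace = TRUE), collapse = "")
    got <- call_polya(paste0("GGGG", t), 4L)$tail_detected
    expect_equal(got, oracle_tail_rule(t), info = t)
  }
})

test_that("cleavage sites are strand-adjusted and need an alignment", {
  r <- call_polya(paste0(strrep("G", 10), strrep("A", 20)), 10L,
                  chrom = "chr1", strand = "+", aln_start = 100L,
                  aln_end = 110L)
  expect_equal(r$cleavage_site, 110L)
  r <- call_polya(paste0(strrep("G", 10), strrep("A", 20)), 10L,
                  chrom = "chr1", strand = "-", aln_start = 100L,
                  aln_end = 110L)
  expect_equal(r$cleavage_site, 99L)
  r <- call_polya(strrep("A", 40), 40L)
  expect_true(is.na(r$cleavage_site))
})

test_that("read-level cleavage sites collapse into per-gene sites", {
  txs <- list(tx("a", c(900, 1000), gene = "g"),
              tx("b", c(900, 1010)),
              tx("c", c(900, 1100)))
  loci <- build_loci(txs)
  calls <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    tail_detected = c(TRUE, TRUE, TRUE, FALSE),
    a_count = 30L, non_a_count = 0L, window_len = 30L,
    chrom = "chr1", strand = "+",
    cleavage_site = c(1000L, 1010L, 1100L, 1100L),
    aligned = TRUE, stringsAsFactors = FALSE)
  ps <- polya_sites_per_gene(calls, loci, collapse_tol_nt = 24L)
  # 1000 and 1010 merge; 1100 stands alone; the tail-less read is ignored
  expect_equal(nrow(ps$per_gene), 2L)
  expect_equal(ps$sites_per_gene$n_sites, 2L)
  expect_equal(ps$histogram$n_genes[ps$histogram$n_sites == 2L], 1L)
})

test_that("composition profiles are simplex rows in transcript orientation", {
  g <- c(chr1 = strrep("T", 200))
  prof <- composition_profile(data.frame(chrom = "chr1", strand = "+",
                                         site = 100L), g)
  expect_true(all(prof$T == 1))
  expect_true(all(abs(rowSums(prof[, c("A", "C", "G", "T")]) - 1) < 1e-12))
  # minus strand reads the reverse complement
  prof2 <- composition_profile(data.frame(chrom = "chr1", strand = "-",
                                          site = 100L), g)
  expect_true(all(prof2$A == 1))
  # planted A-rich block upstream on the transcript strand
  gg <- strrep("C", 200)
  substr(gg, 100 - 20 + 1, 100 - 11 + 1) <- strrep("A", 10)
  prof3 <- composition_profile(data.frame(chrom = "chr1", strand = "+",
                                          site = 100L), c(chr1 = gg))
  expect_true(all(prof3$A[prof3$offset %in% -20:-11] == 1))
  expect_true(all(prof3$A[prof3$offset %in% -5:0] == 0))
})

test_that("planted upstream motifs rank first; self-background is flat", {
  set.seed(12)
  gg <- random_genome(40000, seed = 12)
  sites <- data.frame(chrom = "chr1", strand = "+",
                      site = seq(1000, 39000, length.out = 60))
  for (i in seq_len(nrow(sites))) {
    if (i %% 10 < 7)  # 70% carry the signal
      substr(gg, sites$site[i] - 24, sites$site[i] - 19) <- "AATAAA"
  }
  g <- c(chr1 = gg)
  enr <- upstream_kmer_enrichment(sites, g, k = 6L, seed = 5L)
  expect_equal(enr$kmer[1L], "AATAAA")
  expect_gt(enr$fold[1L], 2)
  # background = the observed windows themselves: every fold is exactly 1
  wins <- substring(gg, sites$site - 50 + 1, sites$site)
  self <- upstream_kmer_enrichment(sites, g, k = 6L, seed = 5L,
                                   background = wins)
  expect_true(all(abs(self$fold - 1) < 1e-12))
  expect_true(all(self$p_value > 0.05 | self$observed == 0))
})

test_that("coupling table partitions the multi-isoform gene set", {
  flags <- data.frame(gene_id = paste0("g", 1:6),
                      has_AS = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                      has_aTSS = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                      has_aTTS = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
                      is_DEG = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  cv <- coupling_venn(flags)
  expect_equal(sum(cv$venn$n_genes), 6L)
  expect_equal(cv$n_genes, 6L)
  all_false <- cv$venn[!cv$venn$has_AS & !cv$venn$has_aTSS &
                         !cv$venn$has_aTTS & !cv$venn$is_DEG, ]
  expect_equal(all_false$n_genes, 1L)
  expect_error(coupling_venn(flags[, 1:3]), "columns")
})
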