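test_that("loci group by single-linkage exonic overlap, strand-aware", {
  t1 <- tx("a", c(0, 100, 200, 300))
  t2 <- tx("b", c(50, 120))           # overlaps a
  t3 <- tx("c", c(0, 100, 200, 300), "-")  # same coords, other strand
  ls <- build_loci(list(t1, t2, t3))
  expect_length(ls$loci, 2L)
  expect_setequal(ls$tx2locus[c("a", "b")],
                  rep(ls$tx2locus[["a"]], 2))
  expect_false(ls$tx2locus[["c"]] == ls$tx2locus[["a"]])
  # transitive chain: A-B overlap, B-C overlap, A and C disjoint
  a <- tx("A", c(0, 100))
  b <- tx("B", c(50, 250))
  c_ <- tx("C", c(200, 400))
  ls2 <- build_loci(list(a, b, c_))
  expect_length(ls2$loci, 1L)
  expect_setequal(ls2$loci[[1L]]$transcript_ids, c("A", "B", "C"))
})

test_that("build_loci matches brute-force transitive closure on random sets", {
  closure_groups <- function(txs) {
    n <- length(txs)
    ov <- function(t, u) {
      if (t$chrom != u$chrom || t$strand != u$strand) return(FALSE)
    any(outer(seq_len(nrow(t$exons)), seq_len(nrow(u$exons)),
              Vectorize(function(i, j)
                max(t$exons[i, 1L], u$exons[j, 1L]) <
                  min(t$exons[i, 2L], u$exons[j, 2L]))))
    }
    adj <- outer(seq_len(n), seq_len(n),
                 Vectorize(function(i, j) ov(txs[[i]], txs[[j]])))
    reach <- adj | diag(n)
    for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ])
    comp <- apply(reach, 1L, function(r) min(which(r)))
    split(vapply(txs, `[[`, character(1), "transcript_id"), comp)
  }
  set.seed(20)
  for (rep in 1:12) {
    n <- sample(3:20, 1L)
    txs <- lapply(seq_len(n), function(i) {
      s <- sample(1:3000, 1L)
      tx(paste0("t", i), c(s, s + sample(50:400, 1L)),
         strand = sample(c("+", "-"), 1L))
    })
    ls <- build_loci(txs)
    got <- split(names(ls$tx2locus), ls$tx2locus)
    want <- closure_groups(txs)
    norm <- function(g) sort(unname(vapply(g, function(x)
      paste(sort(x), collapse = ","), character(1))))
    expect_equal(norm(got), norm(want))
  }
})

test_that("isoform categories follow the full-splice-match rule", {
  ref <- list(tx("r1", c(0, 100, 200, 300, 400, 500), gene = "g1"),
              tx("r2", c(1000, 1400), gene = "g2"))
  # exact intron chain, different ends -> known
  known <- tx("q1", c(20, 100, 200, 300, 400, 480))
  # retains intron (100,200) -> novel of annotated
  ir <- tx("q2", c(0, 300, 400, 500))
  # no overlap at all -> novel locus
  far <- tx("q3", c(5000, 5200))
  # antisense overlap only -> novel locus (strand-aware)
  anti <- tx("q4", c(0, 500), "-")
  got <- classify_isoforms(list(known, ir, far, anti), ref)
  expect_equal(got$category,
               c("known", "novel_of_annotated", "novel_locus",
                 "novel_locus"))
  # mono-exon containment with end tolerance
  mono_in <- tx("m1", c(1010, 1390))
  mono_off <- tx("m2", c(1100, 1390))   # start 100 nt off
  got2 <- classify_isoforms(list(mono_in, mono_off), ref,
                            mono_exon_tol = 50L)
  expect_equal(got2$category, c("known", "novel_of_annotated"))
})

test_that("every reference transcript self-classifies as known", {
  set.seed(33)
  ref <- unlist(lapply(1:6, function(i) {
    txs <- random_locus(n_tx = 2L)
    lapply(seq_along(txs), function(j) {
      t <- txs[[j]]
      t$transcript_id <- sprintf("r%d_%d", i, j)
      t$exons <- t$exons + 5000L * i   # separate loci
      t
    })
  }), recursive = FALSE)
  got <- classify_isoforms(ref, ref)
  expect_true(all(got$category == "known"))
})

test_that("category labels partition the observed set", {
  set.seed(44)
  ref <- list(tx("r", c(0, 100, 200, 300), gene = "g"))
  obs <- c(list(tx("o1", c(0, 100, 200, 300)), tx("o2", c(0, 300)),
                tx("o3", c(900, 1100))),
           random_locus(n_tx = 2L))
  got <- classify_isoforms(obs, ref)
  expect_equal(nrow(got), length(obs))
  expect_true(all(got$category %in%
                    c("known", "novel_of_annotated", "novel_locus")))
})

test_that("per-gene statistics count isoforms and exons exactly", {
  txs <- list(tx("a", c(0, 100, 200, 300), gene = "g"),
              tx("b", c(0, 100, 200, 300, 400, 500)),
              tx("solo", c(9000, 9100)))
  ls <- build_loci(txs)
  st <- per_gene_stats(ls)
  expect_equal(nrow(st), 2L)
  big <- st[st$n_isoforms == 2L, ]
  expect_equal(big$max_exons, 3L)
  expect_equal(big$mean_exons, 2.5)
  expect_equal(big$mean_mrna_length, (200 + 300) / 2)
  solo <- st[st$n_isoforms == 1L, ]
  expect_equal(solo$max_exons, 1L)
  expect_equal(solo$mean_mrna_length, 100)
})

test_that("tissue specificity thresholds FPKM at the boundary", {
  m <- rbind(one = c(5, 0, 0, 0, 0, 0, 0),
             all = c(2, 3, 1, 5, 8, 1, 1),
             sub = c(0.9, 0, 0, 0, 0, 0, 0))
  colnames(m) <- paste0("s", 1:7)
  ts <- tissue_specificity(m, threshold_fpkm = 1)
  per <- ts$per_isoform
  expect_true(per$specific[per$id == "one"])
  expect_equal(per$samples[per$id == "one"], "s1")
  expect_equal(per$n_expressed[per$id == "all"], 7L)
  expect_false(per$specific[per$id == "all"])
  expect_equal(per$n_expressed[per$id == "sub"], 0L)
  expect_equal(sum(ts$overlap_counts$n_isoforms), nrow(m))
  expect_error(tissue_specificity(-m), "negative")
})
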