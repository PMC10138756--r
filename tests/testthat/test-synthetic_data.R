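# Small corpus used by several blocks (40 genes keeps generation ~1 s)
small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 40L, n_lincrnas = 8L, n_lncnats = 4L,
             chrom_length = 400000L, ...)
}

test_that("identical seeds give byte-identical corpora", {
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  simulate_corpus(small_cfg(seed = 7L), d1)
  simulate_corpus(small_cfg(seed = 7L), d2)
  for (f in c("genome.fa", "reference.gtf", "observed.gtf", "flnc.fastq",
              "flnc_alignments.bed12", "counts.tsv", "domains.tsv",
              "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  d3 <- file.path(tempdir(), "simC")
  simulate_corpus(small_cfg(seed = 8L), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("planting rates control the truth tables", {
  d <- file.path(tempdir(), "sim_noir")
  sim <- simulate_corpus(small_cfg(
    seed = 3L, as_rates = c(IR = 0, ES = 0.1, A3SS = 0.1, A5SS = 0.1,
                            MXE = 0.1)), d)
  expect_false("IR" %in% sim$truth$events$event_type)
  counts <- table(sim$truth$events$event_type)
  expect_equal(unname(counts[c("ES", "A3SS", "A5SS", "MXE")]),
               rep(4L, 4L), ignore_attr = TRUE)
  # planted event rows all reference emitted genes
  expect_true(all(sim$truth$events$gene_id %in% sim$truth$genes$gene_id))
  # end flags partition: counts match the configured rates
  expect_equal(sum(sim$truth$ends$atss), round(0.3 * 40))
})

test_that("generated models validate and splice boundaries are canonical", {
  d <- file.path(tempdir(), "sim_valid")
  sim <- simulate_corpus(small_cfg(seed = 5L), d)
  obs <- read_annotation(file.path(d, "observed.gtf"), "gtf")
  expect_equal(length(obs), length(sim$observed))
  genome <- read_genome(file.path(d, "genome.fa"))
  bd <- boundary_dinucleotides(obs, genome)
  expect_equal(bd$fraction_canonical, 1)
})

test_that("pure tails always satisfy the poly(A) rule; impure tails can fail", {
  d <- file.path(tempdir(), "sim_tails")
  sim <- simulate_corpus(small_cfg(seed = 2L, tail_impurity = 0,
                                   tail_len_range = c(30L, 30L)), d)
  fq <- Biostrings::readDNAStringSet(file.path(d, "flnc.fastq"),
                                     format = "fastq")
  reads <- setNames(as.character(fq), sub("\\s.*$", "", names(fq)))
  aln <- read_alignments_bed12(file.path(d, "flnc_alignments.bed12"))
  calls <- call_polya_batch(reads, aln)
  expect_true(all(calls$tail_detected))
  expect_true(all(calls$aligned))
})

test_that("expression realizes planted clusters and correlations", {
  d <- file.path(tempdir(), "sim_expr")
  sim <- simulate_corpus(small_cfg(seed = 9L), d)
  f <- sim$fpkm
  tl <- sim$truth$lncrnas
  cl <- cluster_profiles(f[tl$lnc_id, ], k = 2L, seed = 1L)
  expect_equal(mclust::adjustedRandIndex(cl$assignment[tl$lnc_id],
                                         tl$cluster), 1)
  # planted lncRNA-target pairs correlate strongly at gene level
  iso <- sim$truth$isoforms
  coding <- iso[iso$gene_id %in% sim$truth$genes$gene_id, ]
  gene_f <- rowsum(f[coding$transcript_id, ], group = coding$gene_id)
  r <- vapply(seq_len(nrow(tl)), function(i)
    stats::cor(f[tl$lnc_id[i], ], gene_f[tl$target_gene[i], ]),
    numeric(1))
  expect_true(mean(r > 0.6) >= 0.9)
})

test_that("scoring handles perfect, empty and noisy outputs", {
  d <- file.path(tempdir(), "sim_score")
  sim <- simulate_corpus(small_cfg(seed = 4L), d)
  tev <- sim$truth$events
  perfect <- data.frame(event_type = tev$event_type, chrom = tev$chrom,
                        anchor_start = tev$anchor_start,
                        anchor_end = tev$anchor_end,
                        stringsAsFactors = FALSE)
  sc <- score_against_truth(list(events = perfect), sim$truth)
  vals <- sc$value[grepl("^events_", sc$stage)]
  expect_true(all(vals == 1))
  empty <- perfect[0, ]
  sc0 <- score_against_truth(list(events = empty), sim$truth)
  expect_true(all(sc0$value[sc0$metric == "recall"] == 0))
  expect_true(all(is.na(sc0$value[sc0$metric == "precision"])))
  # one spurious IR among the n correct ones: precision n/(n+1)
  spur <- rbind(perfect,
                data.frame(event_type = "IR", chrom = "chr1",
                           anchor_start = 1L, anchor_end = 2L))
  scs <- score_against_truth(list(events = spur), sim$truth)
  n_ir <- sum(perfect$event_type == "IR")
  expect_equal(scs$value[scs$stage == "events_IR" &
                           scs$metric == "precision"],
               n_ir / (n_ir + 1))
  expect_equal(scs$value[scs$stage == "events_IR" & scs$metric == "recall"],
               1)
})

test_that("coding/noncoding sequence sets are seeded and class-separable", {
  s1 <- simulate_coding_noncoding(n = 10L, seed = 21L)
  s2 <- simulate_coding_noncoding(n = 10L, seed = 21L)
  expect_identical(s1, s2)
  # shuffles preserve mononucleotide composition
  comp <- function(x) sort(table(strsplit(x, "")[[1L]]))
  for (i in 1:5)
    expect_equal(comp(s1$coding[i]), comp(s1$noncoding[i]))
})
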