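test_that("intron chains are the gaps between exons", {
  expect_equal(unname(intron_chain(tx("a", c(100, 200, 300, 400)))),
               matrix(c(200L, 300L), ncol = 2))
  expect_equal(nrow(intron_chain(tx("b", c(0, 500)))), 0L)
  ic <- intron_chain(tx("c", c(0, 10, 20, 30, 40, 50)))
  expect_equal(unname(ic), matrix(c(10L, 20L, 30L, 40L), ncol = 2,
                                  byrow = TRUE))
})

test_that("canonical event configurations are typed correctly", {
  # intron retention
  ev <- detect_events(list(tx("t1", c(0, 100, 200, 300)),
                           tx("t2", c(0, 300))))
  expect_equal(ev$event_type, "IR")
  expect_equal(c(ev$anchor_start, ev$anchor_end), c(100L, 200L))
  expect_equal(ev$inclusion, "t2")   # t2 retains the intron
  expect_equal(ev$exclusion, "t1")
  # exon skipping
  ev <- detect_events(list(tx("t1", c(0, 100, 200, 250, 300, 400)),
                           tx("t2", c(0, 100, 300, 400))))
  expect_equal(ev$event_type, "ES")
  expect_equal(c(ev$anchor_start, ev$anchor_end), c(100L, 300L))
  expect_equal(ev$inclusion, "t1")
  # mutually exclusive exons
  ev <- detect_events(list(tx("t1", c(0, 100, 200, 250, 500, 600)),
                           tx("t2", c(0, 100, 300, 380, 500, 600))))
  expect_equal(ev$event_type, "MXE")
  expect_equal(c(ev$anchor_start, ev$anchor_end), c(100L, 500L))
})

test_that("alternative donor/acceptor typing swaps with strand", {
  plus <- list(tx("t1", c(0, 100, 200, 300)),
               tx("t2", c(0, 120, 200, 300)))
  ev <- detect_events(plus)
  expect_equal(ev$event_type, "A5SS")
  expect_equal(c(ev$anchor_start, ev$anchor_end), c(100L, 120L))
  minus <- list(tx("t1", c(0, 100, 200, 300), "-"),
                tx("t2", c(0, 120, 200, 300), "-"))
  ev <- detect_events(minus)
  expect_equal(ev$event_type, "A3SS")
  # shared donor on + = A3SS
  ev <- detect_events(list(tx("t1", c(0, 100, 200, 300)),
                           tx("t2", c(0, 100, 220, 300))))
  expect_equal(ev$event_type, "A3SS")
})

test_that("detection is symmetric and translation-invariant", {
  set.seed(61)
  for (i in 1:10) {
    txs <- random_locus()
    fwd <- detect_events(txs)$anchor_key
    rev_ <- detect_events(rev(txs))$anchor_key
    expect_setequal(fwd, rev_)
    shift <- 1234L
    shifted <- lapply(txs, function(t) { t$exons <- t$exons + shift; t })
    sk <- detect_events(shifted)
    expect_setequal(paste(sk$event_type, sk$anchor_start - shift,
                          sk$anchor_end - shift),
                    paste(detect_events(txs)$event_type,
                          detect_events(txs)$anchor_start,
                          detect_events(txs)$anchor_end))
  }
})

test_that("detection equals the brute-force enumerator on random loci", {
  set.seed(97)
  for (i in 1:60) {
    txs <- random_locus()
    got <- sort(detect_events(txs)$anchor_key)
    want <- oracle_event_keys(txs)
    expect_equal(got, want)
  }
})

test_that("inclusion and exclusion transcript sets are disjoint", {
  set.seed(15)
  for (i in 1:10) {
    ev <- detect_events(random_locus())
    if (nrow(ev) == 0L) next
    for (r in seq_len(nrow(ev))) {
      inc <- strsplit(ev$inclusion[r], ",")[[1L]]
      exc <- strsplit(ev$exclusion[r], ",")[[1L]]
      expect_length(intersect(inc, exc), 0L)
      expect_gt(length(inc), 0L)
      expect_gt(length(exc), 0L)
    }
  }
})

test_that("splice-site offsets use the dominant site and strand signs", {
  # donors at 100 (3 isoforms) and 104 (1), shared acceptor 200
  txs <- list(tx("a", c(0, 100, 200, 300)), tx("b", c(0, 100, 200, 300)),
              tx("c", c(0, 100, 200, 300)), tx("d", c(0, 104, 200, 300)))
  off <- splice_site_offsets(txs)
  expect_equal(off$site_kind, "donor")
  expect_equal(off$dominant_pos, 100L)
  expect_equal(off$offset, 4L)
  expect_equal(off$n_dominant, 3L)
  # tie 2 vs 2: dominant is the 5'-most in transcript orientation
  tie <- list(tx("a", c(0, 100, 200, 300)), tx("b", c(0, 100, 200, 300)),
              tx("c", c(0, 104, 200, 300)), tx("d", c(0, 104, 200, 300)))
  off <- splice_site_offsets(tie)
  expect_equal(off$dominant_pos, 100L)
  # on the minus strand the same sites flip kind, dominance and sign
  tiem <- lapply(tie, function(t) { t$strand <- "-"; t })
  offm <- splice_site_offsets(tiem)
  expect_equal(offm$site_kind, "acceptor")
  expect_equal(offm$dominant_pos, 104L)
  expect_equal(offm$offset, 4L)   # 100 is downstream of 104 on minus
})

test_that("boundary dinucleotides are strand-aware and canonical GT..AG", {
  #            0....5....1....5....2....5....3
  g <- c(chr1 = "AAAAAGTCCCCCCCCAGAAAAAAAAAAAAA")
  plus <- tx("p", c(0, 5, 17, 25))       # intron (5,17): GT ... AG
  bd <- boundary_dinucleotides(list(plus), g)
  expect_equal(bd$per_intron$donor, "GT")
  expect_equal(bd$per_intron$acceptor, "AG")
  expect_true(bd$per_intron$canonical)
  # minus strand: genomic CT..AC reads GT..AG in transcript orientation
  gm <- c(chr1 = "AAAAACTCCCCCCCCACAAAAAAAAAAAAA")
  minus <- tx("m", c(0, 5, 17, 25), "-")
  bdm <- boundary_dinucleotides(list(minus), gm)
  expect_equal(bdm$per_intron$donor, "GT")
  expect_equal(bdm$per_intron$acceptor, "AG")
  expect_true(bdm$per_intron$canonical)
  # GC..AG is counted but not canonical
  gc <- c(chr1 = "AAAAAGCCCCCCCCCAGAAAAAAAAAAAAA")
  bdn <- boundary_dinucleotides(list(plus), gc)
  expect_false(bdn$per_intron$canonical)
  expect_equal(bdn$fraction_canonical, 0)
})

test_that("structure correlations recover planted monotone relations", {
  gs <- data.frame(gene_id = paste0("g", 1:20),
                   n_isoforms = 1:20, max_exons = 1:20,
                   mean_mrna_length = seq(500, 2400, by = 100),
                   mean_exon_length = seq(400, 20, length.out = 20),
                   mean_gc = seq(0.6, 0.3, length.out = 20))
  res <- as_structure_correlation(gs)
  co <- res$correlations
  expect_equal(co$rho[co$variable == "exon_number"], 1)
  expect_equal(co$rho[co$variable == "exon_length"], -1)
  expect_equal(co$rho[co$variable == "gc_content"], -1)
  # constant isoform count -> undefined, reported as NA
  gs$n_isoforms <- 3L
  co2 <- as_structure_correlation(gs)$correlations
  expect_true(all(is.na(co2$rho)))
  expect_error(as_structure_correlation(gs[1:2, ]), "3 genes")
})

test_that("PSI, Fisher p-values and DAS calls follow the definitions", {
  inc <- rbind(e1 = c(a = 2L, b = 0L), e2 = c(a = 10L, b = 10L),
               e3 = c(a = 0L, b = 5L))
  exc <- rbind(e1 = c(a = 0L, b = 2L), e2 = c(a = 10L, b = 10L),
               e3 = c(a = 0L, b = 5L))
  d <- differential_splicing(inc, exc, pairs = cbind("a", "b"))
  # exhaustive hypergeometric sum for [[2,0],[0,2]]: p = 2/6
  expect_equal(d$p_value[d$event == "e1"], 1 / 3)
  expect_equal(d$psi1[d$event == "e1"], 1)
  expect_equal(d$psi2[d$event == "e1"], 0)
  # identical counts: delta PSI 0, never DAS
  expect_equal(d$delta_psi[d$event == "e2"], 0)
  expect_false(d$das[d$event == "e2"])
  # zero total in one sample: skipped and logged
  expect_false("e3" %in% d$event)
  expect_match(attr(d, "skipped"), "e3", all = FALSE)
})

test_that("BH q-values are monotone in p-rank and bounded below by p", {
  set.seed(8)
  n <- 200L
  inc1 <- rbinom(n, 60, 0.5); inc2 <- rbinom(n, 60, runif(n, 0.3, 0.7))
  inc <- cbind(a = inc1, b = inc2)
  exc <- cbind(a = 60L - inc1, b = 60L - inc2)
  rownames(inc) <- rownames(exc) <- paste0("e", seq_len(n))
  d <- differential_splicing(inc, exc, pairs = cbind("a", "b"))
  expect_true(all(d$q_value >= d$p_value))
  ord <- order(d$p_value)
  expect_true(all(diff(d$q_value[ord]) >= -1e-12))
})
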