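# Seeded synthetic corpus generator with machine-readable ground truth.
#
# The generator emulates the data structure the analysis assumes: multi-exon
# gene loci on a small random genome with canonical GT..AG introns; observed
# isoforms derived from each reference isoform by planting typed AS events
# (IR/ES/A3SS/A5SS/MXE), alternative TSS/TTS shifts, intergenic and antisense
# lncRNA loci; error-free full-length reads carrying poly(A) tails so the
# windowed tail rule fires; a polyadenylation-signal motif written upstream
# of every planted cleavage site at a configured rate; an isoform-by-sample
# count matrix realizing planted expression clusters, planted DEGs and
# planted lncRNA-target correlations; and per-isoform domain tables with
# planted losses/gains. All randomness derives from one seed: identical
# seeds give byte-identical corpora.

#' Default simulation configuration
#'
#' @param seed master RNG seed; every corpus quantity derives from it.
#' @param ... overrides for any default field (unknown names are an error).
#' @return named list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = 2L,
    chrom_length = 1500000L,
    gc = 0.43,
    n_genes = 200L,
    mono_exon_frac = 0.10,
    exon_count_range = c(4L, 8L),
    exon_len_range = c(90L, 250L),
    intron_len_range = c(250L, 500L),
    gene_spacing = 2500L,
    as_rates = c(IR = 0.15, ES = 0.10, A3SS = 0.12, A5SS = 0.12,
                 MXE = 0.10),
    atss_rate = 0.30,
    atts_rate = 0.30,
    end_shift = 200L,
    ss_shift_range = c(3L, 6L),
    mxe_exon_len_range = c(60L, 100L),
    n_reads_per_isoform = 3L,
    tail_len_range = c(25L, 45L),
    tail_impurity = 0.01,
    n_lincrnas = 25L,
    n_lncnats = 10L,
    lnc_exon_len_range = c(250L, 400L),
    polya_motif = "AATAAA",
    motif_rate = 0.70,
    samples = c("B1", "R", "L", "B2", "OR", "S1", "S2"),
    n_expr_clusters = 2L,
    lnc_high_fpkm = 50,
    lnc_low_fpkm = 2,
    deg_rate = 0.30,
    deg_fold = 8,
    noise_sd_log2 = 0.10,
    domain_alphabet = paste0("DOM_", LETTERS[1:5]),
    domain_loss_rate = 0.35,
    domain_gain_rate = 0.25)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) .fail("unknown config field(s): %s",
                         paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  for (r in c("as_rates", "atss_rate", "atts_rate", "motif_rate",
              "tail_impurity", "deg_rate", "domain_loss_rate",
              "domain_gain_rate"))
    if (any(cfg[[r]] < 0) || any(cfg[[r]] > 1))
      .fail("config rate %s out of [0, 1]", r)
  structure(cfg, class = c("sim_config", "list"))
}

# random interval sample helper
.runit <- function(range) {
  if (range[1L] >= range[2L]) return(as.integer(range[1L]))
  sample(seq(range[1L], range[2L]), 1L)
}

# GC3-biased sense-codon pool (weights favor G/C third positions), shared by
# the corpus generator and simulate_coding_noncoding()
.codon_pool <- function() {
  gcode <- Biostrings::GENETIC_CODE
  sense <- names(gcode)[gcode != "*"]
  list(codons = sense,
       w = ifelse(substr(sense, 3L, 3L) %in% c("G", "C"), 3, 1))
}

# codon-structured mRNA of exactly `len` nt: 5' UTR, ATG + biased codons +
# TAA, 3' UTR
.codon_mrna <- function(len) {
  utr5 <- min(24L, max(0L, len - 66L))
  rest <- len - utr5
  ncod <- max(1L, (rest - 45L) %/% 3L - 2L)
  pool <- .codon_pool()
  cds <- paste(c("ATG",
                 sample(pool$codons, ncod, replace = TRUE, prob = pool$w),
                 "TAA"), collapse = "")
  utr3 <- len - utr5 - nchar(cds)
  if (utr3 < 0L) { cds <- substr(cds, 1L, len - utr5); utr3 <- 0L }
  rnt <- function(k) if (k > 0L)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  else ""
  paste0(rnt(utr5), cds, rnt(utr3))
}

#' Generate a synthetic corpus with ground truth
#'
#' Writes `genome.fa`, `reference.gtf`, `observed.gtf`, `flnc.fastq`,
#' `flnc_alignments.bed12`, `counts.tsv`, `domains.tsv`, `go_map.tsv`,
#' `paralog_pairs.tsv` and `truth.json` under `out_dir` and returns the
#' truth tables invisibly augmented with in-memory objects.
#'
#' @param config a [sim_config()] list.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `truth`, `paths`, plus the in-memory
#'   `genome`, `reference`, `observed` transcript lists and `counts` matrix.
#' @export
simulate_corpus <- function(config = sim_config(), out_dir) {
  cfg <- config
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  margin <- cfg$end_shift + 100L

  ## ---- gene structures ----------------------------------------------------
  n_mono <- round(cfg$mono_exon_frac * cfg$n_genes)
  is_mono <- c(rep(TRUE, n_mono), rep(FALSE, cfg$n_genes - n_mono))
  is_mono <- sample(is_mono)
  # interleave lincRNA loci among the coding genes so each has a nearby gene
  kinds <- c(rep("coding", cfg$n_genes), rep("linc", cfg$n_lincrnas))
  kinds <- sample(kinds)
  cursor <- stats::setNames(rep(1000L + margin, length(chroms)), chroms)
  chrom_i <- 0L
  genes <- list()    # coding gene records
  lincs <- list()    # lincRNA records
  gi <- 0L; li <- 0L
  for (kind in kinds) {
    chrom_i <- chrom_i %% length(chroms) + 1L
    chrom <- chroms[chrom_i]
    strand <- sample(c("+", "-"), 1L)
    if (kind == "coding") {
      gi <- gi + 1L
      nex <- if (is_mono[gi]) 1L else .runit(cfg$exon_count_range)
      elens <- vapply(seq_len(nex), function(i) .runit(cfg$exon_len_range),
                      integer(1))
      ilens <- if (nex > 1L)
        vapply(seq_len(nex - 1L), function(i) .runit(cfg$intron_len_range),
               integer(1)) else integer(0)
      start <- cursor[[chrom]]
      starts <- start + cumsum(c(0L, elens[-nex] + ilens))
      exons <- cbind(starts, starts + elens)
      genes[[gi]] <- list(gene_id = sprintf("GENE%04d", gi), chrom = chrom,
                          strand = strand, exons = exons)
      cursor[[chrom]] <- exons[nex, 2L] + cfg$gene_spacing
    } else {
      li <- li + 1L
      nex <- sample(1:2, 1L)
      elens <- vapply(seq_len(nex), function(i)
        .runit(cfg$lnc_exon_len_range), integer(1))
      ilens <- if (nex > 1L) .runit(cfg$intron_len_range) else integer(0)
      start <- cursor[[chrom]]
      starts <- start + cumsum(c(0L, (elens[-nex] + ilens)[seq_len(nex - 1L)]))
      exons <- cbind(starts, starts + elens)
      lincs[[li]] <- list(lnc_id = sprintf("LNC.%d.1", li), chrom = chrom,
                          strand = strand, exons = exons, class = "lincRNA")
      cursor[[chrom]] <- exons[nex, 2L] + cfg$gene_spacing
    }
  }
  if (any(cursor > cfg$chrom_length - margin))
    .fail("infeasible geometry: genes overflow chromosome length %d",
          cfg$chrom_length)

  ## ---- event assignment ---------------------------------------------------
  n_ex_of <- vapply(genes, function(g) nrow(g$exons), integer(1))
  eligible <- which(n_ex_of >= 4L)
  eligible <- sample(eligible)     # shuffled pool, drawn without replacement
  as_counts <- round(cfg$as_rates * cfg$n_genes)
  if (sum(as_counts) > length(eligible))
    .fail("not enough multi-exon genes for the requested AS planting rates")
  as_gene <- stats::setNames(rep(NA_character_, length(genes)),
                             vapply(genes, `[[`, character(1), "gene_id"))
  taken <- 0L
  for (tp in names(as_counts)) {
    idx <- eligible[seq_len(as_counts[[tp]]) + taken]
    taken <- taken + as_counts[[tp]]
    as_gene[idx] <- tp
  }
  atss_genes <- sort(sample(seq_along(genes),
                            round(cfg$atss_rate * cfg$n_genes)))
  atts_genes <- sort(sample(seq_along(genes),
                            round(cfg$atts_rate * cfg$n_genes)))

  ## ---- derive isoforms and plant events -----------------------------------
  edits <- list()   # genome edits: list(chrom, pos0, seq)
  add_edit <- function(chrom, pos0, s)
    edits[[length(edits) + 1L]] <<- list(chrom = chrom, pos0 = pos0, s = s)
  plant_splice <- function(chrom, strand, s, e) {
    if (strand == "+") { add_edit(chrom, s, "GT"); add_edit(chrom, e - 2L, "AG") }
    else { add_edit(chrom, s, "CT"); add_edit(chrom, e - 2L, "AC") }
  }
  truth_events <- list()
  observed <- list()
  obs_meta <- list()  # per observed isoform: gene, kind
  add_obs <- function(id, gene_id, chrom, strand, exons, kind) {
    observed[[length(observed) + 1L]] <<- transcript_model(
      id, chrom, strand, exons, gene_id = paste0("PBG_", gene_id))
    obs_meta[[length(obs_meta) + 1L]] <<- list(id = id, gene = gene_id,
                                               kind = kind)
  }
  reference <- list()
  for (g in seq_along(genes)) {
    gn <- genes[[g]]
    exons <- gn$exons
    nex <- nrow(exons)
    introns <- if (nex > 1L) cbind(exons[-nex, 2L], exons[-1L, 1L]) else
      matrix(integer(0), ncol = 2L)
    for (k in seq_len(nrow(introns)))
      plant_splice(gn$chrom, gn$strand, introns[k, 1L], introns[k, 2L])
    # write a codon-structured mRNA across the reference exons so that the
    # gene's isoforms carry protein-coding sequence signal
    mrna <- .codon_mrna(sum(exons[, 2L] - exons[, 1L]))
    gseq <- if (gn$strand == "-") revcomp(mrna) else mrna
    off <- 0L
    for (k in seq_len(nex)) {
      w <- exons[k, 2L] - exons[k, 1L]
      add_edit(gn$chrom, exons[k, 1L], substr(gseq, off + 1L, off + w))
      off <- off + w
    }
    ref_id <- paste0(gn$gene_id, ".t1")
    reference[[length(reference) + 1L]] <- transcript_model(
      ref_id, gn$chrom, gn$strand, exons, gene_id = gn$gene_id)
    iso_n <- 1L
    add_obs(sprintf("PB.%d.%d", g, iso_n), gn$gene_id, gn$chrom, gn$strand,
            exons, "reference_copy")
    tp <- as_gene[[g]]
    if (!is.na(tp)) {
      iso_n <- iso_n + 1L
      id <- sprintf("PB.%d.%d", g, iso_n)
      nin <- nrow(introns)
      mid_in <- max(1L, nin %/% 2L)
      if (tp == "IR") {
        i <- mid_in
        ex2 <- exons
        ex2[i, 2L] <- ex2[i + 1L, 2L]
        ex2 <- ex2[-(i + 1L), , drop = FALSE]
        anchor <- introns[i, ]
      } else if (tp == "ES") {
        k <- 1L + max(1L, (nex - 2L) %/% 2L)   # a middle internal exon
        ex2 <- exons[-k, , drop = FALSE]
        anchor <- c(introns[k - 1L, 1L], introns[k, 2L])
      } else if (tp == "A5SS" || tp == "A3SS") {
        i <- mid_in
        delta <- .runit(cfg$ss_shift_range)
        s <- introns[i, 1L]; e <- introns[i, 2L]
        donor_side <- (tp == "A5SS") == (gn$strand == "+")
        ex2 <- exons
        if (donor_side) {        # shift the genomic-left boundary inward
          news <- s + delta
          ex2[i, 2L] <- news
          plant_splice(gn$chrom, gn$strand, news, e)
          anchor <- c(s, news)
        } else {                 # shift the genomic-right boundary inward
          newe <- e - delta
          ex2[i + 1L, 1L] <- newe
          plant_splice(gn$chrom, gn$strand, s, newe)
          anchor <- c(newe, e)
        }
      } else {                   # MXE
        k <- 1L + max(1L, (nex - 2L) %/% 2L)   # internal exon to swap out
        intr <- c(exons[k, 2L], exons[k + 1L, 1L])  # downstream intron
        mlen <- .runit(cfg$mxe_exon_len_range)
        slack <- (intr[2L] - intr[1L]) - mlen - 24L
        off <- 12L + if (slack > 0L) sample.int(slack, 1L) else 0L
        newex <- c(intr[1L] + off, intr[1L] + off + mlen)
        ex2 <- exons
        ex2[k, ] <- newex
        # flanking introns of the swapped-in exon get canonical boundaries
        plant_splice(gn$chrom, gn$strand, introns[k - 1L, 1L], newex[1L])
        plant_splice(gn$chrom, gn$strand, newex[2L], introns[k, 2L])
        anchor <- c(introns[k - 1L, 1L], introns[k, 2L])
      }
      add_obs(id, gn$gene_id, gn$chrom, gn$strand, ex2, paste0("AS_", tp))
      truth_events[[length(truth_events) + 1L]] <- data.frame(
        event_type = tp, gene_id = gn$gene_id, chrom = gn$chrom,
        strand = gn$strand, anchor_start = anchor[1L],
        anchor_end = anchor[2L], stringsAsFactors = FALSE)
    }
    if (g %in% atss_genes) {
      iso_n <- iso_n + 1L
      ex2 <- exons
      if (gn$strand == "+") ex2[1L, 1L] <- ex2[1L, 1L] - cfg$end_shift
      else ex2[nrow(ex2), 2L] <- ex2[nrow(ex2), 2L] + cfg$end_shift
      add_obs(sprintf("PB.%d.%d", g, iso_n), gn$gene_id, gn$chrom,
              gn$strand, ex2, "aTSS")
    }
    if (g %in% atts_genes) {
      iso_n <- iso_n + 1L
      ex2 <- exons
      if (gn$strand == "+") ex2[nrow(ex2), 2L] <- ex2[nrow(ex2), 2L] + cfg$end_shift
      else ex2[1L, 1L] <- ex2[1L, 1L] - cfg$end_shift
      add_obs(sprintf("PB.%d.%d", g, iso_n), gn$gene_id, gn$chrom,
              gn$strand, ex2, "aTTS")
    }
  }

  ## ---- antisense lncRNAs over coding genes --------------------------------
  nat_hosts <- sample(which(n_ex_of >= 3L), cfg$n_lncnats)
  lncnats <- lapply(seq_along(nat_hosts), function(j) {
    gn <- genes[[nat_hosts[j]]]
    span <- c(gn$exons[2L, 1L] + 10L, gn$exons[3L, 2L] - 10L)
    list(lnc_id = sprintf("NAT.%d.1", j), chrom = gn$chrom,
         strand = setdiff(c("+", "-"), gn$strand), class = "lncNAT",
         exons = matrix(span, ncol = 2L),
         host = gn$gene_id)
  })
  for (l in c(lincs, lncnats)) {
    if (nrow(l$exons) > 1L)   # spliced lncRNAs get canonical introns too
      for (k in seq_len(nrow(l$exons) - 1L))
        plant_splice(l$chrom, l$strand, l$exons[k, 2L], l$exons[k + 1L, 1L])
    add_obs(l$lnc_id, l$lnc_id, l$chrom, l$strand, l$exons,
            paste0("lnc_", l$class))
  }

  ## ---- truth: ends and poly(A) sites --------------------------------------
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  truth_ends <- data.frame(
    gene_id = gene_ids,
    atss = seq_along(genes) %in% atss_genes,
    atts = seq_along(genes) %in% atts_genes, stringsAsFactors = FALSE)
  cleavage_of <- function(t) if (t$strand == "+") .tx_span(t)[2L] else
    .tx_span(t)[1L] - 1L
  obs_gene <- vapply(obs_meta, `[[`, character(1), "gene")
  truth_polya <- lapply(seq_along(genes), function(g) {
    idx <- which(obs_gene == gene_ids[g])
    sort(unique(vapply(observed[idx], cleavage_of, integer(1))))
  })
  names(truth_polya) <- gene_ids
  lnc_sites <- lapply(c(lincs, lncnats), function(l) {
    t <- transcript_model(l$lnc_id, l$chrom, l$strand, l$exons)
    cleavage_of(t)
  })

  ## ---- plant the polyadenylation-signal motif -----------------------------
  mlen <- nchar(cfg$polya_motif)
  all_sites <- data.frame(
    chrom = c(rep(vapply(genes, `[[`, character(1), "chrom"),
                  lengths(truth_polya)),
              vapply(c(lincs, lncnats), `[[`, character(1), "chrom")),
    strand = c(rep(vapply(genes, `[[`, character(1), "strand"),
                   lengths(truth_polya)),
               vapply(c(lincs, lncnats), `[[`, character(1), "strand")),
    site = c(unlist(truth_polya), unlist(lnc_sites)),
    stringsAsFactors = FALSE)
  has_motif <- stats::runif(nrow(all_sites)) < cfg$motif_rate
  for (i in which(has_motif)) {
    d0 <- sample(seq(mlen + 10L, 30L), 1L)  # motif within -30..-10
    if (all_sites$strand[i] == "+")
      add_edit(all_sites$chrom[i], all_sites$site[i] - d0, cfg$polya_motif)
    else
      add_edit(all_sites$chrom[i], all_sites$site[i] + d0 - mlen + 1L,
               revcomp(cfg$polya_motif))
  }

  ## ---- genome -------------------------------------------------------------
  p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
         T = (1 - cfg$gc) / 2)
  ed_chrom <- vapply(edits, `[[`, character(1), "chrom")
  genome <- stats::setNames(vapply(chroms, function(ch) {
    chars <- sample(names(p), cfg$chrom_length, replace = TRUE, prob = p)
    for (ed in edits[ed_chrom == ch])
      chars[ed$pos0 + seq_len(nchar(ed$s))] <-
        strsplit(ed$s, "", fixed = TRUE)[[1L]]
    paste(chars, collapse = "")
  }, character(1)), chroms)

  ## ---- reads --------------------------------------------------------------
  read_ids <- character(0); read_seqs <- character(0)
  bed <- character(0)
  for (i in seq_along(observed)) {
    t <- observed[[i]]
    body <- transcript_sequence(t, genome)
    span <- .tx_span(t)
    sizes <- t$exons[, 2L] - t$exons[, 1L]
    starts <- t$exons[, 1L] - span[1L]
    for (r in seq_len(cfg$n_reads_per_isoform)) {
      tl <- .runit(cfg$tail_len_range)
      tail <- rep("A", tl)
      imp <- stats::runif(tl) < cfg$tail_impurity
      if (any(imp))
        tail[imp] <- sample(c("C", "G", "T"), sum(imp), replace = TRUE)
      rid <- sprintf("read_%s_%d", t$transcript_id, r)
      read_ids <- c(read_ids, rid)
      read_seqs <- c(read_seqs, paste0(body, paste(tail, collapse = "")))
      bed <- c(bed, sprintf(
        "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
        t$chrom, span[1L], span[2L], rid, t$strand, span[1L], span[2L],
        nrow(t$exons), paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(starts, collapse = ","), ",")))
    }
  }

  ## ---- expression ---------------------------------------------------------
  samples <- cfg$samples
  ns <- length(samples)
  obs_ids <- vapply(observed, `[[`, character(1), "transcript_id")
  lnc_all <- c(lincs, lncnats)
  lnc_ids <- vapply(lnc_all, `[[`, character(1), "lnc_id")
  # lncRNA cluster profiles: block-structured high/low patterns
  blocks <- lapply(seq_len(cfg$n_expr_clusters), function(k)
    which(rep(seq_len(cfg$n_expr_clusters),
              each = ceiling(ns / cfg$n_expr_clusters))[seq_len(ns)] == k))
  lnc_cluster <- rep(seq_len(cfg$n_expr_clusters), length.out = length(lnc_all))
  lnc_prof <- t(vapply(seq_along(lnc_all), function(i) {
    pr <- rep(cfg$lnc_low_fpkm, ns)
    pr[blocks[[lnc_cluster[i]]]] <- cfg$lnc_high_fpkm
    pr
  }, numeric(ns)))
  rownames(lnc_prof) <- lnc_ids
  # lincRNA targets: nearest coding gene, profile tied to the lincRNA
  gene_span <- t(vapply(genes, function(gn)
    c(gn$exons[1L, 1L], gn$exons[nrow(gn$exons), 2L]), integer(2)))
  linc_target <- vapply(lincs, function(l) {
    same <- which(vapply(genes, `[[`, character(1), "chrom") == l$chrom)
    sp <- c(l$exons[1L, 1L], l$exons[nrow(l$exons), 2L])
    d <- pmax(0L, pmax(gene_span[same, 1L] - sp[2L],
                       sp[1L] - gene_span[same, 2L]))
    gene_ids[same[which.min(d)]]
  }, character(1))
  nat_target <- vapply(lncnats, `[[`, character(1), "host")
  corr_targets <- unique(c(linc_target, nat_target))
  deg_planted <- gene_ids[stats::runif(length(genes)) < cfg$deg_rate &
                            !(gene_ids %in% corr_targets)]
  gene_prof <- matrix(0, nrow = length(genes), ncol = ns,
                      dimnames = list(gene_ids, samples))
  for (g in seq_along(genes)) {
    base <- exp(stats::rnorm(1L, log(40), 0.5))
    pr <- rep(base, ns)
    if (gene_ids[g] %in% deg_planted) {
      hi <- sample(seq_len(ns), sample(2:4, 1L))
      pr[hi] <- pr[hi] * cfg$deg_fold
    }
    gene_prof[g, ] <- pr
  }
  # overwrite correlated-target genes with (scaled) partner lncRNA profiles
  for (j in seq_along(lincs))
    gene_prof[linc_target[j], ] <- lnc_prof[lincs[[j]]$lnc_id, ] *
      stats::runif(1L, 0.5, 2)
  for (j in seq_along(lncnats))
    gene_prof[nat_target[j], ] <- lnc_prof[lncnats[[j]]$lnc_id, ] *
      stats::runif(1L, 0.5, 2)
  # per-isoform FPKM: gene profile split across isoforms, then noise
  fpkm_mat <- matrix(0, nrow = length(observed), ncol = ns,
                     dimnames = list(obs_ids, samples))
  for (g in seq_along(genes)) {
    idx <- which(obs_gene == gene_ids[g])
    w <- stats::runif(length(idx), 0.5, 1)
    w <- w / sum(w)
    for (k in seq_along(idx))
      fpkm_mat[idx[k], ] <- gene_prof[g, ] * w[k]
  }
  for (i in seq_along(lnc_all))
    fpkm_mat[lnc_ids[i], ] <- lnc_prof[i, ]
  noise <- matrix(2^stats::rnorm(length(fpkm_mat), 0, cfg$noise_sd_log2),
                  nrow = nrow(fpkm_mat))
  fpkm_mat <- fpkm_mat * noise
  tx_len <- vapply(observed, transcript_length, integer(1))
  counts <- round(fpkm_mat * tx_len / 1000)
  storage.mode(counts) <- "integer"

  ## ---- domains ------------------------------------------------------------
  dom_rows <- list()
  truth_dom <- list()
  multi_genes <- which(vapply(seq_along(genes), function(g)
    sum(obs_gene == gene_ids[g]) >= 2L, logical(1)))
  for (g in multi_genes) {
    idx <- which(obs_gene == gene_ids[g])
    ids <- obs_ids[idx]
    ref_set <- sort(sample(cfg$domain_alphabet, sample(2:3, 1L),
                           replace = TRUE))
    emit <- function(iso, set) {
      for (d in seq_along(set))
        dom_rows[[length(dom_rows) + 1L]] <<- data.frame(
          isoform_id = iso, domain_name = set[d],
          start_aa = 10L + 60L * (d - 1L), end_aa = 50L + 60L * (d - 1L),
          stringsAsFactors = FALSE)
    }
    emit(ids[1L], ref_set)
    truth_dom[[length(truth_dom) + 1L]] <- data.frame(
      gene_id = gene_ids[g], isoform_id = ids[1L],
      reference_isoform_id = ids[1L], lost = "", gained = "",
      class = "unchanged", stringsAsFactors = FALSE)
    for (iso in ids[-1L]) {
      set <- ref_set
      lost <- character(0); gained <- character(0)
      if (stats::runif(1L) < cfg$domain_loss_rate) {
        ndrop <- min(length(set), sample(1:2, 1L, prob = c(0.7, 0.3)))
        di <- sample(seq_along(set), ndrop)
        lost <- set[di]; set <- set[-di]
        if (stats::runif(1L) < cfg$domain_gain_rate) {
          newd <- sample(setdiff(cfg$domain_alphabet, ref_set), 1L)
          gained <- newd; set <- c(set, newd)
        }
      }
      emit(iso, sort(set))
      truth_dom[[length(truth_dom) + 1L]] <- data.frame(
        gene_id = gene_ids[g], isoform_id = iso,
        reference_isoform_id = ids[1L],
        lost = paste(sort(lost), collapse = ","),
        gained = paste(sort(gained), collapse = ","),
        class = if (length(lost) && length(gained)) "both"
        else if (length(lost)) "loss"
        else "unchanged", stringsAsFactors = FALSE)
    }
  }
  domains <- do.call(rbind, dom_rows)

  ## ---- GO map and paralog pairs -------------------------------------------
  terms <- sprintf("T%02d", 1:10)
  go_rows <- lapply(seq_along(genes), function(g) {
    tset <- sample(terms, sample(1:3, 1L))
    if (gene_ids[g] %in% deg_planted && stats::runif(1L) < 0.7)
      tset <- unique(c(tset, "T_DEG"))
    else if (stats::runif(1L) < 0.15)
      tset <- unique(c(tset, "T_DEG"))
    data.frame(term = tset, gene = gene_ids[g], stringsAsFactors = FALSE)
  })
  go_map <- do.call(rbind, go_rows)
  pp <- matrix(sample(gene_ids, 40L), ncol = 2L)
  paralog_pairs <- data.frame(gene1 = pp[, 1L], gene2 = pp[, 2L],
                              stringsAsFactors = FALSE)

  ## ---- write files --------------------------------------------------------
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    reference = file.path(out_dir, "reference.gtf"),
    observed = file.path(out_dir, "observed.gtf"),
    flnc = file.path(out_dir, "flnc.fastq"),
    alignments = file.path(out_dir, "flnc_alignments.bed12"),
    counts = file.path(out_dir, "counts.tsv"),
    domains = file.path(out_dir, "domains.tsv"),
    go_map = file.path(out_dir, "go_map.tsv"),
    paralog_pairs = file.path(out_dir, "paralog_pairs.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_fasta(genome, paths$genome)
  write_gtf(reference, paths$reference)
  write_gtf(observed, paths$observed)
  writeLines(as.vector(rbind(paste0("@", read_ids), read_seqs,
                             "+", strrep("I", nchar(read_seqs)))),
             paths$flnc)
  writeLines(bed, paths$alignments)
  utils::write.table(data.frame(id = rownames(counts), counts,
                                check.names = FALSE),
                     paths$counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(domains, paths$domains, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(go_map, paths$go_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(paralog_pairs, paths$paralog_pairs, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- list(
    config = unclass(cfg),
    genes = data.frame(
      gene_id = gene_ids,
      chrom = vapply(genes, `[[`, character(1), "chrom"),
      strand = vapply(genes, `[[`, character(1), "strand"),
      start = gene_span[, 1L], end = gene_span[, 2L],
      n_isoforms = vapply(gene_ids, function(g) sum(obs_gene == g),
                          integer(1)),
      stringsAsFactors = FALSE, row.names = NULL),
    isoforms = {
      kind <- vapply(obs_meta, `[[`, character(1), "kind")
      nex_obs <- vapply(observed, function(t) nrow(t$exons), integer(1))
      # aTSS/aTTS isoforms of multi-exon genes keep the reference intron
      # chain, hence are full splice matches ("known"); only end-shifted
      # mono-exon isoforms fall outside the end tolerance
      category <- ifelse(
        kind == "reference_copy" |
          (kind %in% c("aTSS", "aTTS") & nex_obs > 1L), "known",
        ifelse(startsWith(kind, "lnc_"), "novel_locus",
               "novel_of_annotated"))
      data.frame(transcript_id = obs_ids, gene_id = obs_gene, kind = kind,
                 category = category, stringsAsFactors = FALSE,
                 row.names = NULL)
    },
    events = do.call(rbind, truth_events),
    ends = truth_ends,
    polya_sites = truth_polya,
    polya_table = cbind(all_sites,
                        gene_id = c(rep(gene_ids, lengths(truth_polya)),
                                    vapply(c(lincs, lncnats), `[[`,
                                           character(1), "lnc_id"))),
    motif = list(motif = cfg$polya_motif,
                 planted_fraction = mean(has_motif),
                 n_sites = nrow(all_sites)),
    lncrnas = data.frame(
      lnc_id = lnc_ids,
      class = vapply(lnc_all, `[[`, character(1), "class"),
      target_gene = c(linc_target, nat_target),
      cluster = lnc_cluster, stringsAsFactors = FALSE, row.names = NULL),
    deg_genes = sort(unique(c(deg_planted, corr_targets))),
    domain_changes = do.call(rbind, truth_dom))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(truth = truth, paths = paths, genome = genome,
                 reference = reference, observed = observed,
                 counts = counts, fpkm = fpkm_mat))
}

#' Generate codon-structured (coding-like) and shuffled (noncoding-like)
#' transcript sequences
#'
#' Coding-like sequences carry a 5' UTR, an ATG-initiated CDS drawn from a
#' GC3-biased codon usage covering most of the transcript, a stop codon and
#' a short 3' UTR; noncoding-like sequences are mononucleotide-preserving
#' shuffles of coding ones, which destroys the reading frame and codon
#' position bias while keeping composition.
#'
#' @param n sequences per class.
#' @param len_range transcript length range in nt.
#' @param seed RNG seed.
#' @return list with character vectors `coding` and `noncoding`.
#' @export
simulate_coding_noncoding <- function(n = 100L, len_range = c(600L, 1500L),
                                      seed = 1L) {
  set.seed(seed)
  coding <- vapply(seq_len(n), function(i)
    .codon_mrna(.runit(len_range)), character(1))
  noncoding <- vapply(coding, function(s)
    paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
  list(coding = coding, noncoding = noncoding)
}
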