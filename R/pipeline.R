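# End-to-end orchestration: run every analysis stage in dependency order on
# one input directory and write plain-text TSV outputs plus a summary table.

#' Default pipeline configuration
#'
#' @param input_dir directory holding `genome.fa`, `reference.gtf`,
#'   `observed.gtf`, `flnc.fastq`, `flnc_alignments.bed12`, `counts.tsv`,
#'   `domains.tsv`, `go_map.tsv` (the [simulate_corpus()] layout; individual
#'   paths can be overridden).
#' @param out_dir output directory.
#' @param ... overrides for any default parameter below.
#' @return named list of class `"run_config"`.
#' @export
pipeline_config <- function(input_dir, out_dir, ...) {
  cfg <- list(
    genome = file.path(input_dir, "genome.fa"),
    reference = file.path(input_dir, "reference.gtf"),
    observed = file.path(input_dir, "observed.gtf"),
    flnc = file.path(input_dir, "flnc.fastq"),
    alignments = file.path(input_dir, "flnc_alignments.bed12"),
    counts = file.path(input_dir, "counts.tsv"),
    domains = file.path(input_dir, "domains.tsv"),
    go_map = file.path(input_dir, "go_map.tsv"),
    out_dir = out_dir,
    seed = 1L,
    classify.mono_exon_tol = 50L,
    expression.expressed_fpkm = 1,
    ends.tolerance_nt = 50L,
    polya.min_a = 8L,
    polya.max_non_a = 1L,
    polya.window = 30L,
    polya.mode = "sliding",
    polya.collapse_tol_nt = 24L,
    kmer.k = 6L,
    kmer.upstream = 50L,
    lncrna.min_len = 200L,
    lncrna.max_orf_aa = 100L,
    lncrna.score_cutoff = 0.5,
    lncrna.max_dist_nt = 1e5,
    lncrna.r_threshold = 0.6,
    das.q_max = 0.05,
    das.min_delta_psi = 0.1,
    deg.min_fold = 1,
    deg.min_fpkm = 1,
    cluster.k = 5L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) .fail("unknown config field(s): %s",
                         paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with `input_dir`, `out_dir` and optional parameter
#'   overrides (keys as in [pipeline_config()]).
#' @return a `"run_config"` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$input_dir) || is.null(y$out_dir))
    .fail("pipeline config must set input_dir and out_dir")
  extra <- y[setdiff(names(y), c("input_dir", "out_dir"))]
  do.call(pipeline_config, c(list(input_dir = y$input_dir,
                                  out_dir = y$out_dir), extra))
}

.need_file <- function(path, stage) {
  if (!file.exists(path))
    .fail("stage %s: required input file missing: %s", stage, path)
  path
}

.write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: input parsing, locus building and isoform
#' classification, AS event detection and differential splicing, end
#' clustering and poly(A) analysis, lncRNA identification and target
#' pairing, the expression stack (FPKM, PCA, clustering, DEG, enrichment),
#' domain-change classification, and the AS/aTSS/aTTS/DEG coupling table.
#' Plain-text TSVs plus `summary.tsv` and `provenance.tsv` (every effective
#' parameter) are written under `config$out_dir`.
#'
#' @param config a `"run_config"` from [pipeline_config()] or a path to a
#'   YAML file for [read_pipeline_config()].
#' @return (invisibly) named list of all stage results, including a
#'   `score_inputs` element shaped for [score_against_truth()].
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## io ----------------------------------------------------------------------
  res <- list()
  res$genome <- stage("io", read_genome(.need_file(cfg$genome, "io")))
  res$reference <- stage("io",
                         read_annotation(.need_file(cfg$reference, "io")))
  res$observed <- stage("io",
                        read_annotation(.need_file(cfg$observed, "io")))
  counts_df <- stage("io", utils::read.delim(
    .need_file(cfg$counts, "io"), check.names = FALSE))
  counts <- as.matrix(counts_df[, -1L, drop = FALSE])
  rownames(counts) <- counts_df[[1L]]

  ## loci / classification ----------------------------------------------------
  res$loci <- stage("locus_model", build_loci(res$observed))
  res$categories <- stage("locus_model", classify_isoforms(
    res$observed, res$reference,
    mono_exon_tol = cfg$classify.mono_exon_tol))
  res$gene_stats <- stage("locus_model",
                          per_gene_stats(res$loci, res$genome))
  tx_len <- vapply(res$observed, transcript_length, integer(1))
  names(tx_len) <- vapply(res$observed, `[[`, character(1), "transcript_id")
  common <- intersect(rownames(counts), names(tx_len))
  counts <- counts[common, , drop = FALSE]
  res$fpkm <- stage("expression", fpkm(counts, tx_len[common]))
  res$specificity <- stage(
    "locus_model",
    tissue_specificity(res$fpkm, cfg$expression.expressed_fpkm))

  ## splicing ------------------------------------------------------------------
  res$events <- stage("splicing", detect_events(res$loci))
  multi <- Filter(function(l) length(l$transcript_idx) >= 2L, res$loci$loci)
  res$dinucs <- stage("splicing",
                      boundary_dinucleotides(res$observed, res$genome))
  res$offsets <- stage("splicing", do.call(rbind, lapply(multi, function(lc)
    splice_site_offsets(res$loci$transcripts[lc$transcript_idx]))))
  res$structure_corr <- stage("splicing",
                              as_structure_correlation(res$gene_stats))
  # event-level inclusion/exclusion counts from the isoform count matrix
  res$das <- stage("splicing", {
    if (nrow(res$events)) {
      sum_rows <- function(ids) {
        ids <- intersect(strsplit(ids, ",", fixed = TRUE)[[1L]],
                         rownames(counts))
        if (length(ids) == 0L) rep(0L, ncol(counts)) else
          colSums(counts[ids, , drop = FALSE])
      }
      inc <- t(vapply(res$events$inclusion, sum_rows,
                      numeric(ncol(counts))))
      exc <- t(vapply(res$events$exclusion, sum_rows,
                      numeric(ncol(counts))))
      rownames(inc) <- rownames(exc) <- res$events$anchor_key
      colnames(inc) <- colnames(exc) <- colnames(counts)
      differential_splicing(inc, exc, q_max = cfg$das.q_max,
                            min_delta_psi = cfg$das.min_delta_psi)
    } else NULL
  })

  ## ends / poly(A) ------------------------------------------------------------
  res$end_flags <- stage("ends_polya", {
    rows <- lapply(multi, function(lc) {
      txs <- res$loci$transcripts[lc$transcript_idx]
      data.frame(
        locus_id = lc$locus_id,
        atss = cluster_ends(txs, "TSS", cfg$ends.tolerance_nt)$alternative,
        atts = cluster_ends(txs, "TTS", cfg$ends.tolerance_nt)$alternative,
        stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, rows) else
      data.frame(locus_id = character(0), atss = logical(0),
                 atts = logical(0))
  })
  reads <- stage("ends_polya", {
    fq <- Biostrings::readDNAStringSet(
      .need_file(cfg$flnc, "ends_polya"), format = "fastq")
    stats::setNames(as.character(fq), sub("\\s.*$", "", names(fq)))
  })
  aln <- stage("ends_polya",
               read_alignments_bed12(.need_file(cfg$alignments,
                                                "ends_polya")))
  res$polya_calls <- stage("ends_polya", call_polya_batch(
    reads, aln, min_a = cfg$polya.min_a, max_non_a = cfg$polya.max_non_a,
    window = cfg$polya.window, mode = cfg$polya.mode))
  res$polya <- stage("ends_polya", polya_sites_per_gene(
    res$polya_calls, res$loci, cfg$polya.collapse_tol_nt))
  locus_info <- data.frame(
    locus_id = vapply(res$loci$loci, `[[`, character(1), "locus_id"),
    chrom = vapply(res$loci$loci, `[[`, character(1), "chrom"),
    strand = vapply(res$loci$loci, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  sites <- stage("ends_polya", {
    s <- merge(res$polya$per_gene, locus_info,
               by.x = "gene_id", by.y = "locus_id")
    s[order(s$chrom, s$site), c("chrom", "strand", "site", "gene_id",
                                "n_reads")]
  })
  res$composition <- stage("ends_polya",
                           composition_profile(sites, res$genome))
  res$kmers <- stage("ends_polya", upstream_kmer_enrichment(
    sites, res$genome, k = cfg$kmer.k, upstream = cfg$kmer.upstream,
    seed = cfg$seed))

  ## lncRNA --------------------------------------------------------------------
  res$lncrnas <- stage("lncrna", identify_lncrnas(
    res$observed, res$genome, res$reference, categories = res$categories,
    min_len = cfg$lncrna.min_len, max_orf_aa = cfg$lncrna.max_orf_aa,
    score_cutoff = cfg$lncrna.score_cutoff))
  # locus-level expression (sum of member isoform FPKM)
  locus_fpkm <- stage("expression", {
    m <- do.call(rbind, lapply(res$loci$loci, function(lc) {
      ids <- intersect(lc$transcript_ids, rownames(res$fpkm))
      if (length(ids) == 0L) rep(0, ncol(res$fpkm)) else
        colSums(res$fpkm[ids, , drop = FALSE])
    }))
    rownames(m) <- vapply(res$loci$loci, `[[`, character(1), "locus_id")
    colnames(m) <- colnames(res$fpkm)
    m
  })
  coding_loci <- stage("lncrna", {
    known_ids <- res$categories$transcript_id[
      res$categories$category != "novel_locus"]
    keep <- vapply(res$loci$loci, function(lc)
      any(lc$transcript_ids %in% known_ids), logical(1))
    data.frame(
      gene_id = vapply(res$loci$loci[keep], `[[`, character(1), "locus_id"),
      chrom = vapply(res$loci$loci[keep], `[[`, character(1), "chrom"),
      strand = vapply(res$loci$loci[keep], `[[`, character(1), "strand"),
      start = vapply(res$loci$loci[keep], function(l) l$span[1L],
                     integer(1)),
      end = vapply(res$loci$loci[keep], function(l) l$span[2L], integer(1)),
      stringsAsFactors = FALSE)
  })
  res$lnc_targets <- stage("lncrna", {
    expr <- rbind(locus_fpkm,
                  res$fpkm[intersect(res$lncrnas$transcript_id,
                                     rownames(res$fpkm)), , drop = FALSE])
    lnc_target_pairs(res$lncrnas, res$observed, coding_loci, expr,
                     max_dist_nt = cfg$lncrna.max_dist_nt,
                     r_threshold = cfg$lncrna.r_threshold)
  })

  ## expression ----------------------------------------------------------------
  res$pca <- stage("expression", pca_expression(res$fpkm))
  res$clusters <- stage("expression", {
    lnc_expr <- res$fpkm[intersect(res$lncrnas$transcript_id,
                                   rownames(res$fpkm)), , drop = FALSE]
    if (nrow(lnc_expr) >= cfg$cluster.k)
      cluster_profiles(lnc_expr, k = cfg$cluster.k, seed = cfg$seed)
    else NULL
  })
  res$deg <- stage("expression", deg_pairwise(
    locus_fpkm, min_fold = cfg$deg.min_fold, min_fpkm = cfg$deg.min_fpkm))
  res$enrichment <- stage("expression", {
    if (file.exists(cfg$go_map) && length(res$deg$union)) {
      go <- utils::read.delim(cfg$go_map)
      lmap <- .locus_gene_overlap_map(res$loci, res$reference)
      sel <- unique(stats::na.omit(lmap[res$deg$union]))
      uni <- unique(stats::na.omit(lmap))
      if (length(sel)) term_enrichment(sel, uni, go) else NULL
    } else NULL
  })

  ## domains -------------------------------------------------------------------
  res$domain_changes <- stage("domains", {
    if (file.exists(cfg$domains)) {
      dom <- read_domains(cfg$domains)
      gi <- lapply(multi, function(lc)
        intersect(lc$transcript_ids, unique(dom$isoform_id)))
      names(gi) <- vapply(multi, `[[`, character(1), "locus_id")
      gi <- gi[lengths(gi) > 0L]
      classify_domain_changes(gi, dom)
    } else NULL
  })

  ## coupling ------------------------------------------------------------------
  res$coupling <- stage("coupling", {
    ids <- vapply(multi, `[[`, character(1), "locus_id")
    has_as <- ids %in% res$events$locus_id
    ef <- res$end_flags[match(ids, res$end_flags$locus_id), ]
    coupling_venn(data.frame(
      gene_id = ids, has_AS = has_as, has_aTSS = ef$atss,
      has_aTTS = ef$atts, is_DEG = ids %in% res$deg$union,
      stringsAsFactors = FALSE))
  })

  ## outputs -------------------------------------------------------------------
  out <- cfg$out_dir
  .write_tsv(res$categories, out, "isoform_categories.tsv")
  .write_tsv(res$gene_stats, out, "gene_stats.tsv")
  .write_tsv(res$specificity$per_isoform, out, "specificity.tsv")
  .write_tsv(res$events, out, "events.tsv")
  if (!is.null(res$das)) .write_tsv(res$das, out, "das.tsv")
  .write_tsv(res$polya_calls, out, "polya_calls.tsv")
  .write_tsv(res$polya$per_gene, out, "polya_sites.tsv")
  .write_tsv(res$composition, out, "composition_profile.tsv")
  .write_tsv(utils::head(res$kmers, 200L), out, "kmer_enrichment.tsv")
  .write_tsv(res$lncrnas, out, "lncrna_records.tsv")
  .write_tsv(res$lnc_targets, out, "lnc_targets.tsv")
  .write_tsv(data.frame(id = rownames(res$fpkm),
                        round(res$fpkm, 4), check.names = FALSE),
             out, "fpkm.tsv")
  if (!is.null(res$clusters))
    .write_tsv(data.frame(id = names(res$clusters$assignment),
                          cluster = res$clusters$assignment),
               out, "clusters.tsv")
  .write_tsv(res$deg$per_pair[res$deg$per_pair$deg, ], out, "deg.tsv")
  if (!is.null(res$enrichment))
    .write_tsv(res$enrichment, out, "enrichment.tsv")
  if (!is.null(res$domain_changes))
    .write_tsv(res$domain_changes, out, "domain_changes.tsv")
  .write_tsv(res$coupling$venn, out, "coupling_venn.tsv")

  cat_tab <- table(res$categories$category)
  ev_tab <- table(factor(res$events$event_type,
                         levels = c("IR", "ES", "A3SS", "A5SS", "MXE")))
  summary_df <- rbind(
    data.frame(section = "isoforms", key = "n_isoforms",
               value = length(res$observed)),
    data.frame(section = "isoforms", key = names(cat_tab),
               value = as.integer(cat_tab)),
    data.frame(section = "loci", key = "n_loci",
               value = length(res$loci$loci)),
    data.frame(section = "loci", key = "n_multi_isoform",
               value = length(multi)),
    data.frame(section = "as_events", key = names(ev_tab),
               value = as.integer(ev_tab)),
    data.frame(section = "as_percent", key = names(ev_tab),
               value = round(100 * as.integer(ev_tab) /
                               max(1L, sum(ev_tab)), 2)),
    data.frame(section = "polya_hist",
               key = as.character(res$polya$histogram$n_sites),
               value = res$polya$histogram$n_genes),
    data.frame(section = "lncrna", key = "n_lncrna",
               value = nrow(res$lncrnas)),
    data.frame(section = "deg", key = "n_deg",
               value = length(res$deg$union)),
    data.frame(section = "coupling",
               key = apply(res$coupling$venn[, 1:4], 1L, function(r)
                 paste0(ifelse(r, "1", "0"), collapse = "")),
               value = res$coupling$venn$n_genes))
  .write_tsv(summary_df, out, "summary.tsv")
  prov <- data.frame(
    parameter = names(cfg),
    value = vapply(cfg, function(v) paste(format(v), collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
  .write_tsv(prov, out, "provenance.tsv")

  res$score_inputs <- list(
    events = res$events, loci = res$loci, end_flags = res$end_flags,
    polya = sites[, c("chrom", "site")], categories = res$categories,
    lncrnas = res$lncrnas,
    clusters = if (!is.null(res$clusters)) res$clusters$assignment else NULL,
    domain_changes = res$domain_changes, deg_genes = res$deg$union)
  invisible(res)
}

# map locus ids to reference gene ids by same-strand span overlap (for
# enrichment, whose term map is keyed by reference gene ids)
.locus_gene_overlap_map <- function(loci, reference) {
  gid <- vapply(reference, `[[`, character(1), "gene_id")
  spans <- t(vapply(reference, .tx_span, integer(2)))
  rchrom <- vapply(reference, `[[`, character(1), "chrom")
  rstrand <- vapply(reference, `[[`, character(1), "strand")
  out <- stats::setNames(rep(NA_character_, length(loci$loci)),
                         vapply(loci$loci, `[[`, character(1), "locus_id"))
  for (lc in loci$loci) {
    hit <- which(rchrom == lc$chrom & rstrand == lc$strand &
                   spans[, 1L] < lc$span[2L] & spans[, 2L] > lc$span[1L])
    if (length(hit)) out[lc$locus_id] <- gid[hit[1L]]
  }
  out
}
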