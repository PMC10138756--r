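# Scoring pipeline outputs against the generator's ground truth.

# map locus ids to truth gene ids by same-strand span overlap
.locus_truth_map <- function(loci, truth_genes) {
  out <- character(0)
  for (lc in loci$loci) {
    hit <- which(truth_genes$chrom == lc$chrom &
                   truth_genes$strand == lc$strand &
                   truth_genes$start < lc$span[2L] &
                   truth_genes$end > lc$span[1L])
    if (length(hit) > 1L) {
      ov <- pmin(truth_genes$end[hit], lc$span[2L]) -
        pmax(truth_genes$start[hit], lc$span[1L])
      hit <- hit[which.max(ov)]
    }
    out[lc$locus_id] <- if (length(hit)) truth_genes$gene_id[hit] else
      NA_character_
  }
  out
}

#' Score pipeline outputs against a synthetic truth table
#'
#' Computes per-stage precision/recall (structural stages), accuracy
#' (classification stages) and adjusted Rand index (clustering) for
#' whichever result components are supplied. Events match truth by
#' (type, chrom, anchor coordinates); end flags, poly(A) sites and DEG flags
#' are mapped from pipeline loci to truth genes by span overlap; poly(A)
#' sites match within `polya_tol` nt.
#'
#' @param results named list; recognized components: `events` (data.frame
#'   from [detect_events()]), `loci` (the `"locus_set"`), `end_flags`
#'   (data.frame: `locus_id`, `atss`, `atts`), `polya` (data.frame: `chrom`,
#'   `site`), `categories` ([classify_isoforms()] output), `lncrnas`
#'   ([identify_lncrnas()] output), `clusters` (named assignment vector),
#'   `domain_changes` ([classify_domain_changes()] output), `deg_genes`
#'   (character vector of DEG locus ids).
#' @param truth truth list from [simulate_corpus()] (or read from
#'   `truth.json`).
#' @param polya_tol matching tolerance for poly(A) sites (default 24 nt).
#' @return data.frame: `stage`, `metric`, `value` (precision/recall values
#'   are NA when undefined, e.g. precision with zero detections).
#' @export
score_against_truth <- function(results, truth, polya_tol = 24L) {
  rows <- list()
  put <- function(stage, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, metric = metric, value = as.numeric(value),
      stringsAsFactors = FALSE)
  truth_genes <- as.data.frame(truth$genes)
  lmap <- if (!is.null(results$loci))
    .locus_truth_map(results$loci, truth_genes) else NULL

  if (!is.null(results$events)) {
    tev <- as.data.frame(truth$events)
    dev <- results$events
    for (tp in c("IR", "ES", "A3SS", "A5SS", "MXE")) {
      tkey <- with(tev[tev$event_type == tp, , drop = FALSE],
                   paste(chrom, anchor_start, anchor_end))
      dkey <- with(dev[dev$event_type == tp, , drop = FALSE],
                   paste(chrom, anchor_start, anchor_end))
      put(paste0("events_", tp), "recall",
          if (length(tkey)) mean(tkey %in% dkey) else NA)
      put(paste0("events_", tp), "precision",
          if (length(dkey)) mean(dkey %in% tkey) else NA)
    }
  }
  if (!is.null(results$end_flags) && !is.null(lmap)) {
    ef <- results$end_flags
    ef$gene_id <- lmap[ef$locus_id]
    ef <- ef[!is.na(ef$gene_id), , drop = FALSE]
    te <- as.data.frame(truth$ends)
    m <- merge(ef, te, by = "gene_id", suffixes = c("_det", "_truth"))
    for (kind in c("atss", "atts")) {
      det <- m[[paste0(kind, "_det")]]
      tru <- m[[paste0(kind, "_truth")]]
      put(paste0("ends_", kind), "recall",
          if (sum(tru)) sum(det & tru) / sum(tru) else NA)
      put(paste0("ends_", kind), "precision",
          if (sum(det)) sum(det & tru) / sum(det) else NA)
    }
  }
  if (!is.null(results$polya)) {
    tp <- as.data.frame(truth$polya_table)
    tchrom <- tp$chrom
    tsite <- tp$site
    det <- results$polya
    match_to <- function(qc, qs, rc, rs)
      vapply(seq_along(qs), function(i)
        any(rc == qc[i] & abs(rs - qs[i]) <= polya_tol), logical(1))
    put("polya", "recall",
        if (length(tsite)) mean(match_to(tchrom, tsite, det$chrom, det$site))
        else NA)
    put("polya", "precision",
        if (nrow(det)) mean(match_to(det$chrom, det$site, tchrom, tsite))
        else NA)
  }
  if (!is.null(results$categories)) {
    ti <- as.data.frame(truth$isoforms)
    m <- merge(results$categories, ti[, c("transcript_id", "category")],
               by = "transcript_id", suffixes = c("_det", "_truth"))
    put("categories", "accuracy", mean(m$category_det == m$category_truth))
  }
  if (!is.null(results$lncrnas)) {
    tl <- as.data.frame(truth$lncrnas)
    det_ids <- results$lncrnas$transcript_id
    put("lncrna", "recall", mean(tl$lnc_id %in% det_ids))
    put("lncrna", "precision",
        if (length(det_ids)) mean(det_ids %in% tl$lnc_id) else NA)
    m <- merge(results$lncrnas, tl, by.x = "transcript_id", by.y = "lnc_id")
    if (nrow(m))
      put("lncrna", "class_accuracy", mean(m$class.x == m$class.y))
  }
  if (!is.null(results$clusters)) {
    tl <- as.data.frame(truth$lncrnas)
    shared <- intersect(names(results$clusters), tl$lnc_id)
    if (length(shared) >= 2L)
      put("clusters", "ari", mclust::adjustedRandIndex(
        results$clusters[shared],
        tl$cluster[match(shared, tl$lnc_id)]))
  }
  if (!is.null(results$domain_changes)) {
    td <- as.data.frame(truth$domain_changes)
    m <- merge(results$domain_changes, td, by = "isoform_id",
               suffixes = c("_det", "_truth"))
    if (nrow(m))
      put("domains", "class_accuracy", mean(m$class_det == m$class_truth))
  }
  if (!is.null(results$deg_genes) && !is.null(lmap)) {
    det <- unique(stats::na.omit(lmap[results$deg_genes]))
    tru <- truth$deg_genes
    put("deg", "recall", if (length(tru)) mean(tru %in% det) else NA)
    put("deg", "precision", if (length(det)) mean(det %in% tru) else NA)
  }
  do.call(rbind, rows)
}
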