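# Gene loci: strand-aware grouping of transcripts, isoform classification
# against a reference annotation, and per-gene summaries.

# intron chain of a transcript as a matrix of (start, end) gaps
.introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) return(matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = t$exons[-n, 2L], end = t$exons[-1L, 1L])
}

# canonical string key of an intron chain (chrom/strand qualified)
.chain_key <- function(t) {
  i <- .introns(t)
  paste(t$chrom, t$strand,
        paste(i[, 1L], i[, 2L], sep = "-", collapse = ","), sep = ":")
}

#' Group transcripts into gene loci by exonic overlap
#'
#' Single-linkage clustering: two transcripts belong to the same locus iff
#' they are connected by a chain of pairs sharing at least 1 bp of exonic
#' sequence on the same chromosome and strand. Locus ids are deterministic,
#' numbered by (chrom, span start).
#'
#' @param transcripts list of `"transcript"` objects.
#' @param prefix id prefix for generated locus ids.
#' @return object of class `"locus_set"`: a list with elements `loci` (list of
#'   locus records: `locus_id`, `chrom`, `strand`, `transcript_ids`, `span`)
#'   and `tx2locus` (named character vector mapping transcript id to locus id).
#' @export
build_loci <- function(transcripts, prefix = "LOC") {
  n <- length(transcripts)
  if (n == 0L) .fail("build_loci: no transcripts")
  ex <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- transcripts[[i]]
    cbind(tx = i, start = t$exons[, 1L], end = t$exons[, 2L])
  }))
  chroms <- vapply(transcripts, `[[`, character(1), "chrom")
  strands <- vapply(transcripts, `[[`, character(1), "strand")
  gr <- GenomicRanges::GRanges(
    seqnames = chroms[ex[, "tx"]],
    ranges = IRanges::IRanges(start = ex[, "start"] + 1L, end = ex[, "end"]),
    strand = strands[ex[, "tx"]])
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
  # union-find over transcript indices
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  qh <- ex[S4Vectors::queryHits(hits), "tx"]
  sh <- ex[S4Vectors::subjectHits(hits), "tx"]
  for (k in seq_along(qh)) {
    a <- find(qh[k]); b <- find(sh[k])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  spans <- lapply(groups, function(idx)
    range(unlist(lapply(transcripts[idx], .tx_span))))
  ord <- order(vapply(groups, function(idx) chroms[idx[1L]], character(1)),
               vapply(spans, `[`, numeric(1), 1L),
               vapply(groups, function(idx) strands[idx[1L]], character(1)))
  groups <- groups[ord]; spans <- spans[ord]
  ids <- sprintf("%s%06d", prefix, seq_along(groups))
  loci <- lapply(seq_along(groups), function(j) {
    idx <- groups[[j]]
    list(locus_id = ids[j],
         chrom = chroms[idx[1L]],
         strand = strands[idx[1L]],
         transcript_ids = sort(vapply(transcripts[idx], `[[`, character(1),
                                      "transcript_id")),
         transcript_idx = idx,
         span = as.integer(spans[[j]]))
  })
  tx2locus <- stats::setNames(
    rep(ids, lengths(groups)),
    unlist(lapply(groups, function(idx)
      vapply(transcripts[idx], `[[`, character(1), "transcript_id"))))
  structure(list(loci = loci, tx2locus = tx2locus,
                 transcripts = transcripts),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d loci, %d transcripts\n",
              length(x$loci), length(x$transcripts)))
  invisible(x)
}

#' Classify observed isoforms against a reference annotation
#'
#' Categories:
#' \describe{
#'   \item{known}{multi-exon isoform whose intron chain exactly matches a
#'     reference transcript on the same chromosome and strand (full splice
#'     match; end positions are free, alternative ends are handled by the
#'     aTSS/aTTS stage), or mono-exon isoform matching a reference mono-exon
#'     transcript with both ends within `mono_exon_tol`.}
#'   \item{novel_of_annotated}{not known, but sharing >= 1 bp exonic overlap
#'     with a reference transcript on the same strand.}
#'   \item{novel_locus}{no same-strand exonic overlap with the reference
#'     (antisense-only overlap counts as novel_locus).}
#' }
#'
#' @param transcripts list of observed `"transcript"` objects.
#' @param reference list of reference `"transcript"` objects.
#' @param mono_exon_tol tolerance (nt) on both ends for mono-exon matching.
#' @return data.frame with columns `transcript_id`, `category`.
#' @export
classify_isoforms <- function(transcripts, reference, mono_exon_tol = 50L) {
  ref_keys <- unique(vapply(reference, .chain_key, character(1))[
    vapply(reference, function(t) nrow(t$exons) > 1L, logical(1))])
  ref_mono <- Filter(function(t) nrow(t$exons) == 1L, reference)
  mono_tab <- if (length(ref_mono)) data.frame(
    chrom = vapply(ref_mono, `[[`, character(1), "chrom"),
    strand = vapply(ref_mono, `[[`, character(1), "strand"),
    start = vapply(ref_mono, function(t) t$exons[1L, 1L], integer(1)),
    end = vapply(ref_mono, function(t) t$exons[1L, 2L], integer(1))) else NULL
  ref_gr <- GenomicRanges::GRanges(
    seqnames = unlist(lapply(reference, function(t)
      rep(t$chrom, nrow(t$exons)))),
    ranges = IRanges::IRanges(
      start = unlist(lapply(reference, function(t) t$exons[, 1L] + 1L)),
      end = unlist(lapply(reference, function(t) t$exons[, 2L]))),
    strand = unlist(lapply(reference, function(t)
      rep(t$strand, nrow(t$exons)))))
  category <- vapply(transcripts, function(t) {
    if (nrow(t$exons) > 1L) {
      if (.chain_key(t) %in% ref_keys) return("known")
    } else if (!is.null(mono_tab)) {
      hit <- mono_tab$chrom == t$chrom & mono_tab$strand == t$strand &
        abs(mono_tab$start - t$exons[1L, 1L]) <= mono_exon_tol &
        abs(mono_tab$end - t$exons[1L, 2L]) <= mono_exon_tol
      if (any(hit)) return("known")
    }
    q <- GenomicRanges::GRanges(
      t$chrom, IRanges::IRanges(t$exons[, 1L] + 1L, t$exons[, 2L]), t$strand)
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(q, ref_gr, ignore.strand = FALSE))
    if (length(hit) > 0L) "novel_of_annotated" else "novel_locus"
  }, character(1))
  data.frame(
    transcript_id = vapply(transcripts, `[[`, character(1), "transcript_id"),
    category = category, stringsAsFactors = FALSE)
}

#' Per-gene structural summaries
#'
#' One row per locus: isoform count, exon-count statistics, mean spliced
#' length, mean exon length, and (when a genome is supplied) mean GC content
#' of the spliced isoform sequences.
#'
#' @param loci a `"locus_set"` from [build_loci()].
#' @param genome optional named character vector from [read_genome()].
#' @return data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `n_isoforms`, `max_exons`, `mean_exons`, `mean_mrna_length`,
#'   `mean_exon_length`, `mean_gc`.
#' @export
per_gene_stats <- function(loci, genome = NULL) {
  rows <- lapply(loci$loci, function(lc) {
    txs <- loci$transcripts[lc$transcript_idx]
    nex <- vapply(txs, function(t) nrow(t$exons), integer(1))
    lens <- vapply(txs, transcript_length, integer(1))
    gc <- NA_real_
    if (!is.null(genome))
      gc <- mean(vapply(txs, function(t)
        gc_content(transcript_sequence(t, genome)), numeric(1)))
    data.frame(gene_id = lc$locus_id, chrom = lc$chrom, strand = lc$strand,
               n_isoforms = length(txs), max_exons = max(nex),
               mean_exons = mean(nex), mean_mrna_length = mean(lens),
               mean_exon_length = sum(lens) / sum(nex), mean_gc = gc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tissue specificity of isoform expression
#'
#' An isoform counts as expressed in a sample when its FPKM is at or above
#' `threshold_fpkm`; it is "specific" when expressed in exactly one sample.
#'
#' @param expression numeric matrix, isoforms x samples (FPKM).
#' @param threshold_fpkm expression call threshold (default 1).
#' @return list with `per_isoform` (data.frame: `id`, `n_expressed`,
#'   `samples`, `specific`) and `overlap_counts` (data.frame: number of
#'   samples expressed in vs isoform count — the n-way overlap summary).
#' @export
tissue_specificity <- function(expression, threshold_fpkm = 1) {
  if (any(expression < 0)) .fail("negative FPKM values in expression matrix")
  expressed <- expression >= threshold_fpkm
  n_exp <- rowSums(expressed)
  samples <- apply(expressed, 1L, function(r)
    paste(colnames(expression)[r], collapse = ","))
  per <- data.frame(id = rownames(expression), n_expressed = n_exp,
                    samples = samples, specific = n_exp == 1L,
                    stringsAsFactors = FALSE, row.names = NULL)
  counts <- as.data.frame(table(factor(n_exp, levels = 0:ncol(expression))),
                          stringsAsFactors = FALSE)
  names(counts) <- c("n_samples", "n_isoforms")
  counts$n_samples <- as.integer(counts$n_samples)
  list(per_isoform = per, overlap_counts = counts)
}
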