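# Long noncoding RNA identification: longest-ORF calling, a transparent
# coding-potential score (ORF length + ORF coverage + Fickett TESTCODE
# statistic combined logistically), positional classification, and
# expression-based target pairing.

# Fickett (1982) TESTCODE lookup tables, as used by the classic coding
# potential tools. Position parameter = max/(min+1) of base counts over the
# three codon positions; content parameter = base fraction.
.fickett_pos_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
.fickett_pos_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_pos_breaks <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
.fickett_cont_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
.fickett_cont_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickett_cont_breaks <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                          0.17, 0.0)

#' Fickett TESTCODE statistic
#'
#' Combines codon-position asymmetry and base composition of a nucleotide
#' sequence via the published lookup tables; higher values indicate
#' protein-coding character (the classic decision threshold is ~0.94).
#'
#' @param seq nucleotide string (any case).
#' @return numeric score.
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  if (length(bases) < 3L) .fail("sequence too short for a Fickett score")
  phase <- (seq_along(bases) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(bases == b & phase == p), integer(1))
    posval <- max(cnt) / (min(cnt) + 1)
    pidx <- which(posval >= .fickett_pos_breaks)[1L]
    score <- score +
      .fickett_pos_prob[[b]][pidx] * .fickett_pos_weight[[b]]
    contval <- mean(bases == b)
    cidx <- which(contval >= .fickett_cont_breaks)[1L]
    score <- score +
      .fickett_cont_prob[[b]][cidx] * .fickett_cont_weight[[b]]
  }
  score
}

#' Longest ATG-initiated open reading frame
#'
#' Scans the three sense-strand frames; each ORF starts at ATG and runs to
#' the first in-frame stop (TAA/TAG/TGA) or, failing that, the transcript
#' end. Returns the longest; ties break toward the 5'-most start.
#'
#' @param seq nucleotide string (transcript orientation, any case).
#' @return list of class `"orf"`: `start` (0-based nt offset of the ATG),
#'   `end` (exclusive nt offset, including the stop codon when present),
#'   `length_aa` (peptide length excluding the stop), `peptide`, `has_stop`.
#'   A sequence without any ATG yields `length_aa = 0` and an empty peptide.
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- list(start = NA_integer_, end = NA_integer_, length_aa = 0L,
               peptide = "", has_stop = FALSE)
  class(best) <- "orf"
  if (n < 3L) return(best)
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    starts0 <- frame + 3L * (seq_len(ncod) - 1L)
    codons <- substring(seq, starts0 + 1L, starts0 + 3L)
    atg_i <- which(codons == "ATG")
    stop_i <- which(codons %in% stops)
    for (ai in atg_i) {
      nxt <- stop_i[stop_i > ai]
      if (length(nxt)) {
        aa <- nxt[1L] - ai
        endnt <- starts0[nxt[1L]] + 3L
        has_stop <- TRUE
      } else {
        aa <- ncod - ai + 1L
        endnt <- starts0[ncod] + 3L
        has_stop <- FALSE
      }
      if (aa > best$length_aa ||
          (aa == best$length_aa && !is.na(best$start) &&
             starts0[ai] < best$start)) {
        best$start <- starts0[ai]
        best$end <- endnt
        best$length_aa <- aa
        best$has_stop <- has_stop
      }
    }
  }
  if (!is.na(best$start)) {
    pep_end <- best$start + 3L * best$length_aa
    cods <- substring(seq, seq(best$start + 1L, pep_end - 2L, by = 3L),
                      seq(best$start + 3L, pep_end, by = 3L))
    gc <- Biostrings::GENETIC_CODE
    best$peptide <- paste(gc[cods], collapse = "")
  }
  best
}

#' @export
print.orf <- function(x, ...) {
  cat(sprintf("<orf> %d aa%s at nt %s\n", x$length_aa,
              if (x$has_stop) " (stop-terminated)" else "",
              if (is.na(x$start)) "-" else x$start))
  invisible(x)
}

#' Coding-potential score
#'
#' A fixed logistic combination of the longest-ORF length, the ORF coverage
#' (ORF nt / transcript nt), and the Fickett TESTCODE statistic; higher
#' values indicate coding character. Weights are fixed package constants
#' chosen so that a full-length codon-structured mRNA scores near 1 and a
#' composition-matched shuffled sequence near 0, with 0.5 as the working
#' cutoff. The score is invariant to input case.
#'
#' @param seq nucleotide string.
#' @param orf optional precomputed [longest_orf()] result.
#' @return score in `[0, 1]`.
#' @export
coding_potential <- function(seq, orf = NULL) {
  seq <- toupper(seq)
  if (is.null(orf)) orf <- longest_orf(seq)
  cov <- if (nchar(seq) > 0L && !is.na(orf$start))
    (3L * orf$length_aa) / nchar(seq) else 0
  fick <- fickett_score(seq)
  stats::plogis(0.02 * orf$length_aa + 3 * cov + 3 * fick - 6.5)
}

#' Identify lncRNA candidates and classify their genomic position
#'
#' Candidates are the observed transcripts not classified `known` against
#' the reference (novel transcripts). A candidate is kept when its spliced
#' length is >= `min_len` nt, its longest ORF is <= `max_orf_aa` amino acids,
#' and its coding-potential score is below `score_cutoff`. Kept records are
#' classified by position relative to the reference coding models:
#' `sense_overlapping` (exonic overlap, same strand), `lncNAT` (exonic
#' overlap, antisense), `intronic` (no exonic overlap, fully inside an
#' intron of a same-strand reference transcript), else `lincRNA`.
#'
#' @param transcripts list of observed `"transcript"` objects.
#' @param genome named character vector from [read_genome()].
#' @param reference list of reference (protein-coding) `"transcript"` models.
#' @param categories data.frame from [classify_isoforms()]; computed when
#'   missing.
#' @param min_len minimum transcript length in nt (default 200).
#' @param max_orf_aa maximum ORF length in aa (default 100).
#' @param score_cutoff coding-potential cutoff (default 0.5).
#' @param min_orf_nt_350 optional secondary filter dropping candidates whose
#'   ORF exceeds `max_orf_aa` *or* whose length is under 350 nt; off by
#'   default.
#' @return data.frame: `transcript_id`, `length_nt`, `n_exons`, `orf_aa`,
#'   `coding_score`, `class`.
#' @export
identify_lncrnas <- function(transcripts, genome, reference,
                             categories = NULL, min_len = 200L,
                             max_orf_aa = 100L, score_cutoff = 0.5,
                             min_orf_nt_350 = FALSE) {
  if (is.null(categories))
    categories <- classify_isoforms(transcripts, reference)
  cand <- transcripts[categories$category != "known"]
  ref_ex <- GenomicRanges::GRanges(
    seqnames = unlist(lapply(reference, function(t)
      rep(t$chrom, nrow(t$exons)))),
    ranges = IRanges::IRanges(
      start = unlist(lapply(reference, function(t) t$exons[, 1L] + 1L)),
      end = unlist(lapply(reference, function(t) t$exons[, 2L]))),
    strand = unlist(lapply(reference, function(t)
      rep(t$strand, nrow(t$exons)))))
  ref_tbl <- data.frame(
    chrom = vapply(reference, `[[`, character(1), "chrom"),
    strand = vapply(reference, `[[`, character(1), "strand"),
    idx = seq_along(reference), stringsAsFactors = FALSE)
  rows <- list()
  for (t in cand) {
    s <- transcript_sequence(t, genome)
    len <- nchar(s)
    if (len < min_len) next
    orf <- longest_orf(s)
    if (orf$length_aa > max_orf_aa) next
    if (min_orf_nt_350 && len < 350L) next
    score <- coding_potential(s, orf)
    if (score >= score_cutoff) next
    q <- GenomicRanges::GRanges(
      t$chrom, IRanges::IRanges(t$exons[, 1L] + 1L, t$exons[, 2L]), t$strand)
    sense_hit <- length(suppressWarnings(GenomicRanges::findOverlaps(
      q, ref_ex, ignore.strand = FALSE))) > 0L
    any_hit <- suppressWarnings(
      GenomicRanges::findOverlaps(q, ref_ex, ignore.strand = TRUE))
    anti_hit <- FALSE
    if (length(any_hit) > 0L) {
      hs <- as.character(BiocGenerics::strand(ref_ex))[
        S4Vectors::subjectHits(any_hit)]
      anti_hit <- any(hs != t$strand)
    }
    cls <- if (sense_hit) "sense_overlapping"
    else if (anti_hit) "lncNAT"
    else {
      span <- .tx_span(t)
      inside <- FALSE
      for (ri in ref_tbl$idx[ref_tbl$chrom == t$chrom &
                               ref_tbl$strand == t$strand]) {
        intr <- .introns(reference[[ri]])
        if (nrow(intr) && any(intr[, 1L] <= span[1L] &
                                intr[, 2L] >= span[2L])) {
          inside <- TRUE; break
        }
      }
      if (inside) "intronic" else "lincRNA"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = t$transcript_id, length_nt = len,
      n_exons = nrow(t$exons), orf_aa = orf$length_aa,
      coding_score = score, class = cls, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(transcript_id = character(0), length_nt = integer(0),
                      n_exons = integer(0), orf_aa = integer(0),
                      coding_score = numeric(0), class = character(0)))
  do.call(rbind, rows)
}

#' Pair lncRNAs with candidate target genes by expression correlation
#'
#' lincRNAs pair with the nearest reference coding gene within
#' `max_dist_nt`; lncNAT / sense_overlapping / intronic records pair with the
#' gene they overlap. The Pearson correlation of the expression profiles
#' classifies each pair: positive (r > `r_threshold`), negative
#' (r < -`r_threshold`), else none. Pairs with a zero-variance profile on
#' either side are skipped (ids in `attr(,"skipped")`).
#'
#' @param lncrnas data.frame from [identify_lncrnas()].
#' @param transcripts observed transcript list (to locate the lncRNAs).
#' @param coding_genes data.frame: `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open spans of the reference coding genes).
#' @param expression numeric matrix whose rows cover both lncRNA transcript
#'   ids and coding gene ids (same sample columns).
#' @param max_dist_nt lincRNA pairing radius (default 1e5).
#' @param r_threshold correlation threshold (default 0.6).
#' @return data.frame: `lnc_id`, `class`, `target_gene`, `distance`, `pcc`,
#'   `pair_class`.
#' @export
lnc_target_pairs <- function(lncrnas, transcripts, coding_genes, expression,
                             max_dist_nt = 1e5, r_threshold = 0.6) {
  tx_by_id <- stats::setNames(
    transcripts, vapply(transcripts, `[[`, character(1), "transcript_id"))
  skipped <- character(0)
  rows <- list()
  for (i in seq_len(nrow(lncrnas))) {
    id <- lncrnas$transcript_id[i]
    t <- tx_by_id[[id]]
    if (is.null(t)) next
    span <- .tx_span(t)
    cand <- coding_genes[coding_genes$chrom == t$chrom, , drop = FALSE]
    if (lncrnas$class[i] == "lincRNA") {
      if (nrow(cand) == 0L) next
      dist <- pmax(0L, pmax(cand$start - span[2L], span[1L] - cand$end))
      j <- which.min(dist)
      if (dist[j] > max_dist_nt) next
      target <- cand$gene_id[j]; d <- dist[j]
    } else {
      want_strand <- if (lncrnas$class[i] == "lncNAT")
        setdiff(c("+", "-"), t$strand) else t$strand
      cand <- cand[cand$strand == want_strand &
                     cand$start < span[2L] & cand$end > span[1L], ,
                   drop = FALSE]
      if (nrow(cand) == 0L) next
      ov <- pmin(cand$end, span[2L]) - pmax(cand$start, span[1L])
      j <- which.max(ov)
      target <- cand$gene_id[j]; d <- 0L
    }
    if (!id %in% rownames(expression) ||
        !target %in% rownames(expression)) next
    x <- expression[id, ]; y <- expression[target, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      skipped <- c(skipped, paste(id, target, sep = "|")); next
    }
    r <- stats::cor(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      lnc_id = id, class = lncrnas$class[i], target_gene = target,
      distance = d, pcc = r,
      pair_class = if (r > r_threshold) "positive"
      else if (r < -r_threshold) "negative" else "none",
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lnc_id = character(0), class = character(0),
               target_gene = character(0), distance = integer(0),
               pcc = numeric(0), pair_class = character(0))
  attr(res, "skipped") <- skipped
  res
}
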