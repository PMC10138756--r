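# Alternative transcript start/termination sites, poly(A) tail and cleavage
# site calling from full-length reads, and downstream site analyses.

# 0-based genomic position of the first (TSS) or last (TTS) transcribed base
.end_pos <- function(t, end_kind) {
  s <- .tx_span(t)
  if (end_kind == "TSS") {
    if (t$strand == "+") s[1L] else s[2L] - 1L
  } else {
    if (t$strand == "+") s[2L] - 1L else s[1L]
  }
}

#' Cluster transcript 5' or 3' ends within a locus
#'
#' 1-D single-linkage clustering of the strand-appropriate end coordinates:
#' ends whose sorted gaps never exceed `tolerance_nt` join one cluster. A
#' locus with two or more clusters carries an alternative TSS (or TTS).
#'
#' @param transcripts list of `"transcript"` objects of one locus.
#' @param end_kind `"TSS"` or `"TTS"`.
#' @param tolerance_nt linkage tolerance in nt (default 50).
#' @return list with `clusters` (data.frame: `cluster`, `representative`
#'   (modal position), `n_members`, `member_ids`) and `alternative`
#'   (TRUE iff >= 2 clusters).
#' @export
cluster_ends <- function(transcripts, end_kind = c("TSS", "TTS"),
                         tolerance_nt = 50L) {
  end_kind <- match.arg(end_kind)
  pos <- vapply(transcripts, .end_pos, integer(1), end_kind = end_kind)
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  cl <- .linkage_1d(pos, tolerance_nt)
  reps <- vapply(sort(unique(cl)), function(k) .int_mode(pos[cl == k]),
                 integer(1))
  clusters <- data.frame(
    cluster = sort(unique(cl)),
    representative = reps,
    n_members = as.integer(table(cl)),
    member_ids = vapply(sort(unique(cl)), function(k)
      paste(sort(ids[cl == k]), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  list(clusters = clusters, alternative = nrow(clusters) >= 2L,
       end_kind = end_kind, tolerance_nt = tolerance_nt)
}

#' Call a poly(A) tail and cleavage site for one full-length read
#'
#' The soft-clipped 3'-terminal segment of the read (everything after the
#' last aligned base) is scanned in 30-base windows; shorter terminal
#' segments are evaluated as-is. A tail is called when some window holds at
#' least `min_a` adenines and at most `max_non_a` non-A bases. The cleavage
#' site is the genomic position immediately following the last aligned
#' transcript base, on the transcript strand.
#'
#' @param read_seq read sequence, 5' to 3' in transcript orientation (FLNC).
#' @param aligned_len number of read bases consumed by the alignment (the
#'   aligned prefix; the remainder is the 3' soft clip).
#' @param chrom,strand,aln_start,aln_end genomic alignment coordinates
#'   (0-based half-open); `NA` for unaligned reads, in which case a tail may
#'   still be called but no cleavage site is reported.
#' @param min_a minimum adenines per window (default 8).
#' @param max_non_a maximum non-A bases per window (default 1; the rule
#'   "fewer than two non-A bases in 30 bases").
#' @param window window width in bases (default 30).
#' @param mode `"sliding"` scans every window over the clipped segment;
#'   `"anchored"` evaluates only the window adjacent to the alignment.
#' @return list: `tail_detected`, `a_count`, `non_a_count`, `window_len`
#'   (statistics of the best window), `cleavage_site` (0-based genomic
#'   coordinate or NA), `chrom`, `strand`, `aligned`.
#' @export
call_polya <- function(read_seq, aligned_len, chrom = NA_character_,
                       strand = NA_character_, aln_start = NA_integer_,
                       aln_end = NA_integer_, min_a = 8L, max_non_a = 1L,
                       window = 30L, mode = c("sliding", "anchored")) {
  mode <- match.arg(mode)
  read_seq <- toupper(read_seq)
  tail_seq <- if (aligned_len < nchar(read_seq))
    substr(read_seq, aligned_len + 1L, nchar(read_seq)) else ""
  len <- nchar(tail_seq)
  best <- c(a = 0L, non_a = 0L, wl = 0L)
  detected <- FALSE
  if (len > 0L) {
    bases <- strsplit(tail_seq, "", fixed = TRUE)[[1L]]
    is_a <- as.integer(bases == "A")
    if (len <= window) {
      offs <- 1L
      wl <- len
    } else {
      offs <- if (mode == "sliding") seq_len(len - window + 1L) else 1L
      wl <- window
    }
    ca <- c(0L, cumsum(is_a))
    for (o in offs) {
      a <- ca[o + wl] - ca[o]
      na <- wl - a
      if (a > best[["a"]]) best <- c(a = a, non_a = na, wl = wl)
      if (a >= min_a && na <= max_non_a) {
        detected <- TRUE
        best <- c(a = a, non_a = na, wl = wl)
        break
      }
    }
  }
  aligned <- !is.na(aln_start) && !is.na(aln_end) && !is.na(strand)
  cleavage <- NA_integer_
  if (aligned)
    cleavage <- if (strand == "+") as.integer(aln_end)
  else as.integer(aln_start) - 1L
  list(tail_detected = detected, a_count = unname(best[["a"]]),
       non_a_count = unname(best[["non_a"]]),
       window_len = unname(best[["wl"]]), cleavage_site = cleavage,
       chrom = chrom, strand = strand, aligned = aligned)
}

#' Read BED12 alignment records for full-length reads
#'
#' Only the fields this pipeline needs are retained: read id, chromosome,
#' strand, alignment span, and the aligned read length (sum of block sizes).
#'
#' @param path BED12 file.
#' @return data.frame: `read_id`, `chrom`, `strand`, `aln_start`, `aln_end`
#'   (0-based half-open), `aligned_len`.
#' @export
read_alignments_bed12 <- function(path) {
  if (!file.exists(path)) .fail("alignment BED12 not found: %s", path)
  bed <- rtracklayer::import(path, format = "bed")
  widths <- vapply(bed$blocks, function(b) sum(BiocGenerics::width(b)),
                   integer(1))
  data.frame(read_id = bed$name,
             chrom = as.character(GenomicRanges::seqnames(bed)),
             strand = as.character(BiocGenerics::strand(bed)),
             aln_start = BiocGenerics::start(bed) - 1L,
             aln_end = BiocGenerics::end(bed),
             aligned_len = widths, stringsAsFactors = FALSE)
}

#' Call poly(A) tails for a batch of reads
#'
#' @param reads named character vector of read sequences (names = read ids).
#' @param alignments data.frame from [read_alignments_bed12()]; reads absent
#'   from it are treated as unaligned.
#' @param ... passed to [call_polya()].
#' @return data.frame, one row per read: `read_id`, `tail_detected`,
#'   `a_count`, `non_a_count`, `window_len`, `chrom`, `strand`,
#'   `cleavage_site`, `aligned`.
#' @export
call_polya_batch <- function(reads, alignments, ...) {
  aln <- alignments[match(names(reads), alignments$read_id), , drop = FALSE]
  rows <- lapply(seq_along(reads), function(i) {
    a <- aln[i, ]
    unaligned <- is.na(a$read_id)
    r <- call_polya(
      reads[[i]],
      aligned_len = if (unaligned) nchar(reads[[i]]) else a$aligned_len,
      chrom = if (unaligned) NA_character_ else a$chrom,
      strand = if (unaligned) NA_character_ else a$strand,
      aln_start = if (unaligned) NA_integer_ else a$aln_start,
      aln_end = if (unaligned) NA_integer_ else a$aln_end, ...)
    if (unaligned) # tail rule can still fire on the whole read 3' end
      r <- utils::modifyList(r, call_polya(reads[[i]], aligned_len = 0L, ...)[
        c("tail_detected", "a_count", "non_a_count", "window_len")])
    data.frame(read_id = names(reads)[i], tail_detected = r$tail_detected,
               a_count = r$a_count, non_a_count = r$non_a_count,
               window_len = r$window_len, chrom = r$chrom,
               strand = r$strand, cleavage_site = r$cleavage_site,
               aligned = r$aligned, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Collapse read-level cleavage sites into per-gene poly(A) sites
#'
#' Calls with a detected tail and a cleavage site are assigned to the locus
#' (same chrom/strand) whose span, extended by `collapse_tol_nt`, contains
#' the site; cleavage positions within `collapse_tol_nt` of each other are
#' merged by single linkage and each merged site is represented by its modal
#' position.
#'
#' @param calls data.frame from [call_polya_batch()].
#' @param loci a `"locus_set"` from [build_loci()].
#' @param collapse_tol_nt merge tolerance in nt (default 24).
#' @return list with `per_gene` (data.frame: `gene_id`, `site`, `n_reads`),
#'   `sites_per_gene` (data.frame: `gene_id`, `n_sites`) and `histogram`
#'   (data.frame: `n_sites`, `n_genes`).
#' @export
polya_sites_per_gene <- function(calls, loci, collapse_tol_nt = 24L) {
  ok <- calls$tail_detected & !is.na(calls$cleavage_site)
  calls <- calls[ok, , drop = FALSE]
  ltab <- data.frame(
    gene_id = vapply(loci$loci, `[[`, character(1), "locus_id"),
    chrom = vapply(loci$loci, `[[`, character(1), "chrom"),
    strand = vapply(loci$loci, `[[`, character(1), "strand"),
    start = vapply(loci$loci, function(l) l$span[1L], integer(1)),
    end = vapply(loci$loci, function(l) l$span[2L], integer(1)),
    stringsAsFactors = FALSE)
  assign_gene <- function(chrom, strand, site) {
    hit <- which(ltab$chrom == chrom & ltab$strand == strand &
                   site >= ltab$start - collapse_tol_nt &
                   site <= ltab$end + collapse_tol_nt)
    if (length(hit) == 0L) return(NA_character_)
    if (length(hit) > 1L) { # nearest span midpoint
      mid <- (ltab$start[hit] + ltab$end[hit]) / 2
      hit <- hit[which.min(abs(site - mid))]
    }
    ltab$gene_id[hit]
  }
  gene <- mapply(assign_gene, calls$chrom, calls$strand, calls$cleavage_site)
  calls <- calls[!is.na(gene), , drop = FALSE]
  gene <- gene[!is.na(gene)]
  per_gene <- list()
  for (g in unique(gene)) {
    pos <- calls$cleavage_site[gene == g]
    cl <- .linkage_1d(pos, collapse_tol_nt)
    for (k in sort(unique(cl)))
      per_gene[[length(per_gene) + 1L]] <- data.frame(
        gene_id = g, site = .int_mode(pos[cl == k]),
        n_reads = sum(cl == k), stringsAsFactors = FALSE)
  }
  per_gene <- if (length(per_gene)) do.call(rbind, per_gene) else
    data.frame(gene_id = character(0), site = integer(0),
               n_reads = integer(0))
  per_gene <- per_gene[order(per_gene$gene_id, per_gene$site), , drop = FALSE]
  spg <- as.data.frame(table(per_gene$gene_id), stringsAsFactors = FALSE)
  names(spg) <- c("gene_id", "n_sites")
  hist <- as.data.frame(table(spg$n_sites), stringsAsFactors = FALSE)
  names(hist) <- c("n_sites", "n_genes")
  hist$n_sites <- as.integer(hist$n_sites)
  list(per_gene = per_gene, sites_per_gene = spg, histogram = hist)
}

#' Nucleotide composition around poly(A) cleavage sites
#'
#' Per signed offset (transcript orientation; negative = upstream of the
#' cleavage site, 0 = first base after the last transcribed base), the
#' A/C/G/T fractions across sites. N bases are excluded and rows renormalized.
#'
#' @param sites data.frame with columns `chrom`, `strand`, `site` (0-based
#'   genomic cleavage coordinate).
#' @param genome named character vector from [read_genome()].
#' @param upstream,downstream window extent (defaults 50 and 10).
#' @return data.frame: `offset`, `A`, `C`, `G`, `T` (fractions summing to 1).
#' @export
composition_profile <- function(sites, genome, upstream = 50L,
                                downstream = 10L) {
  offsets <- seq(-upstream, downstream)
  counts <- matrix(0L, nrow = length(offsets), ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(sites))) {
    chrseq <- genome[[sites$chrom[i]]]
    if (is.null(chrseq)) next
    gpos <- if (sites$strand[i] == "+") sites$site[i] + offsets
    else sites$site[i] - offsets
    valid <- gpos >= 0L & gpos < nchar(chrseq)
    b <- rep(NA_character_, length(offsets))
    b[valid] <- substring(chrseq, gpos[valid] + 1L, gpos[valid] + 1L)
    if (sites$strand[i] == "-") b <- chartr("ACGT", "TGCA", b)
    for (nt in colnames(counts)) {
      hit <- !is.na(b) & b == nt
      counts[hit, nt] <- counts[hit, nt] + 1L
    }
  }
  tot <- rowSums(counts)
  frac <- counts / ifelse(tot == 0L, NA_real_, tot)
  data.frame(offset = offsets, frac, stringsAsFactors = FALSE)
}

#' Upstream k-mer enrichment at poly(A) sites
#'
#' Counts k-mers in the `upstream`-nt windows 5' of each cleavage site
#' (transcript orientation) against a mononucleotide-preserving shuffled
#' background of the same windows (seeded), ranks them by one-sided binomial
#' p-value (BH-corrected) and fold enrichment.
#'
#' @param sites data.frame with `chrom`, `strand`, `site`.
#' @param genome named character vector from [read_genome()].
#' @param k k-mer width (default 6).
#' @param upstream window width in nt (default 50).
#' @param seed RNG seed for the background shuffle.
#' @param background optional character vector of background windows; when
#'   supplied the shuffle is skipped (self-comparison gives fold ~ 1).
#' @return data.frame: `kmer`, `observed`, `expected`, `fold`, `p_value`,
#'   `q_value`, sorted by p then descending fold.
#' @export
upstream_kmer_enrichment <- function(sites, genome, k = 6L, upstream = 50L,
                                     seed = 1L, background = NULL) {
  wins <- character(0)
  for (i in seq_len(nrow(sites))) {
    chrseq <- genome[[sites$chrom[i]]]
    if (is.null(chrseq)) next
    if (sites$strand[i] == "+") {
      s <- sites$site[i] - upstream; e <- sites$site[i]
      if (s < 0L) next
      wins <- c(wins, substr(chrseq, s + 1L, e))
    } else {
      s <- sites$site[i] + 1L; e <- sites$site[i] + upstream
      if (e >= nchar(chrseq)) next
      wins <- c(wins, revcomp(substr(chrseq, s + 1L, e + 1L)))
    }
  }
  if (length(wins) == 0L) .fail("no usable upstream windows")
  if (is.null(background)) {
    set.seed(seed)
    background <- vapply(strsplit(wins, "", fixed = TRUE), function(b)
      paste(sample(b), collapse = ""), character(1))
  }
  count_kmers <- function(ws) {
    tab <- new.env(parent = emptyenv())
    for (w in ws) {
      n <- nchar(w)
      if (n < k) next
      for (j in seq_len(n - k + 1L)) {
        km <- substr(w, j, j + k - 1L)
        tab[[km]] <- (if (is.null(tab[[km]])) 0L else tab[[km]]) + 1L
      }
    }
    unlist(as.list(tab))
  }
  obs <- count_kmers(wins)
  bg <- count_kmers(background)
  n_obs <- sum(obs); n_bg <- sum(bg)
  kmers <- names(obs)
  bgc <- ifelse(is.na(bg[kmers]), 0L, bg[kmers])
  # background frequency; absent k-mers get half a count so fold and p stay
  # defined (a self-comparison run then yields fold exactly 1)
  p0 <- ifelse(bgc > 0, bgc / n_bg, 0.5 / (n_bg + 1))
  pval <- stats::pbinom(obs - 1L, n_obs, p0, lower.tail = FALSE)
  expected <- p0 * n_obs
  res <- data.frame(kmer = kmers, observed = as.integer(obs),
                    expected = expected, fold = obs / expected,
                    p_value = pval,
                    q_value = stats::p.adjust(pval, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p_value, -res$fold, res$kmer), , drop = FALSE]
}

#' Cross-tabulate AS, aTSS, aTTS and DEG status per multi-isoform gene
#'
#' @param gene_flags data.frame with columns `gene_id`, `has_AS`, `has_aTSS`,
#'   `has_aTTS`, `is_DEG` (one row per multi-isoform gene).
#' @return list with `per_gene` (the input, ordered), `venn` (data.frame of
#'   the 16 flag combinations with counts and fractions) and `n_genes`.
#' @export
coupling_venn <- function(gene_flags) {
  req <- c("gene_id", "has_AS", "has_aTSS", "has_aTTS", "is_DEG")
  if (!all(req %in% names(gene_flags)))
    .fail("gene_flags must have columns %s", paste(req, collapse = ", "))
  combos <- expand.grid(has_AS = c(FALSE, TRUE), has_aTSS = c(FALSE, TRUE),
                        has_aTTS = c(FALSE, TRUE), is_DEG = c(FALSE, TRUE))
  cnt <- vapply(seq_len(nrow(combos)), function(i)
    sum(gene_flags$has_AS == combos$has_AS[i] &
          gene_flags$has_aTSS == combos$has_aTSS[i] &
          gene_flags$has_aTTS == combos$has_aTTS[i] &
          gene_flags$is_DEG == combos$is_DEG[i]), integer(1))
  venn <- cbind(combos, n_genes = cnt,
                fraction = cnt / max(1L, nrow(gene_flags)))
  list(per_gene = gene_flags[order(gene_flags$gene_id), , drop = FALSE],
       venn = venn, n_genes = nrow(gene_flags))
}
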