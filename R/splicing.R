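# Alternative-splicing event detection and typing, splice-site analysis, and
# differential splicing.
#
# Event definitions (pairwise, strand-aware; coordinates 0-based half-open):
#   IR   one transcript carries an intron that lies strictly inside an exon of
#        the other (both flanks exonic). Anchor = the intron.
#   ES   one transcript has a run of >= 1 internal exons flanked by introns
#        whose outer boundaries form a single spanning intron of the other.
#        Anchor = the spanning intron.
#   A5SS two introns share the acceptor and differ at the donor
#        (donor = 5' splice site in transcript orientation).
#   A3SS two introns share the donor and differ at the acceptor.
#        Anchor for A5SS/A3SS = interval between the two alternative sites.
#   MXE  each transcript holds exactly one internal exon between a common
#        donor and a common acceptor, and the two exons do not overlap.
#        Anchor = the common outer intron span.
# Events are deduplicated across transcript pairs by (type, anchor) and
# inclusion/exclusion transcript sets accumulated. "Inclusion" is the form
# retaining more exonic sequence (IR: intron retained; ES: exons included;
# A5SS/A3SS: shorter intron); for MXE it is the form carrying the
# genomic-leftmost of the two exons.

#' Intron chain of a transcript
#'
#' @param t a `"transcript"` object.
#' @return two-column integer matrix of (start, end) introns, 0-based
#'   half-open, genomic-ascending; zero rows for mono-exon models.
#' @export
intron_chain <- function(t) .introns(t)

# events between an ordered transcript pair; returns list of event records
.pair_events <- function(t1, t2) {
  ev <- list()
  strand <- t1$strand
  i1 <- .introns(t1); i2 <- .introns(t2)
  e1 <- t1$exons;     e2 <- t2$exons
  add <- function(type, a, b, extra, inc, exc) {
    key <- paste(type, t1$chrom, a, b, extra, sep = ":")
    ev[[length(ev) + 1L]] <<- list(
      type = type, chrom = t1$chrom, strand = strand,
      anchor_start = a, anchor_end = b, key = key,
      inclusion = inc, exclusion = exc)
  }
  ir_scan <- function(intr, ex, id_keep, id_splice) {
    for (k in seq_len(nrow(intr))) {
      hit <- ex[, 1L] < intr[k, 1L] & ex[, 2L] > intr[k, 2L]
      if (any(hit))
        add("IR", intr[k, 1L], intr[k, 2L], "",
            inc = id_keep, exc = id_splice)
    }
  }
  ir_scan(i2, e1, t1$transcript_id, t2$transcript_id)
  ir_scan(i1, e2, t2$transcript_id, t1$transcript_id)
  es_scan <- function(eA, iA, idA, iB, idB) {
    nA <- nrow(eA)
    if (nA < 3L || nrow(iB) < 1L) return()
    for (u in 2:(nA - 1L)) for (v in u:(nA - 1L)) {
      span <- c(iA[u - 1L, 1L], iA[v, 2L])
      if (any(iB[, 1L] == span[1L] & iB[, 2L] == span[2L])) {
        exstr <- paste(eA[u:v, 1L], eA[u:v, 2L], sep = "-", collapse = ",")
        add("ES", span[1L], span[2L], exstr, inc = idA, exc = idB)
      }
    }
  }
  es_scan(e1, i1, t1$transcript_id, i2, t2$transcript_id)
  es_scan(e2, i2, t2$transcript_id, i1, t1$transcript_id)
  # Alternative 5'/3' splice sites: introns sharing exactly one boundary.
  # The exons flanking the differing boundary must overlap each other — this
  # separates genuine site shifts from exon-skipping and mutually-exclusive
  # configurations, which also produce boundary-sharing intron pairs.
  if (nrow(i1) && nrow(i2)) {
    for (a in seq_len(nrow(i1))) for (b in seq_len(nrow(i2))) {
      s1 <- i1[a, 1L]; e1b <- i1[a, 2L]; s2 <- i2[b, 1L]; e2b <- i2[b, 2L]
      if (s1 == s2 && e1b != e2b) {
        x1 <- e1[e1[, 1L] == e1b, 2L][1L]   # downstream exon ends
        x2 <- e2[e2[, 1L] == e2b, 2L][1L]
        if (max(e1b, e2b) >= min(x1, x2)) next
        type <- if (strand == "+") "A3SS" else "A5SS"
        lo <- min(e1b, e2b); hi <- max(e1b, e2b)
        inc <- if (e1b < e2b) t1$transcript_id else t2$transcript_id
        exc <- if (e1b < e2b) t2$transcript_id else t1$transcript_id
        add(type, lo, hi, paste0("S", s1), inc = inc, exc = exc)
      } else if (e1b == e2b && s1 != s2) {
        y1 <- e1[e1[, 2L] == s1, 1L][1L]    # upstream exon starts
        y2 <- e2[e2[, 2L] == s2, 1L][1L]
        if (max(y1, y2) >= min(s1, s2)) next
        type <- if (strand == "+") "A5SS" else "A3SS"
        lo <- min(s1, s2); hi <- max(s1, s2)
        inc <- if (s1 > s2) t1$transcript_id else t2$transcript_id
        exc <- if (s1 > s2) t2$transcript_id else t1$transcript_id
        add(type, lo, hi, paste0("E", e1b), inc = inc, exc = exc)
      }
    }
  }
  # mutually exclusive exons
  n1 <- nrow(e1); n2 <- nrow(e2)
  if (n1 >= 3L && n2 >= 3L) {
    for (k in 2:(n1 - 1L)) for (m in 2:(n2 - 1L)) {
      if (i1[k - 1L, 1L] == i2[m - 1L, 1L] && i1[k, 2L] == i2[m, 2L]) {
        exA <- e1[k, ]; exB <- e2[m, ]
        if (exA[2L] <= exB[1L] || exB[2L] <= exA[1L]) {
          left_first <- exA[1L] < exB[1L]
          exs <- if (left_first) c(exA, exB) else c(exB, exA)
          inc <- if (left_first) t1$transcript_id else t2$transcript_id
          exc <- if (left_first) t2$transcript_id else t1$transcript_id
          add("MXE", i1[k - 1L, 1L], i1[k, 2L],
              paste(exs, collapse = "-"), inc = inc, exc = exc)
        }
      }
    }
  }
  ev
}

#' Detect and type alternative-splicing events within a locus
#'
#' Enumerates all unordered transcript pairs, emits IR/ES/A5SS/A3SS/MXE
#' events per the pairwise definitions, and deduplicates across pairs by the
#' coordinate anchor, accumulating inclusion- and exclusion-form transcript
#' sets.
#'
#' @param transcripts list of `"transcript"` objects on one chrom/strand
#'   (a locus), or a `"locus_set"` to process every multi-transcript locus.
#' @param locus_id id recorded on emitted events (single-locus form).
#' @return data.frame, one row per deduplicated event: `locus_id`,
#'   `event_type`, `chrom`, `strand`, `anchor_start`, `anchor_end`,
#'   `anchor_key`, `inclusion`, `exclusion` (comma-separated transcript ids),
#'   ordered by (chrom, anchor_start, type).
#' @export
detect_events <- function(transcripts, locus_id = "locus") {
  if (inherits(transcripts, "locus_set")) {
    ls <- transcripts
    out <- lapply(ls$loci, function(lc) {
      if (length(lc$transcript_idx) < 2L) return(NULL)
      detect_events(ls$transcripts[lc$transcript_idx], lc$locus_id)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) out <- detect_events(list(), "empty")
    return(out)
  }
  acc <- new.env(parent = emptyenv())
  n <- length(transcripts)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      for (e in .pair_events(transcripts[[i]], transcripts[[j]])) {
        cur <- acc[[e$key]]
        if (is.null(cur)) {
          e$inclusion <- unique(e$inclusion)
          e$exclusion <- unique(e$exclusion)
          acc[[e$key]] <- e
        } else {
          cur$inclusion <- union(cur$inclusion, e$inclusion)
          cur$exclusion <- union(cur$exclusion, e$exclusion)
          acc[[e$key]] <- cur
        }
      }
    }
  }
  evs <- as.list(acc)
  if (length(evs) == 0L)
    return(data.frame(locus_id = character(0), event_type = character(0),
                      chrom = character(0), strand = character(0),
                      anchor_start = integer(0), anchor_end = integer(0),
                      anchor_key = character(0), inclusion = character(0),
                      exclusion = character(0), stringsAsFactors = FALSE))
  df <- data.frame(
    locus_id = locus_id,
    event_type = vapply(evs, `[[`, character(1), "type"),
    chrom = vapply(evs, `[[`, character(1), "chrom"),
    strand = vapply(evs, `[[`, character(1), "strand"),
    anchor_start = vapply(evs, function(e) as.integer(e$anchor_start), integer(1)),
    anchor_end = vapply(evs, function(e) as.integer(e$anchor_end), integer(1)),
    anchor_key = vapply(evs, `[[`, character(1), "key"),
    inclusion = vapply(evs, function(e)
      paste(sort(setdiff(e$inclusion, e$exclusion)), collapse = ","), character(1)),
    exclusion = vapply(evs, function(e)
      paste(sort(e$exclusion), collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  df[order(df$chrom, df$anchor_start, df$event_type, df$anchor_key), ,
     drop = FALSE]
}

#' Alternative splice-site offsets from the dominant site
#'
#' Donor groups share the acceptor of their intron (and vice versa). Within a
#' group the dominant position is the one used by most isoforms; ties break
#' toward the 5'-most site in transcript orientation. Offsets are signed in
#' transcript orientation (positive = downstream of the dominant site).
#'
#' @param transcripts list of `"transcript"` objects of one locus.
#' @return data.frame: `chrom`, `strand`, `site_kind` (donor/acceptor),
#'   `partner_pos`, `dominant_pos`, `alt_pos`, `offset`, `n_dominant`,
#'   `n_alt`; one row per non-dominant alternative site.
#' @export
splice_site_offsets <- function(transcripts) {
  if (length(transcripts) == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      site_kind = character(0), partner_pos = integer(0),
                      dominant_pos = integer(0), alt_pos = integer(0),
                      offset = integer(0), n_dominant = integer(0),
                      n_alt = integer(0)))
  strand <- transcripts[[1L]]$strand
  chrom <- transcripts[[1L]]$chrom
  intr <- do.call(rbind, lapply(transcripts, .introns))
  if (is.null(intr) || nrow(intr) == 0L)
    return(splice_site_offsets(list()))
  # genomic left end = donor on +, acceptor on -; right end the converse
  left_kind <- if (strand == "+") "donor" else "acceptor"
  right_kind <- if (strand == "+") "acceptor" else "donor"
  rows <- list()
  scan_groups <- function(partner_col, var_col, kind) {
    for (p in unique(intr[, partner_col])) {
      vars <- intr[intr[, partner_col] == p, var_col]
      tab <- table(vars)
      if (length(tab) < 2L) next
      pos <- as.integer(names(tab))
      cnt <- as.integer(tab)
      top <- cnt == max(cnt)
      cand <- pos[top]
      # 5'-most in transcript orientation: smallest genomic on +, largest on -
      dom <- if (strand == "+") min(cand) else max(cand)
      for (q in pos[pos != dom]) {
        off <- if (strand == "+") q - dom else dom - q
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = chrom, strand = strand, site_kind = kind,
          partner_pos = as.integer(p), dominant_pos = dom, alt_pos = q,
          offset = off, n_dominant = cnt[pos == dom], n_alt = cnt[pos == q],
          stringsAsFactors = FALSE)
      }
    }
  }
  # group left ends by shared right end, and vice versa
  scan_groups(2L, 1L, left_kind)
  scan_groups(1L, 2L, right_kind)
  if (length(rows) == 0L) return(splice_site_offsets(list()))
  out <- do.call(rbind, rows)
  out[order(out$partner_pos, out$alt_pos), , drop = FALSE]
}

#' Intron boundary dinucleotides and canonical fraction
#'
#' Reports the first and last two intronic bases in transcript orientation;
#' canonical introns read GT..AG (GU..AG at RNA level) on the transcript
#' strand.
#'
#' @param transcripts list of `"transcript"` objects.
#' @param genome named character vector from [read_genome()].
#' @return list with `per_intron` (data.frame: `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `donor`, `acceptor`, `canonical`) and
#'   `fraction_canonical`.
#' @export
boundary_dinucleotides <- function(transcripts, genome) {
  rows <- lapply(transcripts, function(t) {
    intr <- .introns(t)
    if (nrow(intr) == 0L) return(NULL)
    seqchr <- genome[[t$chrom]]
    first2 <- substring(seqchr, intr[, 1L] + 1L, intr[, 1L] + 2L)
    last2 <- substring(seqchr, intr[, 2L] - 1L, intr[, 2L])
    if (t$strand == "+") {
      donor <- first2; acceptor <- last2
    } else {
      donor <- revcomp(last2); acceptor <- revcomp(first2)
    }
    data.frame(transcript_id = t$transcript_id, chrom = t$chrom,
               strand = t$strand, start = intr[, 1L], end = intr[, 2L],
               donor = donor, acceptor = acceptor,
               canonical = donor == "GT" & acceptor == "AG",
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (is.null(per))
    per <- data.frame(transcript_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), donor = character(0),
                      acceptor = character(0), canonical = logical(0))
  list(per_intron = per,
       fraction_canonical = if (nrow(per)) mean(per$canonical) else NA_real_)
}

#' Correlate per-gene isoform counts with gene structure
#'
#' Spearman correlations of the isoform count per gene against exon number,
#' spliced mRNA length, mean exon length, and GC content, plus quintile-binned
#' mean isoform counts for plotting.
#'
#' @param gene_stats data.frame from [per_gene_stats()].
#' @return list with `correlations` (data.frame: `variable`, `rho`, `p_value`,
#'   `n`; degenerate inputs yield NA) and `binned` (per-variable bin means).
#' @export
as_structure_correlation <- function(gene_stats) {
  if (nrow(gene_stats) < 3L) .fail("need at least 3 genes")
  vars <- c(exon_number = "max_exons", mrna_length = "mean_mrna_length",
            exon_length = "mean_exon_length", gc_content = "mean_gc")
  y <- gene_stats$n_isoforms
  corr <- lapply(names(vars), function(v) {
    x <- gene_stats[[vars[[v]]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(variable = v, rho = NA_real_, p_value = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(variable = v, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  })
  binned <- lapply(stats::setNames(names(vars), names(vars)), function(v) {
    x <- gene_stats[[vars[[v]]]]
    ok <- is.finite(x)
    if (!any(ok)) return(NULL)
    br <- unique(stats::quantile(x[ok], probs = seq(0, 1, 0.2)))
    if (length(br) < 2L) return(NULL)
    bin <- cut(x[ok], breaks = br, include.lowest = TRUE)
    data.frame(bin = levels(bin),
               mean_isoforms = as.numeric(tapply(y[ok], bin, mean)),
               n_genes = as.integer(table(bin)), stringsAsFactors = FALSE)
  })
  list(correlations = do.call(rbind, corr), binned = binned)
}

#' Differential alternative splicing (PSI + Fisher exact + BH)
#'
#' Percent spliced-in per event and sample is inclusion/(inclusion+exclusion)
#' read counts. For each requested sample pair a two-sided Fisher exact test
#' on the 2x2 inclusion/exclusion table is BH-corrected across events; an
#' event is called differentially spliced when q < `q_max` and
#' |delta PSI| >= `min_delta_psi`.
#'
#' @param inclusion,exclusion integer matrices (events x samples) of
#'   supporting read counts, identical dimnames.
#' @param pairs two-column matrix or data.frame of sample-name pairs; default
#'   all unordered pairs.
#' @param q_max,min_delta_psi call thresholds (defaults 0.05 and 0.1).
#' @return data.frame: `event`, `sample1`, `sample2`, `psi1`, `psi2`,
#'   `delta_psi`, `p_value`, `q_value`, `das`, `direction` (sample with the
#'   higher inclusion). Events with zero total counts in either sample of a
#'   pair are skipped for that pair (ids in `attr(,"skipped")`).
#' @export
differential_splicing <- function(inclusion, exclusion, pairs = NULL,
                                  q_max = 0.05, min_delta_psi = 0.1) {
  if (any(inclusion < 0) || any(exclusion < 0))
    .fail("negative read counts")
  samples <- colnames(inclusion)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(samples, 2L))
  } else pairs <- as.matrix(pairs)
  skipped <- character(0)
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    s1 <- pairs[r, 1L]; s2 <- pairs[r, 2L]
    i1 <- inclusion[, s1]; x1 <- exclusion[, s1]
    i2 <- inclusion[, s2]; x2 <- exclusion[, s2]
    ok <- (i1 + x1) > 0 & (i2 + x2) > 0
    skipped <- c(skipped, paste(rownames(inclusion)[!ok], s1, s2, sep = "|"))
    if (!any(ok)) next
    idx <- which(ok)
    p <- vapply(idx, function(k)
      stats::fisher.test(matrix(c(i1[k], x1[k], i2[k], x2[k]), nrow = 2L,
                                byrow = TRUE))$p.value, numeric(1))
    q <- stats::p.adjust(p, method = "BH")
    psi1 <- i1[idx] / (i1[idx] + x1[idx])
    psi2 <- i2[idx] / (i2[idx] + x2[idx])
    dpsi <- psi1 - psi2
    out[[length(out) + 1L]] <- data.frame(
      event = rownames(inclusion)[idx], sample1 = s1, sample2 = s2,
      psi1 = psi1, psi2 = psi2, delta_psi = dpsi, p_value = p, q_value = q,
      das = q < q_max & abs(dpsi) >= min_delta_psi,
      direction = ifelse(dpsi > 0, s1, ifelse(dpsi < 0, s2, "equal")),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(event = character(0), sample1 = character(0),
               sample2 = character(0), psi1 = numeric(0), psi2 = numeric(0),
               delta_psi = numeric(0), p_value = numeric(0),
               q_value = numeric(0), das = logical(0),
               direction = character(0))
  attr(res, "skipped") <- skipped
  res
}
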