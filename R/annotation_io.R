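# Transcript models, genome sequences, and annotation I/O.
#
# Internal coordinates are 0-based half-open throughout; GTF/GFF3 use 1-based
# inclusive coordinates and the conversion happens only at the file boundary.

#' Construct a validated transcript model
#'
#' The atomic unit of the package: an exon chain on one strand of one
#' chromosome. Exons are stored genomic-ascending as a two-column matrix of
#' 0-based half-open intervals.
#'
#' @param transcript_id character scalar.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`; unstranded models are rejected because every
#'   downstream comparison (splice-site orientation, TSS/TTS, ORFs) is
#'   strand-aware.
#' @param exons two-column numeric matrix (start, end), 0-based half-open.
#'   Rows may be unsorted; they are sorted and validated.
#' @param gene_id optional gene assignment (filled in by [build_loci()] when
#'   absent).
#' @return an object of class `"transcript"`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons,
                             gene_id = NA_character_) {
  if (!strand %in% c("+", "-"))
    .fail("transcript %s: strand must be '+' or '-', got '%s'",
          transcript_id, strand)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L)
    .fail("transcript %s: at least one exon required", transcript_id)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] >= exons[, 2L]))
    .fail("transcript %s: exon start must be < end", transcript_id)
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] - exons[-nrow(exons), 2L] < 1L))
    .fail("transcript %s: exons must be separated by >= 1 nt", transcript_id)
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = strand,
         exons = exons),
    class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s> %s:%s %d exon(s), span %d-%d, %d nt\n",
              x$transcript_id, x$chrom, x$strand, nrow(x$exons),
              x$exons[1L, 1L], x$exons[nrow(x$exons), 2L],
              transcript_length(x)))
  invisible(x)
}

#' Spliced length of a transcript model
#' @param t a `"transcript"` object.
#' @return integer, sum of exon lengths.
#' @export
transcript_length <- function(t) {
  sum(t$exons[, 2L] - t$exons[, 1L])
}

# genomic span (start, end) of a transcript
.tx_span <- function(t) c(t$exons[1L, 1L], t$exons[nrow(t$exons), 2L])

#' Read transcript models from GTF or GFF3
#'
#' Exon features are grouped per transcript and converted from the 1-based
#' inclusive file convention to 0-based half-open internal coordinates. For
#' GTF, `transcript_id`/`gene_id` attributes are used; for GFF3, the exon
#' `Parent` identifies the transcript and the transcript feature's `Parent`
#' the gene.
#'
#' @param path file path.
#' @param format `"gtf"` or `"gff3"`; guessed from the extension by default.
#' @return list of `"transcript"` objects, ordered by (chrom, start, id).
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE))
      "gff3" else "gtf"
  }
  if (!file.exists(path)) .fail("annotation file not found: %s", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 8L)) {
    bad <- which(body)[which(nfield < 8L)[1L]]
    .fail("malformed %s line %d in %s: fewer than 8 tab-separated fields",
          format, bad, path)
  }
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  ex <- gr[as.character(gr$type) == "exon"]
  if (length(ex) == 0L) .fail("no exon features in %s", path)
  if (format == "gtf") {
    tid <- as.character(ex$transcript_id)
    gid <- as.character(ex$gene_id)
  } else {
    parents <- as(ex$Parent, "CharacterList")
    if (any(lengths(parents) == 0L))
      .fail("GFF3 exon without Parent attribute in %s", path)
    tid <- vapply(parents, `[`, character(1), 1L)
    # map transcript -> gene via the transcript-level features
    txf <- gr[as.character(gr$type) %in%
                c("mRNA", "transcript", "lnc_RNA", "ncRNA")]
    g_of_t <- rep(NA_character_, length(txf))
    if (length(txf)) {
      tp <- as(txf$Parent, "CharacterList")
      g_of_t <- ifelse(lengths(tp) > 0L,
                       vapply(tp, function(p) if (length(p)) p[[1L]] else
                         NA_character_, character(1)),
                       NA_character_)
      names(g_of_t) <- as.character(txf$ID)
    }
    gid <- unname(g_of_t[tid])
  }
  strand_chr <- as.character(BiocGenerics::strand(ex))
  if (any(strand_chr == "*"))
    .fail("unstranded exon record(s) in %s: strand '.' is not supported", path)
  sp <- split(seq_along(ex), tid)
  txs <- lapply(names(sp), function(id) {
    idx <- sp[[id]]
    transcript_model(
      transcript_id = id,
      chrom = as.character(GenomicRanges::seqnames(ex))[idx][1L],
      strand = strand_chr[idx][1L],
      exons = cbind(BiocGenerics::start(ex)[idx] - 1L,
                    BiocGenerics::end(ex)[idx]),
      gene_id = gid[idx][1L])
  })
  ord <- order(vapply(txs, `[[`, character(1), "chrom"),
               vapply(txs, function(t) t$exons[1L, 1L], integer(1)),
               vapply(txs, `[[`, character(1), "transcript_id"))
  txs[ord]
}

#' Write transcript models as GTF
#'
#' Emits one `exon` feature per exon with `gene_id`/`transcript_id`
#' attributes (ensembl dialect), converting back to 1-based inclusive
#' coordinates.
#'
#' @param transcripts list of `"transcript"` objects.
#' @param path output path.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- unlist(lapply(transcripts, function(t) {
    gid <- if (is.na(t$gene_id)) t$transcript_id else t$gene_id
    sprintf('%s\tisoplexr\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            t$chrom, t$exons[, 1L] + 1L, t$exons[, 2L], t$strand,
            gid, t$transcript_id)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write transcript models as GFF3 (gene/mRNA/exon with Parent chains)
#' @inheritParams write_gtf
#' @export
write_gff3 <- function(transcripts, path) {
  out <- "##gff-version 3"
  gids <- vapply(transcripts, function(t)
    if (is.na(t$gene_id)) t$transcript_id else t$gene_id, character(1))
  for (g in unique(gids)) {
    members <- transcripts[gids == g]
    span <- range(unlist(lapply(members, .tx_span)))
    t0 <- members[[1L]]
    out <- c(out, sprintf("%s\tisoplexr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          t0$chrom, span[1L] + 1L, span[2L], t0$strand, g))
    for (t in members) {
      s <- .tx_span(t)
      out <- c(out,
               sprintf("%s\tisoplexr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       t$chrom, s[1L] + 1L, s[2L], t$strand,
                       t$transcript_id, g),
               sprintf("%s\tisoplexr\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       t$chrom, t$exons[, 1L] + 1L, t$exons[, 2L], t$strand,
                       t$transcript_id))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Export transcript models as BED12
#' @inheritParams write_gtf
#' @export
write_bed12 <- function(transcripts, path) {
  lines <- vapply(transcripts, function(t) {
    s <- .tx_span(t)
    sizes <- t$exons[, 2L] - t$exons[, 1L]
    starts <- t$exons[, 1L] - s[1L]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            t$chrom, s[1L], s[2L], t$transcript_id, t$strand,
            s[1L], s[2L], nrow(t$exons),
            paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(starts, collapse = ","), ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one uppercase sequence per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) .fail("genome FASTA not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a named character vector of sequences as FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Spliced transcript sequence (5' to 3')
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for minus-strand models. `N` bases pass through unchanged.
#'
#' @param t a `"transcript"` object.
#' @param genome named character vector from [read_genome()].
#' @return nucleotide string in transcript orientation.
#' @export
transcript_sequence <- function(t, genome) {
  if (!t$chrom %in% names(genome))
    .fail("chromosome %s not in genome", t$chrom)
  chrlen <- nchar(genome[[t$chrom]])
  if (any(t$exons[, 1L] < 0L) || any(t$exons[, 2L] > chrlen))
    .fail("transcript %s: exon outside chromosome bounds (length %d)",
          t$transcript_id, chrlen)
  seqs <- substring(genome[[t$chrom]], t$exons[, 1L] + 1L, t$exons[, 2L])
  s <- paste(seqs, collapse = "")
  if (t$strand == "-") revcomp(s) else s
}

#' GC content of a nucleotide sequence
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param seq nucleotide string (any case).
#' @return fraction of G+C among non-N bases, in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  n_total <- nchar(seq) - nchar(gsub("[^N]", "", seq))
  if (nchar(seq) == 0L || n_total == 0L)
    .fail("GC content undefined for an empty or all-N sequence")
  n_gc <- nchar(gsub("[^GC]", "", seq))
  n_gc / n_total
}
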