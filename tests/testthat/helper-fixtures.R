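# Shared fixtures and independent oracles used across the suite.

# shorthand transcript constructor: ex = c(s1,e1, s2,e2, ...)
tx <- function(id, ex, strand = "+", chrom = "chr1", gene = NA_character_) {
  transcript_model(id, chrom, strand,
                   matrix(ex, ncol = 2, byrow = TRUE), gene_id = gene)
}

# random single-strand locus drawing exon boundaries from a shared site pool
# (heavy boundary reuse creates genuine AS relations between transcripts)
random_locus <- function(n_tx = NULL, max_exons = 8L, pool_size = 14L,
                         span = 4000L) {
  if (is.null(n_tx)) n_tx <- sample(2:5, 1L)
  strand <- sample(c("+", "-"), 1L)
  pool <- sort(sample(seq_len(span), pool_size))
  lapply(seq_len(n_tx), function(i) {
    nex <- sample(seq_len(min(max_exons, pool_size %/% 2L)), 1L)
    b <- sort(sample(pool, 2L * nex))
    transcript_model(paste0("t", i), "chrL", strand,
                     matrix(b, ncol = 2L, byrow = TRUE))
  })
}

# ---- independent brute-force AS-event enumerator -------------------------
# Re-derives every pairwise containment/boundary relation from raw exon
# coordinates with ordered-pair loops; returns the set of event keys in the
# same canonical format detect_events() uses for deduplication.
oracle_event_keys <- function(txs) {
  chrom <- txs[[1L]]$chrom
  strand <- txs[[1L]]$strand
  ex <- lapply(txs, function(t) t$exons)
  keys <- character(0)
  n <- length(txs)
  intr_of <- function(e) {
    k <- nrow(e)
    if (k < 2L) return(NULL)
    cbind(e[-k, 2L], e[-1L, 1L])
  }
  overlap <- function(a1, a2, b1, b2) max(a1, b1) < min(a2, b2)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ei <- ex[[i]]; ej <- ex[[j]]
    ii <- intr_of(ei); ij <- intr_of(ej)
    # IR: some intron of j strictly inside some exon of i (i retains)
    if (!is.null(ij)) for (a in seq_len(nrow(ij)))
      for (b in seq_len(nrow(ei)))
        if (ei[b, 1L] < ij[a, 1L] && ei[b, 2L] > ij[a, 2L])
          keys <- c(keys, paste("IR", chrom, ij[a, 1L], ij[a, 2L], "",
                                sep = ":"))
    # ES: run of internal exons of i whose outer flanks equal an intron of j
    ni <- nrow(ei)
    if (ni >= 3L && !is.null(ij)) for (u in 2:(ni - 1L))
      for (v in u:(ni - 1L)) {
        d <- ei[u - 1L, 2L]; acc <- ei[v + 1L, 1L]
        if (any(ij[, 1L] == d & ij[, 2L] == acc))
          keys <- c(keys, paste(
            "ES", chrom, d, acc,
            paste(ei[u:v, 1L], ei[u:v, 2L], sep = "-", collapse = ","),
            sep = ":"))
      }
    if (i < j) {
      # boundary-sharing intron pairs (flanking exons must overlap)
      if (!is.null(ii) && !is.null(ij))
        for (a in seq_len(nrow(ii))) for (b in seq_len(nrow(ij))) {
          s1 <- ii[a, 1L]; e1 <- ii[a, 2L]
          s2 <- ij[b, 1L]; e2 <- ij[b, 2L]
          if (s1 == s2 && e1 != e2) {
            x1 <- ei[match(e1, ei[, 1L]), 2L]
            x2 <- ej[match(e2, ej[, 1L]), 2L]
            if (overlap(e1, x1, e2, x2)) {
              type <- if (strand == "+") "A3SS" else "A5SS"
              keys <- c(keys, paste(type, chrom, min(e1, e2), max(e1, e2),
                                    paste0("S", s1), sep = ":"))
            }
          }
          if (e1 == e2 && s1 != s2) {
            y1 <- ei[match(s1, ei[, 2L]), 1L]
            y2 <- ej[match(s2, ej[, 2L]), 1L]
            if (overlap(y1, s1, y2, s2)) {
              type <- if (strand == "+") "A5SS" else "A3SS"
              keys <- c(keys, paste(type, chrom, min(s1, s2), max(s1, s2),
                                    paste0("E", e1), sep = ":"))
            }
          }
        }
      # MXE: one internal exon each between common flanks, non-overlapping
      nj <- nrow(ej)
      if (ni >= 3L && nj >= 3L)
        for (a in 2:(ni - 1L)) for (b in 2:(nj - 1L)) {
          if (ei[a - 1L, 2L] == ej[b - 1L, 2L] &&
              ei[a + 1L, 1L] == ej[b + 1L, 1L] &&
              !overlap(ei[a, 1L], ei[a, 2L], ej[b, 1L], ej[b, 2L])) {
            pairex <- if (ei[a, 1L] < ej[b, 1L])
              c(ei[a, ], ej[b, ]) else c(ej[b, ], ei[a, ])
            keys <- c(keys, paste("MXE", chrom, ei[a - 1L, 2L],
                                  ej[b + 1L, 1L],
                                  paste(pairex, collapse = "-"), sep = ":"))
          }
        }
    }
  }
  sort(unique(keys))
}

# ---- independent poly(A) window-rule evaluation --------------------------
oracle_tail_rule <- function(tail, min_a = 8L, max_non_a = 1L,
                             window = 30L) {
  len <- nchar(tail)
  if (len == 0L) return(FALSE)
  b <- strsplit(toupper(tail), "", fixed = TRUE)[[1L]]
  w <- min(window, len)
  for (o in seq_len(len - w + 1L)) {
    win <- b[o:(o + w - 1L)]
    if (sum(win == "A") >= min_a && sum(win != "A") <= max_non_a)
      return(TRUE)
  }
  FALSE
}

# ---- independent multiset-difference classifier --------------------------
oracle_domain_class <- function(ref, iso) {
  nm <- union(ref, iso)
  lost <- sum(vapply(nm, function(d)
    max(0L, sum(ref == d) - sum(iso == d)), integer(1)))
  gained <- sum(vapply(nm, function(d)
    max(0L, sum(iso == d) - sum(ref == d)), integer(1)))
  if (lost == 0L && gained == 0L) "unchanged"
  else if (lost > 0L && gained > 0L) "both"
  else if (lost > 0L) "loss" else "gain"
}

# rank-based AUC (probability a positive scores above a negative)
score_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# small deterministic genome string from a seed
random_genome <- function(len, seed = 1L, gc = 0.45) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}
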