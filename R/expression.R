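# Expression stack: FPKM normalization, PCA, profile clustering,
# no-replicate differential expression, and hypergeometric term enrichment.

#' FPKM normalization
#'
#' FPKM = count * 1e9 / (length_nt * library_size), with the library size
#' defaulting to the column sum of the count matrix.
#'
#' @param counts non-negative matrix, features x samples.
#' @param lengths feature lengths in nt (recycled by row), positive.
#' @param library_sizes optional per-sample totals.
#' @return FPKM matrix with the input dimnames.
#' @export
fpkm <- function(counts, lengths, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .fail("negative counts")
  if (any(lengths <= 0)) .fail("transcript lengths must be positive")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  sweep(counts / lengths, 2L, library_sizes, "/") * 1e9
}

#' PCA of expression profiles across samples
#'
#' Samples are the observations, features the variables; values are
#' log2(FPKM + 1) (optional), feature-centered. Score signs are fixed by
#' making the largest-magnitude loading of each component positive, so the
#' decomposition is fully deterministic.
#'
#' @param mat numeric matrix, features x samples.
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @param n_components number of components to keep.
#' @return list: `scores` (samples x components), `loadings`,
#'   `explained_variance` (fractions of total variance, non-increasing).
#' @export
pca_expression <- function(mat, log_transform = TRUE,
                           n_components = NULL) {
  if (ncol(mat) < 2L) .fail("PCA needs at least 2 samples")
  x <- if (log_transform) log2(mat + 1) else mat
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  k <- if (is.null(n_components)) ncol(pr$x) else
    min(n_components, ncol(pr$x))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = load,
       explained_variance = (pr$sdev^2 / total_var)[seq_len(k)])
}

#' Cluster expression profiles with seeded k-means
#'
#' Rows are z-scored (zero-variance rows dropped and reported), rows are
#' processed in a canonical id order so the result is invariant to input row
#' order, and k-means runs with a fixed seed and `nstart` restarts. Cluster
#' labels are renumbered by descending cluster size.
#'
#' @param mat numeric matrix, features x samples, with rownames.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 25).
#' @return list: `assignment` (named integer vector, feature -> cluster),
#'   `centers` (k x samples mean z-profiles, in final label order),
#'   `dropped` (ids of zero-variance rows).
#' @export
cluster_profiles <- function(mat, k, seed = 1L, nstart = 25L) {
  if (is.null(rownames(mat))) .fail("matrix must have rownames")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  sds <- apply(mat, 1L, stats::sd)
  dropped <- rownames(mat)[sds == 0 | is.na(sds)]
  mat <- mat[!(rownames(mat) %in% dropped), , drop = FALSE]
  if (nrow(mat) < k) .fail("fewer usable rows (%d) than clusters (%d)",
                           nrow(mat), k)
  z <- t(scale(t(mat)))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100L)
  sizes <- as.integer(table(factor(km$cluster, levels = seq_len(k))))
  relabel <- order(-sizes, seq_len(k))
  newlab <- match(km$cluster, relabel)
  centers <- km$centers[relabel, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(assignment = stats::setNames(newlab, rownames(mat)),
       centers = centers, dropped = dropped)
}

#' Pairwise no-replicate differential expression
#'
#' With single samples per condition, a gene is differentially expressed
#' between two samples when |log2((a+1)/(b+1))| >= `min_fold` and
#' max(a, b) >= `min_fpkm`.
#'
#' @param mat FPKM matrix, genes x samples.
#' @param pairs optional two-column matrix of sample names; default all
#'   unordered pairs.
#' @param min_fold minimum absolute log2 fold change (default 1).
#' @param min_fpkm minimum expression of the higher sample (default 1).
#' @return list: `per_pair` (data.frame: `gene_id`, `sample1`, `sample2`,
#'   `log2_fc`, `deg`), `union` (character vector of genes DE in any pair).
#' @export
deg_pairwise <- function(mat, pairs = NULL, min_fold = 1, min_fpkm = 1) {
  samples <- colnames(mat)
  if (is.null(pairs)) pairs <- t(utils::combn(samples, 2L))
  pairs <- as.matrix(pairs)
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- mat[, pairs[r, 1L]]; b <- mat[, pairs[r, 2L]]
    lfc <- log2((a + 1) / (b + 1))
    data.frame(gene_id = rownames(mat), sample1 = pairs[r, 1L],
               sample2 = pairs[r, 2L], log2_fc = lfc,
               deg = abs(lfc) >= min_fold & pmax(a, b) >= min_fpkm,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  per_pair <- do.call(rbind, out)
  list(per_pair = per_pair,
       union = sort(unique(per_pair$gene_id[per_pair$deg])))
}

#' Hypergeometric term over-representation
#'
#' Classic one-sided enrichment: for each term, the probability of drawing
#' at least the observed number of term members when sampling the selected
#' set from the universe, BH-corrected across terms.
#'
#' @param selected character vector, subset of `universe`.
#' @param universe character vector of all testable genes.
#' @param term2gene data.frame with columns `term`, `gene`.
#' @return data.frame: `term`, `n_selected_in_term`, `n_term`, `n_selected`,
#'   `n_universe`, `p_value`, `q_value`, sorted by p.
#' @export
term_enrichment <- function(selected, universe, term2gene) {
  if (length(selected) == 0L) .fail("empty selected set")
  if (!all(selected %in% universe))
    .fail("selected set must be a subset of the universe")
  selected <- unique(selected); universe <- unique(universe)
  n <- length(selected); N <- length(universe)
  terms <- split(term2gene$gene, term2gene$term)
  rows <- lapply(names(terms), function(tm) {
    g <- intersect(unique(terms[[tm]]), universe)
    K <- length(g)
    if (K == 0L) return(NULL)
    x <- length(intersect(g, selected))
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_selected_in_term = x, n_term = K,
               n_selected = n, n_universe = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) .fail("no terms overlap the universe")
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$term), , drop = FALSE]
}
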