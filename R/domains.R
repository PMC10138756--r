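# Conserved-domain comparison across a gene's isoforms: each isoform is
# compared against the gene's reference (fullest-domain) isoform and labelled
# unchanged / loss / gain / both by multiset difference of domain names.

#' Read a per-isoform domain annotation table
#'
#' @param path TSV with columns `isoform_id`, `domain_name`, `start_aa`,
#'   `end_aa` (header required).
#' @return the table as a data.frame.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) .fail("domain table not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("isoform_id", "domain_name", "start_aa", "end_aa")
  if (!all(req %in% names(d)))
    .fail("domain table must have columns %s", paste(req, collapse = ", "))
  d
}

# domain multiset of one isoform as a sorted character vector
.domain_multiset <- function(domains, isoform_id) {
  sort(domains$domain_name[domains$isoform_id == isoform_id])
}

# multiset difference a - b on character vectors
.mdiff <- function(a, b) {
  for (x in b) {
    i <- match(x, a)
    if (!is.na(i)) a <- a[-i]
  }
  a
}

#' Select the reference isoform of a gene
#'
#' The isoform carrying the most domains (multiset cardinality); ties break
#' toward the longest ORF, then the lexicographically smallest id.
#'
#' @param isoform_ids isoforms of the gene.
#' @param domains domain table ([read_domains()] format).
#' @param orf_aa optional named numeric vector of ORF lengths (aa) used for
#'   tie-breaking.
#' @return the selected isoform id.
#' @export
select_reference_isoform <- function(isoform_ids, domains, orf_aa = NULL) {
  if (length(isoform_ids) == 0L) .fail("no isoforms supplied")
  ndom <- vapply(isoform_ids, function(id)
    length(.domain_multiset(domains, id)), integer(1))
  orfs <- if (is.null(orf_aa)) rep(0, length(isoform_ids)) else
    ifelse(is.na(orf_aa[isoform_ids]), 0, orf_aa[isoform_ids])
  ord <- order(-ndom, -orfs, isoform_ids)
  isoform_ids[ord[1L]]
}

#' Classify an isoform's domain change against the reference isoform
#'
#' Lost = reference multiset minus isoform multiset; gained = isoform minus
#' reference (by domain name, with multiplicity). Class is `unchanged` when
#' both are empty, `loss`/`gain` when exactly one is non-empty, `both`
#' otherwise.
#'
#' @param isoform_id,reference_id isoform ids present in `domains` (possibly
#'   with empty domain lists).
#' @param domains domain table.
#' @return list: `isoform_id`, `reference_isoform_id`, `lost`, `gained`
#'   (character vectors), `class`.
#' @export
classify_domain_change <- function(isoform_id, reference_id, domains) {
  iso <- .domain_multiset(domains, isoform_id)
  ref <- .domain_multiset(domains, reference_id)
  lost <- .mdiff(ref, iso)
  gained <- .mdiff(iso, ref)
  cls <- if (length(lost) == 0L && length(gained) == 0L) "unchanged"
  else if (length(lost) > 0L && length(gained) > 0L) "both"
  else if (length(lost) > 0L) "loss" else "gain"
  list(isoform_id = isoform_id, reference_isoform_id = reference_id,
       lost = lost, gained = gained, class = cls)
}

#' Domain-change classification for every isoform of every gene
#'
#' @param gene_isoforms named list: gene id -> character vector of isoform
#'   ids.
#' @param domains domain table.
#' @param orf_aa optional named ORF lengths for reference tie-breaking.
#' @return data.frame: `gene_id`, `isoform_id`, `reference_isoform_id`,
#'   `lost`, `gained` (comma-separated), `class`.
#' @export
classify_domain_changes <- function(gene_isoforms, domains, orf_aa = NULL) {
  rows <- list()
  for (g in names(gene_isoforms)) {
    isos <- sort(gene_isoforms[[g]])
    ref <- select_reference_isoform(isos, domains, orf_aa)
    for (id in isos) {
      ch <- classify_domain_change(id, ref, domains)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, isoform_id = id, reference_isoform_id = ref,
        lost = paste(ch$lost, collapse = ","),
        gained = paste(ch$gained, collapse = ","),
        class = ch$class, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), isoform_id = character(0),
                      reference_isoform_id = character(0),
                      lost = character(0), gained = character(0),
                      class = character(0)))
  do.call(rbind, rows)
}

#' Join domain changes with log2-FPKM expression for a gene family
#'
#' @param isoform_ids isoforms to report (e.g. the members of one family).
#' @param changes data.frame from [classify_domain_changes()].
#' @param expression FPKM matrix with isoform rownames.
#' @return data.frame, one row per isoform in deterministic (gene, isoform)
#'   order: the change columns plus `log2fpkm_<sample>` columns
#'   (log2(FPKM + 1)).
#' @export
family_report <- function(isoform_ids, changes, expression) {
  miss <- setdiff(isoform_ids, rownames(expression))
  if (length(miss))
    .fail("no expression for isoform(s): %s", paste(miss, collapse = ", "))
  sub <- changes[changes$isoform_id %in% isoform_ids, , drop = FALSE]
  sub <- sub[order(sub$gene_id, sub$isoform_id), , drop = FALSE]
  lf <- log2(expression[sub$isoform_id, , drop = FALSE] + 1)
  colnames(lf) <- paste0("log2fpkm_", colnames(lf))
  cbind(sub, as.data.frame(lf, row.names = NULL))
}
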