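# Internal helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' @param seq character vector of DNA sequences (alphabet A/C/G/T/N, any case).
#' @return character vector of reverse complements, uppercase.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

# stopifnot with a formatted message
.fail <- function(...) stop(sprintf(...), call. = FALSE)

# deterministic mode of an integer vector; ties broken toward the smallest
.int_mode <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

# 1-D single-linkage clustering: sorted positions split where the gap between
# consecutive values exceeds `tol`; returns cluster index per input element
.linkage_1d <- function(pos, tol) {
  ord <- order(pos)
  sorted <- pos[ord]
  brk <- c(0L, cumsum(diff(sorted) > tol))
  cl <- integer(length(pos))
  cl[ord] <- brk + 1L
  cl
}
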