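## 5' fragment end-motif spectra. Both physical 5' ends of a double-strand
## fragment contribute: the k bases read forward from the U end, and the
## reverse complement of the k bases ending at the D end.

#' End-motif spectrum of a fragment set
#'
#' @param set a [fragment_set()].
#' @param reference a named [Biostrings::DNAStringSet] (sequences starting
#'   at genomic coordinate 0) or a path to a FASTA file.
#' @param k motif length (default 4).
#' @param mode `"both"` counts both fragment ends (paired-end style);
#'   `"U"`/`"D"` count a single end (single-end style data).
#' @return an object of class `motif_spectrum`: list with `k`, `counts`
#'   (named over all `4^k` motifs), `n_ends`, `n_skipped` (ends at contig
#'   edges or containing non-ACGT bases).
#' @export
end_motif_spectrum <- function(set, reference, k = 4L,
                               mode = c("both", "U", "D")) {
  mode <- match.arg(mode)
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (nrow(set) == 0L) stop("empty fragment set: no ends to profile")
  motifs <- character(0)
  n_ends <- 0L
  for (ch in unique(set$chrom)) {
    if (!(ch %in% names(reference))) stop("reference lacks chromosome ", ch)
    seq_fwd <- toupper(as.character(reference[[ch]]))
    L <- nchar(seq_fwd)
    seq_rc <- as.character(Biostrings::reverseComplement(reference[[ch]]))
    seq_rc <- toupper(seq_rc)
    sel <- set$chrom == ch
    if (mode %in% c("both", "U")) {
      u <- set$start[sel]                      # 0-based; motif [u, u+k)
      ok <- u >= 0L & u + k <= L
      if (any(ok))
        motifs <- c(motifs, substring(seq_fwd, u[ok] + 1L, u[ok] + k))
      n_ends <- n_ends + length(u)
    }
    if (mode %in% c("both", "D")) {
      d <- set$end[sel] - 1L                   # motif rc of [d-k+1, d]
      ok <- d - k + 1L >= 0L & d < L
      ## on the reverse-complemented sequence, genomic base p sits at
      ## index L - p (1-based); the D motif reads rc indices (L-d)..(L-d+k-1)
      if (any(ok))
        motifs <- c(motifs, substring(seq_rc, L - d[ok], L - d[ok] + k - 1L))
      n_ends <- n_ends + length(d)
    }
  }
  all_motifs <- mkmotifs(k)
  valid <- motifs %in% all_motifs
  counts <- table(factor(motifs[valid], levels = all_motifs))
  structure(list(k = as.integer(k),
                 counts = setNames(as.integer(counts), all_motifs),
                 n_ends = as.integer(sum(valid)),
                 n_skipped = as.integer(n_ends - sum(valid))),
            class = "motif_spectrum")
}

## Internal: all 4^k DNA k-mers in lexicographic order.
mkmotifs <- function(k) {
  b <- c("A", "C", "G", "T")
  out <- b
  for (i in seq_len(k - 1L)) out <- as.vector(outer(out, b, paste0))
  sort(out)
}

#' @export
print.motif_spectrum <- function(x, ...) {
  top <- head(sort(motif_frequencies(x), decreasing = TRUE), 5)
  cat("<motif_spectrum> k=", x$k, ", ", x$n_ends, " ends (",
      x$n_skipped, " skipped); top: ",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Motif frequencies of a spectrum
#' @param spectrum a `motif_spectrum`.
#' @return named numeric summing to 1 over all `4^k` motifs.
#' @export
motif_frequencies <- function(spectrum) {
  if (spectrum$n_ends == 0L) stop("spectrum counted no ends")
  spectrum$counts / sum(spectrum$counts)
}

#' Usage of one end motif
#' @param spectrum a `motif_spectrum`.
#' @param motif motif string, e.g. `"CCCA"`.
#' @return its frequency (0 when absent).
#' @export
motif_usage <- function(spectrum, motif = "CCCA") {
  f <- motif_frequencies(spectrum)
  if (!(motif %in% names(f))) return(0)
  unname(f[motif])
}

#' Paired comparison of motif usage between sample types
#'
#' For per-sample usage pairs (e.g. whole-genome sequencing versus MeDIP
#' capture of the same subject), reports the mean per-pair difference
#' (second minus first) and a two-tailed paired t test.
#'
#' @param usage_a,usage_b aligned numeric usage vectors (a = reference
#'   assay, b = comparison assay).
#' @return a list with `mean_diff`, `p_value` (`NA` with fewer than 2
#'   pairs; exactly 1 when all pairs are identical), `n_pairs`.
#' @export
paired_usage_comparison <- function(usage_a, usage_b) {
  stopifnot(length(usage_a) == length(usage_b))
  d <- usage_b - usage_a
  n <- length(d)
  p <- if (n < 2L) {
    NA_real_
  } else {
    ## constant differences degenerate the t statistic: identical pairs
    ## give P = 1, a constant nonzero shift P -> 0
    pv <- tryCatch(t.test(usage_b, usage_a, paired = TRUE)$p.value,
                   error = function(e) NaN)
    if (is.nan(pv)) pv <- as.numeric(all(d == 0))
    pv
  }
  list(mean_diff = mean(d), p_value = p, n_pairs = n)
}
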