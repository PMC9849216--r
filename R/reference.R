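## Synthetic reference sequence. The sequence itself carries no biology
## except the end-motif ground truth: preferred cut sites can be seeded with
## a chosen 4-mer so that motif analyses have recoverable signal.

#' Generate a synthetic reference sequence for a nucleosome track
#'
#' Random uniform A/C/G/T over the track's span (plus padding), except that
#' selected preferred cut sites are seeded with an end motif at a given
#' enrichment: at a seeded upstream cut site the forward-strand 4-mer
#' starting there is set to `motif`; at a seeded downstream cut site the
#' reverse complement of the 4-mer ending there is set to `motif`. By
#' default the linker cut sites are seeded — in the generator's mechanism
#' methylated (nucleosome-protected) DNA is cut in linkers, so the motif
#' tags methylation-associated cutting, mirroring the association of the
#' CCCA motif with methylated-DNA cleavage.
#'
#' @param track a [nucleosome_track()].
#' @param model a [cut_model()] supplying the cut-site offsets.
#' @param motif the end motif to seed (default `"CCCA"`).
#' @param enrichment probability that any given eligible cut site is seeded.
#' @param sites which preferred cut sites to seed: `"linker"`, `"core"`, or
#'   `"none"`.
#' @param pad extra sequence beyond the outermost centers (bp).
#' @param seed integer seed.
#' @return a [Biostrings::DNAStringSet] named by chromosome; sequences start
#'   at genomic coordinate 0.
#' @export
make_reference <- function(track, model = cut_model(), motif = "CCCA",
                           enrichment = 0.7,
                           sites = c("linker", "core", "none"),
                           pad = 200L, seed = 1L) {
  sites <- match.arg(sites)
  if (enrichment < 0 || enrichment > 1) stop("enrichment must be in [0, 1]")
  k <- nchar(motif)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  seqs <- with_seed(seed, {
    lapply(track$centers, function(cent) {
      len <- max(cent) + pad + 1L
      base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      if (sites != "none") {
        u_off <- if (sites == "linker") model$u_linker_offset else model$u_core_offsets
        d_off <- if (sites == "linker") model$d_linker_offset else model$d_core_offsets
        u_sites <- as.vector(outer(cent, u_off, `+`))
        d_sites <- as.vector(outer(cent, d_off, `+`))
        u_sites <- u_sites[runif(length(u_sites)) < enrichment]
        d_sites <- d_sites[runif(length(d_sites)) < enrichment]
        ## U end at position p: forward k-mer occupies [p, p + k)
        for (p in u_sites) {
          if (p >= 0 && p + k <= len)
            base[(p + 1L):(p + k)] <- strsplit(motif, "")[[1]]
        }
        ## D end at position p: k-mer [p - k + 1, p]; its revcomp must read
        ## `motif`, so the forward strand there carries rc(motif)
        for (p in d_sites) {
          if (p - k + 1L >= 0 && p < len)
            base[(p - k + 2L):(p + 1L)] <- strsplit(rc, "")[[1]]
        }
      }
      paste(base, collapse = "")
    })
  })
  Biostrings::DNAStringSet(unlist(seqs))
}
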