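## Fragment-level I/O: BED3+ fragments, BED3 nucleosome-center tracks, TSV
## per-read methylation calls, SAM/BAM paired-end ingestion, deduplication.
## gzip is handled transparently by data.table and R connections.

## Internal: fread with transparent gzip via a base connection (no reliance
## on optional decompression packages).
fread_auto <- function(path, ...) {
  if (file.exists(path) && file.size(path) == 0L)
    return(data.table::data.table())
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    txt <- readLines(con)
    if (length(txt) == 0L) return(data.table::data.table())
    data.table::fread(text = txt, ...)
  } else {
    data.table::fread(path, ...)
  }
}

#' Read fragments from a BED3+ file
#'
#' Columns: chrom, start, end, and optionally sample_id (4th). Coordinates
#' are 0-based half-open. Records with `start >= end` are dropped with a
#' warning; non-numeric coordinates raise an error naming the line.
#'
#' @param path BED file (plain or gzipped).
#' @param sample_id sample id used when the file has no 4th column.
#' @param label sample label attribute.
#' @return a [fragment_set()] in file order.
#' @export
read_fragments_bed <- function(path, sample_id = NULL, label = "control") {
  dt <- fread_auto(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L)
    return(fragment_set(data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0)),
                        sample_id = sample_id %||% "sample", label = label))
  if (ncol(dt) < 3L) stop("BED file must have >= 3 columns: ", path)
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path)
  drop <- which(start >= end)
  if (length(drop)) {
    warning(length(drop), " record(s) with start >= end dropped from ", path)
  }
  keep <- setdiff(seq_len(nrow(dt)), drop)
  sid <- if (ncol(dt) >= 4L) as.character(dt[[4]])[keep]
         else rep(sample_id %||% tools::file_path_sans_ext(basename(path), compression = TRUE),
                  length(keep))
  fragment_set(data.frame(chrom = as.character(dt[[1]])[keep],
                          start = start[keep], end = end[keep],
                          sample_id = sid),
               sample_id = sid[1] %||% "sample", label = label)
}

#' Write fragments as BED3+3
#'
#' Emits chrom, start, end, sample_id, size, strand (`.`), 0-based
#' half-open. `.gz` paths are compressed.
#'
#' @param set a [fragment_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(set, path) {
  dt <- data.table::data.table(chrom = set$chrom, start = set$start,
                               end = set$end, sample_id = set$sample_id,
                               size = set$size, strand = ".")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Reduce paired-end alignments to fragments
#'
#' One fragment per properly paired read pair, spanning the leftmost start
#' to the rightmost end (taken from the leftmost mate's position and TLEN).
#' Secondary, supplementary and unmapped records are skipped; pairs that are
#' not proper or have no usable TLEN are skipped and counted.
#'
#' @param path SAM or BAM file, coordinate order not required.
#' @param sample_id sample id (defaults to the file name).
#' @return a [fragment_set()]; the number of skipped reads is available as
#'   attribute `"n_skipped"`.
#' @export
fragments_from_paired_alignments <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||%
    tools::file_path_sans_ext(basename(path), compression = TRUE)
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE))
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE) else path
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag,
                               what = c("rname", "pos", "isize", "flag"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_total <- length(x$pos)
  proper <- bitwAnd(x$flag, 2L) > 0L
  lead <- proper & !is.na(x$isize) & x$isize > 0L & !is.na(x$pos)
  n_pairs_all <- sum(proper) / 2
  frags <- data.frame(chrom = as.character(x$rname)[lead],
                      start = x$pos[lead] - 1L,             # SAM is 1-based
                      end = x$pos[lead] - 1L + x$isize[lead])
  fs <- fragment_set(frags, sample_id = sample_id)
  attr(fs, "n_skipped") <- n_total - 2L * nrow(frags)
  fs
}

#' Remove duplicate fragments
#'
#' PCR duplicates are fragments with identical ending positions: at most one
#' record per (chrom, start, end) is retained, keeping the first occurrence.
#' Idempotent.
#'
#' @param set a [fragment_set()].
#' @return the deduplicated [fragment_set()].
#' @export
dedup_fragments <- function(set) {
  keep <- !duplicated(data.frame(set$chrom, set$start, set$end))
  as_fragment_set(set[keep, , drop = FALSE], set)
}

#' Read a nucleosome-center track from BED3
#'
#' Centers are the `start` coordinates of 1-bp intervals (DANPOS-style
#' center output). Unsorted input is sorted with a warning.
#'
#' @param path BED file.
#' @inheritParams nucleosome_track
#' @return a [nucleosome_track()].
#' @export
read_nucleosome_track <- function(path, core_halfwidth = 73L,
                                  spacing_halfwidth = 90L) {
  dt <- fread_auto(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) stop("empty nucleosome track: ", path)
  centers <- split(as.integer(dt[[2]]), as.character(dt[[1]]))
  centers <- lapply(centers, function(x) {
    if (is.unsorted(x)) {
      warning("unsorted nucleosome centers; sorting")
      x <- sort(x)
    }
    x
  })
  nucleosome_track(centers, core_halfwidth = core_halfwidth,
                   spacing_halfwidth = spacing_halfwidth)
}

#' Write a nucleosome track as BED3 of 1-bp center intervals
#' @param track a [nucleosome_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nucleosome_track <- function(track, path) {
  dt <- data.table::rbindlist(lapply(names(track$centers), function(ch)
    data.table::data.table(chrom = ch, start = track$centers[[ch]],
                           end = track$centers[[ch]] + 1L)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read per-read methylation calls from TSV
#'
#' Expects columns `fragment_id`, `pos` (CpG coordinate, 0-based), `state`
#' (0/1), with or without header.
#'
#' @param path TSV file (plain or gzipped).
#' @return a data.frame of calls grouped in file order.
#' @export
read_methylation_calls <- function(path) {
  dt <- fread_auto(path, header = "auto", sep = "\t")
  if (ncol(dt) < 3L) stop("methylation calls need 3 columns: ", path)
  data.table::setnames(dt, 1:3, c("fragment_id", "pos", "state"))
  as.data.frame(dt[, .(fragment_id = as.character(fragment_id),
                       pos = as.integer(pos), state = as.integer(state))])
}

#' Write per-read methylation calls as TSV
#' @param calls data.frame (`fragment_id`, `pos`, `state`).
#' @param path output path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_methylation_calls <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Join methylation calls to a fragment set
#'
#' Calls whose `fragment_id` is not present in the set are dropped and
#' counted in attribute `"n_unmatched"`.
#'
#' @param set a [fragment_set()].
#' @param calls calls data.frame.
#' @return the matching subset of `calls`.
#' @export
join_calls <- function(set, calls) {
  keep <- calls$fragment_id %in% set$fragment_id
  out <- calls[keep, , drop = FALSE]
  attr(out, "n_unmatched") <- sum(!keep)
  out
}
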