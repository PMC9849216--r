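## Orientation-aware end profiling against nucleosome centers: size
## partitions, U/D relative-position histograms, within-core fractions,
## peak calling on the profiles, and pseudo-fragment size arithmetic.

#' Partition fragments by size
#'
#' The canonical split: short fragments (size <= 147 bp, at most one
#' nucleosome core's worth of DNA) versus long fragments (size >= 170 bp),
#' with the in-between sizes excluded.
#'
#' @param set a [fragment_set()].
#' @param short_max largest size counted as short (bp).
#' @param long_min smallest size counted as long (bp).
#' @return a list of [fragment_set()]s `short`, `middle`, `long`.
#' @export
partition_by_size <- function(set, short_max = 147L, long_min = 170L) {
  if (short_max >= long_min) stop("short_max must be < long_min")
  list(short = as_fragment_set(set[set$size <= short_max, , drop = FALSE], set),
       middle = as_fragment_set(set[set$size > short_max & set$size < long_min, ,
                                    drop = FALSE], set),
       long = as_fragment_set(set[set$size >= long_min, , drop = FALSE], set))
}

#' Nucleosome-relative fragment-end profile
#'
#' Each U end and each D end is assigned independently to its nearest
#' nucleosome center (ties go to the left center); ends farther than `W` bp
#' from every center are left unassigned and counted. The result is a pair
#' of histograms of relative positions `-W..+W`, one per orientation.
#'
#' @param set a [fragment_set()].
#' @param track a [nucleosome_track()].
#' @param W window half-width in bp (default 93, covering the +/-90 spacing
#'   boundary with margin).
#' @return an object of class `end_profile` with positions, per-position U
#'   and D counts, and unassigned-end counts.
#' @export
relative_end_profile <- function(set, track, W = 93L) {
  if (!inherits(track, "nucleosome_track") || n_centers(track) == 0L)
    stop("empty nucleosome track")
  if (W < 1) stop("W must be >= 1")
  positions <- (-W):W
  u_counts <- d_counts <- integer(2L * W + 1L)
  u_un <- d_un <- 0L
  ends <- fragment_ends(set)
  for (ch in unique(set$chrom)) {
    cent <- track$centers[[ch]]
    sel <- set$chrom == ch
    if (is.null(cent)) {
      u_un <- u_un + sum(sel); d_un <- d_un + sum(sel)
      next
    }
    for (ori in c("u", "d")) {
      e <- ends[[ori]][sel]
      rel <- e - nearest_center(e, cent)
      ok <- abs(rel) <= W
      tab <- tabulate(rel[ok] + W + 1L, nbins = 2L * W + 1L)
      if (ori == "u") {
        u_counts <- u_counts + tab; u_un <- u_un + sum(!ok)
      } else {
        d_counts <- d_counts + tab; d_un <- d_un + sum(!ok)
      }
    }
  }
  structure(list(W = as.integer(W), positions = positions,
                 u_counts = u_counts, d_counts = d_counts,
                 u_unassigned = u_un, d_unassigned = d_un,
                 n_fragments = nrow(set)),
            class = "end_profile")
}

## Internal: nearest center for each coordinate; equidistant points assign
## to the left (lower-index) center.
nearest_center <- function(e, centers) {
  i <- findInterval(e, centers)
  left <- pmax(i, 1L)
  right <- pmin(i + 1L, length(centers))
  dl <- abs(e - centers[left])
  dr <- abs(e - centers[right])
  centers[ifelse(dl <= dr, left, right)]
}

#' @export
print.end_profile <- function(x, ...) {
  cat("<end_profile> window +/-", x$W, " bp; ", sum(x$u_counts), " U ends, ",
      sum(x$d_counts), " D ends assigned (", x$u_unassigned + x$d_unassigned,
      " unassigned)\n", sep = "")
  invisible(x)
}

#' Per-orientation frequencies of an end profile
#' @param profile an `end_profile`.
#' @param orientation `"U"` or `"D"`.
#' @return numeric vector over `profile$positions` summing to 1 (all-zero if
#'   no ends were assigned).
#' @export
profile_frequencies <- function(profile, orientation = c("U", "D")) {
  orientation <- match.arg(orientation)
  cnt <- if (orientation == "U") profile$u_counts else profile$d_counts
  if (sum(cnt) == 0) return(as.numeric(cnt))
  cnt / sum(cnt)
}

#' Fraction of ends within the nucleosome core
#'
#' @param profile an `end_profile`.
#' @param core_halfwidth core half-width in bp (default 73; must be <= the
#'   profile window).
#' @return named numeric `c(U = ..., D = ...)`: per orientation, the
#'   fraction of assigned ends with `|position| <= core_halfwidth`.
#' @export
within_core_fraction <- function(profile, core_halfwidth = 73L) {
  if (core_halfwidth > profile$W) stop("core_halfwidth exceeds profile window")
  core <- abs(profile$positions) <= core_halfwidth
  f <- function(cnt) if (sum(cnt) == 0) NA_real_ else sum(cnt[core]) / sum(cnt)
  c(U = f(profile$u_counts), D = f(profile$d_counts))
}

#' Call peaks in an end profile
#'
#' The per-position frequency series is smoothed with a centered moving
#' average, local maxima are located, and their topographic prominence
#' (height above the higher of the two saddles separating the peak from
#' higher ground; shift-invariant by construction) is compared against
#' `min_prominence`. Peaks closer than `min_separation` are pruned keeping
#' the more prominent one; all ties break toward smaller `|position|`.
#'
#' @param profile an `end_profile`.
#' @param orientation `"U"` or `"D"`.
#' @param min_prominence prominence threshold on the smoothed frequency
#'   scale; default `1.5 * median(smoothed frequencies)`.
#' @param min_separation minimum distance between reported peaks (bp);
#'   default 5, resolving a 10-bp lattice.
#' @param smooth_window moving-average width in bp (odd; default 3).
#' @return an object of class `end_peak_set`: data.frame with `position`,
#'   `height` (smoothed frequency) and `prominence`, ordered by position,
#'   plus the orientation as an attribute.
#' @export
call_end_peaks <- function(profile, orientation = c("U", "D"),
                           min_prominence = NULL, min_separation = 5L,
                           smooth_window = 3L) {
  orientation <- match.arg(orientation)
  cnt <- if (orientation == "U") profile$u_counts else profile$d_counts
  if (sum(cnt) == 0) return(empty_peak_set(orientation))
  ## smooth the integer counts (exact in doubles, so plateau ties survive)
  ## and normalize afterwards: identical to smoothing the frequencies
  y <- moving_average(cnt, smooth_window) / sum(cnt)
  if (is.null(min_prominence)) min_prominence <- 1.5 * median(y)
  plateaus <- local_maxima(y)
  ## a plateau of equal smoothed height resolves to its center; even widths
  ## break toward the smaller |relative coordinate|
  cand <- vapply(plateaus, function(rg) {
    mid <- (rg[1] + rg[2]) / 2
    idx <- unique(as.integer(c(floor(mid), ceiling(mid))))
    idx[order(abs(profile$positions[idx]), profile$positions[idx])[1]]
  }, integer(1))
  if (length(cand) == 0L) return(empty_peak_set(orientation))
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence & y[cand] > 0
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0L) return(empty_peak_set(orientation))
  pos <- profile$positions[cand]
  ## enforce separation: visit by decreasing prominence, |position| breaking ties
  ord <- order(-prom, abs(pos))
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(pos[i] - pos[kept]) >= min_separation)) kept <- c(kept, i)
  }
  kept <- kept[order(pos[kept])]
  structure(data.frame(position = pos[kept], height = y[cand[kept]],
                       prominence = prom[kept]),
            orientation = orientation, class = c("end_peak_set", "data.frame"))
}

empty_peak_set <- function(orientation) {
  structure(data.frame(position = integer(0), height = numeric(0),
                       prominence = numeric(0)),
            orientation = orientation, class = c("end_peak_set", "data.frame"))
}

## Internal: centered moving average with shrinking windows at the edges.
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Internal: local maxima as plateau ranges [start, end] (rising on the
## left, falling on the right).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(list())
  out <- list()
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[j])
        out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

## Internal: topographic prominence of a local maximum at index i.
peak_prominence <- function(y, i) {
  h <- y[i]
  left <- y[seq_len(i - 1L)]
  right <- y[seq.int(i + 1L, length(y))]
  saddle_side <- function(side, from_end) {
    if (length(side) == 0L) return(-Inf)
    s <- if (from_end) rev(side) else side   # walk away from the peak
    higher <- which(s > h)
    if (length(higher) == 0L) return(-Inf)   # no higher ground: side ignored
    min(s[seq_len(higher[1])])
  }
  sl <- saddle_side(left, from_end = TRUE)
  sr <- saddle_side(right, from_end = FALSE)
  ref <- max(sl, sr)
  if (!is.finite(ref)) ref <- min(y)         # global maximum
  h - ref
}

#' Pseudo-fragment sizes from U and D peak positions
#'
#' Every pairing of a U-end peak with a D-end peak downstream of it implies
#' a preferred fragment of inclusive length `d - u + 1` (both cut bases
#' covered); these in-silico sizes line up with the sub-147 bp peaks of the
#' cfDNA size distribution.
#'
#' @param u_peaks,d_peaks `end_peak_set`s (or numeric position vectors).
#' @return data.frame with `u`, `d`, `size`, all pairs with `d > u`, ordered
#'   by size.
#' @export
pseudo_fragment_sizes <- function(u_peaks, d_peaks) {
  u <- if (is.data.frame(u_peaks)) u_peaks$position else u_peaks
  d <- if (is.data.frame(d_peaks)) d_peaks$position else d_peaks
  if (length(u) == 0L || length(d) == 0L)
    stop("both peak sets must be non-empty")
  g <- expand.grid(u = u, d = d)
  g <- g[g$d > g$u, , drop = FALSE]
  g$size <- g$d - g$u + 1L
  g[order(g$size, g$u), , drop = FALSE]
}

#' Fragment size distribution
#'
#' 1-bp histogram of fragment sizes within `[min_size, max_size]` and its
#' mode (ties broken toward the smaller size).
#'
#' @param set a [fragment_set()].
#' @param min_size,max_size histogram range (bp).
#' @return a list with `size`, `count`, `mode` (NA with a warning when no
#'   fragment falls in range) and `n_in_range`.
#' @export
size_distribution <- function(set, min_size = 50L, max_size = 400L) {
  if (min_size >= max_size) stop("min_size must be < max_size")
  sizes <- set$size[set$size >= min_size & set$size <= max_size]
  count <- tabulate(sizes - min_size + 1L, nbins = max_size - min_size + 1L)
  size <- min_size:max_size
  if (length(sizes) == 0L) {
    warning("no fragments within the size range; mode undefined")
    mode <- NA_integer_
  } else {
    mode <- size[which.max(count)]   # which.max takes the first = smaller size
  }
  list(size = size, count = count, mode = mode, n_in_range = length(sizes))
}
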