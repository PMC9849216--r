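## Shared domain containers: nucleosome tracks, fragment sets, cut models,
## methylation landscapes. All are light S3 wrappers over base structures.

#' Nucleosome-center track
#'
#' Ordered nucleosome center coordinates per chromosome, with the canonical
#' core geometry: the nucleosome core covers +/-73 bp around the center
#' (147 bp of wrapped DNA) and adjacent-nucleosome spacing is described by a
#' +/-90 bp half-width.
#'
#' @param centers named list of integer vectors (one per chromosome, 0-based
#'   bp, strictly increasing), or a single numeric vector together with
#'   `chrom`.
#' @param chrom chromosome name used when `centers` is a plain vector.
#' @param core_halfwidth nucleosome core half-width in bp (default 73).
#' @param spacing_halfwidth nucleosome spacing half-width in bp (default 90).
#' @return an object of class `nucleosome_track`.
#' @export
nucleosome_track <- function(centers, chrom = "chrS",
                             core_halfwidth = 73L, spacing_halfwidth = 90L) {
  if (!is.list(centers)) centers <- setNames(list(centers), chrom)
  centers <- lapply(centers, function(x) as.integer(round(x)))
  for (nm in names(centers)) {
    x <- centers[[nm]]
    if (length(x) == 0L) stop("empty center list for chromosome ", nm)
    if (is.unsorted(x, strictly = TRUE))
      stop("nucleosome centers must be strictly increasing on ", nm)
    if (length(x) > 1L && any(diff(x) < 2L * core_halfwidth))
      stop("adjacent nucleosome centers closer than 2 x core half-width (",
           2L * core_halfwidth, " bp) on ", nm)
  }
  structure(list(centers = centers,
                 core_halfwidth = as.integer(core_halfwidth),
                 spacing_halfwidth = as.integer(spacing_halfwidth)),
            class = "nucleosome_track")
}

#' @export
print.nucleosome_track <- function(x, ...) {
  n <- sum(vapply(x$centers, length, 1L))
  cat("<nucleosome_track> ", n, " centers on ", length(x$centers),
      " chromosome(s); core +/-", x$core_halfwidth,
      " bp, spacing +/-", x$spacing_halfwidth, " bp\n", sep = "")
  invisible(x)
}

#' Number of nucleosome centers in a track
#' @param track a [nucleosome_track()].
#' @return integer count over all chromosomes.
#' @export
n_centers <- function(track) sum(vapply(track$centers, length, 1L))

#' Fragment set
#'
#' A collection of cfDNA fragments from one sample: a data.frame with columns
#' `chrom`, `start`, `end` (0-based half-open), `size`, `fragment_id`,
#' `sample_id` and optionally `origin` (provenance after mixing). The sample
#' label ("control"/"cancer") and tumor fraction ride along as attributes.
#'
#' @param frags data.frame with at least `chrom`, `start`, `end`.
#' @param sample_id sample identifier (recycled into the table).
#' @param label sample label, e.g. "control" or "cancer".
#' @param tumor_fraction optional tumor DNA fraction in `[0, 1]`.
#' @return an object of class `fragment_set` (also a data.frame).
#' @export
fragment_set <- function(frags, sample_id = "sample", label = "control",
                         tumor_fraction = NA_real_) {
  frags <- as.data.frame(frags)
  stopifnot(all(c("chrom", "start", "end") %in% names(frags)))
  frags$start <- as.integer(frags$start)
  frags$end <- as.integer(frags$end)
  if (nrow(frags) > 0 && any(frags$end <= frags$start))
    stop("fragment with end <= start")
  frags$size <- frags$end - frags$start
  if (is.null(frags$sample_id))
    frags$sample_id <- rep_len(sample_id, nrow(frags))
  if (is.null(frags$fragment_id))
    frags$fragment_id <- if (nrow(frags)) paste0(sample_id, "_", seq_len(nrow(frags))) else character(0)
  structure(frags,
            label = label, tumor_fraction = tumor_fraction,
            class = c("fragment_set", "data.frame"))
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> ", nrow(x), " fragments; sample ",
      x$sample_id[1] %||% "?", " (", attr(x, "label") %||% "?", ")\n", sep = "")
  if (nrow(x)) {
    cat("  size: median ", stats::median(x$size), " bp, range [",
        min(x$size), ", ", max(x$size), "]\n", sep = "")
  }
  invisible(x)
}

## Internal: coerce back to fragment_set after data.frame ops.
as_fragment_set <- function(frags, template) {
  structure(as.data.frame(frags),
            label = attr(template, "label"),
            tumor_fraction = attr(template, "tumor_fraction"),
            class = c("fragment_set", "data.frame"))
}

#' U and D end coordinates of a fragment set
#'
#' The upstream (U) end of a fragment is the genomic position `start`; the
#' downstream (D) end is `end - 1`, the last covered base. Ends are defined
#' purely by coordinate order; strand plays no role.
#'
#' @param set a [fragment_set()].
#' @return a list with integer vectors `u` and `d` and `chrom`.
#' @export
fragment_ends <- function(set) {
  list(chrom = set$chrom, u = set$start, d = set$end - 1L)
}

#' Nuclease cut-site model for the synthetic generator
#'
#' Parameterizes where the simulated nuclease prefers to cut relative to a
#' nucleosome center and how local DNA methylation modulates intra-core
#' cutting. Intra-core upstream (U) preferred offsets sit on a 10-bp lattice
#' ending at -68 bp; intra-core downstream (D) offsets start at +63 bp with
#' the outermost at +74 bp; linker cuts sit at -83/+82 bp so that the
#' canonical linker-to-linker fragment has inclusive length
#' 82 - (-83) + 1 = 166 bp. The intra-core cut weight falls from
#' `w_core_unmeth` toward `w_core_meth` as local methylation `m` rises:
#' `w(m) = w_core_meth + (w_core_unmeth - w_core_meth) * (1 - m)^s`
#' with sensitivity exponent `s = meth_sensitivity` (`s = 0` switches the
#' methylation-size coupling off; linker cutting is never modulated).
#'
#' @param u_core_offsets intra-core preferred U-end offsets (bp from center).
#' @param d_core_offsets intra-core preferred D-end offsets (bp from center).
#' @param u_linker_offset,d_linker_offset linker cut offsets (bp from center).
#' @param peak_sd Gaussian s.d. of positional noise around a preferred cut
#'   site (bp).
#' @param w_core_unmeth intra-core cut weight in a fully unmethylated context.
#' @param w_core_meth intra-core cut weight in a fully methylated context.
#' @param w_linker linker cut weight (not methylation-modulated).
#' @param meth_sensitivity exponent linking local methylation to the
#'   intra-core weight; 0 disables the coupling.
#' @return an object of class `cut_model`.
#' @export
cut_model <- function(u_core_offsets = seq(-68L, -8L, by = 10L),
                      d_core_offsets = c(63L, 74L),
                      u_linker_offset = -83L,
                      d_linker_offset = 82L,
                      peak_sd = 1.5,
                      w_core_unmeth = 1.0,
                      w_core_meth = 0.25,
                      w_linker = 3.0,
                      meth_sensitivity = 1.0) {
  offs <- c(u_core_offsets, d_core_offsets, u_linker_offset, d_linker_offset)
  if (any(offs < -90 | offs > 90))
    stop("cut offsets must lie within [-90, +90] bp of the nucleosome center")
  if (u_linker_offset >= d_linker_offset)
    stop("linker U offset must be smaller than linker D offset")
  w <- c(w_core_unmeth, w_core_meth, w_linker)
  if (any(w < 0)) stop("cut weights must be >= 0")
  if (peak_sd < 0) stop("peak_sd must be >= 0")
  structure(list(u_core_offsets = as.integer(u_core_offsets),
                 d_core_offsets = as.integer(d_core_offsets),
                 u_linker_offset = as.integer(u_linker_offset),
                 d_linker_offset = as.integer(d_linker_offset),
                 peak_sd = peak_sd,
                 w_core_unmeth = w_core_unmeth,
                 w_core_meth = w_core_meth,
                 w_linker = w_linker,
                 meth_sensitivity = meth_sensitivity),
            class = "cut_model")
}

## Internal: intra-core weight at local methylation level m.
core_weight <- function(model, m) {
  model$w_core_meth +
    (model$w_core_unmeth - model$w_core_meth) * (1 - pmin(pmax(m, 0), 1))^model$meth_sensitivity
}

#' Sample specification for the synthetic generator
#'
#' @param label "control" or "cancer".
#' @param n_fragments number of fragments to draw.
#' @param tumor_fraction tumor DNA fraction in `[0, 1]`; must be 0 for
#'   controls.
#' @param seed integer seed for this sample's draws.
#' @param sample_id sample identifier.
#' @param background_profile,tumor_profile landscape profile names used for
#'   the background and tumor components.
#' @return an object of class `sample_spec`.
#' @export
sample_spec <- function(label = c("control", "cancer"), n_fragments = 200000L,
                        tumor_fraction = 0, seed = 1L,
                        sample_id = NULL,
                        background_profile = "blood", tumor_profile = "tumor") {
  label <- match.arg(label)
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must be in [0, 1]")
  if (label == "control" && tumor_fraction != 0)
    stop("controls must have tumor_fraction = 0")
  structure(list(label = label, n_fragments = as.integer(n_fragments),
                 tumor_fraction = tumor_fraction, seed = as.integer(seed),
                 sample_id = sample_id %||% paste0(label, "_s", seed),
                 background_profile = background_profile,
                 tumor_profile = tumor_profile),
            class = "sample_spec")
}
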