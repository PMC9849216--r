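## Synthetic cfDNA generator. The generative mechanism: nucleosome-protected
## DNA is released by nucleases that cut preferentially in linkers; low local
## DNA methylation opens the nucleosome and lets nucleases cut inside the
## core at 10-bp phased sites, producing short (<147 bp) fragments whose ends
## fall on the helical-pitch lattice.

#' Generate a phased nucleosome array
#'
#' Emulates a region with well-positioned nucleosomes (the chr12p11.1-type
#' model locus contains ~400 of them): centers at
#' `origin + k * spacing`, optionally jittered, re-sorted, and returned as a
#' [nucleosome_track()].
#'
#' @param n_nucleosomes number of nucleosomes (>= 1).
#' @param spacing center-to-center spacing in bp (>= 147, or nucleosomes
#'   would overlap).
#' @param chrom chromosome name.
#' @param origin coordinate of the first center (0-based bp).
#' @param jitter_sd Gaussian s.d. of positional jitter applied to each
#'   center (bp).
#' @param seed integer seed.
#' @return a [nucleosome_track()] with `n_nucleosomes` centers.
#' @examples
#' trk <- make_nucleosome_array(400, 185, seed = 1)
#' n_centers(trk)
#' @export
make_nucleosome_array <- function(n_nucleosomes, spacing = 185L,
                                  chrom = "chrS", origin = 1000L,
                                  jitter_sd = 0, seed = 1L) {
  if (n_nucleosomes < 1) stop("n_nucleosomes must be >= 1")
  if (spacing < 147) stop("spacing below 147 bp: nucleosomes would overlap")
  centers <- with_seed(seed, {
    x <- origin + (seq_len(n_nucleosomes) - 1L) * spacing
    if (jitter_sd > 0) x <- x + rnorm(n_nucleosomes, 0, jitter_sd)
    sort(round(x))
  })
  nucleosome_track(centers, chrom = chrom)
}

#' Generate a methylation landscape over a nucleosome track
#'
#' Places CpG sites every `cpg_step` bp across the track's half-open span
#' (first center minus the spacing half-width up to last center plus the
#' spacing half-width) and assigns each site a methylation probability for
#' each named tissue profile. Site probabilities are drawn hierarchically:
#' a domain-level mean (Beta around the tissue mean, domains of
#' `domain_size` bp) plus site-level Beta noise, which gives the
#' nucleosome-scale heterogeneity that couples local methylation to cutting
#' in the generator. For the `"tumor"` profile a fraction
#' `hypo_domain_fraction` of domains is forced to a hypomethylated level,
#' mimicking the global hypomethylation of malignant genomes (the target
#' profile can be changed via `hypo_domain_profile`).
#'
#' @param track a [nucleosome_track()].
#' @param cpg_step distance between consecutive CpG sites (bp).
#' @param profiles named numeric vector of per-tissue mean methylation
#'   levels in `[0, 1]`.
#' @param hypo_domain_fraction fraction of domains set to `hypo_level` for
#'   the `hypo_domain_profile` profile.
#' @param hypo_domain_profile name of the profile receiving hypomethylated
#'   domains (default `"tumor"`).
#' @param domain_size methylation-domain size (bp).
#' @param domain_concentration,site_concentration Beta concentration
#'   parameters for domain- and site-level draws (larger = tighter).
#' @param hypo_level methylation level assigned to hypomethylated tumor
#'   domains.
#' @param seed integer seed.
#' @return an object of class `methylation_landscape`: per chromosome, CpG
#'   positions and a site-by-profile probability matrix.
#' @export
make_methylation_landscape <- function(track, cpg_step = 25L,
                                       profiles = c(blood = 0.8, tumor = 0.4),
                                       hypo_domain_fraction = 0.3,
                                       hypo_domain_profile = "tumor",
                                       domain_size = 2000L,
                                       domain_concentration = 8,
                                       site_concentration = 50,
                                       hypo_level = 0.05,
                                       seed = 1L) {
  if (!inherits(track, "nucleosome_track") || n_centers(track) == 0L)
    stop("track must be a non-empty nucleosome_track")
  if (any(profiles < 0 | profiles > 1)) stop("profile means must be in [0, 1]")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be named")
  pad <- track$spacing_halfwidth
  chroms <- with_seed(seed, {
    lapply(track$centers, function(cent) {
      span_start <- min(cent) - pad
      span_end <- max(cent) + pad            # half-open [span_start, span_end)
      pos <- seq.int(span_start, span_end - 1L, by = cpg_step)
      probs <- vapply(names(profiles), function(tissue) {
        mu <- profiles[[tissue]]
        dom <- (pos - span_start) %/% domain_size
        nd <- max(dom) + 1L
        dom_mu <- draw_beta(nd, mu, domain_concentration)
        if (tissue == hypo_domain_profile && hypo_domain_fraction > 0) {
          hypo <- runif(nd) < hypo_domain_fraction
          dom_mu[hypo] <- hypo_level
        }
        draw_beta(length(pos), dom_mu[dom + 1L], site_concentration)
      }, numeric(length(pos)))
      if (is.null(dim(probs))) probs <- matrix(probs, nrow = length(pos),
                                               dimnames = list(NULL, names(profiles)))
      list(pos = as.integer(pos), probs = probs)
    })
  })
  structure(list(chroms = chroms, profiles = names(profiles),
                 cpg_step = as.integer(cpg_step)),
            class = "methylation_landscape")
}

## Beta draw with mean mu and concentration kappa; degenerate means pass
## through exactly (mu 0 or 1 must yield all-0/all-1 probabilities).
draw_beta <- function(n, mu, kappa) {
  mu <- rep_len(mu, n)
  out <- mu
  ok <- mu > 0 & mu < 1
  if (any(ok)) out[ok] <- rbeta(sum(ok), mu[ok] * kappa, (1 - mu[ok]) * kappa)
  out
}

#' @export
print.methylation_landscape <- function(x, ...) {
  n <- sum(vapply(x$chroms, function(ch) length(ch$pos), 1L))
  cat("<methylation_landscape> ", n, " CpG sites, step ", x$cpg_step,
      " bp; profiles: ", paste(x$profiles, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## Internal: per-nucleosome mean methylation probability within the core
## (+/- core_halfwidth), one column per profile. Falls back to the
## chromosome-wide mean when a core covers no CpG site.
local_core_methylation <- function(track, landscape, chrom) {
  cent <- track$centers[[chrom]]
  ls <- landscape$chroms[[chrom]]
  if (is.null(ls)) stop("landscape has no chromosome ", chrom)
  hw <- track$core_halfwidth
  lo <- findInterval(cent - hw - 0.5, ls$pos) + 1L
  hi <- findInterval(cent + hw + 0.5, ls$pos)
  cums <- apply(ls$probs, 2, function(p) cumsum(c(0, p)))
  out <- vapply(seq_len(ncol(ls$probs)), function(j) {
    s <- cums[hi + 1L, j] - cums[lo, j]
    n <- hi - lo + 1L
    m <- ifelse(n > 0, s / pmax(n, 1L), mean(ls$probs[, j]))
    m
  }, numeric(length(cent)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(cent))
  colnames(out) <- colnames(ls$probs)
  out
}

#' Draw synthetic cfDNA fragments from the nucleosomal cut model
#'
#' For each fragment a nucleosome is chosen uniformly; the local methylation
#' level of its core sets the intra-core cut weight through the
#' [cut_model()] sensitivity curve. The upstream cut is drawn among the
#' intra-core U offsets (weight `w(m)` each) and the linker U offset (weight
#' `w_linker`), the downstream cut likewise from the D offsets; Gaussian
#' positional noise (`peak_sd`) is added and draws with D <= U are redrawn.
#' Fragments from the tumor component (per-fragment Bernoulli with the
#' spec's tumor fraction) use the `"tumor"` methylation profile for both the
#' cut weights and the per-CpG Bernoulli states.
#'
#' @param track a [nucleosome_track()].
#' @param landscape a [make_methylation_landscape()] result.
#' @param model a [cut_model()].
#' @param spec a [sample_spec()].
#' @param emit_methylation if `TRUE` (default) per-CpG binary states are
#'   drawn for every fragment and returned as a calls table.
#' @return a list with `fragments` (a [fragment_set()], with an `origin`
#'   column giving the background/tumor provenance) and `calls` (a
#'   data.frame `fragment_id`, `pos`, `state`, or `NULL` when
#'   `emit_methylation = FALSE`).
#' @examples
#' trk <- make_nucleosome_array(50, 185, seed = 1)
#' ls <- make_methylation_landscape(trk, seed = 1)
#' smp <- sample_fragments(trk, ls, cut_model(),
#'                         sample_spec("control", 2000, seed = 7))
#' table(cut(smp$fragments$size, c(0, 147, 169, Inf)))
#' @export
sample_fragments <- function(track, landscape, model = cut_model(), spec,
                             emit_methylation = TRUE) {
  stopifnot(inherits(track, "nucleosome_track"),
            inherits(landscape, "methylation_landscape"),
            inherits(model, "cut_model"), inherits(spec, "sample_spec"))
  if (spec$tumor_fraction > 0 &&
      !(spec$tumor_profile %in% landscape$profiles))
    stop("tumor_fraction > 0 but landscape has no '", spec$tumor_profile,
         "' profile")
  if (!(spec$background_profile %in% landscape$profiles))
    stop("landscape has no '", spec$background_profile, "' profile")
  n <- spec$n_fragments
  chrom <- names(track$centers)[1]   # single-chromosome generator
  if (n == 0L) {
    fs <- fragment_set(data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0)),
                       sample_id = spec$sample_id, label = spec$label,
                       tumor_fraction = spec$tumor_fraction)
    return(list(fragments = fs,
                calls = if (emit_methylation)
                  data.frame(fragment_id = character(0), pos = integer(0),
                             state = integer(0)) else NULL))
  }
  cent <- track$centers[[chrom]]
  m_local <- local_core_methylation(track, landscape, chrom)
  k_u <- length(model$u_core_offsets)
  k_d <- length(model$d_core_offsets)

  with_seed(spec$seed, {
    is_tumor <- runif(n) < spec$tumor_fraction
    prof <- ifelse(is_tumor, spec$tumor_profile, spec$background_profile)
    nuc <- sample.int(length(cent), n, replace = TRUE)
    m <- m_local[cbind(nuc, match(prof, colnames(m_local)))]
    w <- core_weight(model, m)

    u_link <- runif(n) < model$w_linker / (model$w_linker + k_u * w)
    u_off <- ifelse(u_link, model$u_linker_offset,
                    model$u_core_offsets[sample.int(k_u, n, replace = TRUE)])
    d_link <- runif(n) < model$w_linker / (model$w_linker + k_d * w)
    d_off <- ifelse(d_link, model$d_linker_offset,
                    model$d_core_offsets[sample.int(k_d, n, replace = TRUE)])

    u_pos <- cent[nuc] + u_off + as.integer(round(rnorm(n, 0, model$peak_sd)))
    d_pos <- cent[nuc] + d_off + as.integer(round(rnorm(n, 0, model$peak_sd)))
    bad <- which(d_pos <= u_pos)
    it <- 0L
    while (length(bad) && it < 50L) {     # redraw noise where D <= U
      u_pos[bad] <- cent[nuc[bad]] + u_off[bad] +
        as.integer(round(rnorm(length(bad), 0, model$peak_sd)))
      d_pos[bad] <- cent[nuc[bad]] + d_off[bad] +
        as.integer(round(rnorm(length(bad), 0, model$peak_sd)))
      bad <- bad[d_pos[bad] <= u_pos[bad]]
      it <- it + 1L
    }
    if (length(bad)) d_pos[bad] <- u_pos[bad] + 1L  # degenerate fallback

    frags <- data.frame(chrom = chrom, start = u_pos, end = d_pos + 1L,
                        origin = ifelse(is_tumor, "tumor", "background"))
    fs <- fragment_set(frags, sample_id = spec$sample_id, label = spec$label,
                       tumor_fraction = spec$tumor_fraction)
    calls <- NULL
    if (emit_methylation) {
      ls <- landscape$chroms[[chrom]]
      lo <- findInterval(fs$start - 0.5, ls$pos) + 1L
      hi <- findInterval(fs$end - 0.5, ls$pos)   # sites with start <= pos < end
      cnt <- pmax(hi - lo + 1L, 0L)
      idx <- sequence(cnt, from = lo)
      frag_i <- rep.int(seq_len(n), cnt)
      p <- ls$probs[cbind(idx, match(prof[frag_i], colnames(ls$probs)))]
      calls <- data.frame(fragment_id = fs$fragment_id[frag_i],
                          pos = ls$pos[idx],
                          state = rbinom(length(idx), 1L, p))
    }
    list(fragments = fs, calls = calls)
  })
}

#' Mix control and tumor fragment pools
#'
#' Draws `n` fragments, each taken from the tumor pool with probability
#' `tumor_fraction` (with replacement), emulating plasma carrying a given
#' tumor DNA load. Provenance is retained in the `origin` column.
#'
#' @param control,tumor [fragment_set()] pools to draw from.
#' @param tumor_fraction probability that a drawn fragment is tumor-derived.
#' @param n number of fragments in the mixture.
#' @param seed integer seed.
#' @param sample_id identifier for the mixed sample.
#' @return a [fragment_set()] with `origin` in `{"control", "tumor"}`.
#' @export
mix_samples <- function(control, tumor, tumor_fraction, n, seed = 1L,
                        sample_id = "mixture") {
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must be in [0, 1]")
  if (tumor_fraction > 0 && nrow(tumor) == 0L)
    stop("tumor pool is empty but tumor_fraction > 0")
  if (tumor_fraction < 1 && nrow(control) == 0L)
    stop("control pool is empty but tumor_fraction < 1")
  with_seed(seed, {
    take_tumor <- runif(n) < tumor_fraction
    n_t <- sum(take_tumor)
    pick <- function(pool, k) pool[sample.int(nrow(pool), k, replace = TRUE),
                                   c("chrom", "start", "end"), drop = FALSE]
    out <- data.frame(chrom = character(n), start = integer(n),
                      end = integer(n), origin = character(n))
    if (n_t > 0) {
      out[take_tumor, c("chrom", "start", "end")] <- pick(tumor, n_t)
      out$origin[take_tumor] <- "tumor"
    }
    if (n_t < n) {
      out[!take_tumor, c("chrom", "start", "end")] <- pick(control, n - n_t)
      out$origin[!take_tumor] <- "control"
    }
    fragment_set(out, sample_id = sample_id,
                 label = if (tumor_fraction > 0) "cancer" else "control",
                 tumor_fraction = tumor_fraction)
  })
}

#' Simulate MeDIP-style capture of methylated fragments
#'
#' Methylated-DNA immunoprecipitation retains each fragment with probability
#' `min(1, w * m)` where `m` is the number of methylated CpGs the fragment
#' carries, enriching the pool for methylated molecules.
#'
#' @param set a [fragment_set()].
#' @param calls methylation calls (`fragment_id`, `pos`, `state`) for the
#'   fragments in `set`.
#' @param capture_weight per-methylated-CpG capture weight `w` (>= 0).
#' @param seed integer seed.
#' @return the retained [fragment_set()].
#' @export
simulate_medip_capture <- function(set, calls, capture_weight = 0.25,
                                   seed = 1L) {
  if (capture_weight < 0) stop("capture_weight must be >= 0")
  dt <- data.table::as.data.table(calls)
  mcount <- dt[, .(m = sum(state)), by = fragment_id]
  m <- mcount$m[match(set$fragment_id, mcount$fragment_id)]
  m[is.na(m)] <- 0L
  keep <- with_seed(seed, runif(nrow(set)) < pmin(1, capture_weight * m))
  as_fragment_set(set[keep, , drop = FALSE], set)
}
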