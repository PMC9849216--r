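## Per-read methylation classification and its relationship to fragment
## size: hyper/hypo read classes, class-wise size distributions, and the
## genomewide size-versus-methylation regression.

#' Rule for classifying reads by methylation
#'
#' A read is classified only if it covers at least `min_cpgs` CpG sites;
#' it is hyper-methylated when its average methylation is strictly greater
#' than `hyper` (default 0.80) and hypo-methylated when strictly lower than
#' `hypo` (default 0.20). Boundary values are unclassified.
#'
#' @param min_cpgs minimum CpG count (default 2; 5 is a stricter
#'   alternative).
#' @param hyper hyper-methylation threshold (exclusive).
#' @param hypo hypo-methylation threshold (exclusive).
#' @return an object of class `methylation_class_rule`.
#' @export
methylation_class_rule <- function(min_cpgs = 2L, hyper = 0.80, hypo = 0.20) {
  if (hypo >= hyper) stop("hypo threshold must be below hyper threshold")
  if (min_cpgs < 1) stop("min_cpgs must be >= 1")
  structure(list(min_cpgs = as.integer(min_cpgs), hyper = hyper, hypo = hypo),
            class = "methylation_class_rule")
}

#' Classify one read from its CpG states
#'
#' @param states binary vector of per-CpG methylation states (order is
#'   irrelevant).
#' @param rule a [methylation_class_rule()].
#' @return `"hyper"`, `"hypo"` or `"unclassified"`.
#' @export
classify_fragment <- function(states, rule = methylation_class_rule()) {
  if (length(states) < rule$min_cpgs) return("unclassified")
  m <- mean(states)
  if (m > rule$hyper) "hyper"
  else if (m < rule$hypo) "hypo"
  else "unclassified"
}

#' Classify every fragment with calls
#'
#' @param calls calls data.frame (`fragment_id`, `pos`, `state`).
#' @param rule a [methylation_class_rule()].
#' @return data.frame `fragment_id`, `n_cpg`, `mean_meth`, `class`.
#' @export
classify_fragments <- function(calls, rule = methylation_class_rule()) {
  dt <- data.table::as.data.table(calls)
  ag <- dt[, .(n_cpg = .N, mean_meth = mean(state)), by = fragment_id]
  ag[, class := data.table::fifelse(
    n_cpg < rule$min_cpgs, "unclassified",
    data.table::fifelse(mean_meth > rule$hyper, "hyper",
      data.table::fifelse(mean_meth < rule$hypo, "hypo", "unclassified")))]
  as.data.frame(ag)
}

#' Size distributions of hyper- versus hypo-methylated reads
#'
#' Joins calls to fragments, classifies each read, builds per-class 1-bp
#' size histograms, reports the short-fragment fraction (size <=
#' `short_max`) per class, and compares the hypo and hyper size
#' distributions by a paired t test across matched size bins of the
#' cumulative frequency curves (per-bin densities are normalized, so their
#' differences sum to zero identically; the cumulative curves carry the
#' stochastic ordering — a positive mean difference means hypo reads run
#' shorter).
#'
#' @param set a [fragment_set()].
#' @param calls calls data.frame joinable to `set` via `fragment_id`.
#' @param rule a [methylation_class_rule()].
#' @param short_max short-fragment threshold (bp).
#' @param size_range histogram range (bp).
#' @return a list: `histograms` (bin-by-class count matrix), `frequencies`
#'   (column-normalized), `short_fraction` (per class), `n` (reads per
#'   class), `test` (list with `p_value` and `mean_diff` of the per-bin
#'   hypo-minus-hyper cumulative frequencies, or `insufficient = TRUE`).
#' @export
size_by_methylation_class <- function(set, calls,
                                      rule = methylation_class_rule(),
                                      short_max = 147L,
                                      size_range = c(50L, 400L)) {
  cls <- classify_fragments(join_calls(set, calls), rule)
  cls <- cls[match(set$fragment_id, cls$fragment_id), ]
  lab <- ifelse(is.na(cls$class), "unclassified", cls$class)
  bins <- size_range[1]:size_range[2]
  classes <- c("hyper", "hypo", "unclassified")
  hist <- sapply(classes, function(cl) {
    s <- set$size[lab == cl & set$size >= size_range[1] & set$size <= size_range[2]]
    tabulate(s - size_range[1] + 1L, nbins = length(bins))
  })
  rownames(hist) <- bins
  freq <- apply(hist, 2, function(x) if (sum(x) > 0) x / sum(x) else x * 0)
  short_fraction <- vapply(classes, function(cl) {
    s <- set$size[lab == cl]
    if (length(s) == 0L) NA_real_ else mean(s <= short_max)
  }, numeric(1))
  n <- vapply(classes, function(cl) sum(lab == cl), integer(1))
  test <- if (n[["hyper"]] == 0L || n[["hypo"]] == 0L) {
    list(insufficient = TRUE)
  } else {
    cum_hypo <- cumsum(freq[, "hypo"])
    cum_hyper <- cumsum(freq[, "hyper"])
    d <- cum_hypo - cum_hyper
    p <- if (sd(d) == 0) as.numeric(all(d == 0))
         else t.test(cum_hypo, cum_hyper, paired = TRUE)$p.value
    list(insufficient = FALSE, mean_diff = mean(d), p_value = p)
  }
  list(histograms = hist, frequencies = freq, short_fraction = short_fraction,
       n = n, test = test)
}

#' Genomewide fragment size versus methylation curve
#'
#' Per-fragment mean methylation is averaged within 1-bp size bins; the
#' per-size means are regressed on size by count-weighted ordinary least
#' squares. A positive slope reproduces the genomewide positive correlation
#' between cfDNA size and methylation level.
#'
#' @param set a [fragment_set()].
#' @param calls calls data.frame.
#' @param size_range size bins used (bp).
#' @return a list: `curve` (data.frame `size`, `mean_meth`, `count`),
#'   `slope` (per bp), `slope_se`, `p_value`, `r` (count-weighted Pearson
#'   correlation), `n_sizes`.
#' @export
size_methylation_curve <- function(set, calls, size_range = c(50L, 400L)) {
  cls <- classify_fragments(join_calls(set, calls),
                            methylation_class_rule(min_cpgs = 1L))
  idx <- match(cls$fragment_id, set$fragment_id)
  df <- data.frame(size = set$size[idx], meth = cls$mean_meth)
  df <- df[df$size >= size_range[1] & df$size <= size_range[2], ]
  dt <- data.table::as.data.table(df)
  curve <- as.data.frame(dt[, .(mean_meth = mean(meth), count = .N),
                            by = .(size)][order(size)])
  if (nrow(curve) < 2L) stop("need >= 2 distinct sizes with data")
  fit <- stats::lm(mean_meth ~ size, data = curve, weights = count)
  sm <- summary(fit)$coefficients
  cw <- cov.wt(curve[, c("size", "mean_meth")], wt = curve$count, cor = TRUE)
  list(curve = curve,
       slope = unname(sm["size", "Estimate"]),
       slope_se = unname(sm["size", "Std. Error"]),
       p_value = unname(sm["size", "Pr(>|t|)"]),
       r = cw$cor["size", "mean_meth"],
       n_sizes = nrow(curve))
}

#' Select CpG sites differentially methylated between two references
#'
#' Sites methylated at `>= hi` in reference A while `<= lo` in reference B
#' (e.g. hyper in liver, hypo in blood) mark fragments of A-tissue origin.
#'
#' @param pos CpG coordinates (shared between the two references).
#' @param level_a,level_b per-site methylation levels aligned to `pos`.
#' @param hi,lo selection thresholds (defaults 0.8 / 0.2).
#' @return integer vector of selected positions.
#' @export
select_differential_cpgs <- function(pos, level_a, level_b,
                                     hi = 0.8, lo = 0.2) {
  if (hi <= lo) stop("hi must be > lo")
  stopifnot(length(pos) == length(level_a), length(pos) == length(level_b))
  pos[level_a >= hi & level_b <= lo]
}

#' Fragments covering given CpG sites
#'
#' @param set a [fragment_set()].
#' @param sites integer positions, or a named list of position vectors (one
#'   per site class).
#' @return the covering [fragment_set()] subset, or a named list of subsets
#'   when `sites` is a list (a fragment covering sites of several classes
#'   appears in each).
#' @export
fragments_covering <- function(set, sites) {
  if (is.list(sites)) return(lapply(sites, function(s) fragments_covering(set, s)))
  sites <- sort(as.integer(sites))
  hit <- findInterval(set$end - 0.5, sites) - findInterval(set$start - 0.5, sites) > 0
  as_fragment_set(set[hit, , drop = FALSE], set)
}

#' Overall methylation density of a sample
#'
#' @param calls calls data.frame.
#' @return methylated CpG observations / total CpG observations, or `NA`
#'   with a warning when there are no observations.
#' @export
sample_methylation_density <- function(calls) {
  if (nrow(calls) == 0L) {
    warning("no CpG observations; methylation density undefined")
    return(NA_real_)
  }
  mean(calls$state)
}
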