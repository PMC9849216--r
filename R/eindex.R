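## The ending-preference model and E-index. Pooled healthy-control fragments
## define, for every genomic locus, how often it serves as a U or a D end;
## a sample's E-index is the mean over its fragments of the model counts at
## its own U and D end positions — low values flag ending patterns atypical
## of healthy plasma.

#' Build the pooled-control ending-preference model
#'
#' For every fragment in every control set, the count of its U coordinate
#' serving as a U end and of its D coordinate (`end - 1`) serving as a D
#' end is incremented. Counts are raw: one model is built and applied
#' everywhere, so no normalization is needed (or applied).
#'
#' @param controls a [fragment_set()] or list of them, each already
#'   deduplicated ([dedup_fragments()]).
#' @return an object of class `end_model`: a sparse count table
#'   (chrom, pos, countU, countD) plus the pooled fragment count and the
#'   contributing sample ids.
#' @export
build_end_model <- function(controls) {
  if (inherits(controls, "fragment_set")) controls <- list(controls)
  if (length(controls) == 0L || sum(vapply(controls, nrow, 1L)) == 0L)
    stop("empty control pool")
  tabs <- lapply(controls, function(s) {
    e <- fragment_ends(s)
    data.table::data.table(chrom = c(e$chrom, e$chrom),
                           pos = c(e$u, e$d),
                           u = rep(c(1L, 0L), c(length(e$u), length(e$d))),
                           d = rep(c(0L, 1L), c(length(e$u), length(e$d))))
  })
  tab <- data.table::rbindlist(tabs)[, .(countU = sum(u), countD = sum(d)),
                                     by = .(chrom, pos)]
  data.table::setkeyv(tab, c("chrom", "pos"))
  structure(list(tab = tab,
                 n_fragments = sum(vapply(controls, nrow, 1L)),
                 samples = vapply(controls, function(s)
                   s$sample_id[1] %||% NA_character_, character(1))),
            class = "end_model")
}

#' @export
print.end_model <- function(x, ...) {
  cat("<end_model> ", nrow(x$tab), " loci from ", x$n_fragments,
      " pooled fragments (", length(x$samples), " sample(s))\n", sep = "")
  invisible(x)
}

#' E-index of a sample against an ending-preference model
#'
#' For each fragment i, `M_U` is the model's U count at the fragment's U
#' coordinate and `M_D` the D count at its D coordinate (positions absent
#' from the model contribute 0, no pseudocount); the E-index is
#' `(1/N) * sum_i (M_U + M_D)` over the sample's N fragments.
#'
#' @param set a deduplicated [fragment_set()] with `N >= 1` fragments.
#' @param model an [build_end_model()] result.
#' @return an object of class `eindex_result`: list with `sample_id`, `n`,
#'   `e_index`, and `n_missing_u` / `n_missing_d` (ends at loci the model
#'   never saw).
#' @export
e_index <- function(set, model) {
  if (nrow(set) == 0L) stop("empty sample")
  e <- fragment_ends(set)
  q_u <- data.table::data.table(chrom = e$chrom, pos = e$u)
  q_d <- data.table::data.table(chrom = e$chrom, pos = e$d)
  mu <- model$tab[q_u, countU, on = c("chrom", "pos")]
  md <- model$tab[q_d, countD, on = c("chrom", "pos")]
  miss_u <- is.na(mu); miss_d <- is.na(md)
  mu[miss_u] <- 0L; md[miss_d] <- 0L
  structure(list(sample_id = set$sample_id[1] %||% "sample",
                 n = nrow(set),
                 e_index = mean(mu + md),
                 n_missing_u = sum(miss_u), n_missing_d = sum(miss_d)),
            class = "eindex_result")
}

#' @export
print.eindex_result <- function(x, ...) {
  cat("<eindex_result> ", x$sample_id, ": E-index ",
      format(x$e_index, digits = 6), " over ", x$n, " fragments\n", sep = "")
  invisible(x)
}

#' Serialize an ending-preference model to TSV
#' @param model an `end_model`.
#' @param path output path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_end_model <- function(model, path) {
  data.table::fwrite(model$tab, path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Load an ending-preference model from TSV
#' @param path TSV written by [write_end_model()].
#' @param n_fragments optional pooled fragment count to restore.
#' @return an `end_model`.
#' @export
read_end_model <- function(path, n_fragments = NA_integer_) {
  tab <- fread_auto(path, sep = "\t")
  data.table::setnames(tab, 1:4, c("chrom", "pos", "countU", "countD"))
  data.table::setkeyv(tab, c("chrom", "pos"))
  if (is.na(n_fragments)) n_fragments <- sum(tab$countU)
  structure(list(tab = tab, n_fragments = n_fragments, samples = NA_character_),
            class = "end_model")
}

#' Evaluate diagnostic scores by ROC analysis
#'
#' Uses the convention that lower scores indicate cancer (scores are negated
#' for ranking), so an informative E-index yields AUC > 0.5. The AUC is the
#' Mann-Whitney statistic; its difference from 0.5 is tested by a two-sided
#' Z test with the Hanley-McNeil standard error, and the group difference by
#' a two-sided Mann-Whitney U test.
#'
#' @param scores numeric scores (e.g. E-index values).
#' @param labels vector with two levels; `positive` marks the cancer group.
#' @param positive label of the positive (cancer) class.
#' @param lower_is_positive if `TRUE` (default) low scores indicate the
#'   positive class.
#' @return a list with `auc`, `z`, `p_z`, `p_mw`, `n_positive`,
#'   `n_negative`.
#' @export
evaluate_scores <- function(scores, labels, positive = "cancer",
                            lower_is_positive = TRUE) {
  labels <- as.character(labels)
  if (!(positive %in% labels) || all(labels == positive))
    stop("both classes must be present")
  s <- if (lower_is_positive) -scores else scores
  pos <- s[labels == positive]
  neg <- s[labels != positive]
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ## Hanley & McNeil (1982) SE of the AUC
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- if (se > 0) (auc - 0.5) / se else Inf * sign(auc - 0.5)
  p_z <- if (is.finite(z)) 2 * pnorm(-abs(z)) else 0
  p_mw <- suppressWarnings(wilcox.test(pos, neg)$p.value)
  list(auc = auc, z = z, p_z = p_z, p_mw = p_mw,
       n_positive = n1, n_negative = n0)
}

#' Correlation between scores and tumor DNA load
#'
#' @param scores numeric E-index values (>= 3 samples).
#' @param tumor_fractions aligned tumor DNA fractions.
#' @return a list with Pearson `r` and two-sided `p_value` (`NA` with a
#'   warning if either input is constant).
#' @export
tumor_load_correlation <- function(scores, tumor_fractions) {
  stopifnot(length(scores) == length(tumor_fractions))
  if (length(scores) < 3L) stop("need >= 3 samples")
  if (sd(scores) == 0 || sd(tumor_fractions) == 0) {
    warning("constant input; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_))
  }
  ct <- cor.test(scores, tumor_fractions, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Combine methylation density and E-index for diagnosis
#'
#' Two-feature logistic regression scored by leave-one-out: each sample's
#' combined score is its predicted cancer probability from a model fitted
#' to all other samples. Individual AUCs are computed under the same
#' leave-one-out single-feature protocol so the three numbers are directly
#' comparable (mixing in-sample feature AUCs with out-of-sample combined
#' scores would bias the comparison against the combination).
#'
#' @param methylation_density per-sample methylation densities.
#' @param e_index per-sample E-index values.
#' @param labels per-sample labels; `positive` marks cancer.
#' @param positive label of the cancer class.
#' @return a list with `auc_methylation`, `auc_eindex`, `auc_combined` (all
#'   leave-one-out) and `combined_scores` (leave-one-out cancer
#'   probabilities of the two-feature model).
#' @export
combine_features <- function(methylation_density, e_index, labels,
                             positive = "cancer") {
  stopifnot(length(methylation_density) == length(e_index),
            length(labels) == length(e_index))
  y <- as.integer(as.character(labels) == positive)
  df <- data.frame(y = y, meth = methylation_density, eidx = e_index)
  loo_scores <- function(formula) {
    vapply(seq_len(nrow(df)), function(i) {
      fit <- suppressWarnings(glm(formula, family = binomial(),
                                  data = df[-i, ]))
      as.numeric(suppressWarnings(predict(fit, df[i, ], type = "response")))
    }, numeric(1))
  }
  pred <- loo_scores(y ~ meth + eidx)
  auc_of <- function(scores) evaluate_scores(scores, labels, positive,
                                             lower_is_positive = FALSE)$auc
  list(auc_methylation = auc_of(loo_scores(y ~ meth)),
       auc_eindex = auc_of(loo_scores(y ~ eidx)),
       auc_combined = auc_of(pred),
       combined_scores = pred)
}
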