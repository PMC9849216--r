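test_that("the end model counts U and D appearances per locus", {
  one <- fragment_set(data.frame(chrom = "chrS", start = 10, end = 20))
  m <- build_end_model(one)
  expect_equal(nrow(m$tab), 2)
  expect_equal(m$tab[list("chrS", 10L), countU, on = c("chrom", "pos")], 1L)
  expect_equal(m$tab[list("chrS", 10L), countD, on = c("chrom", "pos")], 0L)
  expect_equal(m$tab[list("chrS", 19L), countD, on = c("chrom", "pos")], 1L)

  # additivity: pooling a set twice doubles every count
  m2 <- build_end_model(list(one, one))
  expect_equal(m2$tab$countU, 2L * m$tab$countU)
  expect_equal(m2$tab$countD, 2L * m$tab$countD)

  expect_error(build_end_model(list()), "empty")
})

test_that("model counts conserve the pooled fragment number", {
  controls <- lapply(1:4, function(i)
    dedup_fragments(draw_sample(5000, seed = 80 + i,
                                emit_methylation = FALSE)$fragments))
  m <- build_end_model(controls)
  n_pooled <- sum(vapply(controls, nrow, 1L))
  expect_equal(sum(m$tab$countU), n_pooled)
  expect_equal(sum(m$tab$countD), n_pooled)
  expect_equal(m$n_fragments, n_pooled)
})

test_that("the E-index evaluates the weighted-average formula exactly", {
  model <- build_end_model(fragment_set(data.frame(chrom = "chrS",
                                                   start = 10, end = 20)))
  # inflate counts to the worked values {10: (5,0), 19: (0,3)}
  model$tab[, countU := countU * 5L]
  model$tab[, countD := countD * 3L]
  smp <- fragment_set(data.frame(chrom = "chrS", start = 10, end = 20))
  r <- e_index(smp, model)
  expect_equal(r$e_index, 8)
  expect_equal(r$n, 1)

  miss <- fragment_set(data.frame(chrom = "chrS", start = 500, end = 700))
  rm_ <- e_index(miss, model)
  expect_equal(rm_$e_index, 0)
  expect_equal(rm_$n_missing_u + rm_$n_missing_d, 2)

  expect_error(e_index(miss[0, ], model), "empty")
})

test_that("sparse-model E-index equals the brute-force per-read oracle", {
  for (s in 1:100) {
    controls <- lapply(1:3, function(i)
      dedup_fragments(random_fragments(400, seed = 7000 + 13 * s + i)))
    smp <- dedup_fragments(random_fragments(1000, seed = 9000 + s))
    model <- build_end_model(controls)
    expect_identical(e_index(smp, model)$e_index,
                     eindex_oracle(smp, controls))
  }
})

test_that("duplicating the pooled controls doubles every E-index", {
  controls <- lapply(1:3, function(i)
    dedup_fragments(draw_sample(4000, seed = 90 + i,
                                emit_methylation = FALSE)$fragments))
  smp <- dedup_fragments(draw_sample(3000, seed = 95,
                                     emit_methylation = FALSE)$fragments)
  m1 <- build_end_model(controls)
  m2 <- build_end_model(c(controls, controls))
  expect_equal(e_index(smp, m2)$e_index, 2 * e_index(smp, m1)$e_index)
})

test_that("off-lattice perturbation lowers the score of a matched sample", {
  controls <- lapply(1:4, function(i)
    dedup_fragments(draw_sample(20000, seed = 100 + i,
                                emit_methylation = FALSE)$fragments))
  model <- build_end_model(controls)
  smp <- dedup_fragments(draw_sample(10000, seed = 110,
                                     emit_methylation = FALSE)$fragments)
  shifted <- smp
  shifted$start <- shifted$start + 3L
  shifted$end <- shifted$end + 3L
  expect_gt(e_index(smp, model)$e_index,
            e_index(fragment_set(as.data.frame(shifted)), model)$e_index)
})

test_that("model serialization round-trips through TSV", {
  controls <- dedup_fragments(draw_sample(3000, seed = 120,
                                          emit_methylation = FALSE)$fragments)
  m <- build_end_model(controls)
  p <- withr::local_tempfile(fileext = ".tsv.gz")
  write_end_model(m, p)
  back <- read_end_model(p)
  expect_equal(as.data.frame(back$tab), as.data.frame(m$tab))
  smp <- dedup_fragments(draw_sample(1000, seed = 121,
                                     emit_methylation = FALSE)$fragments)
  expect_equal(e_index(smp, back)$e_index, e_index(smp, m)$e_index)
})

test_that("E-index decreases monotonically with tumor fraction", {
  controls <- lapply(1:5, function(i)
    dedup_fragments(draw_sample(20000, seed = 130 + i,
                                emit_methylation = FALSE)$fragments))
  model <- build_end_model(controls)
  fractions <- seq(0, 0.5, by = 0.1)
  scores <- vapply(seq_along(fractions), function(i) {
    smp <- draw_sample(50000, seed = 140 + i, tumor_fraction = fractions[i],
                       emit_methylation = FALSE)$fragments
    e_index(dedup_fragments(smp), model)$e_index
  }, numeric(1))
  expect_true(all(diff(scores) < 0))

  tl <- tumor_load_correlation(scores, fractions)
  expect_lt(tl$r, -0.8)
  expect_lt(tl$p_value, 0.05)
})

test_that("score evaluation handles perfect, null and degenerate cases", {
  perfect <- evaluate_scores(c(1, 2, 3, 10, 11, 12),
                             rep(c("cancer", "control"), each = 3))
  expect_equal(perfect$auc, 1)
  expect_lt(perfect$p_mw, 0.2)

  null <- evaluate_scores(rep(c(5, 6, 7), 2),
                          rep(c("cancer", "control"), each = 3))
  expect_equal(null$auc, 0.5)

  expect_error(evaluate_scores(1:3, rep("cancer", 3)), "class")

  # agreement with an established ROC implementation
  set.seed(1)
  sc <- c(rnorm(20, 5), rnorm(20, 6))
  lab <- rep(c("cancer", "control"), each = 20)
  ours <- evaluate_scores(sc, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("cancer", "control"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref)
})

test_that("tumor-load correlation flags degenerate inputs", {
  expect_error(tumor_load_correlation(1:2, 1:2), "3")
  expect_warning(r0 <- tumor_load_correlation(c(1, 1, 1), c(0, 0.1, 0.2)),
                 "constant")
  expect_true(is.na(r0$r))
  anti <- tumor_load_correlation(c(10, 8, 5, 2), c(0, 0.1, 0.3, 0.5))
  expect_lt(anti$r, -0.9)
})

test_that("combining methylation density and E-index never loses much accuracy", {
  set.seed(42)
  n <- 24
  lab <- rep(c("control", "cancer"), each = n / 2)
  # one perfectly separating feature dominates
  meth_perfect <- c(rnorm(n / 2, 10, 0.1), rnorm(n / 2, 0, 0.1))
  eidx_noise <- rnorm(n)
  comb <- combine_features(meth_perfect, eidx_noise, lab)
  expect_equal(comb$auc_combined, 1)

  # two pure-noise features stay near chance
  noise <- combine_features(rnorm(n), rnorm(n), lab)
  expect_lt(abs(noise$auc_combined - 0.5), 0.35)

  # correlated informative features on a cohort shaped like a WGBS
  # validation set (37 controls, 8 cancers): on average over seeds the
  # combination keeps pace with the better single feature (leave-one-out
  # fold noise makes single instances fluctuate by a few rank swaps)
  diffs <- vapply(1:12, function(s) {
    set.seed(s)
    n0 <- 37; n1 <- 8
    lab2 <- rep(c("control", "cancer"), c(n0, n1))
    latent <- c(rnorm(n0, 0), rnorm(n1, 3))
    meth <- 0.75 - 0.02 * latent + rnorm(n0 + n1, 0, 0.015)
    eidx <- 50 - 4 * latent + rnorm(n0 + n1, 0, 3)
    both <- combine_features(meth, eidx, lab2)
    both$auc_combined - max(both$auc_methylation, both$auc_eindex)
  }, numeric(1))
  expect_gte(mean(diffs), -0.02)
})

test_that("synthetic 12-vs-12 panels separate with high AUC across runs", {
  controls <- lapply(1:6, function(i)
    dedup_fragments(draw_sample(20000, seed = 150 + i,
                                emit_methylation = FALSE)$fragments))
  model <- build_end_model(controls)
  n_runs <- 50
  hits <- 0
  for (run in seq_len(n_runs)) {
    scores <- labels <- NULL
    for (j in 1:12) {
      ctl <- draw_sample(4000, seed = 10000 + 100 * run + j,
                         emit_methylation = FALSE)$fragments
      can <- draw_sample(4000, seed = 20000 + 100 * run + j,
                         tumor_fraction = 0.3, emit_methylation = FALSE)$fragments
      scores <- c(scores, e_index(dedup_fragments(ctl), model)$e_index,
                  e_index(dedup_fragments(can), model)$e_index)
      labels <- c(labels, "control", "cancer")
    }
    if (evaluate_scores(scores, labels)$auc >= 0.9) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.9)
})
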