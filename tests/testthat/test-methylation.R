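test_that("read classification follows the strict CpG-count and level thresholds", {
  rule <- methylation_class_rule()
  expect_equal(classify_fragment(c(1, 1, 1), rule), "hyper")
  expect_equal(classify_fragment(c(0, 0, 0), rule), "hypo")
  expect_equal(classify_fragment(1, rule), "unclassified")        # < 2 CpGs
  expect_equal(classify_fragment(c(1, 0), rule), "unclassified")  # 0.5 in band
  # boundary values are unclassified: thresholds are strict inequalities
  expect_equal(classify_fragment(c(1, 1, 1, 1, 0), rule), "unclassified") # 0.8
  expect_equal(classify_fragment(c(1, 0, 0, 0, 0), rule), "unclassified") # 0.2
  expect_equal(classify_fragment(rep(c(1, 0), c(9, 1)), rule), "hyper")   # 0.9
  # invariant to CpG ordering
  expect_equal(classify_fragment(c(0, 1, 1, 1, 1, 1), rule),
               classify_fragment(c(1, 1, 1, 1, 1, 0), rule))

  strict <- methylation_class_rule(min_cpgs = 5)
  expect_equal(classify_fragment(c(1, 1, 1), strict), "unclassified")
  expect_error(methylation_class_rule(hyper = 0.2, hypo = 0.8), "below")
})

test_that("class counts partition the called reads", {
  smp <- draw_sample(10000, seed = 61)
  cls <- classify_fragments(smp$calls)
  expect_equal(sum(table(cls$class)), length(unique(smp$calls$fragment_id)))
  expect_setequal(unique(cls$class),
                  intersect(c("hyper", "hypo", "unclassified"),
                            unique(cls$class)))
  # vectorized classification agrees with the single-read rule
  one <- smp$calls[smp$calls$fragment_id == cls$fragment_id[1], "state"]
  expect_equal(cls$class[1], classify_fragment(one))
})

test_that("hypo-methylated reads are shorter when the generator couples the two", {
  smp <- draw_sample(60000, seed = 62)
  res <- size_by_methylation_class(smp$fragments, smp$calls)
  expect_gt(res$short_fraction[["hypo"]], res$short_fraction[["hyper"]])
  expect_false(res$test$insufficient)
  expect_lt(res$test$p_value, 0.05)
  expect_gt(res$test$mean_diff, 0)  # hypo CDF dominates: stochastically shorter
  expect_equal(sum(res$n), nrow(smp$fragments))
})

test_that("degenerate methylation-class inputs are signaled", {
  fs <- fragment_set(data.frame(chrom = "chrS", start = c(0, 10),
                                end = c(100, 110)))
  # single-CpG calls everywhere: everything unclassified
  calls <- data.frame(fragment_id = fs$fragment_id, pos = c(5L, 15L),
                      state = c(1L, 0L))
  res <- size_by_methylation_class(fs, calls)
  expect_true(res$test$insufficient)
  expect_equal(unname(res$n[c("hyper", "hypo")]), c(0L, 0L))

  # two classes with identical size distributions: no difference, P = 1
  fs2 <- fragment_set(data.frame(chrom = "chrS",
                                 start = rep(0, 40),
                                 end = rep(c(100, 120), each = 20)))
  calls2 <- data.frame(fragment_id = rep(fs2$fragment_id, each = 2),
                       pos = rep(c(10L, 20L), 40),
                       state = rep(rep(c(1L, 0L), each = 2), 20))
  res2 <- size_by_methylation_class(fs2, calls2)
  expect_equal(res2$test$mean_diff, 0)
  expect_equal(res2$test$p_value, 1)
})

test_that("size-methylation regression recovers the generator's coupling", {
  # closed-form two-point check: (0.8 - 0.2) / (200 - 100) = 0.006 per bp
  fs <- fragment_set(data.frame(chrom = "chrS", start = c(0, 0),
                                end = c(100, 200)))
  calls <- data.frame(fragment_id = rep(fs$fragment_id, each = 5),
                      pos = rep(seq(10L, 50L, 10L), 2),
                      state = c(0L, 0L, 1L, 0L, 0L,    # size 100: mean 0.2
                                1L, 1L, 1L, 1L, 0L))   # size 200: mean 0.8
  cv <- size_methylation_curve(fs, calls)
  expect_equal(cv$slope, 0.006)
  expect_equal(cv$r, 1)

  smp <- draw_sample(60000, seed = 63)
  cv2 <- size_methylation_curve(smp$fragments, smp$calls)
  expect_gt(cv2$slope, 0)
  expect_lt(cv2$p_value, 0.05)
  expect_true(all(cv2$curve$mean_meth >= 0 & cv2$curve$mean_meth <= 1))

  one_size <- fragment_set(data.frame(chrom = "chrS", start = 0, end = 100))
  calls1 <- data.frame(fragment_id = one_size$fragment_id, pos = 10L,
                       state = 1L)
  expect_error(size_methylation_curve(one_size, calls1), "2 distinct sizes")
})

test_that("coupling on yields positive slopes across seeds; coupling off does not", {
  slopes_on <- vapply(1:25, function(s) {
    smp <- draw_sample(10000, seed = 200 + s)
    size_methylation_curve(smp$fragments, smp$calls)$slope
  }, numeric(1))
  expect_gte(mean(slopes_on > 0), 0.95)

  uncoupled <- cut_model(meth_sensitivity = 0)
  slopes_off <- vapply(1:25, function(s) {
    smp <- draw_sample(10000, seed = 300 + s, model = uncoupled)
    size_methylation_curve(smp$fragments, smp$calls)$slope
  }, numeric(1))
  # with the coupling disabled the slope has no systematic sign
  expect_gt(mean(slopes_off > 0), 0.1)
  expect_lt(mean(slopes_off > 0), 0.9)
  expect_lt(abs(mean(slopes_off)), abs(mean(slopes_on)))
})

test_that("differential CpG sites mark short-fragment (accessible) territory", {
  pos <- c(100L, 200L, 300L)
  sel <- select_differential_cpgs(pos, level_a = c(0.9, 0.9, 0.3),
                                  level_b = c(0.1, 0.5, 0.1))
  expect_equal(sel, 100L)
  expect_error(select_differential_cpgs(pos, 1, 1, hi = 0.2, lo = 0.8), "hi")

  # landscape where the "blood" profile carries hypomethylated domains and
  # a stable "liver" reference stays uniformly high: sites hyper-in-liver /
  # hypo-in-blood sit in accessible territory, so fragments covering them
  # are cut intra-core and run short
  trk <- fx$track
  ls <- make_methylation_landscape(trk, profiles = c(liver = 0.85, blood = 0.85),
                                   hypo_domain_fraction = 0.35,
                                   hypo_domain_profile = "blood", seed = 64)
  smp <- sample_fragments(trk, ls, fx$model,
                          sample_spec("control", 60000, seed = 65,
                                      background_profile = "blood"),
                          emit_methylation = FALSE)
  chS <- ls$chroms$chrS
  diff_sites <- select_differential_cpgs(chS$pos, chS$probs[, "liver"],
                                         chS$probs[, "blood"])
  both_hyper <- chS$pos[chS$probs[, "liver"] >= 0.8 & chS$probs[, "blood"] >= 0.8]
  expect_gt(length(diff_sites), 10)
  covered <- fragments_covering(smp$fragments,
                                list(blood_hypo = diff_sites,
                                     background = both_hyper))
  expect_gt(mean(covered$blood_hypo$size <= 147),
            mean(covered$background$size <= 147))
})

test_that("fragment-site coverage uses half-open interval logic", {
  fs <- fragment_set(data.frame(chrom = "chrS", start = c(0, 50),
                                end = c(50, 100)))
  expect_equal(nrow(fragments_covering(fs, 49L)), 1)
  expect_equal(fragments_covering(fs, 50L)$start, 50)  # end is exclusive
  expect_equal(nrow(fragments_covering(fs, 120L)), 0)
})

test_that("sample methylation density summarizes all CpG observations", {
  calls <- data.frame(fragment_id = c("a", "a", "b"), pos = c(1L, 2L, 3L),
                      state = c(1L, 1L, 1L))
  expect_equal(sample_methylation_density(calls), 1)
  expect_warning(d <- sample_methylation_density(calls[0, ]), "undefined")
  expect_true(is.na(d))

  ctrl <- draw_sample(20000, seed = 66)
  tum <- draw_sample(20000, seed = 67, tumor_fraction = 1)
  expect_lt(sample_methylation_density(tum$calls),
            sample_methylation_density(ctrl$calls))
})
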