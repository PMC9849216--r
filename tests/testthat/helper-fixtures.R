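# Shared fixtures, all built in code. Sizes are kept small except where a
# check needs the pooled-scale structure (documented in the methods
# vignette). Seeds are fixed a priori.

fx <- new.env()

# Canonical synthetic study conditions: the ~400-nucleosome phased array and
# a blood/tumor methylation landscape at the generator defaults.
fx$track <- make_nucleosome_array(400, 185, seed = 1)
fx$landscape <- make_methylation_landscape(fx$track, seed = 1)
fx$model <- cut_model()

# One pooled-scale control sample (the generator's default per-sample size).
fx$control <- sample_fragments(fx$track, fx$landscape, fx$model,
                               sample_spec("control", 200000, seed = 1))
fx$short <- partition_by_size(fx$control$fragments)$short
fx$long <- partition_by_size(fx$control$fragments)$long
fx$prof_short <- relative_end_profile(fx$short, fx$track, 93)

# Synthetic reference with CCCA seeded at the linker (methylation-
# associated) cut sites, at the generator's default enrichment.
fx$reference <- make_reference(fx$track, fx$model, enrichment = 0.7, seed = 1)

# Small track/landscape for cheap unit tests.
fx$track_small <- make_nucleosome_array(60, 185, seed = 2)
fx$landscape_small <- make_methylation_landscape(fx$track_small, seed = 2)

# Landscape with a uniform methylation level (no domain structure), used to
# isolate the effect of the mean level.
flat_landscape <- function(track, level, seed = 1) {
  make_methylation_landscape(track, profiles = c(blood = level, tumor = 0.4),
                             hypo_domain_fraction = 0,
                             domain_concentration = 1e6,
                             site_concentration = 1e6, seed = seed)
}

draw_sample <- function(n, seed, tumor_fraction = 0, track = fx$track,
                        landscape = fx$landscape, model = fx$model,
                        emit_methylation = TRUE,
                        label = if (tumor_fraction > 0) "cancer" else "control") {
  sample_fragments(track, landscape, model,
                   sample_spec(label, n, tumor_fraction = tumor_fraction,
                               seed = seed),
                   emit_methylation = emit_methylation)
}

# Independent E-index oracle: plain named-vector count tables and a per-read
# loop; shares no code with the sparse data.table model.
eindex_oracle <- function(sample_set, control_sets) {
  u_keys <- unlist(lapply(control_sets, function(s)
    paste(s$chrom, s$start)))
  d_keys <- unlist(lapply(control_sets, function(s)
    paste(s$chrom, s$end - 1L)))
  tab_u <- table(u_keys)
  tab_d <- table(d_keys)
  total <- 0
  for (i in seq_len(nrow(sample_set))) {
    ku <- paste(sample_set$chrom[i], sample_set$start[i])
    kd <- paste(sample_set$chrom[i], sample_set$end[i] - 1L)
    mu <- if (ku %in% names(tab_u)) tab_u[[ku]] else 0
    md <- if (kd %in% names(tab_d)) tab_d[[kd]] else 0
    total <- total + mu + md
  }
  total / nrow(sample_set)
}

# Random fragment sets unrelated to the nucleosomal generator.
random_fragments <- function(n, seed, sample_id = "rand", width_max = 300L) {
  withr::with_seed(seed, {
    start <- sample.int(5000L, n, replace = TRUE)
    fragment_set(data.frame(chrom = "chrR", start = start,
                            end = start + sample.int(width_max, n,
                                                     replace = TRUE)),
                 sample_id = sample_id)
  })
}

# Minimal SAM text for paired-end ingestion tests.
write_test_sam <- function(path, records) {
  header <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chrS\tLN:100000")
  writeLines(c(header, records), path)
}

sam_pair <- function(qname, pos1, pos2, read_len = 60L, proper = TRUE,
                     secondary = FALSE) {
  # pos1/pos2 are 1-based leftmost positions of the two mates
  f1 <- 0x1 + 0x40 + 0x20; f2 <- 0x1 + 0x80 + 0x10
  if (proper) { f1 <- f1 + 0x2; f2 <- f2 + 0x2 }
  if (secondary) { f1 <- f1 + 0x100; f2 <- f2 + 0x100 }
  tlen <- pos2 + read_len - pos1
  cig <- paste0(read_len, "M")
  seqs <- strrep("A", read_len)
  qual <- strrep("I", read_len)
  c(paste(qname, f1, "chrS", pos1, 60, cig, "=", pos2, tlen, seqs, qual,
          sep = "\t"),
    paste(qname, f2, "chrS", pos2, 60, cig, "=", pos1, -tlen, seqs, qual,
          sep = "\t"))
}
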