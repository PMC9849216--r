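## End-to-end orchestration: simulate -> import -> profile -> periodicity ->
## methylation -> motifs -> E-index -> JSON report, driven by one config.

#' Pipeline configuration
#'
#' All stage parameters with their defaults; any entry can be overridden by
#' passing a named list (nested by stage). The configuration round-trips
#' unchanged through [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param outdir output directory for all stage products.
#' @param seed global seed.
#' @param overrides named nested list of parameter overrides, e.g.
#'   `list(simulate = list(n_fragments = 5000))`.
#' @param stages character vector of stages to run, in dependency order.
#' @return an object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(outdir, seed = 1L, overrides = list(),
                            stages = c("simulate", "profile", "periodicity",
                                       "methylation", "motifs", "eindex")) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed), stages = stages,
    simulate = list(n_fragments = 200000L, n_controls = 24L, n_cancer = 2L,
                    tumor_fraction = 0.3, n_nucleosomes = 400L,
                    spacing = 185L, cpg_step = 25L,
                    blood_mean = 0.8, tumor_mean = 0.4,
                    hypo_domain_fraction = 0.3, motif_enrichment = 0.7),
    profile = list(W = 93L, short_max = 147L, long_min = 170L,
                   core_halfwidth = 73L),
    periodicity = list(span = 0.3, band = c(5, 20)),
    methylation = list(min_cpgs = 2L, hyper = 0.8, hypo = 0.2),
    motifs = list(k = 4L, motif = "CCCA", medip_weight = 0.25),
    eindex = list(holdout_controls = 1L))
  for (stage in names(overrides)) {
    if (is.list(overrides[[stage]]))
      cfg[[stage]][names(overrides[[stage]])] <- overrides[[stage]]
    else cfg[[stage]] <- overrides[[stage]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (JSON)
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return `path` invisibly; [read_pipeline_config()] returns the config.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic fixture
#' bundle, writing per-stage TSVs, a JSON summary, an effective-config
#' snapshot and a log under `config$outdir`. Every stage output is a pure
#' function of (inputs, parameters, seed).
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly (also `summary.json` on disk).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logf <- file.path(outdir, "pipeline.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                ..., "\n", sep = "", file = logf, append = TRUE)
  cat("fragaxis ", as.character(utils::packageVersion("fragaxis")),
      "; seed ", cfg$seed, "\n", sep = "", file = logf)
  write_pipeline_config(cfg, file.path(outdir, "effective_config.json"))
  summary <- list(seed = cfg$seed)
  simdir <- file.path(outdir, "sim")
  stages <- cfg$stages

  if ("simulate" %in% stages) {
    log_line("stage simulate")
    s <- cfg$simulate
    write_fixture_bundle(simdir, seed = cfg$seed,
                         n_fragments = s$n_fragments,
                         n_controls = s$n_controls, n_cancer = s$n_cancer,
                         tumor_fraction = s$tumor_fraction,
                         n_nucleosomes = s$n_nucleosomes, spacing = s$spacing,
                         cpg_step = s$cpg_step,
                         profiles = c(blood = s$blood_mean,
                                      tumor = s$tumor_mean),
                         hypo_domain_fraction = s$hypo_domain_fraction,
                         motif_enrichment = s$motif_enrichment)
  }
  manifest_path <- file.path(simdir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("missing upstream output for stage import: ", manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  track <- read_nucleosome_track(file.path(simdir, "nucleosomes.bed"))
  ctrl_files <- list.files(simdir, "^control_[0-9]+\\.bed$", full.names = TRUE)
  cancer_files <- list.files(simdir, "^cancer_[0-9]+\\.bed$", full.names = TRUE)
  controls <- lapply(ctrl_files, read_fragments_bed, label = "control")
  cancers <- lapply(cancer_files, read_fragments_bed, label = "cancer")
  pool <- as_fragment_set(do.call(rbind, lapply(controls, as.data.frame)),
                          controls[[1]])
  parts <- partition_by_size(pool, cfg$profile$short_max, cfg$profile$long_min)
  prof_short <- relative_end_profile(parts$short, track, cfg$profile$W)

  if ("profile" %in% stages) {
    log_line("stage profile")
    prof_long <- relative_end_profile(parts$long, track, cfg$profile$W)
    u_peaks <- call_end_peaks(prof_short, "U")
    d_peaks <- call_end_peaks(prof_short, "D")
    sd_ctrl <- size_distribution(controls[[1]])
    data.table::fwrite(data.table::data.table(
      position = prof_short$positions,
      countU = prof_short$u_counts, countD = prof_short$d_counts,
      freqU = profile_frequencies(prof_short, "U"),
      freqD = profile_frequencies(prof_short, "D")),
      file.path(outdir, "profile_short.tsv"), sep = "\t")
    summary$profile <- list(
      modal_size = sd_ctrl$mode,
      within_core_short = as.list(within_core_fraction(prof_short,
                                                       cfg$profile$core_halfwidth)),
      within_core_long = as.list(within_core_fraction(prof_long,
                                                      cfg$profile$core_halfwidth)),
      u_peaks = u_peaks$position, d_peaks = d_peaks$position,
      pseudo_sizes = if (nrow(u_peaks) && nrow(d_peaks))
        pseudo_fragment_sizes(u_peaks, d_peaks)$size else integer(0))
  }

  if ("periodicity" %in% stages) {
    log_line("stage periodicity")
    dom <- function(orient) {
      f <- profile_frequencies(prof_short, orient)
      dominant_period(periodogram(detrend(f, cfg$periodicity$span)),
                      cfg$periodicity$band)
    }
    summary$periodicity <- list(dominant_period_U = dom("U"),
                                dominant_period_D = dom("D"))
  }

  if ("methylation" %in% stages) {
    log_line("stage methylation")
    calls_path <- file.path(simdir, "calls_control_01.tsv")
    if (!file.exists(calls_path))
      stop("missing upstream output for stage methylation: ", calls_path)
    calls <- read_methylation_calls(calls_path)
    rule <- methylation_class_rule(cfg$methylation$min_cpgs,
                                   cfg$methylation$hyper, cfg$methylation$hypo)
    cls <- size_by_methylation_class(controls[[1]], calls, rule)
    curve <- size_methylation_curve(controls[[1]], calls)
    data.table::fwrite(curve$curve, file.path(outdir, "size_meth_curve.tsv"),
                       sep = "\t")
    summary$methylation <- list(
      short_fraction = as.list(cls$short_fraction),
      class_counts = as.list(cls$n),
      slope = curve$slope, slope_p = curve$p_value,
      density = sample_methylation_density(calls))
  }

  if ("motifs" %in% stages) {
    log_line("stage motifs")
    reference <- Biostrings::readDNAStringSet(file.path(simdir, "reference.fa"))
    calls <- read_methylation_calls(file.path(simdir, "calls_control_01.tsv"))
    parent <- controls[[1]]
    captured <- simulate_medip_capture(parent, calls,
                                       cfg$motifs$medip_weight,
                                       seed = cfg$seed + 99L)
    spec_parent <- end_motif_spectrum(parent, reference, cfg$motifs$k)
    spec_medip <- end_motif_spectrum(captured, reference, cfg$motifs$k)
    data.table::fwrite(data.table::data.table(
      motif = names(spec_parent$counts), count = spec_parent$counts,
      frequency = motif_frequencies(spec_parent)),
      file.path(outdir, "motif_spectrum.tsv"), sep = "\t")
    summary$motifs <- list(
      usage_parent = motif_usage(spec_parent, cfg$motifs$motif),
      usage_medip = motif_usage(spec_medip, cfg$motifs$motif))
  }

  if ("eindex" %in% stages) {
    log_line("stage eindex")
    nh <- min(cfg$eindex$holdout_controls, length(controls) - 1L)
    train <- controls[seq_len(length(controls) - nh)]
    held <- controls[seq.int(length(controls) - nh + 1L, length(controls))]
    model <- build_end_model(lapply(train, dedup_fragments))
    write_end_model(model, file.path(outdir, "end_model.tsv.gz"))
    scored <- c(held, cancers)
    res <- lapply(scored, function(s) e_index(dedup_fragments(s), model))
    tab <- data.table::data.table(
      sample = vapply(res, `[[`, "", "sample_id"),
      label = vapply(scored, function(s) attr(s, "label"), ""),
      n = vapply(res, `[[`, 1L, "n"),
      e_index = vapply(res, `[[`, 1, "e_index"))
    data.table::fwrite(tab, file.path(outdir, "eindex_scores.tsv"), sep = "\t")
    summary$eindex <- list(scores = as.list(setNames(tab$e_index, tab$sample)))
    if (length(unique(tab$label)) == 2L && all(table(tab$label) >= 2L)) {
      ev <- evaluate_scores(tab$e_index, tab$label)
      summary$eindex$auc <- ev$auc
      summary$eindex$p_mw <- ev$p_mw
    }
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done")
  invisible(summary)
}
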