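## Self-contained fixture bundle: every input file the analysis chain needs,
## generated from the synthetic model and written as plain text with a JSON
## manifest. Byte-reproducible under a fixed seed.

#' Write a synthetic cfDNA fixture bundle
#'
#' Emits a nucleosome-center track (BED3), a synthetic reference (FASTA),
#' per-sample control and cancer fragment files (BED3+3), methylation calls
#' (TSV) for the first control and each cancer sample, and a JSON manifest
#' recording parameters, per-file record counts, and the fraction of
#' fragments carrying at least one CpG.
#'
#' @param outdir output directory (created if missing).
#' @param seed master seed; per-sample seeds are derived from it.
#' @param n_fragments fragments per sample.
#' @param n_controls,n_cancer number of control / cancer samples.
#' @param tumor_fraction tumor DNA fraction of the cancer samples.
#' @param n_nucleosomes,spacing nucleosome-array geometry
#'   ([make_nucleosome_array()]).
#' @param cpg_step,profiles,hypo_domain_fraction landscape parameters
#'   ([make_methylation_landscape()]).
#' @param model a [cut_model()].
#' @param motif_enrichment reference motif-seeding enrichment
#'   ([make_reference()]).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_fixture_bundle <- function(outdir, seed = 1L,
                                 n_fragments = 200000L,
                                 n_controls = 24L, n_cancer = 2L,
                                 tumor_fraction = 0.3,
                                 n_nucleosomes = 400L, spacing = 185L,
                                 cpg_step = 25L,
                                 profiles = c(blood = 0.8, tumor = 0.4),
                                 hypo_domain_fraction = 0.3,
                                 model = cut_model(),
                                 motif_enrichment = 0.7) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", outdir)
  }
  track <- make_nucleosome_array(n_nucleosomes, spacing, seed = seed)
  landscape <- make_methylation_landscape(track, cpg_step = cpg_step,
                                          profiles = profiles,
                                          hypo_domain_fraction = hypo_domain_fraction,
                                          seed = seed + 1L)
  reference <- make_reference(track, model, enrichment = motif_enrichment,
                              seed = seed + 2L)
  files <- list()
  add_file <- function(name, path, n) {
    files[[length(files) + 1L]] <<- list(name = name,
                                         path = basename(path),
                                         n_records = n)
  }
  p_nuc <- file.path(outdir, "nucleosomes.bed")
  write_nucleosome_track(track, p_nuc)
  add_file("nucleosome_track", p_nuc, n_centers(track))
  p_ref <- file.path(outdir, "reference.fa")
  Biostrings::writeXStringSet(reference, p_ref)
  add_file("reference", p_ref, length(reference))

  cpg_fraction <- list()
  emit_sample <- function(label, i, tf) {
    tag <- sprintf("%s_%02d", label, i)
    with_calls <- (label == "control" && i == 1L) || label == "cancer"
    sp <- sample_spec(label, n_fragments, tumor_fraction = tf,
                      seed = seed + 10L + i + ifelse(label == "cancer", 500L, 0L),
                      sample_id = tag)
    smp <- sample_fragments(track, landscape, model, sp,
                            emit_methylation = with_calls)
    p <- file.path(outdir, paste0(tag, ".bed"))
    write_fragments_bed(smp$fragments, p)
    add_file(tag, p, nrow(smp$fragments))
    if (with_calls) {
      pc <- file.path(outdir, paste0("calls_", tag, ".tsv"))
      write_methylation_calls(smp$calls, pc)
      add_file(paste0("calls_", tag), pc, nrow(smp$calls))
      cpg_fraction[[tag]] <<- mean(smp$fragments$fragment_id %in%
                                     smp$calls$fragment_id)
    }
    smp$fragments
  }
  for (i in seq_len(n_controls)) emit_sample("control", i, 0)
  for (i in seq_len(n_cancer)) emit_sample("cancer", i, tumor_fraction)

  manifest <- list(
    seed = seed,
    params = list(n_fragments = n_fragments, n_controls = n_controls,
                  n_cancer = n_cancer, tumor_fraction = tumor_fraction,
                  n_nucleosomes = n_nucleosomes, spacing = spacing,
                  cpg_step = cpg_step, profiles = as.list(profiles),
                  hypo_domain_fraction = hypo_domain_fraction,
                  motif_enrichment = motif_enrichment,
                  cut_model = unclass(model)),
    files = files,
    cpg_fraction = cpg_fraction)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
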