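# End-to-end pipeline: simulate (or load) peak tables, filter, align,
# diversity statistics with producer/non-producer comparison, peak sharing,
# annotation of aligned features, theoretical-space enumeration, and VIGS
# design on a (simulated or supplied) transcriptome. Every stage writes a
# stable filename into the output directory and the effective configuration
# is echoed as JSON.

#' Pipeline configuration
#'
#' @param seed Master seed; reseeds the simulators unless they were passed
#'   explicitly with their own seed.
#' @param sim [peak_sim_config()] used when no input peak table is supplied.
#' @param transcriptome [transcriptome_sim_config()] used when no FASTA
#'   inputs are supplied; set to NULL to skip the VIGS stage.
#' @param input_peaks,input_meta Optional CSV paths; when given, these
#'   replace the simulation stage.
#' @param vigs_targets,vigs_offtargets Optional FASTA paths for VIGS design.
#' @param intensity_threshold Intensity filter (default 500).
#' @param mz_tol,rt_tol Alignment tolerances (Da, minutes).
#' @param tol_ppm Annotation mass tolerance (ppm).
#' @param add Adduct label assumed during annotation.
#' @param annotate_top Number of most intense aligned features to annotate.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, transcriptome = NULL,
                            input_peaks = NULL, input_meta = NULL,
                            vigs_targets = NULL, vigs_offtargets = NULL,
                            intensity_threshold = 500, mz_tol = 0.02,
                            rt_tol = 0.1, tol_ppm = 5, add = "[M+HCOO]-",
                            annotate_top = 100L) {
  if (is.null(sim)) sim <- peak_sim_config(seed = seed)
  if (is.null(transcriptome) && is.null(vigs_targets))
    transcriptome <- transcriptome_sim_config(seed = seed)
  structure(list(seed = seed, sim = sim, transcriptome = transcriptome,
                 input_peaks = input_peaks, input_meta = input_meta,
                 vigs_targets = vigs_targets,
                 vigs_offtargets = vigs_offtargets,
                 intensity_threshold = intensity_threshold,
                 mz_tol = mz_tol, rt_tol = rt_tol, tol_ppm = tol_ppm,
                 add = add, annotate_top = annotate_top),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  emit <- function(tag, file) { paths[[tag]] <<- file.path(out_dir, file); paths[[tag]] }

  # --- inputs: simulate or load --------------------------------------
  if (is.null(config$input_peaks)) {
    sim <- .stage("simulate", simulate_peak_tables(config$sim))
    .stage("simulate", write_peak_sim(sim, out_dir))
    peaks_path <- file.path(out_dir, "peaks.csv")
    meta_path <- file.path(out_dir, "sample_meta.csv")
  } else {
    peaks_path <- config$input_peaks
    meta_path <- config$input_meta
  }
  meta <- .stage("load", {
    if (is.null(meta_path)) NULL else read_sample_meta(meta_path)
  })
  peaks <- .stage("load", read_peak_table(peaks_path, meta))

  # --- filter and align ----------------------------------------------
  filtered <- .stage("filter", filter_intensity(peaks, config$intensity_threshold))
  apm <- .stage("align", align_peaks(filtered, config$mz_tol, config$rt_tol))
  .stage("align", write_aligned_matrix(apm, emit("aligned", "aligned_matrix.tsv")))

  # --- diversity ------------------------------------------------------
  div <- .stage("diversity", diversity_stats(apm))
  .stage("diversity", write_diversity(div, apm, out_dir, meta))
  paths$diversity_samples <- file.path(out_dir, "diversity_samples.tsv")
  paths$diversity_features <- file.path(out_dir, "diversity_features.tsv")
  if (!is.null(meta) && length(unique(meta$group)) == 2L) {
    grp <- meta$group[match(apm$samples, meta$sample_id)]
    h_prod <- div$H[grp == "producer"]; h_non <- div$H[grp == "nonproducer"]
    if (length(h_prod) >= 2 && length(h_non) >= 2) {
      ks <- .stage("diversity", compare_entropy_groups(h_prod, h_non))
      utils::write.table(
        data.frame(D = ks$D, p_value = ks$p_value,
                   higher = c(A = "producer", B = "nonproducer")[ks$higher],
                   median_producer = ks$median_a,
                   median_nonproducer = ks$median_b),
        emit("ks", "ks_test.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- peak sharing ---------------------------------------------------
  share <- .stage("share", sharing_matrix(apm))
  utils::write.table(round(share, 2), emit("sharing", "sharing_matrix.tsv"),
                     sep = "\t", quote = FALSE)

  # --- annotation of top aligned features ----------------------------
  ann <- .stage("annotate", {
    intensity <- apply(.intensity_matrix(apm), 2, max)
    top <- order(-intensity)[seq_len(min(config$annotate_top, length(intensity)))]
    rows <- lapply(top, function(j) {
      hits <- decompose_mass(apm$features$mz[j], config$add, config$tol_ppm)
      if (!nrow(hits)) return(NULL)
      cbind(observed_mz = apm$features$mz[j], rt = apm$features$rt[j],
            adduct = config$add, hits)
    })
    do.call(rbind, rows)
  })
  if (!is.null(ann))
    write_annotations(ann, emit("annotations", "annotations.tsv"))

  # --- theoretical enumeration ---------------------------------------
  .stage("enumerate", {
    cs <- chain_sets()
    counts <- data.frame(
      model = c("tetra: short x3 + full x1 (positional)",
                "tetra: full alphabet (multiset)"),
      count = c(count_theoretical(positions = list(cs$short, cs$short,
                                                   cs$short, cs$full))$count,
                count_theoretical(alphabet = cs$full, n_chains = 4)$count))
    utils::write.table(counts, emit("enumeration", "enumeration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- VIGS design ----------------------------------------------------
  if (!is.null(config$vigs_targets) || !is.null(config$transcriptome)) {
    vg <- .stage("vigs", {
      if (!is.null(config$vigs_targets)) {
        vigs_design(config$vigs_targets, config$vigs_offtargets)
      } else {
        tsim <- simulate_transcriptome(config$transcriptome)
        write_transcriptome_sim(tsim, out_dir)
        # design against the rest of the simulated transcriptome
        vigs_design(tsim$sequences[1:min(3, length(tsim$sequences))],
                    tsim$sequences)
      }
    })
    utils::write.table(vg$windows, emit("vigs_windows", "vigs_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(vg$regions, emit("vigs_regions", "vigs_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- echo effective config -----------------------------------------
  cfg_json <- config
  cfg_json$sim$alphabet <- NULL  # recorded implicitly; keep the echo compact
  jsonlite::write_json(cfg_json, emit("config", "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(paths)
}
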