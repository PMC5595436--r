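# Seeded generators for synthetic peak tables and toy transcriptomes with the
# statistical structure the analyses assume: producer species with many,
# high-intensity, largely species-specific acylsugar peaks whose m/z values
# are exact adduct masses of known compositions (plus measurement jitter);
# non-producers with only sparse noise peaks straddling the 500-intensity
# filter; tissue replicates sharing most of a species' peaks; and toy
# transcriptomes with planted identical paralog blocks and homopolymer runs.

# run expr with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# normal jitter truncated at +/- `bound` (rejection sampling)
.rnorm_trunc <- function(n, sd, bound) {
  x <- stats::rnorm(n, 0, sd)
  bad <- which(abs(x) > bound)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > bound]
  }
  x
}

#' Configuration for the peak-table simulator
#'
#' Defaults encode the study conditions the pipeline is meant for: ten
#' acylsugar-producing and ten non-producing species, two tissue replicates
#' each; producer species carry 100-300 true acylsugar peaks (log-normal
#' intensities, floored above the 500 filter) of which only a small fraction
#' is shared between species, while every sample additionally receives 10-30
#' noise peaks with intensities straddling 500 so the intensity filter is
#' exercised. True-peak m/z values are exact adduct masses of randomly drawn
#' 2-6-chain compositions plus measurement jitter distributed as a normal
#' with 5 ppm spread truncated at +/-5 ppm (instrument error sits inside the
#' default annotation tolerance).
#'
#' @param n_producers,n_nonproducers Species counts per group.
#' @param tissues_per_species Tissue replicates per species.
#' @param peaks_per_producer Range of true-peak panel sizes per producer
#'   species.
#' @param peaks_per_nonproducer Range of noise-peak counts per sample.
#' @param shared_fraction_within_species Probability that a tissue sample
#'   carries each peak of its species panel.
#' @param shared_fraction_between_species Fraction of a producer panel drawn
#'   from a between-species shared pool.
#' @param intensity_log10_mean,intensity_log10_sd True-peak height model
#'   (log10 units).
#' @param noise_log10_mean,noise_log10_sd Noise-peak height model.
#' @param mz_jitter_ppm m/z jitter spread, truncated at the same value.
#' @param add Adduct generating observed m/z (default formate).
#' @param rt_range Chromatographic gradient window (minutes).
#' @param noise_mz_range m/z range for noise peaks.
#' @param alphabet Chain alphabet for planted compositions.
#' @param seed RNG seed.
#' @return A `peak_sim_config` list.
#' @export
peak_sim_config <- function(n_producers = 10L, n_nonproducers = 10L,
                            tissues_per_species = 2L,
                            peaks_per_producer = c(100L, 300L),
                            peaks_per_nonproducer = c(10L, 30L),
                            shared_fraction_within_species = 0.8,
                            shared_fraction_between_species = 0.05,
                            intensity_log10_mean = 4.0,
                            intensity_log10_sd = 0.6,
                            noise_log10_mean = log10(500),
                            noise_log10_sd = 0.3,
                            mz_jitter_ppm = 5,
                            add = "[M+HCOO]-",
                            rt_range = c(0.5, 20),
                            noise_mz_range = c(300, 1100),
                            alphabet = default_chain_alphabet(),
                            seed = 1L) {
  cfg <- list(n_producers = n_producers, n_nonproducers = n_nonproducers,
              tissues_per_species = tissues_per_species,
              peaks_per_producer = peaks_per_producer,
              peaks_per_nonproducer = peaks_per_nonproducer,
              shared_fraction_within_species = shared_fraction_within_species,
              shared_fraction_between_species = shared_fraction_between_species,
              intensity_log10_mean = intensity_log10_mean,
              intensity_log10_sd = intensity_log10_sd,
              noise_log10_mean = noise_log10_mean,
              noise_log10_sd = noise_log10_sd,
              mz_jitter_ppm = mz_jitter_ppm, add = add,
              rt_range = rt_range, noise_mz_range = noise_mz_range,
              alphabet = alphabet, seed = seed)
  fr <- c(shared_fraction_within_species, shared_fraction_between_species)
  if (any(fr < 0 | fr > 1)) stop("shared fractions must be in [0, 1]")
  if (any(peaks_per_producer <= 0) || any(peaks_per_nonproducer <= 0))
    stop("peak-count ranges must be positive")
  if (n_producers < 0 || n_nonproducers < 0) stop("species counts must be >= 0")
  if (tissues_per_species < 1) stop("need at least one tissue per species")
  structure(cfg, class = "peak_sim_config")
}

# sample m random 2-6-chain acylsucrose compositions; names and masses are
# computed in closed form (mass depends only on chain count and total
# carbons), which keeps large panels cheap. Equivalence with the
# composition layer is asserted in the test suite.
.sample_compositions <- function(alphabet, m, add, min_chains = 2L,
                                 max_chains = 6L) {
  mH <- .MONO_MASS[["H"]]; mO <- .MONO_MASS[["O"]]
  core_mass <- formula_mass(sugar_core("sucrose")$formula)
  n <- sample(min_chains:max_chains, m, replace = TRUE)
  name <- character(m); mz <- numeric(m)
  for (i in seq_len(m)) {
    carbons <- sort(sample(alphabet$carbons, n[i], replace = TRUE))
    total <- sum(carbons)
    mass <- core_mass + total * (12 + 2 * mH) + n[i] * (mO - 2 * mH)
    name[i] <- sprintf("S%d:%d(%s)", n[i], total, paste(carbons, collapse = ","))
    mz[i] <- mass + add$mass_shift
  }
  data.frame(name = name, mz_true = mz, stringsAsFactors = FALSE)
}

#' Simulate multi-sample peak tables with planted acylsugar compositions
#'
#' Deterministic under the config seed. Every true peak's observed m/z is the
#' exact adduct m/z of its recorded composition times (1 + jitter), jitter a
#' truncated normal in ppm; the ground-truth table records the composition
#' and both m/z values for every emitted true peak.
#'
#' @param cfg A [peak_sim_config()].
#' @return list(peaks, meta, truth, config): peak table
#'   (sample, mz, rt, height, area), sample metadata, ground-truth table, and
#'   the config used.
#' @export
simulate_peak_tables <- function(cfg = peak_sim_config()) {
  stopifnot(inherits(cfg, "peak_sim_config"))
  .with_seed(cfg$seed, {
    add <- if (is.character(cfg$add)) adduct(cfg$add) else cfg$add
    species <- c(if (cfg$n_producers) sprintf("prod%02d", seq_len(cfg$n_producers)),
                 if (cfg$n_nonproducers) sprintf("nonp%02d", seq_len(cfg$n_nonproducers)))
    group <- rep(c("producer", "nonproducer"),
                 c(cfg$n_producers, cfg$n_nonproducers))
    if (!length(species)) stop("config yields no samples")

    # between-species shared composition pool
    pool_size <- max(10L, ceiling(cfg$shared_fraction_between_species *
                                    max(cfg$peaks_per_producer) * 2))
    shared_pool <- .sample_compositions(cfg$alphabet, pool_size, add)
    shared_pool$rt <- stats::runif(pool_size, cfg$rt_range[1], cfg$rt_range[2])

    peaks <- list(); meta <- list(); truth <- list()
    for (si in seq_along(species)) {
      sp <- species[si]
      panel <- NULL
      if (group[si] == "producer") {
        p_n <- sample(cfg$peaks_per_producer[1]:cfg$peaks_per_producer[2], 1L)
        n_shared <- round(cfg$shared_fraction_between_species * p_n)
        own <- .sample_compositions(cfg$alphabet, p_n - n_shared, add)
        own$rt <- stats::runif(nrow(own), cfg$rt_range[1], cfg$rt_range[2])
        panel <- rbind(if (n_shared)
          shared_pool[sample.int(nrow(shared_pool), n_shared), ], own)
        panel$height <- pmax(501, 10^stats::rnorm(p_n, cfg$intensity_log10_mean,
                                                  cfg$intensity_log10_sd))
      }
      for (ti in seq_len(cfg$tissues_per_species)) {
        sid <- sprintf("%s_t%d", sp, ti)
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sid, species = sp, tissue = sprintf("tissue%d", ti),
          dry_weight_mg = round(stats::runif(1, 5, 15), 2),
          istd_area = round(10^stats::rnorm(1, 5, 0.1), 1),
          group = group[si], stringsAsFactors = FALSE)
        if (!is.null(panel) && nrow(panel)) {
          keep <- stats::runif(nrow(panel)) < cfg$shared_fraction_within_species
          if (!any(keep)) keep[sample.int(nrow(panel), 1L)] <- TRUE
          sub <- panel[keep, , drop = FALSE]
          jit <- .rnorm_trunc(nrow(sub), cfg$mz_jitter_ppm, cfg$mz_jitter_ppm)
          h <- pmax(501, sub$height * 10^stats::rnorm(nrow(sub), 0, 0.1))
          obs_mz <- sub$mz_true * (1 + jit * 1e-6)
          obs_rt <- pmax(0, sub$rt + stats::rnorm(nrow(sub), 0, 0.01))
          peaks[[length(peaks) + 1L]] <- data.frame(
            sample = sid, mz = obs_mz, rt = obs_rt, height = h,
            area = h * stats::runif(nrow(sub), 0.05, 0.2),
            stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            sample = sid, species = sp, name = sub$name,
            mz_true = sub$mz_true, observed_mz = obs_mz, rt = obs_rt,
            height = h, stringsAsFactors = FALSE)
        }
        n_noise <- sample(cfg$peaks_per_nonproducer[1]:cfg$peaks_per_nonproducer[2], 1L)
        nh <- 10^stats::rnorm(n_noise, cfg$noise_log10_mean, cfg$noise_log10_sd)
        peaks[[length(peaks) + 1L]] <- data.frame(
          sample = sid,
          mz = stats::runif(n_noise, cfg$noise_mz_range[1], cfg$noise_mz_range[2]),
          rt = stats::runif(n_noise, cfg$rt_range[1], cfg$rt_range[2]),
          height = nh, area = nh * stats::runif(n_noise, 0.05, 0.2),
          stringsAsFactors = FALSE)
      }
    }
    peaks <- do.call(rbind, peaks)
    rownames(peaks) <- NULL
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(sample = character(), species = character(),
                 name = character(), mz_true = numeric(),
                 observed_mz = numeric(), rt = numeric(), height = numeric())
    list(peaks = peaks, meta = do.call(rbind, meta), truth = truth,
         config = cfg)
  })
}

#' Write a simulated peak dataset to disk
#'
#' Emits `peaks.csv`, `sample_meta.csv` and `ground_truth.tsv`.
#'
#' @param sim Output of [simulate_peak_tables()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_peak_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$peaks, file.path(dir, "peaks.csv"), row.names = FALSE)
  utils::write.csv(sim$meta, file.path(dir, "sample_meta.csv"), row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Configuration for the toy-transcriptome simulator
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Transcript length range (nt).
#' @param gc GC fraction of the random background.
#' @param n_paralog_blocks Number of planted identical paralog blocks; each
#'   appears verbatim in exactly two transcripts.
#' @param paralog_block_length Block length (nt; >= 20 so shared 20-mers
#'   exist).
#' @param n_homopolymer_runs Number of planted single-base runs.
#' @param homopolymer_run_length Run length (nt; >= 11 so a 20-nt window
#'   containing it is flagged).
#' @param seed RNG seed.
#' @return A `transcriptome_sim_config` list.
#' @export
transcriptome_sim_config <- function(n_transcripts = 20L,
                                     length_range = c(800L, 1500L),
                                     gc = 0.4,
                                     n_paralog_blocks = 5L,
                                     paralog_block_length = 40L,
                                     n_homopolymer_runs = 5L,
                                     homopolymer_run_length = 12L,
                                     seed = 1L) {
  if (paralog_block_length > length_range[1])
    stop("paralog block longer than the shortest transcript")
  if (homopolymer_run_length > length_range[1])
    stop("homopolymer run longer than the shortest transcript")
  if (n_paralog_blocks > 0 && n_transcripts < 2)
    stop("planting paralog blocks needs at least two transcripts")
  structure(list(n_transcripts = n_transcripts, length_range = length_range,
                 gc = gc, n_paralog_blocks = n_paralog_blocks,
                 paralog_block_length = paralog_block_length,
                 n_homopolymer_runs = n_homopolymer_runs,
                 homopolymer_run_length = homopolymer_run_length,
                 seed = seed),
            class = "transcriptome_sim_config")
}

.random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# sample a non-overlapping interval of `len` within 1..L given reserved
# intervals (list of c(start, end)); NULL if no room found
.free_offset <- function(L, len, reserved, tries = 200L) {
  for (i in seq_len(tries)) {
    s <- sample.int(L - len + 1L, 1L)
    e <- s + len - 1L
    clash <- any(vapply(reserved, function(r) s <= r[2] && e >= r[1], logical(1)))
    if (!clash) return(s)
  }
  NULL
}

#' Simulate a toy transcriptome with planted paralogs and homopolymers
#'
#' Deterministic under the config seed. Every planted paralog block appears
#' verbatim in exactly two transcripts at recorded offsets; homopolymer runs
#' are placed at recorded offsets. Planted features never overlap each other.
#'
#' @param cfg A [transcriptome_sim_config()].
#' @return list(sequences = named DNAStringSet, paralogs, homopolymers,
#'   config); paralogs has columns block_id, seq, transcript_a, start_a,
#'   transcript_b, start_b, length; homopolymers has transcript, start,
#'   length, base.
#' @export
simulate_transcriptome <- function(cfg = transcriptome_sim_config()) {
  stopifnot(inherits(cfg, "transcriptome_sim_config"))
  .with_seed(cfg$seed, {
    ids <- sprintf("T%02d", seq_len(cfg$n_transcripts))
    lens <- sample(cfg$length_range[1]:cfg$length_range[2],
                   cfg$n_transcripts, replace = TRUE)
    seqs <- vapply(lens, .random_dna, character(1), gc = cfg$gc)
    reserved <- rep(list(list()), cfg$n_transcripts)
    plant <- function(ti, s, block) {
      substr(seqs[ti], s, s + nchar(block) - 1L) <<- block
      reserved[[ti]][[length(reserved[[ti]]) + 1L]] <<-
        c(s, s + nchar(block) - 1L)
    }
    paralogs <- list()
    for (b in seq_len(cfg$n_paralog_blocks)) {
      block <- .random_dna(cfg$paralog_block_length, cfg$gc)
      pair <- sample.int(cfg$n_transcripts, 2L)
      s1 <- .free_offset(lens[pair[1]], nchar(block), reserved[[pair[1]]])
      s2 <- .free_offset(lens[pair[2]], nchar(block), reserved[[pair[2]]])
      if (is.null(s1) || is.null(s2)) stop("no room to plant paralog block")
      plant(pair[1], s1, block); plant(pair[2], s2, block)
      paralogs[[b]] <- data.frame(block_id = sprintf("block%02d", b),
                                  seq = block,
                                  transcript_a = ids[pair[1]], start_a = s1,
                                  transcript_b = ids[pair[2]], start_b = s2,
                                  length = nchar(block),
                                  stringsAsFactors = FALSE)
    }
    homos <- list()
    for (h in seq_len(cfg$n_homopolymer_runs)) {
      base <- sample(c("A", "C", "G", "T"), 1L)
      run <- strrep(base, cfg$homopolymer_run_length)
      ti <- sample.int(cfg$n_transcripts, 1L)
      s <- .free_offset(lens[ti], nchar(run), reserved[[ti]])
      if (is.null(s)) stop("no room to plant homopolymer run")
      plant(ti, s, run)
      homos[[h]] <- data.frame(transcript = ids[ti], start = s,
                               length = cfg$homopolymer_run_length,
                               base = base, stringsAsFactors = FALSE)
    }
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- ids
    list(sequences = sequences,
         paralogs = if (length(paralogs)) do.call(rbind, paralogs) else NULL,
         homopolymers = if (length(homos)) do.call(rbind, homos) else NULL,
         config = cfg)
  })
}

#' Write a simulated transcriptome to disk
#'
#' Emits `transcriptome.fasta` plus `paralogs.tsv` and `homopolymers.tsv`
#' ground-truth tables.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_transcriptome_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$sequences, file.path(dir, "transcriptome.fasta"))
  if (!is.null(sim$paralogs))
    utils::write.table(sim$paralogs, file.path(dir, "paralogs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$homopolymers))
    utils::write.table(sim$homopolymers, file.path(dir, "homopolymers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
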