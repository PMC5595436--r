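small_cfg <- function(seed = 1L)
  peak_sim_config(n_producers = 3, n_nonproducers = 3,
                  peaks_per_producer = c(30L, 60L), seed = seed)

test_that("the peak simulator is deterministic under its seed", {
  a <- simulate_peak_tables(small_cfg(5))
  b <- simulate_peak_tables(small_cfg(5))
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  c <- simulate_peak_tables(small_cfg(6))
  expect_false(identical(a$peaks, c$peaks))
})

test_that("a producer-free config emits only non-producer samples", {
  sim <- simulate_peak_tables(peak_sim_config(n_producers = 0,
                                              n_nonproducers = 4, seed = 2))
  expect_true(all(sim$meta$group == "nonproducer"))
  expect_identical(nrow(sim$truth), 0L)
  expect_true(all(sim$peaks$sample %in% sim$meta$sample_id))
})

test_that("true peak m/z values are exact adduct masses plus bounded jitter", {
  sim <- simulate_peak_tables(small_cfg(3))
  recomputed <- vapply(sim$truth$name, function(nm)
    adduct_mz(composition_from_name(nm), "[M+HCOO]-"), numeric(1))
  expect_equal(unname(recomputed), sim$truth$mz_true, tolerance = 1e-12)
  err_ppm <- (sim$truth$observed_mz - sim$truth$mz_true) / sim$truth$mz_true * 1e6
  expect_true(all(abs(err_ppm) <= 5))
  expect_true(stats::sd(err_ppm) > 1)  # jitter is real, not degenerate
})

test_that("ground truth survives the CSV -> filter -> align round trip", {
  sim <- simulate_peak_tables(small_cfg(4))
  dir <- tempfile(); write_peak_sim(sim, dir)
  peaks <- read_peak_table(file.path(dir, "peaks.csv"),
                           read_sample_meta(file.path(dir, "sample_meta.csv")))
  filtered <- filter_intensity(peaks, 500)
  # every true peak is above the filter by construction
  expect_true(all(sim$truth$height > 500))
  expect_identical(nrow(filtered), sum(peaks$height > 500))
  apm <- align_peaks(filtered)
  # each sample retains at least its true peak count among matrix entries
  for (sid in unique(sim$truth$sample)) {
    n_true <- sum(sim$truth$sample == sid)
    expect_true(sum(apm$height[sid, ] > 0) >= n_true * 0.95)
  }
})

test_that("within-species sharing exceeds between-species sharing", {
  sim <- simulate_peak_tables(small_cfg(7))
  apm <- align_peaks(filter_intensity(sim$peaks, 500))
  sh <- sharing_matrix(apm)
  sp <- sim$meta$species[match(apm$samples, sim$meta$sample_id)]
  grp <- sim$meta$group[match(apm$samples, sim$meta$sample_id)]
  same <- outer(sp, sp, "==") & !diag(length(sp))
  producers <- grp == "producer"
  within <- sh[same & outer(producers, producers, "&")]
  between <- sh[!same & outer(producers, producers, "&")]
  expect_true(mean(within) > mean(between))
})

test_that("producers separate from non-producers in entropy (single seed)", {
  sim <- simulate_peak_tables(peak_sim_config(seed = 8))
  apm <- align_peaks(filter_intensity(sim$peaks, 500))
  H <- diversity_stats(apm)$H
  grp <- sim$meta$group[match(apm$samples, sim$meta$sample_id)]
  ks <- compare_entropy_groups(H[grp == "producer"], H[grp == "nonproducer"])
  expect_lt(ks$p_value, 0.01)
  expect_identical(ks$higher, "A")
})

test_that("the transcriptome simulator plants features verbatim and reproducibly", {
  cfg <- transcriptome_sim_config(n_transcripts = 8,
                                  length_range = c(400L, 700L), seed = 9)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  for (i in seq_len(nrow(a$paralogs))) {
    p <- a$paralogs[i, ]
    sa <- as.character(a$sequences[[p$transcript_a]])
    sb <- as.character(a$sequences[[p$transcript_b]])
    expect_identical(substr(sa, p$start_a, p$start_a + p$length - 1), p$seq)
    expect_identical(substr(sb, p$start_b, p$start_b + p$length - 1), p$seq)
  }
  for (i in seq_len(nrow(a$homopolymers))) {
    h <- a$homopolymers[i, ]
    s <- as.character(a$sequences[[h$transcript]])
    expect_identical(substr(s, h$start, h$start + h$length - 1),
                     strrep(h$base, h$length))
  }
})

test_that("planted blocks and runs are flagged by the VIGS screen", {
  sim <- simulate_transcriptome(transcriptome_sim_config(
    n_transcripts = 6, length_range = c(500L, 800L), n_paralog_blocks = 2,
    paralog_block_length = 40L, n_homopolymer_runs = 2, seed = 10))
  p <- sim$paralogs[1, ]
  flags <- screen_transcript(sim$sequences[p$transcript_a], sim$sequences)
  # all 40 - 20 + 1 = 21 windows inside the planted block match its twin
  inside <- flags$start >= p$start_a & flags$end <= p$start_a + p$length - 1
  expect_identical(sum(inside), 21L)
  expect_true(all(flags$flagged_identity[inside]))

  h <- sim$homopolymers[1, ]
  hf <- screen_transcript(sim$sequences[h$transcript], sim$sequences)
  covering <- hf$start <= h$start & hf$end >= h$start + 10  # >= 11 run nt inside
  expect_true(all(hf$flagged_homopolymer[covering]))
})
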