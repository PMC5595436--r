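rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("window tiling covers L - k + 1 starts at step 1", {
  expect_identical(tile_windows(300), 1:281)
  expect_identical(tile_windows(20), 1L)
  expect_error(tile_windows(19), "shorter than window")
  expect_identical(tile_windows(100, k = 20, step = 10), seq(1L, 81L, 10L))
})

test_that("identity flagging is strict: 20/20 flags, 19/20 does not", {
  win <- rand_dna(20, seed = 41)
  off <- c(db1 = paste0(rand_dna(50), win, rand_dna(50)))
  hit <- flag_identity(win, off)
  expect_true(hit$flagged)
  expect_identical(hit$best$identity, 1)
  expect_identical(hit$best$subject, "db1")

  # one mismatch: 19/20 = 0.95, not strictly greater than 0.95
  mut <- win
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(win, 10, 10))[1]
  expect_false(flag_identity(mut, off)$flagged)
  # but it is flagged under a lower threshold
  expect_true(flag_identity(mut, off, threshold = 0.90)$flagged)
})

test_that("reverse-complement matches are flagged", {
  win <- rand_dna(20, seed = 42)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
  off <- c(db1 = paste0(rand_dna(30), rc, rand_dna(30)))
  expect_true(flag_identity(win, off)$flagged)
})

test_that("homopolymer flagging uses the strict >50% longest-run rule", {
  expect_true(flag_homopolymer(strrep("A", 20)))
  expect_false(flag_homopolymer(paste0(strrep("A", 10), strrep("C", 10))))
  expect_true(flag_homopolymer(paste0(strrep("A", 11), rand_dna(9, seed = 43))))
  expect_false(flag_homopolymer(strrep("AC", 10)))
  # dominant-base alternative counts totals, not runs
  expect_true(flag_homopolymer(paste0(strrep("AC", 5), strrep("A", 10)),
                               method = "dominant"))
})

test_that("clean-region selection respects the >12-window rule", {
  t300 <- c(tx = rand_dna(300, seed = 44))
  flags <- screen_transcript(t300, c(other = rand_dna(100)))
  expect_false(any(flags$flagged))
  regions <- select_vigs_regions(flags)
  expect_identical(nrow(regions), 1L)
  expect_identical(regions$start, 1L)
  expect_identical(regions$end, 300L)
  expect_identical(regions$n_clean_windows, 281L)
  expect_identical(regions$construct_start, 1L)
  expect_identical(regions$construct_end, 300L)

  # a run of exactly 12 clean windows is rejected (12 is not > 12)
  flags12 <- flags[1:12, ]
  expect_identical(nrow(select_vigs_regions(flags12)), 0L)
  flags13 <- flags[1:13, ]
  expect_identical(nrow(select_vigs_regions(flags13)), 1L)
})

test_that("a planted off-target 20-mer splits the transcript into two regions", {
  set.seed(45)
  left <- rand_dna(150); mid <- rand_dna(20); right <- rand_dna(150)
  target <- c(tx = paste0(left, mid, right))
  off <- c(db = paste0(rand_dna(40), mid, rand_dna(40)))
  flags <- screen_transcript(target, off)
  # only the window coinciding with the planted 20-mer matches verbatim
  expect_identical(sum(flags$flagged_identity), 1L)
  expect_identical(flags$start[flags$flagged_identity], 151L)
  regions <- select_vigs_regions(flags)
  expect_identical(nrow(regions), 2L)
  # no window contained in a region is flagged (regions are made of clean
  # windows; the planted 20-mer never fits inside a selected region)
  for (i in seq_len(nrow(regions)))
    expect_false(any(flags$flagged &
                       flags$start >= regions$start[i] &
                       flags$end <= regions$end[i]))
})

test_that("selection shrinks monotonically as off-targets accumulate", {
  set.seed(46)
  target <- c(tx = rand_dna(400))
  kmer1 <- substr(target, 101, 120)
  kmer2 <- substr(target, 301, 320)
  off1 <- c(a = paste0(rand_dna(20), kmer1, rand_dna(20)))
  off2 <- c(off1, b = paste0(rand_dna(20), kmer2, rand_dna(20)))
  r0 <- select_vigs_regions(screen_transcript(target, c(z = rand_dna(60))))
  r1 <- select_vigs_regions(screen_transcript(target, off1))
  r2 <- select_vigs_regions(screen_transcript(target, off2))
  expect_true(sum(r1$n_clean_windows) <= sum(r0$n_clean_windows))
  expect_true(sum(r2$n_clean_windows) <= sum(r1$n_clean_windows))
  # off-target order does not matter
  r2b <- select_vigs_regions(screen_transcript(target, rev(off2)))
  expect_equal(r2[order(r2$start), ], r2b[order(r2b$start), ], ignore_attr = TRUE)
})

test_that("the target itself and declared homologs are not off-targets", {
  set.seed(47)
  seqs <- c(tx = rand_dna(300))
  seqs["homolog"] <- seqs[["tx"]]
  flags_self <- screen_transcript(seqs["tx"], seqs["tx"])
  expect_false(any(flags_self$flagged_identity))
  flags_hom <- screen_transcript(seqs["tx"], seqs, exclude = "homolog")
  expect_false(any(flags_hom$flagged_identity))
  flags_off <- screen_transcript(seqs["tx"], seqs)
  expect_true(all(flags_off$flagged_identity))
})

test_that("vigs_design runs from FASTA files end to end", {
  set.seed(48)
  sim <- simulate_transcriptome(transcriptome_sim_config(
    n_transcripts = 6, length_range = c(400L, 600L), n_paralog_blocks = 2,
    n_homopolymer_runs = 2, seed = 48))
  dir <- tempfile(); dir.create(dir)
  write_transcriptome_sim(sim, dir)
  fa <- file.path(dir, "transcriptome.fasta")
  res <- vigs_design(fa, fa)
  expect_true(all(c("windows", "regions") %in% names(res)))
  expect_true(all(res$regions$n_clean_windows >= 13))
})
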