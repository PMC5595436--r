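# Silencing-fragment selection for virus-induced gene silencing (VIGS):
# tile a target transcript into overlapping 20-nt windows, flag windows with
# off-target similarity (>95% identity on either strand) or homopolymeric
# stretches (>50% of the window), and report contiguous clean regions with
# more than 12 unflagged windows as candidates for ~300 bp constructs.
#
# Coordinates are 1-based inclusive throughout (the R/Bioconductor
# convention), including in output tables.

.as_dna_set <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (inherits(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x)) {
    s <- Biostrings::DNAStringSet(toupper(x))
    if (is.null(names(x))) names(s) <- sprintf("seq%d", seq_along(x))
    else names(s) <- names(x)
    return(s)
  }
  stop("cannot interpret input as DNA sequences")
}

#' Tile a transcript into overlapping k-mers
#'
#' @param x Sequence (character/DNAString) or its length.
#' @param k Window size in nt (default 20).
#' @param step Tiling step (default 1: densest overlap).
#' @return Integer vector of 1-based window start positions
#'   (1, 1+step, ..., L-k+1).
#' @export
tile_windows <- function(x, k = 20L, step = 1L) {
  len <- if (is.numeric(x)) as.integer(x) else nchar(as.character(x))
  k <- as.integer(k); step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  if (len < k) stop("transcript shorter than window size k = ", k)
  seq.int(1L, len - k + 1L, by = step)
}

# smallest match count whose identity strictly exceeds the threshold
.required_matches <- function(k, threshold) floor(k * threshold + 1e-9) + 1L

#' Flag a window for off-target identity
#'
#' A window is flagged when some off-target sequence contains an ungapped
#' alignment of the k-mer, on either strand, with identity strictly greater
#' than the threshold. For k = 20 and the default 0.95 this requires a
#' perfect 20/20 match (19/20 = 95% is not > 95%).
#'
#' @param window Window sequence (length-k string).
#' @param offtargets Off-target sequences (FASTA path, DNAStringSet or named
#'   character). The target transcript itself must not be among them.
#' @param threshold Identity fraction (default 0.95, strict inequality).
#' @return list(flagged, best) where best = list(subject, identity) for the
#'   highest-identity hit found at or above the flagging level, else NULL.
#' @export
flag_identity <- function(window, offtargets, threshold = 0.95) {
  window <- toupper(as.character(window))
  k <- nchar(window)
  offtargets <- .as_dna_set(offtargets)
  max_mm <- k - .required_matches(k, threshold)
  if (max_mm < 0) return(list(flagged = FALSE, best = NULL))
  pat <- Biostrings::DNAString(window)
  rc <- Biostrings::reverseComplement(pat)
  subjects <- names(offtargets)
  for (mm in 0:max_mm) {
    fwd <- Biostrings::vcountPattern(pat, offtargets, max.mismatch = mm)
    rev <- Biostrings::vcountPattern(rc, offtargets, max.mismatch = mm)
    hit <- which(fwd + rev > 0)
    if (length(hit))
      return(list(flagged = TRUE,
                  best = list(subject = subjects[hit[1L]],
                              identity = (k - mm) / k)))
  }
  list(flagged = FALSE, best = NULL)
}

#' Flag a window for homopolymeric content
#'
#' Default interpretation: the longest single-nucleotide run must exceed
#' `fraction` of the window (for k = 20 and 0.5, a run of 11 nt or longer;
#' a 10-nt run is exactly 50% and is not flagged). The alternative
#' `"dominant"` method flags on the total count of the most common base.
#'
#' @param window Window sequence.
#' @param fraction Homopolymer fraction threshold (default 0.5, strict).
#' @param method `"run"` (default) or `"dominant"`.
#' @return Logical.
#' @export
flag_homopolymer <- function(window, fraction = 0.5, method = c("run", "dominant")) {
  method <- match.arg(method)
  chars <- strsplit(toupper(as.character(window)), "")[[1]]
  k <- length(chars)
  stat <- if (method == "run") max(rle(chars)$lengths) else max(table(chars))
  stat > fraction * k
}

# all k-mers of a DNAStringSet, both strands, as a data.frame(kmer, subject)
.kmer_table <- function(seqs, k) {
  seqs <- .as_dna_set(seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    L <- nchar(s)
    if (L < k) return(NULL)
    fwd <- substring(s, 1:(L - k + 1), k:L)
    rc <- as.character(Biostrings::reverseComplement(seqs[[i]]))
    rev <- substring(rc, 1:(L - k + 1), k:L)
    data.frame(kmer = c(fwd, rev), subject = names(seqs)[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen one transcript: per-window off-target and homopolymer flags
#'
#' @param target Target transcript (single named sequence; character,
#'   DNAString(Set) of length 1, or FASTA path with one record).
#' @param offtargets Off-target sequence set; any record whose name equals
#'   the target's, or appears in `exclude`, is dropped (self and known
#'   homologs must not count as off-targets).
#' @param k,step Window size and tiling step (defaults 20 and 1).
#' @param identity_threshold Off-target identity threshold (default 0.95,
#'   strict; at k = 20 this reduces to exact-match scanning on both strands).
#' @param homopolymer_fraction Homopolymer threshold (default 0.5, strict).
#' @param exclude Off-target record names to exclude.
#' @return data.frame: transcript, start, end, flagged_identity,
#'   flagged_homopolymer, flagged, best_offtarget, best_identity.
#' @export
screen_transcript <- function(target, offtargets, k = 20L, step = 1L,
                              identity_threshold = 0.95,
                              homopolymer_fraction = 0.5,
                              exclude = character()) {
  target <- .as_dna_set(target)
  if (length(target) != 1L) stop("target must be a single transcript")
  tid <- names(target)
  offtargets <- .as_dna_set(offtargets)
  offtargets <- offtargets[!names(offtargets) %in% c(tid, exclude)]
  seq <- as.character(target[[1L]])
  starts <- tile_windows(seq, k, step)
  wins <- substring(seq, starts, starts + k - 1L)

  max_mm <- k - .required_matches(k, identity_threshold)
  best_sub <- rep(NA_character_, length(starts))
  best_id <- rep(NA_real_, length(starts))
  if (max_mm < 0 || !length(offtargets)) {
    fid <- rep(FALSE, length(starts))
  } else if (max_mm == 0L) {
    kt <- .kmer_table(offtargets, k)
    if (is.null(kt)) {
      fid <- rep(FALSE, length(starts))
    } else {
      kt <- kt[!duplicated(kt$kmer), , drop = FALSE]
      idx <- match(wins, kt$kmer)
      fid <- !is.na(idx)
      best_sub[fid] <- kt$subject[idx[fid]]
      best_id[fid] <- 1
    }
  } else {
    res <- lapply(wins, flag_identity, offtargets = offtargets,
                  threshold = identity_threshold)
    fid <- vapply(res, `[[`, logical(1), "flagged")
    for (i in which(fid)) {
      best_sub[i] <- res[[i]]$best$subject
      best_id[i] <- res[[i]]$best$identity
    }
  }
  fhp <- vapply(wins, flag_homopolymer, logical(1),
                fraction = homopolymer_fraction, USE.NAMES = FALSE)
  data.frame(transcript = tid, start = starts, end = starts + k - 1L,
             flagged_identity = fid, flagged_homopolymer = fhp,
             flagged = fid | fhp,
             best_offtarget = best_sub, best_identity = best_id,
             stringsAsFactors = FALSE)
}

#' Select contiguous clean regions for VIGS constructs
#'
#' Maximal runs of consecutive unflagged windows of at least `min_clean`
#' windows (the default 13 encodes the "> 12 unflagged fragments" rule).
#' Each region spans from the first clean window's start to the last clean
#' window's end; when a region is at least `target_len` nt long, a suggested
#' construct sub-interval of exactly `target_len` nt is reported (leftmost
#' placement; within a clean run all placements hold equally many clean
#' windows).
#'
#' @param flags Per-window flag table from [screen_transcript()], sorted by
#'   start.
#' @param k,step Window size and tiling step used to build `flags`.
#' @param min_clean Minimum run length in windows (default 13).
#' @param target_len Desired construct length in nt (default 300).
#' @return data.frame sorted by n_clean_windows descending: transcript,
#'   start, end, n_clean_windows, construct_start, construct_end (NA when
#'   the region is shorter than `target_len`).
#' @export
select_vigs_regions <- function(flags, k = 20L, step = 1L, min_clean = 13L,
                                target_len = 300L) {
  empty <- data.frame(transcript = character(), start = integer(),
                      end = integer(), n_clean_windows = integer(),
                      construct_start = integer(), construct_end = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(flags)) return(empty)
  flags <- flags[order(flags$start), , drop = FALSE]
  clean <- !flags$flagged
  # break runs at flagged windows and at tiling gaps
  grp <- cumsum(!clean | c(TRUE, diff(flags$start) != step))
  rows <- list()
  for (g in split(which(clean), grp[clean])) {
    if (length(g) < min_clean) next
    s <- flags$start[g[1L]]
    e <- flags$end[g[length(g)]]
    cs <- if (e - s + 1L >= target_len) s else NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(
      transcript = flags$transcript[g[1L]], start = s, end = e,
      n_clean_windows = length(g),
      construct_start = cs,
      construct_end = if (is.na(cs)) NA_integer_ else cs + target_len - 1L,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_clean_windows, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end VIGS fragment design
#'
#' Screens every target transcript against the off-target set (minus itself
#' and `exclude`) and selects clean regions.
#'
#' @param targets Target transcript(s): FASTA path, DNAStringSet or named
#'   character vector.
#' @param offtargets Off-target sequences (e.g. the rest of the
#'   transcriptome plus a related genome's transcripts).
#' @inheritParams screen_transcript
#' @param min_clean,target_len Passed to [select_vigs_regions()].
#' @return list(windows, regions): combined per-window flag table and
#'   selected-region table over all targets.
#' @export
vigs_design <- function(targets, offtargets, k = 20L, step = 1L,
                        identity_threshold = 0.95,
                        homopolymer_fraction = 0.5, min_clean = 13L,
                        target_len = 300L, exclude = character()) {
  targets <- .as_dna_set(targets)
  offtargets <- .as_dna_set(offtargets)
  windows <- list(); regions <- list()
  for (i in seq_along(targets)) {
    fl <- screen_transcript(targets[i], offtargets, k = k, step = step,
                            identity_threshold = identity_threshold,
                            homopolymer_fraction = homopolymer_fraction,
                            exclude = exclude)
    windows[[i]] <- fl
    regions[[i]] <- select_vigs_regions(fl, k = k, step = step,
                                        min_clean = min_clean,
                                        target_len = target_len)
  }
  list(windows = do.call(rbind, windows), regions = do.call(rbind, regions))
}
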