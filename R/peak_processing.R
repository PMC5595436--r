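# Multi-sample peak tables: load, intensity filter, internal-standard
# normalisation, greedy centroid alignment, and the peak-sharing matrix.

#' Read a peak table CSV
#'
#' Expected header: `sample,mz,rt,height,area`. Peak invariants (positive m/z,
#' non-negative rt/height/area) are validated on load.
#'
#' @param path CSV path.
#' @param meta Optional sample metadata data.frame ([read_sample_meta()]);
#'   when given, every peak's sample must appear in it.
#' @return data.frame of peaks.
#' @export
read_peak_table <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("peak table file not found: ", path)
  peaks <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample", "mz", "rt", "height", "area")
  missing <- setdiff(required, names(peaks))
  if (length(missing))
    stop("peak table is missing column(s): ", paste(missing, collapse = ", "))
  peaks <- peaks[required]
  if (!nrow(peaks))  # header-only file: fix the column types
    for (col in c("mz", "rt", "height", "area")) peaks[[col]] <- numeric()
  for (col in c("mz", "rt", "height", "area"))
    if (!is.numeric(peaks[[col]]))
      stop("non-numeric values in column ", col)
  if (nrow(peaks)) {
    if (any(peaks$mz <= 0)) stop("m/z values must be positive")
    if (any(peaks$rt < 0) || any(peaks$height < 0) || any(peaks$area < 0))
      stop("rt, height and area must be non-negative")
  }
  if (!is.null(meta)) {
    unknown <- setdiff(unique(peaks$sample), meta$sample_id)
    if (length(unknown))
      stop("sample id(s) absent from metadata: ", paste(unknown, collapse = ", "))
  }
  peaks
}

#' Read a sample metadata CSV
#'
#' Expected columns: `sample_id,species,tissue,dry_weight_mg,istd_area,group`
#' with group in producer/nonproducer.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("sample metadata file not found: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "species", "tissue", "dry_weight_mg",
                "istd_area", "group")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("sample metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (any(meta$dry_weight_mg <= 0)) stop("dry_weight_mg must be positive")
  if (any(meta$istd_area <= 0)) stop("istd_area must be positive")
  meta
}

#' Intensity filter
#'
#' Keeps peaks with height strictly greater than the threshold; the default
#' 500 removes most background noise in the instrument's raw chromatograms.
#' Idempotent at a fixed threshold.
#'
#' @param peaks Peak data.frame.
#' @param threshold Intensity cutoff (default 500).
#' @return Filtered peak data.frame.
#' @export
filter_intensity <- function(peaks, threshold = 500) {
  if (threshold < 0) stop("threshold must be non-negative")
  peaks[peaks$height > threshold, , drop = FALSE]
}

#' Internal-standard and dry-weight normalisation
#'
#' Normalized peak area = (peak area / internal standard area) / dry weight.
#'
#' @param area Peak area(s).
#' @param istd_area Internal-standard peak area (> 0).
#' @param dry_weight_mg Tissue dry weight in mg (> 0).
#' @return Normalized area (per mg).
#' @export
normalize_area <- function(area, istd_area, dry_weight_mg) {
  if (any(istd_area <= 0)) stop("istd_area must be positive")
  if (any(dry_weight_mg <= 0)) stop("dry_weight_mg must be positive")
  (area / istd_area) / dry_weight_mg
}

#' Align peaks across samples into a feature matrix
#'
#' Greedy centroid grouping: peaks are visited in decreasing height (ties
#' broken by mz, rt, sample); each peak joins the nearest existing feature
#' lying within both the m/z and rt tolerances, otherwise founds a new
#' feature. Feature consensus m/z and rt are height-weighted means, updated
#' as members join. Deterministic and invariant to sample order.
#'
#' @param peaks Peak data.frame (columns sample, mz, rt, height, area).
#' @param mz_tol m/z tolerance in Da (default 0.02).
#' @param rt_tol Retention-time tolerance in minutes (default 0.1).
#' @return An `aligned_peak_matrix`: list(features = data.frame(mz, rt),
#'   samples, height, area) with samples x features intensity matrices.
#'   Multiple peaks of one sample joining one feature are summed.
#' @export
align_peaks <- function(peaks, mz_tol = 0.02, rt_tol = 0.1) {
  if (mz_tol <= 0 || rt_tol <= 0) stop("tolerances must be positive")
  samples <- sort(unique(peaks$sample))
  ord <- order(-peaks$height, peaks$mz, peaks$rt, peaks$sample)
  peaks <- peaks[ord, , drop = FALSE]
  n <- nrow(peaks)
  cap <- max(16L, n)
  f_mz <- numeric(cap); f_rt <- numeric(cap); f_wt <- numeric(cap)
  nf <- 0L
  assign_idx <- integer(n)
  for (i in seq_len(n)) {
    mz <- peaks$mz[i]; rt <- peaks$rt[i]; h <- peaks$height[i]
    j <- 0L
    if (nf > 0L) {
      idx <- seq_len(nf)
      dmz <- abs(f_mz[idx] - mz); drt <- abs(f_rt[idx] - rt)
      ok <- which(dmz <= mz_tol & drt <= rt_tol)
      if (length(ok)) {
        d <- (dmz[ok] / mz_tol)^2 + (drt[ok] / rt_tol)^2
        j <- ok[which.min(d)]
      }
    }
    if (j == 0L) {
      nf <- nf + 1L
      j <- nf
      f_mz[j] <- mz; f_rt[j] <- rt; f_wt[j] <- max(h, .Machine$double.eps)
    } else {
      w <- max(h, .Machine$double.eps)
      tot <- f_wt[j] + w
      f_mz[j] <- (f_mz[j] * f_wt[j] + mz * w) / tot
      f_rt[j] <- (f_rt[j] * f_wt[j] + rt * w) / tot
      f_wt[j] <- tot
    }
    assign_idx[i] <- j
  }
  feat_ord <- order(f_mz[seq_len(nf)], f_rt[seq_len(nf)])
  rank <- match(seq_len(nf), feat_ord)
  height <- matrix(0, length(samples), nf,
                   dimnames = list(samples, sprintf("F%04d", seq_len(nf))))
  area <- height
  if (n) {
    si <- match(peaks$sample, samples)
    for (i in seq_len(n)) {
      j <- rank[assign_idx[i]]
      height[si[i], j] <- height[si[i], j] + peaks$height[i]
      area[si[i], j] <- area[si[i], j] + peaks$area[i]
    }
  }
  features <- data.frame(mz = f_mz[feat_ord], rt = f_rt[feat_ord])
  structure(list(features = features, samples = samples,
                 height = height, area = area,
                 mz_tol = mz_tol, rt_tol = rt_tol),
            class = "aligned_peak_matrix")
}

#' @export
print.aligned_peak_matrix <- function(x, ...) {
  cat(sprintf("aligned peak matrix: %d samples x %d features (mz_tol %g Da, rt_tol %g min)\n",
              length(x$samples), nrow(x$features), x$mz_tol, x$rt_tol))
  invisible(x)
}

# extract the samples x features intensity matrix from either an
# aligned_peak_matrix or a plain matrix
.intensity_matrix <- function(x, type = c("height", "area")) {
  type <- match.arg(type)
  if (inherits(x, "aligned_peak_matrix")) x[[type]]
  else as.matrix(x)
}

#' Peak-sharing matrix
#'
#' Cell (r, c) is the percentage of the row sample's features (presence =
#' intensity > 0) that are also present in the column sample. Rows are
#' normalised to the row sample's own feature count, so the matrix is
#' generally asymmetric; the diagonal is 100 for any sample with at least one
#' feature. A sample with zero features gets a 0 row, with a warning.
#'
#' @param x `aligned_peak_matrix` or samples x features matrix.
#' @param type Intensity used for presence: `"height"` (default) or `"area"`.
#' @return Square percentage matrix (samples x samples).
#' @export
sharing_matrix <- function(x, type = "height") {
  m <- .intensity_matrix(x, type)
  if (!nrow(m)) stop("need at least one sample")
  pres <- m > 0
  counts <- pres %*% t(pres)                 # |r AND c|
  own <- rowSums(pres)                       # |r|
  if (any(own == 0))
    warning("sample(s) with zero features: ",
            paste(rownames(m)[own == 0], collapse = ", "))
  share <- 100 * sweep(counts, 1, pmax(own, 1), "/")
  share[own == 0, ] <- 0
  dimnames(share) <- list(rownames(m), rownames(m))
  share
}

#' Write an aligned peak matrix as wide TSV
#'
#' Features as rows: consensus mz, rt, then one intensity column per sample.
#'
#' @param apm `aligned_peak_matrix`.
#' @param path Output path.
#' @param type `"height"` or `"area"`.
#' @export
write_aligned_matrix <- function(apm, path, type = "height") {
  m <- .intensity_matrix(apm, type)
  out <- cbind(apm$features, as.data.frame(t(m)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
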