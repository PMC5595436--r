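# Shannon-entropy surface-metabolite diversity statistics: per-sample entropy
# H_j, per-feature mean frequency P_i and specificity S_i, per-sample
# specialization index delta_j, and producer/non-producer comparison.
#
# Conventions: log base 2 throughout; 0 * log2(0) is taken as 0.

#' Per-sample relative peak frequencies
#'
#' P_ij = I_ij / sum_i I_ij, so each sample's row sums to 1.
#'
#' @param x `aligned_peak_matrix` or samples x features intensity matrix.
#' @param type Intensity used: `"height"` (default; entropy is computed on
#'   peak intensity) or `"area"`.
#' @return Samples x features matrix of relative frequencies.
#' @export
relative_frequencies <- function(x, type = "height") {
  m <- .intensity_matrix(x, type)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("all-zero sample(s): ",
         paste(rownames(m)[tot <= 0], collapse = ", "))
  sweep(m, 1, tot, "/")
}

#' Shannon entropy of a relative-frequency vector (bits)
#'
#' H = -sum_i P_i log2(P_i), with 0 log2 0 = 0. For a matrix, entropy is
#' computed per row (per sample).
#'
#' @param p Relative-frequency vector summing to 1, or a matrix of such rows.
#' @return Entropy in bits (scalar or per-row vector).
#' @export
shannon_entropy <- function(p) {
  ent <- function(v) {
    if (abs(sum(v) - 1) > 1e-9) stop("frequencies must sum to 1")
    v <- v[v > 0]
    -sum(v * log2(v))
  }
  if (is.matrix(p)) apply(p, 1, ent) else ent(p)
}

#' Mean frequency and specificity of each peak
#'
#' P_i = (1/t) sum_j P_ij is the average relative frequency of peak i over
#' the t samples, and its specificity is
#' S_i = (1/t) sum_j (P_ij / P_i) log2(P_ij / P_i),
#' zero for a peak with equal frequency in every sample and log2(t) for a
#' peak found in exactly one sample. Features absent everywhere (P_i = 0)
#' are excluded with a warning (S_i = NA).
#'
#' @param P Samples x features relative-frequency matrix
#'   ([relative_frequencies()]).
#' @return Named list: P_bar (per-feature mean frequency), S (per-feature
#'   specificity, bits).
#' @export
peak_specificity <- function(P) {
  t_n <- nrow(P)
  P_bar <- colMeans(P)
  absent <- P_bar == 0
  if (any(absent))
    warning(sum(absent), " feature(s) absent from every sample excluded")
  S <- rep(NA_real_, ncol(P))
  if (any(!absent)) {
    F <- sweep(P[, !absent, drop = FALSE], 2, P_bar[!absent], "/")
    term <- ifelse(F > 0, F * log2(F), 0)
    S[!absent] <- colSums(term) / t_n
  }
  names(S) <- colnames(P)
  names(P_bar) <- colnames(P)
  list(P_bar = P_bar, S = S)
}

#' Sample specialization index
#'
#' delta_j = sum_i P_ij S_i: the intensity-weighted mean specificity of the
#' sample's peaks. Zero when every peak of the sample occurs at equal
#' frequency across all samples; log2(t) when all its peaks are unique to it.
#'
#' @param P Samples x features relative-frequency matrix.
#' @param S Per-feature specificity; computed from `P` when missing. NA
#'   entries (features absent everywhere) contribute 0 — their P_ij is 0.
#' @return Per-sample specialization (bits).
#' @export
specialization_index <- function(P, S = NULL) {
  if (is.null(S)) S <- peak_specificity(P)$S
  if (length(S) != ncol(P))
    stop("S length does not match the feature dimension of P")
  S0 <- ifelse(is.na(S), 0, S)
  as.vector(P %*% S0)
}

#' Compare entropy distributions of two groups
#'
#' Two-sample, two-sided Kolmogorov-Smirnov test (asymptotic by default; the
#' exact small-sample p-value can be requested). Also reports which group's
#' distribution is higher, by median.
#'
#' @param h_a,h_b Entropy values for groups A and B (each length >= 2).
#' @param exact Passed to [stats::ks.test()] (default FALSE: asymptotic).
#' @return list(D, p_value, higher, median_a, median_b).
#' @export
compare_entropy_groups <- function(h_a, h_b, exact = FALSE) {
  if (length(h_a) < 2 || length(h_b) < 2)
    stop("each group needs at least 2 values")
  kt <- suppressWarnings(stats::ks.test(h_a, h_b, exact = exact))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       higher = if (stats::median(h_a) >= stats::median(h_b)) "A" else "B",
       median_a = stats::median(h_a), median_b = stats::median(h_b))
}

#' Full diversity suite for an aligned peak matrix
#'
#' @param x `aligned_peak_matrix` or samples x features matrix.
#' @param type Intensity used (default `"height"`).
#' @return A `diversity_result`: H (per sample, bits), P_bar and S (per
#'   feature), delta (per sample, bits), m features, t samples.
#' @export
diversity_stats <- function(x, type = "height") {
  m <- .intensity_matrix(x, type)
  P <- relative_frequencies(m)
  spec <- peak_specificity(P)
  structure(list(H = shannon_entropy(P),
                 P_bar = spec$P_bar, S = spec$S,
                 delta = specialization_index(P, spec$S),
                 m = ncol(m), t = nrow(m)),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("diversity over %d samples x %d features\n", x$t, x$m))
  cat(sprintf("  H:     %.3f .. %.3f bits\n", min(x$H), max(x$H)))
  cat(sprintf("  delta: %.3f .. %.3f bits\n", min(x$delta), max(x$delta)))
  invisible(x)
}

#' Write diversity tables
#'
#' Emits a per-sample TSV (sample, m_present, H, delta, and group when
#' metadata is supplied) and a per-feature TSV (mz, rt, P_bar, S).
#'
#' @param res `diversity_result`.
#' @param apm The `aligned_peak_matrix` the result came from.
#' @param dir Output directory.
#' @param meta Optional sample metadata with group labels.
#' @return Paths of the two files, invisibly.
#' @export
write_diversity <- function(res, apm, dir, meta = NULL) {
  m <- .intensity_matrix(apm, "height")
  per_sample <- data.frame(sample = rownames(m),
                           m_present = rowSums(m > 0),
                           H = res$H, delta = res$delta)
  if (!is.null(meta))
    per_sample$group <- meta$group[match(per_sample$sample, meta$sample_id)]
  per_feature <- data.frame(mz = apm$features$mz, rt = apm$features$rt,
                            P_bar = res$P_bar, S = res$S)
  p1 <- file.path(dir, "diversity_samples.tsv")
  p2 <- file.path(dir, "diversity_features.tsv")
  utils::write.table(per_sample, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(per_feature, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
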