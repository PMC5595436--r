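# Independent oracles used across the suite. These deliberately avoid the
# package's search/closed-form code paths: enumeration is exhaustive and the
# diversity formulas are re-evaluated with explicit loops.

# all unordered multisets of size n over `items`
multisets_of <- function(items, n) {
  if (n == 0L) return(list(character()))
  out <- list()
  for (i in seq_along(items))
    for (tail in multisets_of(items[i:length(items)], n - 1L))
      out[[length(out) + 1L]] <- c(items[i], tail)
  out
}

# brute-force mass decomposition oracle: exhaustively enumerate every
# 2-6-chain carbon multiset over the alphabet (branch isomers are
# mass-degenerate, so label multisets collapse to carbon multisets), push
# each through the composition layer once, and filter by ppm. The table is
# cached per (alphabet, adduct) because it is expensive to build.
.oracle_env <- new.env()
oracle_mass_table <- function(add, alphabet = default_chain_alphabet(),
                              min_chains = 2L, max_chains = 6L) {
  key <- paste(add$label, min_chains, max_chains,
               paste(sort(unique(alphabet$carbons)), collapse = "."))
  if (!is.null(.oracle_env[[key]])) return(.oracle_env[[key]])
  carbons <- as.character(sort(unique(alphabet$carbons)))
  rows <- list()
  for (n in min_chains:max_chains) {
    for (ms in multisets_of(carbons, n)) {
      comp <- compose_acylsugar("sucrose", paste0("C", ms))
      rows[[length(rows) + 1L]] <- data.frame(
        name = acylsugar_name(comp), mz = adduct_mz(comp, add),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  .oracle_env[[key]] <- tab
  tab
}

oracle_decompose <- function(observed_mz, add, tol_ppm,
                             alphabet = default_chain_alphabet(),
                             min_chains = 2L, max_chains = 6L) {
  tab <- oracle_mass_table(add, alphabet, min_chains, max_chains)
  hit <- abs(observed_mz - tab$mz) / observed_mz * 1e6 <= tol_ppm
  sort(unique(tab$name[hit]))
}

# direct loop re-evaluation of the diversity formulas
oracle_diversity <- function(I) {
  t_n <- nrow(I); m <- ncol(I)
  P <- matrix(0, t_n, m)
  for (j in 1:t_n) P[j, ] <- I[j, ] / sum(I[j, ])
  H <- numeric(t_n)
  for (j in 1:t_n)
    for (i in 1:m)
      if (P[j, i] > 0) H[j] <- H[j] - P[j, i] * log2(P[j, i])
  P_bar <- numeric(m); S <- numeric(m)
  for (i in 1:m) P_bar[i] <- sum(P[, i]) / t_n
  for (i in 1:m) {
    acc <- 0
    for (j in 1:t_n) {
      f <- P[j, i] / P_bar[i]
      if (f > 0) acc <- acc + f * log2(f)
    }
    S[i] <- acc / t_n
  }
  delta <- numeric(t_n)
  for (j in 1:t_n)
    for (i in 1:m) delta[j] <- delta[j] + P[j, i] * S[i]
  list(P = P, H = H, P_bar = P_bar, S = S, delta = delta)
}

# random intensity matrix with no all-zero sample and no all-zero feature
random_intensity_matrix <- function(t_n, m) {
  I <- matrix(stats::rexp(t_n * m), t_n, m)
  I[stats::runif(t_n * m) < 0.4] <- 0
  for (j in seq_len(t_n)) if (all(I[j, ] == 0)) I[j, sample.int(m, 1)] <- 1
  for (i in seq_len(m)) if (all(I[, i] == 0)) I[sample.int(t_n, 1), i] <- 1
  dimnames(I) <- list(sprintf("s%02d", seq_len(t_n)),
                      sprintf("f%03d", seq_len(m)))
  I
}

# write a peak data.frame to a temp CSV
write_temp_peaks <- function(peaks) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(peaks, path, row.names = FALSE)
  path
}
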