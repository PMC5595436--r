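# Mass-based acylsugar annotation: decompose pseudomolecular m/z values into
# candidate core + chain-multiset compositions and score them against CID
# fragment evidence.
#
# Key identity: for n saturated chains of total T carbons, the summed ester
# net addition is T*(12 + 2*mH) + n*(mO - 2*mH) Da, so the neutral mass
# depends only on (core, n, T). Search therefore solves for T per chain
# count and expands the bounded integer partitions of T, which keeps the
# worst case tiny (partitions of at most 72).

.acylsugar_cache <- new.env(parent = emptyenv())

# partitions of `total` into `n` parts drawn (with repetition) from the sorted
# ascending `allowed` carbon counts; parts non-decreasing
.carbon_partitions <- function(total, n, allowed) {
  if (n == 0L) return(if (total == 0L) list(integer()) else list())
  out <- list()
  for (i in seq_along(allowed)) {
    a <- allowed[i]
    rest <- total - a
    # remaining n-1 parts each >= a, so bound the recursion
    if (rest < a * (n - 1L) || rest > max(allowed) * (n - 1L)) next
    for (tail in .carbon_partitions(rest, n - 1L, allowed[i:length(allowed)]))
      out[[length(out) + 1L]] <- c(a, tail)
  }
  out
}

# branch labels in `alphabet` consistent with each carbon count
.labels_for_carbons <- function(carbons, alphabet) {
  vapply(carbons, function(c_i)
    paste(alphabet$label[alphabet$carbons == c_i], collapse = "|"),
    character(1))
}

#' Decompose an observed m/z into candidate acylsugar compositions
#'
#' Finds every composition (core + chain multiset over the given alphabet)
#' whose adduct m/z lies within `tol_ppm` of the observation. Chain multisets
#' that differ only in branch labels are mass-degenerate and are collapsed to
#' one row per carbon partition by default, with all consistent labels
#' reported.
#'
#' @param observed_mz Observed m/z (positive scalar).
#' @param add Adduct (object or label) assumed for the ion.
#' @param tol_ppm Mass tolerance in ppm (> 0).
#' @param alphabet Chain alphabet data.frame ([default_chain_alphabet()]).
#' @param cores List of `sugar_core` objects to consider.
#' @param min_chains,max_chains Bounds on the number of chains (plant
#'   acylsugars carry 2-6).
#' @param collapse_branch Collapse branch-degenerate multisets (default TRUE).
#' @return data.frame sorted by |mass_error_ppm| with columns name, core,
#'   n_chains, total_carbons, carbons (comma string), chain_labels, formula,
#'   neutral_mass, mz, mass_error_ppm.
#' @export
decompose_mass <- function(observed_mz, add = adduct(), tol_ppm = 5,
                           alphabet = default_chain_alphabet(),
                           cores = default_sugar_cores(),
                           min_chains = 2L, max_chains = 6L,
                           collapse_branch = TRUE) {
  if (is.character(add)) add <- adduct(add)
  if (!is.numeric(observed_mz) || observed_mz <= 0)
    stop("observed_mz must be positive")
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  if (!nrow(alphabet)) stop("empty chain alphabet")
  if (min_chains > max_chains) stop("min_chains > max_chains")

  mH <- .MONO_MASS[["H"]]; mO <- .MONO_MASS[["O"]]
  per_carbon <- 12 + 2 * mH
  per_chain <- mO - 2 * mH
  allowed <- sort(unique(alphabet$carbons))
  target <- observed_mz - add$mass_shift
  tol_da <- observed_mz * tol_ppm * 1e-6

  rows <- list()
  for (core in cores) {
    core_mass <- formula_mass(core$formula)
    cf <- unclass(core$formula)
    for (n in seq.int(min_chains, min(max_chains, core$free_hydroxyls))) {
      t_real <- (target - core_mass - n * per_chain) / per_carbon
      t_lo <- ceiling(t_real - tol_da / per_carbon)
      t_hi <- floor(t_real + tol_da / per_carbon)
      if (t_hi < t_lo) next
      for (total in seq.int(t_lo, t_hi)) {
        if (total < n * min(allowed) || total > n * max(allowed)) next
        mass <- core_mass + total * per_carbon + n * per_chain
        err_ppm <- (observed_mz - (mass + add$mass_shift)) / observed_mz * 1e6
        if (abs(err_ppm) > tol_ppm) next
        parts <- .carbon_partitions(total, n, allowed)
        if (!length(parts)) next
        # all partitions share (n, total), hence formula and mass
        formula_str <- sprintf("C%dH%dO%d", cf[["C"]] + total,
                               cf[["H"]] + 2L * total - 2L * n, cf[["O"]] + n)
        rows[[length(rows) + 1L]] <- data.frame(
          name = vapply(parts, function(p)
            sprintf("%s%d:%d(%s)", core$letter, n, total,
                    paste(p, collapse = ",")), character(1)),
          core = core$name,
          n_chains = n,
          total_carbons = total,
          carbons = vapply(parts, paste, character(1), collapse = ","),
          chain_labels = vapply(parts, function(p)
            paste(.labels_for_carbons(p, alphabet), collapse = ";"),
            character(1)),
          formula = formula_str,
          neutral_mass = mass,
          mz = mass + add$mass_shift,
          mass_error_ppm = err_ppm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(name = character(), core = character(),
                      n_chains = integer(), total_carbons = integer(),
                      carbons = character(), chain_labels = character(),
                      formula = character(), neutral_mass = numeric(),
                      mz = numeric(), mass_error_ppm = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  if (!collapse_branch) {
    # expand each carbon partition into every consistent label multiset
    expanded <- lapply(seq_len(nrow(out)), function(i) {
      part <- as.integer(strsplit(out$carbons[i], ",")[[1]])
      opts <- lapply(part, function(c_i) alphabet$label[alphabet$carbons == c_i])
      grid <- expand.grid(opts, stringsAsFactors = FALSE)
      # unordered multisets: keep one representative per sorted label tuple
      key <- apply(grid, 1L, function(r) paste(sort(r), collapse = ","))
      grid <- grid[!duplicated(key), , drop = FALSE]
      r <- out[rep(i, nrow(grid)), , drop = FALSE]
      r$chain_labels <- apply(grid, 1L, paste, collapse = ";")
      r
    })
    out <- do.call(rbind, expanded)
  }
  out <- out[order(abs(out$mass_error_ppm), out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict CID fragments for an acylsugar composition
#'
#' Negative mode: the `[M-H]-` ion loses each distinct chain's ester net
#' addition (ketene-equivalent loss, the default) and ultimately yields the
#' fully deacylated sugar ion. Acid-form losses (net addition + H2O) can be
#' enabled additionally. Positive mode (`[M+NH4]+`): glycosidic cleavage with
#' neutral loss of an unacylated hexose plus NH3 (197 Da nominal) leaves the
#' acylated-pyranose fragment; for each ring-split hypothesis the furanose
#' ring departs with its own chains, enlarging the loss accordingly.
#'
#' @param comp `acylsugar_composition` with at least one chain.
#' @param add Adduct; polarity decides the fragmentation model.
#' @param ring_split Optional list of integer vectors, each the carbon counts
#'   of chains assigned to the departing furanose ring (must be sub-multisets
#'   of the composition's chains). Default: all distinct sub-multisets,
#'   i.e. every "k chains on one ring" hypothesis.
#' @param losses Negative-mode loss forms: `"ketene"` (default) and/or
#'   `"acid"`.
#' @return A `fragment_prediction`: list(mode, precursor_mz, fragments)
#'   where fragments is a data.frame(mz, description).
#' @export
predict_fragments <- function(comp, add = adduct("[M-H]-"), ring_split = NULL,
                              losses = "ketene") {
  if (is.character(add)) add <- adduct(add)
  n <- nrow(comp$chains)
  if (n == 0L) stop("cannot predict fragments for a chainless composition")
  precursor <- adduct_mz(comp$neutral_mass, add)
  frags <- list()
  push <- function(mz, desc)
    frags[[length(frags) + 1L]] <<- data.frame(mz = mz, description = desc,
                                               stringsAsFactors = FALSE)
  if (add$polarity == "-") {
    losses <- match.arg(losses, c("ketene", "acid"), several.ok = TRUE)
    for (c_i in unique(comp$chains$carbons)) {
      net <- formula_mass(chain_net_addition(c_i))
      if ("ketene" %in% losses)
        push(precursor - net,
             sprintf("loss of C%d chain (ketene form, %s)", c_i,
                     format_formula(chain_net_addition(c_i))))
      if ("acid" %in% losses)
        push(precursor - net - formula_mass(parse_formula("H2O")),
             sprintf("loss of C%d chain (acid form)", c_i))
    }
    push(adduct_mz(formula_mass(comp$core$formula), add),
         sprintf("fully deacylated %s ion", comp$core$name))
  } else {
    if (add$label != "[M+NH4]+")
      stop("positive-mode fragment model is defined for [M+NH4]+")
    hexose_nh3 <- formula_mass(parse_formula("C6H12O6")) +
      formula_mass(parse_formula("NH3"))
    if (is.null(ring_split)) {
      carbons <- sort(comp$chains$carbons)
      ring_split <- list(integer())
      for (k in seq_len(n - 1L)) {
        subs <- utils::combn(carbons, k, simplify = FALSE)
        subs <- subs[!duplicated(vapply(subs, paste, character(1), collapse = ","))]
        ring_split <- c(ring_split, subs)
      }
    }
    all_c <- sort(comp$chains$carbons)
    for (fur in ring_split) {
      fur <- sort(as.integer(fur))
      leftover <- all_c
      for (c_i in fur) {
        hit <- match(c_i, leftover)
        if (is.na(hit)) stop("ring_split is not a sub-multiset of the chains")
        leftover <- leftover[-hit]
      }
      loss <- hexose_nh3 + sum(vapply(fur, function(c_i)
        formula_mass(chain_net_addition(c_i)), numeric(1)))
      desc <- if (length(fur))
        sprintf("loss of hexose + NH3 + furanose chains (%s); %d chains on pyranose",
                paste0("C", fur, collapse = ","), length(leftover))
      else
        sprintf("neutral loss of hexose + NH3 (197 Da); all %d chains on one ring", n)
      push(precursor - loss, desc)
    }
  }
  fragments <- do.call(rbind, frags)
  fragments <- fragments[fragments$mz > 0, , drop = FALSE]
  rownames(fragments) <- NULL
  structure(list(mode = add$polarity, precursor_mz = precursor,
                 fragments = fragments),
            class = "fragment_prediction")
}

#' Score an annotation against observed fragments
#'
#' Fraction of predicted fragment m/z values matched by at least one observed
#' fragment within the ppm tolerance. An empty prediction scores 0.
#'
#' @param observed_fragments Numeric vector of observed fragment m/z.
#' @param prediction A `fragment_prediction`.
#' @param tol_ppm Tolerance in ppm (> 0).
#' @return Fraction in \[0, 1\].
#' @export
score_annotation <- function(observed_fragments, prediction, tol_ppm = 10) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  pred <- prediction$fragments$mz
  if (!length(pred)) return(0)
  if (!length(observed_fragments)) return(0)
  matched <- vapply(pred, function(p)
    any(abs(observed_fragments - p) / p * 1e6 <= tol_ppm), logical(1))
  mean(matched)
}

#' m/z and mass-defect envelope of theoretical acylsucroses
#'
#' Enumerates all 2-6-chain acylsucrose masses under the alphabet and returns
#' the sorted theoretical m/z values and overall m/z range under the adduct.
#' Because the mass defect of acylsugars grows with mass (CH2-rich additions
#' contribute ~+0.0157 Da each) a single global fractional-mass window is
#' vacuous over a wide m/z range; the screen in [acylsugar_like()] therefore
#' uses the local envelope of theoretical neighbours.
#'
#' @param alphabet Chain alphabet.
#' @param add Adduct.
#' @param min_chains,max_chains Chain-count bounds.
#' @return list(mz_range, mz): range and sorted vector of theoretical m/z.
#' @export
acylsugar_envelope <- function(alphabet = default_chain_alphabet(),
                               add = adduct(), min_chains = 2L,
                               max_chains = 6L) {
  if (is.character(add)) add <- adduct(add)
  key <- paste(add$label, min_chains, max_chains,
               paste(sort(unique(alphabet$carbons)), collapse = "."), sep = "|")
  if (!is.null(.acylsugar_cache[[key]])) return(.acylsugar_cache[[key]])
  core_mass <- formula_mass(sugar_core("sucrose")$formula)
  mH <- .MONO_MASS[["H"]]; mO <- .MONO_MASS[["O"]]
  allowed <- sort(unique(alphabet$carbons))
  mzs <- c()
  for (n in seq.int(min_chains, max_chains)) {
    totals <- .reachable_totals(n, allowed)
    mzs <- c(mzs, core_mass + totals * (12 + 2 * mH) + n * (mO - 2 * mH) +
               add$mass_shift)
  }
  env <- list(mz_range = range(mzs), mz = sort(mzs))
  .acylsugar_cache[[key]] <- env
  env
}

# achievable total carbon counts for n chains over `allowed`
.reachable_totals <- function(n, allowed) {
  sums <- 0L
  for (i in seq_len(n)) sums <- unique(as.vector(outer(sums, allowed, `+`)))
  sort(sums)
}

#' Screen an m/z for acylsugar-like mass and mass defect
#'
#' An m/z passes when it lies inside the theoretical acylsucrose m/z range
#' and its fractional mass falls inside the mass-local defect window: the
#' \[min, max\] envelope of the fractional masses of theoretical
#' acylsucroses within `neighborhood_da` of the observation, padded by
#' `pad`. Both the range and the window can be overridden explicitly (an
#' explicit `defect_window` is applied globally).
#'
#' @param observed_mz m/z value(s).
#' @param mz_range,defect_window Optional explicit overrides.
#' @param add Adduct used when deriving the default envelope.
#' @param neighborhood_da Half-width of the theoretical neighbourhood
#'   defining the local window (default 25 Da).
#' @param pad Padding of the defect window (default 0.01 Da).
#' @return Logical vector.
#' @export
acylsugar_like <- function(observed_mz, mz_range = NULL, defect_window = NULL,
                           add = adduct(), neighborhood_da = 25, pad = 0.01) {
  env <- acylsugar_envelope(add = add)
  if (is.null(mz_range)) mz_range <- env$mz_range
  frac <- observed_mz - floor(observed_mz)
  in_range <- observed_mz >= mz_range[1] & observed_mz <= mz_range[2]
  if (!is.null(defect_window))
    return(in_range & frac >= defect_window[1] & frac <= defect_window[2])
  theo_frac <- env$mz - floor(env$mz)
  vapply(seq_along(observed_mz), function(i) {
    if (!in_range[i]) return(FALSE)
    near <- abs(env$mz - observed_mz[i]) <= neighborhood_da
    if (!any(near)) return(FALSE)
    w <- range(theo_frac[near]) + c(-pad, pad)
    frac[i] >= w[1] && frac[i] <= w[2]
  }, logical(1))
}

#' Write annotations to TSV
#' @param annotations data.frame from [decompose_mass()] (possibly with extra
#'   columns such as observed_mz or fragment_score).
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
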