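# Elemental mass table and acylsugar composition arithmetic.
#
# Monoisotopic masses: IUPAC/AME2020 atomic mass evaluation (Da).
# Nominal masses are the mass numbers of the most abundant isotope, not
# rounded monoisotopic masses (the two agree for CHNO formulas below ~1200 Da,
# asserted in the test suite).
.MONO_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)
.NOMINAL_MASS <- c(C = 12, H = 1, N = 14, O = 16)
.ELECTRON_MASS <- 0.000548579909
.PROTON_MASS <- 1.00727646688

#' Parse a molecular formula string
#'
#' Parses a concatenation of element symbols with optional positive integer
#' counts (e.g. `"C12H22O11"`, `"NH3"`) into a named count vector. Only the
#' elements C, H, N and O are recognised: acylsugars and their adducts are
#' CHNO-only species.
#'
#' @param text Formula string.
#' @return A `chem_formula`: named integer vector with entries C, H, N, O.
#' @examples
#' parse_formula("C12H22O11")
#' parse_formula("NH3")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (paste(tokens, collapse = "") != text)
    stop("malformed formula: ", text)
  counts <- stats::setNames(integer(length(.MONO_MASS)), names(.MONO_MASS))
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% names(counts))
      stop("unknown element symbol: ", sym)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (is.na(n) || n <= 0L)
      stop("zero or negative element count in formula: ", tok)
    counts[sym] <- counts[sym] + n
  }
  chem_formula(counts)
}

#' Construct a chemical formula from element counts
#'
#' @param counts Named numeric vector over C, H, N, O; unlisted elements are 0.
#' @return A `chem_formula` object.
#' @export
chem_formula <- function(counts = integer()) {
  out <- stats::setNames(integer(length(.MONO_MASS)), names(.MONO_MASS))
  if (length(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% names(out)))
      stop("unknown element symbol in counts")
    if (any(counts < 0)) stop("element counts must be non-negative")
    out[names(counts)] <- out[names(counts)] + as.integer(counts)
  }
  structure(out, class = "chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' Render a formula as a Hill-ish string (C, H, then N, O)
#' @param f A `chem_formula`.
#' @return Character scalar, e.g. `"C12H22O11"`.
#' @export
format_formula <- function(f) {
  nz <- f[f > 0]
  if (!length(nz)) return("")
  paste0(names(nz), ifelse(nz == 1, "", nz), collapse = "")
}

#' Add or subtract chemical formulas element-wise
#'
#' Subtraction errors if any element count would go negative.
#'
#' @param a,b `chem_formula` objects.
#' @return A `chem_formula`.
#' @export
formula_add <- function(a, b) chem_formula(unclass(a) + unclass(b))

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  d <- unclass(a) - unclass(b)
  if (any(d < 0)) stop("formula subtraction yields negative element count")
  chem_formula(d)
}

#' Monoisotopic or nominal mass of a formula
#'
#' @param f A `chem_formula` (or named count vector).
#' @param kind `"monoisotopic"` (default) or `"nominal"`. Nominal sums mass
#'   numbers of the most abundant isotope and is always an integer.
#' @return Mass in Da.
#' @examples
#' formula_mass(parse_formula("C6H12O6"), "nominal") # 180
#' @export
formula_mass <- function(f, kind = c("monoisotopic", "nominal")) {
  kind <- match.arg(kind)
  f <- chem_formula(f[f != 0])
  tab <- if (kind == "monoisotopic") .MONO_MASS else .NOMINAL_MASS
  sum(unclass(f) * tab[names(f)])
}

# ---- acyl chains and sugar cores ----------------------------------------

#' Net formula gain of esterifying one saturated acyl chain
#'
#' An n-carbon saturated acyl chain adds CnH(2n-2)O to the sugar upon ester
#' formation (the acid, minus the water of condensation).
#'
#' @param carbons Chain length in carbons (2-12).
#' @return A `chem_formula`.
#' @export
chain_net_addition <- function(carbons) {
  carbons <- as.integer(carbons)
  if (is.na(carbons) || carbons < 2L || carbons > 12L)
    stop("chain length must be 2-12 carbons")
  chem_formula(c(C = carbons, H = 2L * carbons - 2L, O = 1L))
}

#' Construct an acyl chain
#'
#' @param label Chain label, e.g. `"aiC5"`, `"C2"`, `"nC12"`.
#' @param carbons Carbon count (2-12); inferred from the label if missing.
#' @param branch One of `"n"` (straight), `"i"` (iso), `"ai"` (anteiso);
#'   inferred from the label if missing. Branch isomers of equal carbon
#'   number are mass-degenerate.
#' @return One-row data.frame with columns label, carbons, branch.
#' @export
acyl_chain <- function(label, carbons = NULL, branch = NULL) {
  if (is.null(carbons)) {
    carbons <- as.integer(sub("^(ai|i|n)?C", "", label))
    if (is.na(carbons)) stop("cannot infer carbon count from label: ", label)
  }
  if (is.null(branch)) {
    branch <- sub("C[0-9]+$", "", label)
    if (!nzchar(branch)) branch <- "n"
  }
  if (!branch %in% c("n", "i", "ai")) stop("branch must be n, i or ai")
  carbons <- as.integer(carbons)
  if (carbons < 2L || carbons > 12L) stop("chain length must be 2-12 carbons")
  data.frame(label = label, carbons = carbons, branch = branch,
             stringsAsFactors = FALSE)
}

#' Default acyl-chain alphabet
#'
#' The twelve aliphatic chains observed across Solanaceae acylsugars:
#' a short set (C2, C3, C4, iC5, aiC5, iC6, aiC6, C8) and a long set
#' (nC10, iC10, nC11, nC12).
#'
#' @return data.frame with columns label, carbons, branch, set.
#' @export
default_chain_alphabet <- function() {
  short <- c("C2", "C3", "C4", "iC5", "aiC5", "iC6", "aiC6", "C8")
  long <- c("nC10", "iC10", "nC11", "nC12")
  ab <- do.call(rbind, lapply(c(short, long), acyl_chain))
  ab$set <- rep(c("short", "long"), c(length(short), length(long)))
  ab
}

#' Load a chain alphabet from a JSON config
#'
#' Expected shape: a JSON array of objects with fields `label`, and optionally
#' `carbons` and `branch` (inferred from the label when absent).
#'
#' @param path Path to a JSON file.
#' @return data.frame as [default_chain_alphabet()].
#' @export
load_chain_alphabet <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.data.frame(cfg)) {
    rows <- lapply(seq_len(nrow(cfg)), function(i)
      acyl_chain(cfg$label[i],
                 if ("carbons" %in% names(cfg)) cfg$carbons[i] else NULL,
                 if ("branch" %in% names(cfg)) cfg$branch[i] else NULL))
  } else {
    rows <- lapply(cfg, function(x)
      acyl_chain(x$label, x$carbons, x$branch))
  }
  do.call(rbind, rows)
}

#' Sugar cores
#'
#' Sucrose carries eight free hydroxyls available for acylation; a hexose
#' (glucose/fructose) core carries five.
#'
#' @param name `"sucrose"` or `"hexose"`.
#' @return A `sugar_core` list: name, letter, formula, free_hydroxyls.
#' @export
sugar_core <- function(name = c("sucrose", "hexose")) {
  name <- match.arg(name)
  core <- switch(name,
    sucrose = list(name = "sucrose", letter = "S",
                   formula = parse_formula("C12H22O11"), free_hydroxyls = 8L),
    hexose = list(name = "hexose", letter = "H",
                  formula = parse_formula("C6H12O6"), free_hydroxyls = 5L))
  structure(core, class = "sugar_core")
}

#' @rdname sugar_core
#' @export
default_sugar_cores <- function() list(sugar_core("sucrose"), sugar_core("hexose"))

# ---- composition ---------------------------------------------------------

#' Assemble an acylsugar composition
#'
#' Combines a sugar core with a multiset of acyl chains; the derived formula
#' is core + sum of chain net additions, and chains are stored sorted by
#' (carbons, branch) so equal multisets compare identical.
#'
#' @param core A `sugar_core` or core name.
#' @param chains Chain labels (character) or a chain data.frame as returned
#'   by [acyl_chain()] / [default_chain_alphabet()]. May be empty.
#' @return An `acylsugar_composition`: core, chains, formula, neutral_mass.
#' @examples
#' compose_acylsugar("sucrose", c("aiC5", "aiC5", "aiC5"))
#' @export
compose_acylsugar <- function(core, chains = character()) {
  if (is.character(core)) core <- sugar_core(core)
  if (is.character(chains)) {
    chains <- if (length(chains)) do.call(rbind, lapply(chains, acyl_chain))
              else acyl_chain("C2")[0, ]
  }
  if (nrow(chains) > core$free_hydroxyls)
    stop("too many chains: ", nrow(chains), " > ", core$free_hydroxyls,
         " free hydroxyls on ", core$name)
  chains <- chains[order(chains$carbons, chains$branch, chains$label), ,
                   drop = FALSE]
  rownames(chains) <- NULL
  f <- core$formula
  for (c_i in chains$carbons) f <- formula_add(f, chain_net_addition(c_i))
  structure(list(core = core, chains = chains, formula = f,
                 neutral_mass = formula_mass(f)),
            class = "acylsugar_composition")
}

#' @export
print.acylsugar_composition <- function(x, ...) {
  cat(sprintf("%s  %s  M = %.4f Da\n", acylsugar_name(x),
              format_formula(x$formula), x$neutral_mass))
  invisible(x)
}

#' Sn:m(c1,...,cn) acylsugar name
#'
#' Core letter (S = sucrose, H = hexose), number of chains, total acyl
#' carbons, and the per-chain carbon counts in ascending order; branch
#' information is not carried (branch isomers are mass-degenerate and share
#' a name).
#'
#' @param comp An `acylsugar_composition`.
#' @return Name string such as `"S3:15(5,5,5)"`.
#' @export
acylsugar_name <- function(comp) {
  cc <- sort(comp$chains$carbons)
  sprintf("%s%d:%d(%s)", comp$core$letter, length(cc), sum(cc),
          paste(cc, collapse = ","))
}

#' Parse an Sn:m(...) acylsugar name
#'
#' @param name Name string like `"S4:17(2,5,5,5)"`.
#' @return List with core_letter, n_chains, total_carbons, carbons (sorted).
#' @export
parse_acylsugar_name <- function(name) {
  m <- regmatches(name, regexec("^([SH])([0-9]+):([0-9]+)\\(([0-9,]*)\\)$", name))[[1]]
  if (!length(m)) stop("malformed acylsugar name: ", name)
  carbons <- if (nzchar(m[5])) as.integer(strsplit(m[5], ",")[[1]]) else integer()
  n <- as.integer(m[3]); total <- as.integer(m[4])
  if (length(carbons) != n)
    stop("chain count ", n, " does not match listed chains in ", name)
  if (sum(carbons) != total)
    stop("total carbons ", total, " does not match sum of chains in ", name)
  list(core_letter = m[2], n_chains = n, total_carbons = total,
       carbons = sort(carbons))
}

#' Build a composition from its name
#'
#' Chains are instantiated as straight-chain (`n`) isomers; branch identity is
#' not encoded in names.
#'
#' @param name Acylsugar name string.
#' @return An `acylsugar_composition`.
#' @export
composition_from_name <- function(name) {
  p <- parse_acylsugar_name(name)
  core <- sugar_core(if (p$core_letter == "S") "sucrose" else "hexose")
  chains <- if (p$n_chains)
    do.call(rbind, lapply(p$carbons, function(c_i)
      acyl_chain(paste0("C", c_i), c_i, "n")))
  else acyl_chain("C2")[0, ]
  compose_acylsugar(core, chains)
}

# ---- adducts -------------------------------------------------------------

#' Ionisation adducts
#'
#' Singly charged adducts with proton/electron-correct m/z shifts.
#' `[M+NH4]+` is the positive-mode pseudomolecular ion; in negative mode the
#' formate adduct `[M+HCOO]-` is the default with `[M-H]-` also available.
#'
#' @param label One of `"[M+NH4]+"`, `"[M-H]-"`, `"[M+HCOO]-"`.
#' @return An `adduct` list: label, mass_shift, polarity.
#' @export
adduct <- function(label = c("[M+HCOO]-", "[M+NH4]+", "[M-H]-")) {
  label <- match.arg(label)
  mH <- .MONO_MASS[["H"]]; mN <- .MONO_MASS[["N"]]
  mC <- .MONO_MASS[["C"]]; mO <- .MONO_MASS[["O"]]
  shift <- switch(label,
    "[M+NH4]+" = mN + 4 * mH - .ELECTRON_MASS,
    "[M-H]-" = -.PROTON_MASS,
    "[M+HCOO]-" = mC + mH + 2 * mO + .ELECTRON_MASS)
  structure(list(label = label, mass_shift = shift,
                 polarity = if (grepl("\\+$", label)) "+" else "-"),
            class = "adduct")
}

#' m/z of a neutral mass under an adduct
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), or an
#'   `acylsugar_composition`.
#' @param add An `adduct` or adduct label.
#' @param polarity Optional required polarity (`"+"` or `"-"`); errors on
#'   mismatch.
#' @return m/z (singly charged).
#' @export
adduct_mz <- function(neutral_mass, add = adduct(), polarity = NULL) {
  if (is.character(add)) add <- adduct(add)
  if (inherits(neutral_mass, "acylsugar_composition"))
    neutral_mass <- neutral_mass$neutral_mass
  if (!is.null(polarity) && add$polarity != polarity)
    stop("adduct ", add$label, " does not match required polarity ", polarity)
  neutral_mass + add$mass_shift
}
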