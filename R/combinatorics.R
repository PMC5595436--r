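# Enumeration of the theoretical acylsugar space.
#
# Two counting semantics are exposed. Positional mode treats the acylation
# positions on the sugar core as distinguishable and counts ordered
# assignments (the arithmetic behind the 8*8*8*12 = 6144 tetra-acylsucrose
# estimate: eight short chains at three positions, twelve chains at the
# fourth). Multiset mode counts unordered chain combinations, which is the
# resolution of mass-based Sn:m(...) compositions.

#' Named chain subsets of the default alphabet
#'
#' `short` = C2, C3, C4, iC5, aiC5, iC6, aiC6, C8; `long` = nC10, iC10,
#' nC11, nC12; `full` = both.
#'
#' @return Named list of character vectors of chain labels.
#' @export
chain_sets <- function() {
  ab <- default_chain_alphabet()
  list(short = ab$label[ab$set == "short"],
       long = ab$label[ab$set == "long"],
       full = ab$label)
}

#' Count (and optionally list) the theoretical acylsugar space
#'
#' @param positions Positional mode: list of chain-label vectors, one allowed
#'   alphabet per acylation position; the count is the product of their
#'   sizes. Mutually exclusive with `alphabet`/`n_chains`.
#' @param alphabet,n_chains Multiset mode: one chain-label vector and a
#'   number of chains; the count is the number of size-`n_chains` multisets,
#'   choose(a + n - 1, n).
#' @param core Sugar core bounding the number of positions (default sucrose,
#'   8 free hydroxyls).
#' @param enumerate Also return the explicit enumeration (data.frame with one
#'   chain column per position/slot). Only for desk-scale spaces.
#' @return list(count, mode, enumeration?) with `count` an exact integer-valued
#'   numeric.
#' @examples
#' cs <- chain_sets()
#' count_theoretical(positions = list(cs$short, cs$short, cs$short, cs$full))$count
#' @export
count_theoretical <- function(positions = NULL, alphabet = NULL,
                              n_chains = NULL, core = sugar_core("sucrose"),
                              enumerate = FALSE) {
  if (!is.null(positions) == !is.null(alphabet))
    stop("supply exactly one of `positions` (positional mode) or ",
         "`alphabet` + `n_chains` (multiset mode)")
  if (!is.null(positions)) {
    if (length(positions) > core$free_hydroxyls)
      stop("more positions than free hydroxyls on ", core$name)
    sizes <- lengths(positions)
    if (any(sizes == 0)) stop("empty position alphabet")
    out <- list(count = prod(sizes), mode = "positional")
    if (enumerate) {
      grid <- expand.grid(positions, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      names(grid) <- sprintf("position_%d", seq_along(positions))
      out$enumeration <- grid
    }
  } else {
    if (is.null(n_chains)) stop("multiset mode needs `n_chains`")
    if (!length(alphabet)) stop("empty chain alphabet")
    if (n_chains > core$free_hydroxyls)
      stop("more chains than free hydroxyls on ", core$name)
    a <- length(alphabet)
    out <- list(count = choose(a + n_chains - 1, n_chains), mode = "multiset")
    if (enumerate) {
      combos <- .multisets(alphabet, n_chains)
      grid <- as.data.frame(do.call(rbind, combos), stringsAsFactors = FALSE)
      names(grid) <- sprintf("chain_%d", seq_len(n_chains))
      out$enumeration <- grid
    }
  }
  out
}

# all multisets of size n over `items` (each multiset sorted by item order)
.multisets <- function(items, n) {
  if (n == 0L) return(list(character()))
  out <- list()
  for (i in seq_along(items))
    for (tail in .multisets(items[i:length(items)], n - 1L))
      out[[length(out) + 1L]] <- c(items[i], tail)
  out
}
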