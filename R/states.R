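#' Founder letters and diplotype states
#'
#' The eight DO founder haplotypes are labelled `A`--`H`. Founders `A`--`E`
#' are the "classical" inbred strains; `F` (CAST), `G` (PWK) and `H` (WSB)
#' are wild-derived. A diplotype is an unordered pair of founders, giving
#' 36 states: 8 homozygous plus 28 heterozygous.
#'
#' @return `do_founders()` returns the 8 founder letters; `founder_class()`
#'   returns `"classical"` or `"wild"` per founder; `diplotype_states()`
#'   returns a two-column integer matrix (36 rows, columns `f1 <= f2`) with
#'   rownames like `"AB"`; `diplotype_state_index(f1, f2)` maps a founder
#'   pair (integers 1--8, any order) to its state index.
#' @examples
#' diplotype_states()[1:5, ]
#' diplotype_state_index(2, 1)  # "AB"
#' @export
do_founders <- function() LETTERS[1:8]

#' @rdname do_founders
#' @param founder character vector of founder letters
#' @export
founder_class <- function(founder) {
  stopifnot(all(founder %in% do_founders()))
  ifelse(founder %in% LETTERS[1:5], "classical", "wild")
}

#' @rdname do_founders
#' @export
diplotype_states <- function() {
  idx <- which(upper.tri(diag(8), diag = TRUE), arr.ind = TRUE)
  st <- cbind(f1 = idx[, "row"], f2 = idx[, "col"])
  st <- st[order(st[, "f1"], st[, "f2"]), , drop = FALSE]
  rownames(st) <- paste0(LETTERS[st[, 1]], LETTERS[st[, 2]])
  st
}

#' @rdname do_founders
#' @param f1,f2 founder indices (1--8)
#' @export
diplotype_state_index <- function(f1, f2) {
  a <- pmin(f1, f2)
  b <- pmax(f1, f2)
  stopifnot(all(a >= 1), all(b <= 8))
  # states ordered (1,1),(1,2)...(1,8),(2,2),...,(8,8)
  as.integer(9L * (a - 1L) - (a - 1L) * a / 2L + (b - a) + 1L)
}

# per-state dose matrix: markers x 36 alternate-allele doses implied by the
# founder alleles at each marker
state_doses <- function(alleles) {
  st <- diplotype_states()
  alleles[, st[, 1], drop = FALSE] + alleles[, st[, 2], drop = FALSE]
}
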