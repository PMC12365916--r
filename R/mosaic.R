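#' Expected observed crossovers under the linear accumulation model
#'
#' DO mice accumulate recombination with each outbreeding generation; the
#' number of observed crossovers per mouse grows approximately linearly.
#' Anchored at a reference generation with a known count, the expectation at
#' a later generation is `count_anchor + rate_per_gen * (gen_target -
#' gen_anchor)`.
#'
#' @param gen_target target outbreeding generation (>= `gen_anchor`)
#' @param gen_anchor anchor generation with a measured count
#' @param count_anchor observed crossovers per mouse at the anchor
#' @param rate_per_gen new observed crossovers added per generation
#' @return expected observed crossover count (numeric)
#' @examples
#' expected_crossovers(41, 11, 400, 23.9)  # ~1117
#' @export
expected_crossovers <- function(gen_target, gen_anchor = 11,
                                count_anchor = 400, rate_per_gen = 23.9) {
  if (rate_per_gen < 0) stop("`rate_per_gen` must be non-negative")
  if (any(gen_target < gen_anchor)) stop("`gen_target` must be >= `gen_anchor`")
  count_anchor + rate_per_gen * (gen_target - gen_anchor)
}

# default breakpoint intensity scale: calibrated so a 1400-cM genome at
# generation 41 carries the expected ~1117 observed crossovers
# (2 homologs x scale x n_gen x total_Morgans)
default_xo_rate_scale <- function() {
  expected_crossovers(41, 11, 400, 23.9) / (2 * 41 * 1400 / 100)
}

#' Simulate DO founder diplotype mosaics
#'
#' Each sample carries two homologous chromosomes, each a mosaic of founder
#' haplotype segments. Per homolog, breakpoints form a Poisson process on
#' the genetic map with intensity `xo_rate_scale * n_gen` per Morgan;
#' founder identities are uniform over the 8 founders with no
#' self-transitions. Junctions where the founder changes on at least one
#' homolog are "observable"; a change on both homologs at once is two
#' crossovers.
#'
#' @param panel a `founder_panel` supplying the chromosome span and map
#' @param n_gen outbreeding generation (>= 1)
#' @param n_samples number of mice
#' @param xo_rate_scale breakpoint intensity per Morgan per generation per
#'   homolog; the default is calibrated so a 1400-cM genome at generation 41
#'   accumulates ~1117 observed crossovers
#' @param seed optional integer seed
#' @return a list (class `do_cohort`) of `do_mosaic` objects; each is a list
#'   of two homolog tibbles (`start_bp`, `end_bp`, `founder`) with
#'   attributes `n_gen` and junction counts
#' @export
simulate_do_diplotypes <- function(panel, n_gen, n_samples,
                                   xo_rate_scale = default_xo_rate_scale(),
                                   seed = NULL) {
  validate_panel(panel)
  if (n_gen < 1) stop("`n_gen` must be >= 1")
  stopifnot(n_samples >= 1, xo_rate_scale > 0)
  if (!is.null(seed)) set.seed(seed)

  span_bp <- c(1, panel$chrom_length_bp)
  len_morgan <- (max(panel$map$cM) - min(panel$map$cM) +
                   (panel$chrom_length_bp - diff(range(panel$map$pos_bp))) *
                   map_density_cM_per_bp(panel)) / 100
  rate <- xo_rate_scale * n_gen * len_morgan

  cohort <- lapply(seq_len(n_samples), function(i) {
    homologs <- lapply(1:2, function(h) sim_homolog(span_bp, rate))
    m <- structure(homologs, class = "do_mosaic", n_gen = n_gen)
    attr(m, "n_junctions_true") <- sum(vapply(homologs, nrow, integer(1)) - 1L)
    attr(m, "n_junctions_observable") <- count_observable_junctions(m)
    m
  })
  structure(cohort, class = "do_cohort", n_gen = n_gen,
            chrom = panel$chrom, chrom_length_bp = panel$chrom_length_bp)
}

map_density_cM_per_bp <- function(panel) {
  diff(range(panel$map$cM)) / diff(range(panel$map$pos_bp))
}

sim_homolog <- function(span_bp, rate) {
  n_bk <- rpois(1, rate)
  bk <- sort(runif(n_bk, span_bp[1], span_bp[2]))
  starts <- c(span_bp[1], bk)
  ends <- c(bk, span_bp[2])
  founders <- integer(n_bk + 1)
  founders[1] <- sample.int(8, 1)
  if (n_bk > 0) {
    for (k in 2:(n_bk + 1)) {
      founders[k] <- sample(setdiff(1:8, founders[k - 1]), 1)
    }
  }
  tibble::tibble(start_bp = starts, end_bp = ends,
                 founder = do_founders()[founders])
}

# junctions where the unordered founder pair changes across the breakpoint:
# for each homolog's junctions, the diplotype before is {prev founder, other
# homolog's founder} and after is {next founder, other homolog's founder}
count_observable_junctions <- function(mosaic) {
  total <- 0L
  for (h in 1:2) {
    hom <- mosaic[[h]]
    other <- mosaic[[3 - h]]
    n_seg <- nrow(hom)
    if (n_seg < 2) next
    bks <- hom$end_bp[-n_seg]
    oth <- founder_at(other, bks)
    before <- hom$founder[-n_seg]
    after <- hom$founder[-1]
    obs <- mapply(function(b, a, o) !identical(sort(c(b, o)), sort(c(a, o))),
                  before, after, oth)
    total <- total + sum(obs)
  }
  total
}

founder_at <- function(homolog, pos) {
  homolog$founder[findInterval(pos, homolog$start_bp)]
}

#' True founder doses and allele probabilities of a mosaic
#'
#' `mosaic_doses()` returns the true alternate-allele dose (0/1/2) at each
#' panel marker; `mosaic_alleleprobs()` returns the true 8-founder allele
#' probability matrix (rows sum to 1; a heterozygous diplotype contributes
#' 1/2 to each carried founder).
#'
#' @param mosaic a `do_mosaic`
#' @param panel the `founder_panel` the mosaic was simulated on
#' @return integer vector of doses, or a markers x 8 probability matrix
#' @export
mosaic_doses <- function(mosaic, panel) {
  f <- mosaic_founders(mosaic, panel)
  a1 <- panel$alleles[cbind(seq_len(nrow(panel$map)), f[, 1])]
  a2 <- panel$alleles[cbind(seq_len(nrow(panel$map)), f[, 2])]
  as.integer(a1 + a2)
}

#' @rdname mosaic_doses
#' @export
mosaic_alleleprobs <- function(mosaic, panel) {
  f <- mosaic_founders(mosaic, panel)
  p <- matrix(0, nrow(panel$map), 8, dimnames = list(panel$map$marker, do_founders()))
  p[cbind(seq_len(nrow(p)), f[, 1])] <- p[cbind(seq_len(nrow(p)), f[, 1])] + 0.5
  p[cbind(seq_len(nrow(p)), f[, 2])] <- p[cbind(seq_len(nrow(p)), f[, 2])] + 0.5
  p
}

# markers x 2 matrix of founder indices carried at each panel marker
mosaic_founders <- function(mosaic, panel) {
  stopifnot(inherits(mosaic, "do_mosaic"))
  pos <- panel$map$pos_bp
  f1 <- match(founder_at(mosaic[[1]], pos), do_founders())
  f2 <- match(founder_at(mosaic[[2]], pos), do_founders())
  cbind(f1, f2)
}

# true diplotype state index per marker
mosaic_states <- function(mosaic, panel) {
  f <- mosaic_founders(mosaic, panel)
  diplotype_state_index(f[, 1], f[, 2])
}

#' Swap founder labels inside engineered IBD blocks
#'
#' Creates the "alternative reconstruction" truth: wherever a homolog
#' carries one member of an IBD founder pair inside the pair's engineered
#' block, the label is switched to the other member. The sequence content is
#' unchanged (the pair is identical over the block), so this emulates the
#' label ambiguity a reconstruction method faces in founder IBD regions.
#'
#' @param mosaic a `do_mosaic`
#' @param ibd_truth tibble of engineered blocks (`founder1`, `founder2`,
#'   `start_bp`, `end_bp`)
#' @return a `do_mosaic` with swapped labels
#' @export
swap_ibd_founders <- function(mosaic, ibd_truth) {
  stopifnot(inherits(mosaic, "do_mosaic"))
  out <- lapply(mosaic, function(hom) {
    for (k in seq_len(nrow(ibd_truth))) {
      blk <- ibd_truth[k, ]
      hom <- split_homolog_at(hom, c(blk$start_bp, blk$end_bp))
      inside <- hom$start_bp >= blk$start_bp & hom$end_bp <= blk$end_bp
      swap <- inside & hom$founder %in% c(blk$founder1, blk$founder2)
      hom$founder[swap] <- ifelse(hom$founder[swap] == blk$founder1,
                                  blk$founder2, blk$founder1)
    }
    merge_adjacent_segments(hom)
  })
  structure(out, class = "do_mosaic", n_gen = attr(mosaic, "n_gen"))
}

split_homolog_at <- function(hom, cuts) {
  for (cut in cuts) {
    hit <- which(hom$start_bp < cut & hom$end_bp > cut)
    if (length(hit)) {
      seg <- hom[hit, ]
      hom <- dplyr::bind_rows(
        hom[seq_len(hit - 1), ],
        tibble::tibble(start_bp = seg$start_bp, end_bp = cut, founder = seg$founder),
        tibble::tibble(start_bp = cut, end_bp = seg$end_bp, founder = seg$founder),
        hom[-seq_len(hit), ]
      )
    }
  }
  hom
}

merge_adjacent_segments <- function(hom) {
  keep <- c(TRUE, hom$founder[-1] != hom$founder[-nrow(hom)])
  hom$.grp <- cumsum(keep)
  hom |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(start_bp = min(start_bp), end_bp = max(end_bp),
                     founder = founder[1], .groups = "drop") |>
    dplyr::select(start_bp, end_bp, founder)
}

#' @export
print.do_mosaic <- function(x, ...) {
  cat(sprintf("<do_mosaic> gen %s; %d + %d segments; %d observable junction(s)\n",
              attr(x, "n_gen"), nrow(x[[1]]), nrow(x[[2]]),
              count_observable_junctions(x)))
  invisible(x)
}

#' @export
print.do_cohort <- function(x, ...) {
  cat(sprintf("<do_cohort> %d samples, gen %s, chr%s\n",
              length(x), attr(x, "n_gen"), attr(x, "chrom")))
  invisible(x)
}

#' Tidy a mosaic into BED-like segments
#'
#' @param x a `do_mosaic`
#' @param ... unused
#' @return tibble with `homolog`, `start_bp`, `end_bp`, `founder`
#' @export
tidy.do_mosaic <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x[[1]], homolog = 1L, .before = 1),
    dplyr::mutate(x[[2]], homolog = 2L, .before = 1)
  )
}
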