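#' Simulate a founder haplotype reference panel
#'
#' Generates one chromosome of biallelic, segregating SNPs for the eight DO
#' founder strains, optionally engineering identity-by-descent (IBD) blocks
#' in which a founder pair carries byte-identical alleles. The panel is the
#' reference used for genotype imputation, haplotype reconstruction and
#' founder IBD detection.
#'
#' Marker positions are drawn uniformly over the chromosome and sorted; the
#' genetic map is linear in bp at `cM_per_Mb`. Per-marker alternate-allele
#' frequencies among the 8 founders are drawn uniformly in `maf_range`
#' (counts 1--7 of the 8 founders carry the alternate allele), so every
#' marker segregates.
#'
#' @param n_markers number of SNPs to simulate (>= 2)
#' @param chrom_length_bp chromosome length in bp
#' @param ibd_spec optional tibble/data.frame with columns `founder1`,
#'   `founder2` (letters A--H), `start_bp`, `end_bp`: over each interval the
#'   second founder's alleles are copied from the first. Intervals for the
#'   same pair must not overlap.
#' @param maf_range length-2 numeric, range of founder alternate-allele
#'   frequency (in (0,1)); realized counts are clamped to 1..7 of 8
#' @param chrom chromosome name
#' @param cM_per_Mb genetic map density (uniform map)
#' @param seed optional integer seed
#' @return an object of class `founder_panel`: a list with `chrom`,
#'   `map` (tibble: `marker`, `pos_bp`, `cM`), `alleles` (n_markers x 8
#'   binary matrix, columns `A`--`H`) and `ibd_truth` (tibble as `ibd_spec`,
#'   possibly empty).
#' @examples
#' pan <- simulate_founder_panel(100, 10e6, seed = 1)
#' pan
#' @export
simulate_founder_panel <- function(n_markers, chrom_length_bp,
                                   ibd_spec = NULL,
                                   maf_range = c(0.125, 0.5),
                                   chrom = "1", cM_per_Mb = 0.5,
                                   seed = NULL) {
  if (n_markers < 2) stop("`n_markers` must be >= 2 (empty panels rejected)")
  stopifnot(chrom_length_bp > n_markers, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] < 1)
  ibd_spec <- check_ibd_spec(ibd_spec, chrom_length_bp)
  if (!is.null(seed)) set.seed(seed)

  pos <- sort(sample.int(chrom_length_bp - 2L, n_markers, replace = FALSE)) + 1L
  freq <- runif(n_markers, maf_range[1], maf_range[2])
  n_alt <- pmin(pmax(round(freq * 8), 1L), 7L)
  alleles <- matrix(0L, n_markers, 8, dimnames = list(NULL, do_founders()))
  for (m in seq_len(n_markers)) {
    alleles[m, sample.int(8, n_alt[m])] <- 1L
  }

  # engineer IBD blocks by copying founder1 -> founder2 over the span
  if (nrow(ibd_spec)) {
    for (k in seq_len(nrow(ibd_spec))) {
      in_span <- pos >= ibd_spec$start_bp[k] & pos <= ibd_spec$end_bp[k]
      alleles[in_span, ibd_spec$founder2[k]] <- alleles[in_span, ibd_spec$founder1[k]]
      # re-segregate any marker made monomorphic by the copy
      bad <- in_span & (rowSums(alleles) %in% c(0L, 8L))
      if (any(bad)) {
        flip <- setdiff(do_founders(), c(ibd_spec$founder1[k], ibd_spec$founder2[k]))[1]
        alleles[bad, flip] <- 1L - alleles[bad, flip]
      }
    }
  }

  panel <- structure(list(
    chrom = as.character(chrom),
    map = tibble::tibble(
      marker = sprintf("%s_%d", chrom, pos),
      pos_bp = as.integer(pos),
      cM = pos / 1e6 * cM_per_Mb
    ),
    alleles = alleles,
    ibd_truth = ibd_spec,
    chrom_length_bp = as.numeric(chrom_length_bp)
  ), class = "founder_panel")
  validate_panel(panel)
  panel
}

check_ibd_spec <- function(ibd_spec, chrom_length_bp) {
  if (is.null(ibd_spec) || !nrow(ibd_spec)) {
    return(tibble::tibble(founder1 = character(), founder2 = character(),
                          start_bp = numeric(), end_bp = numeric()))
  }
  ibd_spec <- tibble::as_tibble(ibd_spec)
  stopifnot(all(c("founder1", "founder2", "start_bp", "end_bp") %in% names(ibd_spec)))
  if (any(ibd_spec$start_bp < 1) || any(ibd_spec$end_bp > chrom_length_bp) ||
      any(ibd_spec$start_bp > ibd_spec$end_bp)) {
    stop("ibd_spec intervals must lie within the chromosome")
  }
  key <- paste(pmin(ibd_spec$founder1, ibd_spec$founder2),
               pmax(ibd_spec$founder1, ibd_spec$founder2))
  for (k in unique(key)) {
    iv <- ibd_spec[key == k, ]
    iv <- iv[order(iv$start_bp), ]
    if (nrow(iv) > 1 && any(iv$start_bp[-1] <= iv$end_bp[-nrow(iv)])) {
      stop("overlapping ibd_spec intervals for founder pair ", k)
    }
  }
  ibd_spec
}

validate_panel <- function(panel) {
  stopifnot(inherits(panel, "founder_panel"))
  with(panel, {
    if (any(diff(map$pos_bp) <= 0)) stop("marker positions must be strictly increasing")
    if (any(diff(map$cM) < 0)) stop("genetic map must be non-decreasing")
    if (!all(alleles %in% c(0L, 1L))) stop("founder alleles must be binary")
    rs <- rowSums(alleles)
    if (any(rs == 0 | rs == 8)) stop("all markers must segregate among the 8 founders")
  })
  invisible(panel)
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("<founder_panel> chr%s: %d markers over %.1f Mb (%.1f cM), %d engineered IBD block(s)\n",
              x$chrom, nrow(x$map), diff(range(x$map$pos_bp)) / 1e6,
              diff(range(x$map$cM)), nrow(x$ibd_truth)))
  invisible(x)
}

#' Filter raw founder genotype calls to reconstruction-ready sites
#'
#' Reproduces the reference-preparation rules: retain only biallelic sites
#' that are homozygous in every founder (any heterozygous or missing call
#' drops the site) and that segregate among the 8 founders. Site order is
#' preserved.
#'
#' @param raw_calls tibble/data.frame with columns `marker`, `pos_bp`, and
#'   one column per founder `A`--`H` holding diploid genotype strings
#'   (`"0/0"`, `"1/1"` kept; `"0/1"`, `"1/0"`, `"./."`, multiallelic codes
#'   such as `"2/2"` dropped)
#' @param chrom chromosome name for the returned panel
#' @param cM_per_Mb genetic map density applied to retained positions
#' @return a `founder_panel` of the retained sites, with attribute
#'   `filter_counts` (named integer vector: input, het_or_missing,
#'   multiallelic, non_segregating, retained)
#' @export
filter_founder_sites <- function(raw_calls, chrom = "1", cM_per_Mb = 0.5) {
  raw_calls <- tibble::as_tibble(raw_calls)
  stopifnot(all(c("marker", "pos_bp", do_founders()) %in% names(raw_calls)))
  gt <- as.matrix(raw_calls[, do_founders()])
  a1 <- matrix(substr(gt, 1, 1), nrow(gt))
  a2 <- matrix(substr(gt, 3, 3), nrow(gt))
  het_or_missing <- rowSums(a1 != a2 | a1 == "." | a2 == ".") > 0
  multi <- rowSums(matrix(!(a1 %in% c("0", "1", ".")) |
                            !(a2 %in% c("0", "1", ".")), nrow(gt))) > 0
  dose <- matrix(NA_integer_, nrow(gt), 8)
  ok <- !het_or_missing & !multi
  dose[ok, ] <- as.integer(a1[ok, ] == "1")
  nonseg <- ok & (rowSums(dose) %in% c(0L, 8L))
  keep <- ok & !nonseg
  counts <- c(input = nrow(gt),
              het_or_missing = sum(het_or_missing),
              multiallelic = sum(multi & !het_or_missing),
              non_segregating = sum(nonseg),
              retained = sum(keep))
  if (!any(keep)) {
    stop("no sites survive founder filtering (counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  }
  alleles <- dose[keep, , drop = FALSE]
  colnames(alleles) <- do_founders()
  panel <- structure(list(
    chrom = as.character(chrom),
    map = tibble::tibble(marker = raw_calls$marker[keep],
                         pos_bp = as.integer(raw_calls$pos_bp[keep]),
                         cM = raw_calls$pos_bp[keep] / 1e6 * cM_per_Mb),
    alleles = alleles,
    ibd_truth = check_ibd_spec(NULL, Inf),
    chrom_length_bp = max(raw_calls$pos_bp)
  ), class = "founder_panel")
  attr(panel, "filter_counts") <- counts
  validate_panel(panel)
  panel
}

#' Select an evenly spaced physical marker grid
#'
#' Anchors haplotype reconstruction to an (approximately) evenly spaced
#' physical grid: `n_grid` target positions are placed evenly across the
#' marker span and for each target the nearest panel marker is chosen.
#' Duplicate choices are collapsed, so fewer than `n_grid` indices may be
#' returned.
#'
#' @param panel a `founder_panel`
#' @param n_grid number of grid targets (>= 1)
#' @return sorted integer vector of marker indices into `panel$map`
#' @export
select_grid <- function(panel, n_grid) {
  validate_panel(panel)
  n <- nrow(panel$map)
  if (n_grid < 1) stop("`n_grid` must be >= 1")
  if (n_grid > n) stop("`n_grid` exceeds the number of panel markers")
  pos <- panel$map$pos_bp
  targets <- if (n_grid == 1) {
    mean(range(pos))
  } else {
    seq(min(pos), max(pos), length.out = n_grid)
  }
  # nearest marker per target; ties resolved to the earlier marker
  idx <- vapply(targets, function(t) which.min(abs(pos - t)), integer(1))
  sort(unique(idx))
}
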