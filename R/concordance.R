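#' Cosine similarity of two founder allele-probability vectors
#'
#' `cos(G, Q) = sum(G_i Q_i) / (||G|| ||Q||)`. For non-negative probability
#' vectors this lies in [0, 1]; it is insensitive to the overall scale of
#' either vector, so it measures the absolute similarity of two haplotype
#' reconstructions at a locus. The canonical discordance threshold 0.87 is
#' the cosine between a reconstruction calling a heterozygous {G, H}
#' diplotype and one splitting founder G's probability with founder F.
#'
#' @param g,q numeric vectors of equal length (neither all-zero)
#' @return cosine similarity (scalar)
#' @examples
#' cosine_similarity(c(0, 0, 0, 0, 0, 0, 0.5, 0.5),
#'                   c(0, 0, 0, 0, 0, 0.25, 0.25, 0.5))  # ~0.866
#' @export
cosine_similarity <- function(g, q) {
  stopifnot(length(g) == length(q))
  ng <- sqrt(sum(g^2))
  nq <- sqrt(sum(q^2))
  if (ng == 0 || nq == 0) stop("cosine similarity undefined for a zero vector")
  sum(g * q) / (ng * nq)
}

#' Interpolate allele probabilities onto a new marker map
#'
#' Linearly interpolates each founder-probability column in physical
#' position, then renormalizes each row to sum to 1. Target positions
#' outside the source span take the nearest end row. A step dialect
#' (`method = "step"`: carry the previous source marker forward) is
#' provided for sensitivity analysis.
#'
#' @param probs markers x 8 allele-probability matrix on `from_map`
#' @param from_map,to_map tibbles with `pos_bp` (same chromosome)
#' @param method `"linear"` (default) or `"step"`
#' @return length(to_map) x 8 probability matrix on the target map
#' @export
interpolate_probs <- function(probs, from_map, to_map,
                              method = c("linear", "step")) {
  method <- match.arg(method)
  if (!nrow(from_map)) stop("empty source map")
  stopifnot(nrow(probs) == nrow(from_map))
  x <- from_map$pos_bp
  xout <- to_map$pos_bp
  out <- vapply(seq_len(ncol(probs)), function(j) {
    if (nrow(from_map) == 1) return(rep(probs[1, j], length(xout)))
    approx(x, probs[, j], xout = xout, rule = 2,
           method = if (method == "linear") "linear" else "constant",
           f = 0, ties = "ordered")$y
  }, numeric(length(xout)))
  out <- matrix(out, nrow = length(xout), ncol = ncol(probs),
                dimnames = list(to_map$marker, colnames(probs)))
  out / rowSums(out)
}

#' Per-marker concordance track between two reconstructions
#'
#' Computes the cosine similarity of two allele-probability matrices at
#' each marker of a shared map, for one sample.
#'
#' @param probs_g,probs_q markers x 8 probability matrices on the same map
#' @param map tibble with `marker`, `pos_bp`
#' @return tibble of class `concordance_track`: `marker`, `pos_bp`,
#'   `cosine`; attribute `mean_cosine`
#' @export
concordance_track <- function(probs_g, probs_q, map) {
  stopifnot(nrow(probs_g) == nrow(map), nrow(probs_q) == nrow(map))
  num <- rowSums(probs_g * probs_q)
  den <- sqrt(rowSums(probs_g^2)) * sqrt(rowSums(probs_q^2))
  if (any(den == 0)) stop("zero-norm probability row")
  track <- tibble::tibble(marker = map$marker, pos_bp = map$pos_bp,
                          cosine = num / den)
  attr(track, "mean_cosine") <- mean(track$cosine)
  class(track) <- c("concordance_track", class(track))
  track
}

#' Flag discordant regions on a concordance track
#'
#' A discordant region is a maximal run of consecutive markers whose cosine
#' similarity falls below `threshold` (default 0.87). Single-marker runs
#' are kept; the region span runs from the first to the last marker of the
#' run.
#'
#' @param track a `concordance_track` (or tibble with `pos_bp`, `cosine`)
#' @param threshold cosine threshold
#' @return tibble: `start_bp`, `end_bp`, `n_markers`, `mean_cosine`,
#'   `start_idx`, `end_idx`
#' @export
flag_discordant_regions <- function(track, threshold = 0.87) {
  below <- track$cosine < threshold
  if (!any(below)) {
    return(tibble::tibble(start_bp = numeric(), end_bp = numeric(),
                          n_markers = integer(), mean_cosine = numeric(),
                          start_idx = integer(), end_idx = integer()))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    start_bp = track$pos_bp[starts[keep]],
    end_bp = track$pos_bp[ends[keep]],
    n_markers = r$lengths[keep],
    mean_cosine = vapply(which(keep), function(k) {
      mean(track$cosine[starts[k]:ends[k]])
    }, numeric(1)),
    start_idx = starts[keep],
    end_idx = ends[keep]
  )
}

#' Classify discordant regions against founder IBD segments
#'
#' For each discordant region, founder sets are taken as the founders whose
#' region-mean allele probability exceeds `prob_floor` in each
#' reconstruction. The region is `ibd_explained` when an IBD segment
#' overlapping it by at least `min_overlap_bp` involves a founder pair that
#' (a) touches the founders on which the two reconstructions disagree (the
#' symmetric difference of the two founder sets) and (b) lies within the
#' union of the two founder sets — i.e. the methods swapped probability
#' between two founders that are IBD there. The sharing category of the
#' explaining pair is `classical-only` (both of A--E), `classical+WSB`
#' (a classical founder with H), `PWK-CAST` (the pair {F, G}), otherwise
#' `other`; unexplained regions are `none`.
#'
#' @param regions tibble from [flag_discordant_regions()] (needs
#'   `start_bp`, `end_bp`, `start_idx`, `end_idx`)
#' @param ibd_segments tibble from [find_ibd_segments()]
#' @param probs_g,probs_q markers x 8 allele-probability matrices on the
#'   track's map
#' @param min_overlap_bp minimum IBD overlap (default 10 kb)
#' @param prob_floor founder-presence floor on region-mean probability
#'   (in (0, 1))
#' @return `regions` with added `founders_g`, `founders_q` (comma-joined),
#'   `ibd_explained`, `sharing_category`
#' @export
classify_discordance_ibd <- function(regions, ibd_segments, probs_g, probs_q,
                                     min_overlap_bp = 10000, prob_floor = 0.1) {
  if (prob_floor >= 1 || prob_floor <= 0) stop("`prob_floor` must be in (0, 1)")
  founders <- do_founders()
  n <- nrow(regions)
  founders_g <- founders_q <- character(n)
  explained <- logical(n)
  category <- rep("none", n)
  for (k in seq_len(n)) {
    idx <- regions$start_idx[k]:regions$end_idx[k]
    mg <- colMeans(probs_g[idx, , drop = FALSE])
    mq <- colMeans(probs_q[idx, , drop = FALSE])
    set_g <- founders[mg > prob_floor]
    set_q <- founders[mq > prob_floor]
    founders_g[k] <- paste(set_g, collapse = ",")
    founders_q[k] <- paste(set_q, collapse = ",")
    disagree <- union(setdiff(set_g, set_q), setdiff(set_q, set_g))
    if (!length(disagree)) next
    # 1-based inclusive intervals: overlap length in bases
    ov <- pmin(ibd_segments$end_bp, regions$end_bp[k]) -
      pmax(ibd_segments$start_bp, regions$start_bp[k]) + 1
    cand <- ibd_segments[ov >= min_overlap_bp, , drop = FALSE]
    if (!nrow(cand)) next
    uni <- union(set_g, set_q)
    hit <- (cand$founder1 %in% disagree | cand$founder2 %in% disagree) &
      cand$founder1 %in% uni & cand$founder2 %in% uni
    if (any(hit)) {
      explained[k] <- TRUE
      category[k] <- sharing_category(cand$founder1[hit], cand$founder2[hit])
    }
  }
  dplyr::mutate(regions, founders_g = founders_g, founders_q = founders_q,
                ibd_explained = explained, sharing_category = category)
}

# category of the explaining founder pair(s); if several pairs explain a
# region the most specific single-pair label is taken in the order below
sharing_category <- function(f1, f2) {
  lab <- vapply(seq_along(f1), function(i) {
    pair <- sort(c(f1[i], f2[i]))
    cls <- founder_class(pair)
    if (all(cls == "classical")) return("classical-only")
    if (identical(pair, c("F", "G"))) return("PWK-CAST")
    if (any(cls == "classical") && "H" %in% pair) return("classical+WSB")
    "other"
  }, character(1))
  pref <- c("classical-only", "classical+WSB", "PWK-CAST", "other")
  pref[min(match(lab, pref))]
}
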