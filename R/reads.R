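#' Simulate low-coverage sequencing allele depths
#'
#' Emulates aligned low-coverage whole-genome sequencing at the panel
#' markers: per-marker total depth is Poisson(`coverage`) and the
#' alternate-allele count is Binomial(depth, p) with p = `base_error`, 0.5,
#' or 1 - `base_error` for true dose 0, 1, 2.
#'
#' @param mosaics a `do_cohort` (or list of `do_mosaic`)
#' @param panel the `founder_panel` used to simulate the mosaics
#' @param coverage nominal mean reads per site (> 0)
#' @param base_error per-read error probability (in [0, 0.5))
#' @param marker_subset optional integer indices restricting sequencing to a
#'   marker subset (e.g. a ddRADseq-like "fewer markers, higher depth" arm)
#' @param seed optional integer seed
#' @return an `allele_depths` object: list with `ref` and `alt` (samples x
#'   markers integer matrices), `map`, `nominal_coverage`
#' @export
simulate_reads <- function(mosaics, panel, coverage, base_error = 0.001,
                           marker_subset = NULL, seed = NULL) {
  validate_panel(panel)
  if (coverage <= 0) stop("`coverage` must be > 0")
  if (base_error < 0 || base_error >= 0.5) stop("`base_error` must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  idx <- if (is.null(marker_subset)) seq_len(nrow(panel$map)) else sort(unique(marker_subset))
  n_s <- length(mosaics)
  n_m <- length(idx)
  ref <- alt <- matrix(0L, n_s, n_m,
                       dimnames = list(sprintf("S%03d", seq_len(n_s)),
                                       panel$map$marker[idx]))
  p_alt <- c(base_error, 0.5, 1 - base_error)
  for (i in seq_len(n_s)) {
    dose <- mosaic_doses(mosaics[[i]], panel)[idx]
    tot <- rpois(n_m, coverage)
    a <- rbinom(n_m, tot, p_alt[dose + 1L])
    alt[i, ] <- a
    ref[i, ] <- tot - a
  }
  new_allele_depths(ref, alt, panel$map[idx, ], coverage)
}

new_allele_depths <- function(ref, alt, map, nominal_coverage) {
  stopifnot(all(ref >= 0), all(alt >= 0), identical(dim(ref), dim(alt)))
  structure(list(ref = ref, alt = alt, map = tibble::as_tibble(map),
                 nominal_coverage = nominal_coverage),
            class = "allele_depths")
}

#' @export
print.allele_depths <- function(x, ...) {
  cat(sprintf("<allele_depths> %d samples x %d markers; nominal %.3gx, realized %.3gx\n",
              nrow(x$ref), ncol(x$ref), x$nominal_coverage,
              mean(x$ref + x$alt)))
  invisible(x)
}

#' Thin sequencing depth to a lower target coverage
#'
#' Down-samples an allele-depth matrix by keeping each read independently
#' with probability `target_cov / current coverage` (binomial thinning of
#' ref and alt counts separately) — the depth-level equivalent of
#' down-sampling alignments by a fixed percentage.
#'
#' @param depths an `allele_depths` object
#' @param target_cov target mean coverage (> 0 and <= current estimated
#'   coverage)
#' @param seed optional integer seed
#' @return an `allele_depths` object at the thinned coverage
#' @export
downsample_depths <- function(depths, target_cov, seed = NULL) {
  stopifnot(inherits(depths, "allele_depths"))
  if (target_cov <= 0) stop("`target_cov` must be > 0")
  cur <- depths$nominal_coverage
  if (target_cov > cur) stop("`target_cov` exceeds current coverage (", cur, ")")
  keep_p <- target_cov / cur
  if (!is.null(seed)) set.seed(seed)
  if (keep_p == 1) return(depths)
  ref <- depths$ref
  alt <- depths$alt
  ref[] <- rbinom(length(ref), as.vector(ref), keep_p)
  alt[] <- rbinom(length(alt), as.vector(alt), keep_p)
  new_allele_depths(ref, alt, depths$map, target_cov)
}

#' Simulate array-style hard genotype calls on a sparse marker map
#'
#' Emulates a GigaMUGA-like genotyping array: hard 0/1/2 calls at a sparser
#' subset of the panel markers. Each call equals the true dose with
#' probability `1 - call_error`; otherwise one of the two other doses is
#' reported (uniformly).
#'
#' @param mosaics a `do_cohort`
#' @param panel the `founder_panel`
#' @param array_marker_indices integer indices into the panel map (non-empty)
#' @param call_error per-call error probability
#' @param seed optional integer seed
#' @return a `genotype_calls` object: list with `calls` (samples x markers
#'   integer matrix, values 0/1/2 or NA) and `map` of the array markers
#' @export
simulate_array_calls <- function(mosaics, panel, array_marker_indices,
                                 call_error = 0.002, seed = NULL) {
  validate_panel(panel)
  if (!length(array_marker_indices)) stop("`array_marker_indices` must be non-empty")
  stopifnot(all(array_marker_indices >= 1),
            all(array_marker_indices <= nrow(panel$map)),
            call_error >= 0, call_error < 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(unique(array_marker_indices))
  n_s <- length(mosaics)
  n_m <- length(idx)
  calls <- matrix(NA_integer_, n_s, n_m,
                  dimnames = list(sprintf("S%03d", seq_len(n_s)),
                                  panel$map$marker[idx]))
  for (i in seq_len(n_s)) {
    dose <- mosaic_doses(mosaics[[i]], panel)[idx]
    err <- runif(n_m) < call_error
    call <- dose
    if (any(err)) {
      # miscall: one of the two other doses, uniformly
      call[err] <- vapply(dose[err], function(d) sample(setdiff(0:2, d), 1L), integer(1))
    }
    calls[i, ] <- call
  }
  structure(list(calls = calls, map = panel$map[idx, ], marker_indices = idx),
            class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("<genotype_calls> %d samples x %d array markers\n",
              nrow(x$calls), ncol(x$calls)))
  invisible(x)
}
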