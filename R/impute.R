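#' Genotype likelihoods from allele depths
#'
#' For each sample-marker cell, the likelihood of alternate dose
#' g in {0, 1, 2} is the binomial pmf of the alt count given total depth and
#' alt-read probability `base_error`, 0.5, `1 - base_error` respectively.
#' Likelihoods are stored on the natural-log scale, renormalized so the
#' maximum of each triple is 0; zero-depth cells give a flat triple.
#'
#' @param depths an `allele_depths` object
#' @param base_error per-read error probability (in (0, 0.5))
#' @return a `genotype_likelihoods` object: list with `loglik` (samples x
#'   markers x 3 array), `map`, `base_error`
#' @export
genotype_likelihoods <- function(depths, base_error = 0.001) {
  stopifnot(inherits(depths, "allele_depths"))
  if (base_error <= 0 || base_error >= 0.5) stop("`base_error` must be in (0, 0.5)")
  alt <- depths$alt
  tot <- depths$ref + depths$alt
  if (any(alt > tot)) stop("alt count exceeds total depth")
  p_alt <- c(base_error, 0.5, 1 - base_error)
  ll <- array(NA_real_, c(dim(alt), 3L),
              dimnames = c(dimnames(alt), list(g0 = c("0", "1", "2"))))
  for (g in 1:3) {
    ll[, , g] <- dbinom(alt, tot, p_alt[g], log = TRUE)
  }
  ll <- ll - array(pmax(ll[, , 1], ll[, , 2], ll[, , 3]), dim(ll))
  structure(list(loglik = ll, map = depths$map, base_error = base_error),
            class = "genotype_likelihoods")
}

#' @export
print.genotype_likelihoods <- function(x, ...) {
  cat(sprintf("<genotype_likelihoods> %d samples x %d markers (base error %.4g)\n",
              dim(x$loglik)[1], dim(x$loglik)[2], x$base_error))
  invisible(x)
}

#' IMPUTE-style per-marker INFO score
#'
#' Measures how much of the binomial dosage variance expected at the
#' estimated allele frequency is resolved by the posterior dose
#' distributions: `info = 1 - sum_i Var_i(dose) / (2 N theta (1 - theta))`
#' with `theta = sum_i E_i[dose] / (2N)`, clamped to [0, 1]. Monomorphic
#' sites (`theta` 0 or 1) are defined to have info 1.
#'
#' @param dose_post samples x 3 matrix of posterior dose probabilities for
#'   one marker, or a samples x markers x 3 array for many markers
#' @return numeric info score(s) in [0, 1]
#' @export
info_score <- function(dose_post) {
  if (is.matrix(dose_post)) dose_post <- array(dose_post, c(nrow(dose_post), 1L, 3L))
  stopifnot(length(dim(dose_post)) == 3, dim(dose_post)[3] == 3)
  if (dim(dose_post)[1] < 1) stop("empty cohort")
  N <- dim(dose_post)[1]
  e1 <- dose_post[, , 2, drop = FALSE] + 2 * dose_post[, , 3, drop = FALSE]
  e2 <- dose_post[, , 2, drop = FALSE] + 4 * dose_post[, , 3, drop = FALSE]
  v <- e2 - e1^2
  theta <- colSums(matrix(e1, N)) / (2 * N)
  denom <- 2 * N * theta * (1 - theta)
  info <- 1 - colSums(matrix(v, N)) / denom
  info[theta <= 0 | theta >= 1] <- 1
  pmin(pmax(info, 0), 1)
}

#' Impute genotype dosages with the diplotype HMM
#'
#' Runs the 36-state founder diplotype forward-backward per sample on
#' genotype likelihoods, collapses state posteriors to alternate-dose
#' posteriors through each state's implied dose at each marker, and
#' returns expected dosages plus per-marker INFO scores.
#'
#' @param gl a `genotype_likelihoods` object (markers must match the panel)
#' @param panel the `founder_panel` reference
#' @param n_gen outbreeding generation (HMM transition scale)
#' @return a `site_imputation` object: list with `dosage` (samples x
#'   markers), `dose_post` (samples x markers x 3), `info` (per marker),
#'   `hard_call` (argmax dose), `map`
#' @export
impute_cohort <- function(gl, panel, n_gen) {
  stopifnot(inherits(gl, "genotype_likelihoods"))
  validate_panel(panel)
  if (!identical(as.character(gl$map$marker), as.character(panel$map$marker))) {
    stop("genotype-likelihood markers do not match the panel markers")
  }
  recon <- reconstruct_cohort(gl, panel, n_gen)
  structure(list(dosage = recon$dosage, dose_post = recon$dose_post,
                 info = recon$info, hard_call = recon$hard_call,
                 map = panel$map), class = "site_imputation")
}

#' @export
print.site_imputation <- function(x, ...) {
  cat(sprintf("<site_imputation> %d samples x %d markers; mean INFO %.3f\n",
              nrow(x$dosage), ncol(x$dosage), mean(x$info)))
  invisible(x)
}

#' Tidy per-marker imputation statistics
#'
#' @param x a `site_imputation` object
#' @param ... unused
#' @return tibble with `marker`, `pos_bp`, `info`, `mean_dosage`
#' @export
tidy.site_imputation <- function(x, ...) {
  tibble::tibble(marker = x$map$marker, pos_bp = x$map$pos_bp,
                 info = x$info, mean_dosage = colMeans(x$dosage))
}
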