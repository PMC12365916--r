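#' Build an expression-truth table for simulation
#'
#' Assigns genes evenly spaced midpoints along the chromosome and plants
#' additive founder allele effects at a subset of them. A causal gene's
#' effect vector puts `+effect_size` on one random founder and
#' `-effect_size` on another (a strong local-eQTL-like allele contrast, in
#' latent expression SD units); non-causal genes have a zero effect vector.
#'
#' @param panel a `founder_panel` (gene midpoints are placed on its span)
#' @param n_genes number of genes
#' @param n_causal number with planted local effects
#' @param effect_size latent-SD amplitude of the planted founder contrast
#' @param dispersion negative-binomial dispersion (1/size; > 0)
#' @param seed optional integer seed
#' @return tibble of class `expression_truth`: `gene`, `chrom`,
#'   `midpoint_bp`, `causal`, `beta_A`..`beta_H`, `dispersion`
#' @export
make_expression_truth <- function(panel, n_genes, n_causal,
                                  effect_size = 2.5, dispersion = 0.02,
                                  seed = NULL) {
  validate_panel(panel)
  stopifnot(n_causal <= n_genes, n_genes >= 1)
  if (dispersion <= 0) stop("`dispersion` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  span <- range(panel$map$pos_bp)
  mid <- round(seq(span[1], span[2], length.out = n_genes + 2)[-c(1, n_genes + 2)])
  beta <- matrix(0, n_genes, 8, dimnames = list(NULL, paste0("beta_", do_founders())))
  causal <- sort(sample.int(n_genes, n_causal))
  for (g in causal) {
    pair <- sample.int(8, 2)
    beta[g, pair[1]] <- effect_size
    beta[g, pair[2]] <- -effect_size
  }
  out <- tibble::tibble(gene = sprintf("gene%03d", seq_len(n_genes)),
                        chrom = panel$chrom, midpoint_bp = mid,
                        causal = seq_len(n_genes) %in% causal)
  out <- dplyr::bind_cols(out, tibble::as_tibble(beta))
  out$dispersion <- dispersion
  class(out) <- c("expression_truth", class(out))
  out
}

#' Simulate expression counts with founder allele effects
#'
#' The latent trait of gene g in sample i is
#' `sum_j f_ij beta_jg + sex_i beta_sex + gen_i beta_gen + e_i`,
#' with `f_ij` the true founder allele probability (dose / 2) at the marker
#' nearest the gene midpoint and `e_i ~ N(0, 1)` (so planted effects are in
#' latent SD units). Counts are negative-binomial with mean
#' `size_factor_i * exp(log_mu0 + latent_scale * latent)` and the gene's
#' dispersion.
#'
#' @param mosaics a `do_cohort`
#' @param panel the `founder_panel`
#' @param truth an `expression_truth` tibble
#' @param covariates optional tibble with `sex` (0/1) and `generation` per
#'   sample; simulated if `NULL` (gen 40--45 as in a modern DO cohort)
#' @param beta_sex,beta_gen covariate effects on the latent scale
#' @param log_mu0 baseline log mean count
#' @param latent_scale multiplier from latent SD units to log-count units
#' @param seed optional integer seed
#' @return list of class `expression_sim`: `counts` (samples x genes),
#'   `covariates` (tibble with `sample`, `sex`, `generation`),
#'   `size_factors`, `truth`
#' @export
simulate_expression <- function(mosaics, panel, truth, covariates = NULL,
                                beta_sex = 0.25, beta_gen = 0.05,
                                log_mu0 = log(500), latent_scale = 0.5,
                                seed = NULL) {
  validate_panel(panel)
  stopifnot(inherits(truth, "expression_truth"))
  if (any(truth$dispersion <= 0)) stop("`dispersion` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_s <- length(mosaics)
  n_g <- nrow(truth)
  if (is.null(covariates)) {
    covariates <- tibble::tibble(sample = sprintf("S%03d", seq_len(n_s)),
                                 sex = sample(0:1, n_s, replace = TRUE),
                                 generation = sample(40:45, n_s, replace = TRUE))
  }
  size_factors <- exp(rnorm(n_s, 0, 0.1))
  # true founder allele probabilities at the marker nearest each midpoint
  marker_idx <- vapply(truth$midpoint_bp,
                       function(b) which.min(abs(panel$map$pos_bp - b)), integer(1))
  f <- array(NA_real_, c(n_s, n_g, 8))
  for (i in seq_len(n_s)) {
    ap <- mosaic_alleleprobs(mosaics[[i]], panel)
    f[i, , ] <- ap[marker_idx, , drop = FALSE]
  }
  beta <- as.matrix(truth[, paste0("beta_", do_founders())])
  counts <- matrix(NA_integer_, n_s, n_g,
                   dimnames = list(covariates$sample, truth$gene))
  gen_c <- covariates$generation - mean(covariates$generation)
  for (g in seq_len(n_g)) {
    latent <- f[, g, ] %*% beta[g, ] +
      covariates$sex * beta_sex + gen_c * beta_gen + rnorm(n_s)
    mu <- size_factors * exp(log_mu0 + latent_scale * as.vector(latent))
    counts[, g] <- rnbinom(n_s, size = 1 / truth$dispersion[g], mu = mu)
  }
  structure(list(counts = counts, covariates = covariates,
                 size_factors = size_factors, truth = truth),
            class = "expression_sim")
}

#' @export
print.expression_sim <- function(x, ...) {
  cat(sprintf("<expression_sim> %d samples x %d genes (%d causal)\n",
              nrow(x$counts), ncol(x$counts), sum(x$truth$causal)))
  invisible(x)
}
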