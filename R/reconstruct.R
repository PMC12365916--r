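#' Reconstruct founder haplotypes for a cohort
#'
#' The central driver: builds per-state emissions from sequencing genotype
#' likelihoods or array hard calls, runs the 36-state diplotype
#' forward-backward over the chromosome for every sample, and condenses
#' posteriors to founder allele probabilities, alternate-dose posteriors,
#' expected dosages and maximum-marginal state calls.
#'
#' @param input a `genotype_likelihoods` object (sequencing model), an
#'   `allele_depths` object (converted with [genotype_likelihoods()]), or a
#'   `genotype_calls` object (array model)
#' @param panel the `founder_panel`; when the input covers a marker subset
#'   (e.g. array markers) the panel is subset to match by marker id
#' @param n_gen outbreeding generation (HMM transition scale)
#' @param array_error emission error rate for array calls
#' @param minprob minimum posterior for a maximum-marginal state call
#' @param keep_diplotype keep the full samples x markers x 36 posterior
#'   array (memory-heavy; needed only for state-level inspection)
#' @return a `haplo_recon` object: list with `alleleprob` (samples x
#'   markers x 8), `dose_post` (samples x markers x 3), `dosage`,
#'   `hard_call`, `maxmarg` (state indices, `NA` below `minprob`),
#'   `maxmarg_prob`, `info` (per marker), `map`, `loglik`, and optionally
#'   `diplotype`
#' @export
reconstruct_cohort <- function(input, panel, n_gen, array_error = 0.002,
                               minprob = 0.95, keep_diplotype = FALSE) {
  validate_panel(panel)
  if (inherits(input, "allele_depths")) input <- genotype_likelihoods(input)
  sub <- match(as.character(input$map$marker), as.character(panel$map$marker))
  if (anyNA(sub)) stop("input markers are not a subset of the panel markers")
  alleles <- panel$alleles[sub, , drop = FALSE]
  map <- panel$map[sub, ]
  doses36 <- state_doses(alleles)  # markers x 36

  if (inherits(input, "genotype_likelihoods")) {
    lik <- exp(input$loglik)  # S x M x 3, max-normalized
    samples <- rownames(input$loglik)
  } else if (inherits(input, "genotype_calls")) {
    calls <- input$calls
    lik <- array(array_error / 2, c(dim(calls), 3L))
    for (g in 0:2) {
      hit <- !is.na(calls) & calls == g
      lik[, , g + 1][hit] <- 1 - array_error
    }
    miss <- is.na(calls)
    for (g in 1:3) lik[, , g][miss] <- 1
    samples <- rownames(calls)
  } else {
    stop("unsupported input type: ", paste(class(input), collapse = "/"))
  }

  S <- dim(lik)[1]
  M <- dim(lik)[2]
  emis <- array(NA_real_, c(36L, S, M))
  for (m in seq_len(M)) {
    emis[, , m] <- t(matrix(lik[, m, ], S, 3L)[, doses36[m, ] + 1L, drop = FALSE])
  }
  trans <- interval_transitions(map, n_gen)
  fb <- forward_backward_cohort(emis, trans)

  K <- condensation_matrix()
  alleleprob <- array(NA_real_, c(S, M, 8L),
                      dimnames = list(samples, map$marker, do_founders()))
  dose_post <- array(NA_real_, c(S, M, 3L),
                     dimnames = list(samples, map$marker, c("0", "1", "2")))
  mm <- matrix(NA_integer_, S, M, dimnames = list(samples, map$marker))
  mmp <- matrix(NA_real_, S, M, dimnames = list(samples, map$marker))
  for (m in seq_len(M)) {
    p <- t(matrix(fb$posterior[, , m], 36L, S))  # S x 36
    alleleprob[, m, ] <- p %*% K
    for (g in 0:2) {
      sel <- doses36[m, ] == g
      dose_post[, m, g + 1L] <- if (any(sel)) rowSums(p[, sel, drop = FALSE]) else 0
    }
    idx <- max.col(p, ties.method = "first")
    mm[, m] <- idx
    mmp[, m] <- p[cbind(seq_len(S), idx)]
  }
  dosage <- dose_post[, , 2, drop = FALSE][, , 1] + 2 * dose_post[, , 3, drop = FALSE][, , 1]
  dosage <- matrix(dosage, S, M, dimnames = list(samples, map$marker))
  hard_call <- matrix(max.col(matrix(aperm(dose_post, c(3, 1, 2)), 3L) |> t(),
                              ties.method = "first") - 1L,
                      S, M, dimnames = list(samples, map$marker))
  maxmarg <- mm
  maxmarg[mmp < minprob] <- NA_integer_

  out <- list(alleleprob = alleleprob, dose_post = dose_post, dosage = dosage,
              hard_call = hard_call, maxmarg = maxmarg, maxmarg_prob = mmp,
              info = setNames(info_score(dose_post), map$marker),
              map = map, n_gen = n_gen, loglik = fb$loglik)
  if (keep_diplotype) {
    out$diplotype <- aperm(fb$posterior, c(2, 3, 1))
    dimnames(out$diplotype) <- list(samples, map$marker, rownames(diplotype_states()))
  }
  structure(out, class = "haplo_recon")
}

#' @export
print.haplo_recon <- function(x, ...) {
  cat(sprintf("<haplo_recon> %d samples x %d markers (n_gen %s); mean INFO %.3f; %.1f%% markers called at maxmarg\n",
              dim(x$alleleprob)[1], dim(x$alleleprob)[2], x$n_gen,
              mean(x$info), 100 * mean(!is.na(x$maxmarg))))
  invisible(x)
}

#' Tidy founder allele probabilities into long form
#'
#' @param x a `haplo_recon` object
#' @param ... unused
#' @return tibble with `sample`, `marker`, `pos_bp`, `founder`, `prob`
#' @export
tidy.haplo_recon <- function(x, ...) {
  d <- dim(x$alleleprob)
  tibble::tibble(
    sample = rep(dimnames(x$alleleprob)[[1]], times = d[2] * d[3]),
    marker = rep(rep(x$map$marker, each = d[1]), times = d[3]),
    pos_bp = rep(rep(x$map$pos_bp, each = d[1]), times = d[3]),
    founder = rep(do_founders(), each = d[1] * d[2]),
    prob = as.vector(x$alleleprob)
  )
}

#' @rdname tidy.haplo_recon
#' @return `glance()`: one-row tibble with sample/marker counts, mean INFO,
#'   mean maxmarg call rate and total log-likelihood
#' @export
glance.haplo_recon <- function(x, ...) {
  tibble::tibble(n_samples = dim(x$alleleprob)[1],
                 n_markers = dim(x$alleleprob)[2],
                 mean_info = mean(x$info),
                 maxmarg_call_rate = mean(!is.na(x$maxmarg)),
                 loglik = sum(x$loglik))
}

#' Count crossovers for every sample of a reconstruction
#'
#' Applies [maxmarg_path()] thresholding (already stored in the
#' reconstruction) and [locate_crossovers()] per sample.
#'
#' @param recon a `haplo_recon` object
#' @return tibble with `sample`, `n_crossovers`, `n_boundaries`,
#'   `median_block_bp`
#' @export
count_crossovers <- function(recon) {
  stopifnot(inherits(recon, "haplo_recon"))
  purrr::imap(split(seq_len(nrow(recon$maxmarg)), seq_len(nrow(recon$maxmarg))),
              function(i, nm) {
    xo <- suppressWarnings(locate_crossovers(recon$maxmarg[i, ], recon$map))
    tibble::tibble(sample = rownames(recon$maxmarg)[i],
                   n_crossovers = xo$n_crossovers,
                   n_boundaries = nrow(xo$crossovers),
                   median_block_bp = stats::median(xo$blocks$length_bp))
  }) |> purrr::list_rbind()
}
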