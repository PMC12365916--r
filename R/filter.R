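#' Hardy-Weinberg equilibrium goodness-of-fit p-value
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency.
#' Monomorphic sites (allele frequency 0 or 1) are defined to have p = 1.
#'
#' @param n0,n1,n2 counts of alternate-dose 0, 1, 2 genotypes (vectors
#'   allowed; recycled elementwise)
#' @param exact use the mid-p-free exact conditional test
#'   (Wigginton-style enumeration of heterozygote counts) instead of the
#'   chi-square approximation
#' @return p-value vector
#' @examples
#' hwe_pvalue(25, 50, 25)  # exactly HWE -> 1
#' hwe_pvalue(50, 0, 50)   # extreme departure
#' @export
hwe_pvalue <- function(n0, n1, n2, exact = FALSE) {
  n <- n0 + n1 + n2
  if (any(n <= 0)) stop("genotype counts must not be all zero")
  if (any(c(n0, n1, n2) < 0)) stop("genotype counts must be non-negative")
  if (exact) {
    return(mapply(hwe_exact_one, n0, n1, n2))
  }
  p <- (n1 + 2 * n2) / (2 * n)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  stat <- ifelse(p <= 0 | p >= 1, 0,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# exact HWE test: condition on allele counts, enumerate heterozygote counts
hwe_exact_one <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  n_alt <- n1 + 2 * n2
  if (n_alt == 0 || n_alt == 2 * n) return(1)
  hets <- seq(n_alt %% 2, min(n_alt, 2 * n - n_alt), by = 2)
  logp <- vapply(hets, function(h) {
    a <- (n_alt - h) / 2
    r <- n - h - a
    lgamma(n + 1) - lgamma(h + 1) - lgamma(a + 1) - lgamma(r + 1) +
      h * log(2) + lgamma(n_alt + 1) + lgamma(2 * n - n_alt + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hets == n1] + 1e-12])
}

#' Adaptive INFO-score marker filter
#'
#' Reproduces the per-chromosome marker-retention heuristic used ahead of
#' haplotype reconstruction: candidate sites must pass a Hardy-Weinberg
#' screen (`hwe_p > hwe_alpha`); the INFO cutoff starts at `start_cutoff`
#' and is relaxed by `step` until strictly more than `min_snps` candidates
#' exceed it (or the cutoff reaches 0, in which case all candidates are
#' returned with a warning flag).
#'
#' @param info per-marker INFO scores
#' @param hwe_p per-marker HWE p-values (same length)
#' @param start_cutoff starting INFO cutoff
#' @param step cutoff decrement (> 0)
#' @param min_snps retention target (strictly exceeded)
#' @param hwe_alpha HWE screening level
#' @param chrom chromosome label for the report
#' @return list with `retained` (integer indices) and `report` (one-row
#'   tibble: `chrom`, `n_input`, `n_hwe_pass`, `n_retained`,
#'   `final_info_cutoff`, `hwe_alpha`, `target_met`)
#' @export
adaptive_info_filter <- function(info, hwe_p, start_cutoff = 0.95,
                                 step = 0.01, min_snps = 10000,
                                 hwe_alpha = 0.05, chrom = "1") {
  if (step <= 0) stop("`step` must be > 0")
  stopifnot(length(info) == length(hwe_p))
  candidates <- which(hwe_p > hwe_alpha)
  cutoff <- start_cutoff
  repeat {
    retained <- candidates[info[candidates] > cutoff]
    if (length(retained) > min_snps || cutoff <= 0) break
    cutoff <- cutoff - step
  }
  target_met <- length(retained) > min_snps
  if (!target_met) {
    cutoff <- 0
    retained <- candidates  # fall back to all HWE-passing sites
  }
  list(
    retained = retained,
    report = tibble::tibble(chrom = chrom, n_input = length(info),
                            n_hwe_pass = length(candidates),
                            n_retained = length(retained),
                            final_info_cutoff = max(cutoff, 0),
                            hwe_alpha = hwe_alpha,
                            target_met = target_met)
  )
}
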