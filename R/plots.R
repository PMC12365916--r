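# ggplot2 views of the main result types

#' Plot a concordance track
#'
#' Per-marker cosine similarity along the chromosome with the discordance
#' threshold drawn as a dashed line.
#'
#' @param object a `concordance_track`
#' @param threshold threshold line to draw
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.concordance_track <- function(object, threshold = 0.87, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = pos_bp / 1e6, y = cosine)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Position (Mb)", y = "Cosine similarity") +
    ggplot2::theme_minimal()
}

#' Plot LOD curves of a scan
#'
#' @param object a `do_scan1`
#' @param genes optional subset of trait names
#' @param threshold horizontal reference line (default 8)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.do_scan1 <- function(object, genes = NULL, threshold = 8, ...) {
  df <- tidy.do_scan1(object)
  if (!is.null(genes)) df <- dplyr::filter(df, gene %in% genes)
  ggplot2::ggplot(df, ggplot2::aes(x = pos_bp / 1e6, y = lod, colour = gene)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "LOD") +
    ggplot2::theme_minimal()
}

#' Founder allele-probability heat strip for one sample
#'
#' @param recon a `haplo_recon`
#' @param sample sample index or name
#' @return a ggplot
#' @export
plot_alleleprobs <- function(recon, sample = 1) {
  p <- matrix(recon$alleleprob[sample, , ], ncol = 8)
  df <- tibble::tibble(
    pos_bp = rep(recon$map$pos_bp, times = 8),
    founder = rep(do_founders(), each = nrow(p)),
    prob = as.vector(p)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = pos_bp / 1e6, y = founder, fill = prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Position (Mb)", y = "Founder", fill = "P(founder)") +
    ggplot2::theme_minimal()
}

#' Coverage-ladder summary plot of a benchmark run
#'
#' @param run a `benchmark_run`
#' @return a ggplot of mean concordance against coverage (log scale)
#' @export
plot_coverage_ladder <- function(run) {
  ggplot2::ggplot(run$summary,
                  ggplot2::aes(x = coverage, y = mean_concordance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Sequencing coverage (x)", y = "Mean cosine concordance") +
    ggplot2::theme_minimal()
}

#' Founder allele-effect bars at an eQTL
#'
#' @param effects named length-8 vector from [allele_effects()] (or a
#'   named list of them for side-by-side methods)
#' @return a ggplot
#' @export
plot_allele_effects <- function(effects) {
  if (!is.list(effects)) effects <- list(effects = effects)
  df <- purrr::imap(effects, function(e, nm) {
    tibble::tibble(method = nm, founder = names(e), effect = unname(e))
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = founder, y = effect, fill = method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Founder", y = "Centered additive effect") +
    ggplot2::theme_minimal()
}
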