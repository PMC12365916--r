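#' Detect identity-by-descent segments among founder pairs
#'
#' For every pair of the 8 founder strains, scores each marker with a
#' log10 likelihood ratio of IBD versus non-IBD: a genotype match scores
#' `log10((1 - err) / p_match)` where `p_match = p0^2 + p1^2` from the
#' founder allele frequencies at the marker, and a mismatch scores
#' `log10(err / (1 - p_match))`. Maximal-scoring contiguous marker runs are
#' found by Ruzzo-Tompa maximal-scoring-subsequence decomposition and runs
#' with total score at or above `min_lod` are reported with their bp span.
#'
#' Allele frequencies are computed over the 8 founders themselves, so a
#' match at a common allele is weak evidence while a shared rare allele is
#' strong evidence.
#'
#' @param panel a `founder_panel`
#' @param min_lod minimum segment LOD (> 0); the reference analysis used 10
#' @param err allowed genotype discrepancy rate inside IBD segments
#'   (0 < err < 0.5); smaller values forbid internal mismatches
#' @return tibble of class `ibd_segments`: `founder1`, `founder2`, `chrom`,
#'   `start_bp`, `end_bp`, `lod`, `n_markers`
#' @export
find_ibd_segments <- function(panel, min_lod = 10, err = 0.01) {
  validate_panel(panel)
  if (min_lod <= 0) stop("`min_lod` must be > 0")
  if (err <= 0 || err >= 0.5) stop("`err` must be in (0, 0.5)")
  p1 <- rowMeans(panel$alleles)
  p_match <- p1^2 + (1 - p1)^2
  match_score <- log10((1 - err) / p_match)
  mismatch_score <- log10(err / (1 - p_match))
  founders <- do_founders()
  out <- list()
  for (i in 1:7) {
    for (j in (i + 1):8) {
      same <- panel$alleles[, i] == panel$alleles[, j]
      s <- ifelse(same, match_score, mismatch_score)
      runs <- ruzzo_tompa(s)
      runs <- runs[runs$score >= min_lod, , drop = FALSE]
      if (nrow(runs)) {
        out[[length(out) + 1]] <- tibble::tibble(
          founder1 = founders[i], founder2 = founders[j],
          chrom = panel$chrom,
          start_bp = panel$map$pos_bp[runs$start],
          end_bp = panel$map$pos_bp[runs$end],
          lod = runs$score,
          n_markers = runs$end - runs$start + 1L
        )
      }
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(founder1 = character(), founder2 = character(),
                   chrom = character(), start_bp = numeric(),
                   end_bp = numeric(), lod = numeric(), n_markers = integer())
  }
  res <- dplyr::arrange(res, founder1, founder2, start_bp)
  class(res) <- c("ibd_segments", class(res))
  res
}

# Ruzzo-Tompa all maximal scoring subsequences of a score vector.
# Returns a data.frame with 1-based start/end indices and total score.
ruzzo_tompa <- function(scores) {
  n <- length(scores)
  # stack of candidate subsequences: start, end, L (cum before start), R (cum at end)
  st_start <- st_end <- integer(n)
  st_L <- st_R <- numeric(n)
  top <- 0L
  cum <- 0
  for (k in seq_len(n)) {
    s <- scores[k]
    prev_cum <- cum
    cum <- cum + s
    if (s <= 0) next
    # new candidate [k, k]
    cs <- k; ce <- k; cL <- prev_cum; cR <- cum
    repeat {
      # find rightmost j on stack with L_j < cL
      j <- top
      while (j >= 1L && st_L[j] >= cL) j <- j - 1L
      if (j == 0L || st_R[j] >= cR) {
        # no qualifying j, or its cumulative maximum dominates: the candidate
        # joins the list as its own (so-far) maximal subsequence
        top <- top + 1L
        st_start[top] <- cs; st_end[top] <- ce
        st_L[top] <- cL; st_R[top] <- cR
        break
      } else {
        # extend the candidate left through subsequence j (and drop j and
        # everything after it from the list), then re-test
        cs <- st_start[j]
        cL <- st_L[j]
        top <- j - 1L
      }
    }
  }
  if (top == 0L) {
    return(data.frame(start = integer(), end = integer(), score = numeric()))
  }
  idx <- seq_len(top)
  data.frame(start = st_start[idx], end = st_end[idx],
             score = st_R[idx] - st_L[idx])
}

#' @export
print.ibd_segments <- function(x, ...) {
  cat(sprintf("<ibd_segments> %d segment(s) across %d founder pair(s)\n",
              nrow(x), dplyr::n_distinct(paste(x$founder1, x$founder2))))
  NextMethod()
}
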