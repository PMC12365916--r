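# --- expression-trait preparation -------------------------------------------

#' Filter genes for eQTL mapping
#'
#' Keeps genes whose summed counts across samples strictly exceed
#' `min_total` and which show at least `min_unique` distinct values —
#' guarding against low-information and heavily tied traits whose
#' non-normality could bias one genotyping method over another.
#'
#' @param counts samples x genes numeric matrix (column names = gene ids)
#' @param min_total total-count threshold (strict `>`)
#' @param min_unique minimum number of distinct values (`>=`)
#' @return character vector of retained gene ids, with attribute `report`
#'   (tibble: gene, total, n_unique, retained)
#' @export
filter_genes <- function(counts, min_total = 3000, min_unique = 100) {
  if (!length(counts)) stop("empty count matrix")
  counts <- as.matrix(counts)
  total <- colSums(counts)
  n_unique <- apply(counts, 2, function(x) length(unique(x)))
  keep <- total > min_total & n_unique >= min_unique
  out <- colnames(counts)[keep]
  attr(out, "report") <- tibble::tibble(gene = colnames(counts), total = total,
                                        n_unique = n_unique, retained = keep)
  out
}

#' Rank-Z (inverse-normal) transform
#'
#' Maps values to standard-normal quantiles of their mid-ranks:
#' `qnorm((rank - 0.5) / n)`, with ties sharing average ranks.
#'
#' @param values numeric vector (length >= 3, not constant)
#' @return transformed vector
#' @export
rankz <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  if (length(unique(values)) < 2) stop("constant trait cannot be rank-Z transformed")
  qnorm((rank(values, ties.method = "average") - 0.5) / length(values))
}

#' Variance-stabilize and rank-Z transform a count matrix
#'
#' Applies a log-based variance stabilization `log2(count / size_factor +
#' 1)` (size factors default to library size over its mean), filters genes
#' with [filter_genes()], and rank-Z transforms each retained gene. Rank-Z
#' absorbs any monotone difference between this stabilization and
#' alternatives, so downstream LODs are insensitive to the exact transform.
#'
#' @param counts samples x genes count matrix
#' @param size_factors optional per-sample size factors
#' @param min_total,min_unique passed to [filter_genes()] (applied to the
#'   raw counts)
#' @return list of class `prepared_traits`: `traits` (samples x retained
#'   genes, rank-Z scale), `genes`, `filter_report`
#' @export
prepare_traits <- function(counts, size_factors = NULL,
                           min_total = 3000, min_unique = 100) {
  counts <- as.matrix(counts)
  if (is.null(size_factors)) {
    ls <- rowSums(counts)
    size_factors <- ls / mean(ls)
  }
  keep <- filter_genes(counts, min_total, min_unique)
  if (!length(keep)) stop("no genes survive filtering")
  vst <- log2(sweep(counts[, keep, drop = FALSE], 1, size_factors, "/") + 1)
  traits <- apply(vst, 2, rankz)
  rownames(traits) <- rownames(counts)
  structure(list(traits = traits, genes = keep,
                 filter_report = attr(keep, "report")),
            class = "prepared_traits")
}

# --- kinship -----------------------------------------------------------------

#' Leave-one-chromosome-out kinship matrices
#'
#' Allele-probability kinship: for chromosome c,
#' `K_c = mean over markers m not on c of P_m P_m^T`, where `P_m` is the
#' samples x 8 founder allele-probability matrix at marker m. Identical
#' genomes give off-diagonal entries equal to their self-kinship.
#'
#' @param recons named list of `haplo_recon` objects, one per chromosome
#'   (>= 2 chromosomes)
#' @return named list of samples x samples kinship matrices (class
#'   `kinship_set`)
#' @export
loco_kinship <- function(recons) {
  if (length(recons) < 2) {
    stop("leave-one-chromosome-out kinship needs at least 2 chromosomes")
  }
  parts <- lapply(recons, function(r) {
    d <- dim(r$alleleprob)
    acc <- matrix(0, d[1], d[1])
    for (m in seq_len(d[2])) {
      acc <- acc + tcrossprod(matrix(r$alleleprob[, m, ], d[1], 8))
    }
    list(sum = acc, n = d[2])
  })
  ks <- lapply(seq_along(recons), function(c) {
    other <- parts[-c]
    tot <- Reduce(`+`, lapply(other, `[[`, "sum"))
    tot / sum(vapply(other, `[[`, numeric(1), "n"))
  })
  names(ks) <- names(recons)
  structure(ks, class = "kinship_set")
}

# --- the genome scan ---------------------------------------------------------

#' Haplotype-regression eQTL scan
#'
#' At each marker, compares the covariate-only model
#' `y = intercept + sex + generation` against the model adding the 8
#' founder allele probabilities (one founder column dropped for
#' identifiability): `LOD = (n/2) log10(RSS0 / RSS1)`. With `kinship`, a
#' one-random-effect mixed model is used: the null-model heritability is
#' estimated once per chromosome per trait by maximum likelihood in the
#' kinship eigenbasis, and generalized least squares with the implied
#' weights replaces ordinary least squares at every marker.
#'
#' @param traits samples x genes matrix on the rank-Z scale
#' @param recons a `haplo_recon` or named list of them (one per chromosome)
#' @param covariates tibble with `sex` and `generation` columns (rows in
#'   sample order)
#' @param kinship optional `kinship_set` from [loco_kinship()]
#' @return object of class `do_scan1`: list with `lod` (markers x genes),
#'   `map` (tibble: `chrom`, `marker`, `pos_bp`), `n`
#' @export
scan1 <- function(traits, recons, covariates, kinship = NULL) {
  if (inherits(recons, "haplo_recon") || !is.null(recons[["alleleprob"]])) {
    recons <- list(`1` = recons)
  }
  traits <- as.matrix(traits)
  n <- nrow(traits)
  X0 <- covariate_matrix(covariates, n)
  if (qr(X0)$rank < ncol(X0)) stop("rank-deficient covariates")
  lod_blocks <- list()
  map_blocks <- list()
  for (c_idx in seq_along(recons)) {
    r <- recons[[c_idx]]
    chrom <- names(recons)[c_idx] %||% as.character(c_idx)
    stopifnot(dim(r$alleleprob)[1] == n)
    if (is.null(kinship)) {
      yr <- traits
      X0r <- X0
      pr <- r$alleleprob
    } else {
      K <- kinship[[c_idx]]
      eig <- eigen(K, symmetric = TRUE)
      rot <- t(eig$vectors)
      yrot <- rot %*% traits
      X0rot <- rot %*% X0
      h2 <- vapply(seq_len(ncol(traits)), function(j) {
        null_h2(yrot[, j], X0rot, eig$values)
      }, numeric(1))
      # weights differ per trait; handle by scanning each trait separately
      lod <- matrix(NA_real_, dim(r$alleleprob)[2], ncol(traits))
      for (j in seq_len(ncol(traits))) {
        w <- 1 / sqrt(h2[j] * eig$values + (1 - h2[j]))
        prot <- array(NA_real_, dim(r$alleleprob))
        for (f in 1:8) prot[, , f] <- (rot %*% r$alleleprob[, , f]) * w
        lod[, j] <- scan_core(w * yrot[, j, drop = FALSE], X0rot * w, prot)
      }
      lod_blocks[[c_idx]] <- lod
      map_blocks[[c_idx]] <- dplyr::mutate(r$map, chrom = chrom, .before = 1)
      next
    }
    lod_blocks[[c_idx]] <- scan_core(yr, X0r, pr)
    map_blocks[[c_idx]] <- dplyr::mutate(r$map, chrom = chrom, .before = 1)
  }
  lod <- do.call(rbind, lod_blocks)
  map <- dplyr::bind_rows(map_blocks)
  colnames(lod) <- colnames(traits)
  rownames(lod) <- map$marker
  structure(list(lod = lod, map = map[, c("chrom", "marker", "pos_bp")], n = n),
            class = "do_scan1")
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  covariates <- tibble::as_tibble(covariates)
  X0 <- cbind(intercept = 1,
              sex = as.numeric(covariates$sex),
              generation = as.numeric(covariates$generation))
  stopifnot(nrow(X0) == n)
  X0
}

# OLS scan over all markers of one chromosome for a trait matrix;
# returns markers x genes LOD
scan_core <- function(Y, X0, probs) {
  n <- nrow(Y)
  M <- dim(probs)[2]
  q0 <- qr(X0)
  rss0 <- colSums(qr.resid(q0, Y)^2)
  lod <- matrix(NA_real_, M, ncol(Y))
  for (m in seq_len(M)) {
    X1 <- cbind(X0, matrix(probs[, m, 1:7], n, 7))
    q1 <- qr(X1)
    res <- qr.resid(q1, Y)
    rss1 <- colSums(res^2)
    lod[m, ] <- (n / 2) * (log10(rss0) - log10(pmax(rss1, 1e-300)))
  }
  lod
}

# ML heritability of the null model in the kinship eigenbasis
null_h2 <- function(y_rot, X_rot, lambda) {
  n <- length(y_rot)
  negll <- function(h2) {
    v <- h2 * lambda + (1 - h2)
    w <- 1 / sqrt(v)
    fit <- lm.fit(X_rot * w, y_rot * w)
    rss <- sum(fit$residuals^2)
    n * log(rss / n) + sum(log(v))
  }
  optimize(negll, c(0, 0.99))$minimum
}

#' Tidy and summarize scan results
#'
#' @param x a `do_scan1` object
#' @param ... unused
#' @return `tidy()`: long tibble (`gene`, `chrom`, `marker`, `pos_bp`,
#'   `lod`); `glance()`: one row per gene with the genome-wide maximum
#' @export
tidy.do_scan1 <- function(x, ...) {
  tibble::tibble(
    gene = rep(colnames(x$lod), each = nrow(x$lod)),
    chrom = rep(x$map$chrom, times = ncol(x$lod)),
    marker = rep(x$map$marker, times = ncol(x$lod)),
    pos_bp = rep(x$map$pos_bp, times = ncol(x$lod)),
    lod = as.vector(x$lod)
  )
}

#' @rdname tidy.do_scan1
#' @export
glance.do_scan1 <- function(x, ...) {
  idx <- apply(x$lod, 2, which.max)
  tibble::tibble(gene = colnames(x$lod),
                 max_lod = x$lod[cbind(idx, seq_len(ncol(x$lod)))],
                 chrom = x$map$chrom[idx],
                 peak_bp = x$map$pos_bp[idx])
}

#' @export
print.do_scan1 <- function(x, ...) {
  cat(sprintf("<do_scan1> %d markers x %d traits (n = %d); max LOD %.2f\n",
              nrow(x$lod), ncol(x$lod), x$n, max(x$lod)))
  invisible(x)
}

# --- peaks -------------------------------------------------------------------

#' Call eQTL peaks with support intervals
#'
#' Per trait and chromosome: local LOD maxima at or above `threshold` are
#' candidate peaks; adjacent candidates are merged unless the valley
#' between them drops at least `peakdrop` below the smaller summit. Each
#' retained peak gets a support interval extending to the outermost
#' contiguous markers within `drop` LOD of the summit (bounded by the
#' valleys separating it from neighbouring peaks).
#'
#' @param scan a `do_scan1` object
#' @param threshold minimum peak LOD (default 8)
#' @param peakdrop valley depth required to split twin summits (default 5)
#' @param drop LOD drop defining the support interval (default 1.5)
#' @return tibble of class `eqtl_peaks`: `gene`, `chrom`, `peak_marker`,
#'   `peak_bp`, `lod`, `ci_lo_bp`, `ci_hi_bp`
#' @export
find_peaks <- function(scan, threshold = 8, peakdrop = 5, drop = 1.5) {
  stopifnot(inherits(scan, "do_scan1"))
  out <- list()
  for (gene in colnames(scan$lod)) {
    for (ch in unique(scan$map$chrom)) {
      sel <- which(scan$map$chrom == ch)
      pk <- peaks_1d(scan$lod[sel, gene], scan$map$pos_bp[sel],
                     threshold, peakdrop, drop)
      if (nrow(pk)) {
        pk$gene <- gene
        pk$chrom <- ch
        pk$peak_marker <- scan$map$marker[sel][pk$peak_idx]
        out[[length(out) + 1]] <- pk
      }
    }
  }
  if (!length(out)) {
    res <- tibble::tibble(gene = character(), chrom = character(),
                          peak_marker = character(), peak_bp = numeric(),
                          lod = numeric(), ci_lo_bp = numeric(),
                          ci_hi_bp = numeric())
  } else {
    res <- dplyr::bind_rows(out) |>
      dplyr::select(gene, chrom, peak_marker, peak_bp, lod, ci_lo_bp, ci_hi_bp) |>
      dplyr::arrange(gene, chrom, peak_bp)
  }
  class(res) <- c("eqtl_peaks", class(res))
  res
}

peaks_1d <- function(lod, pos, threshold, peakdrop, drop) {
  empty <- tibble::tibble(peak_idx = integer(), peak_bp = numeric(),
                          lod = numeric(), ci_lo_bp = numeric(),
                          ci_hi_bp = numeric())
  n <- length(lod)
  left <- c(-Inf, lod[-n])
  right <- c(lod[-1], -Inf)
  maxima <- which(lod >= threshold & lod >= left & lod >= right)
  # collapse plateaus of equal height to their first marker
  if (length(maxima) > 1) {
    maxima <- maxima[c(TRUE, !(diff(maxima) == 1 &
                                 lod[maxima[-1]] == lod[maxima[-length(maxima)]]))]
  }
  if (!length(maxima)) return(empty)
  # merge twin summits separated by shallow valleys
  repeat {
    if (length(maxima) == 1) break
    merged <- FALSE
    for (k in seq_len(length(maxima) - 1)) {
      m1 <- maxima[k]; m2 <- maxima[k + 1]
      valley <- min(lod[m1:m2])
      if (min(lod[m1], lod[m2]) - valley < peakdrop) {
        keep <- if (lod[m1] >= lod[m2]) m1 else m2
        maxima <- c(maxima[seq_len(k - 1)], keep,
                    maxima[setdiff(seq_along(maxima), seq_len(k + 1))])
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # segment bounds: argmin valleys between retained peaks
  bounds <- c(0L, vapply(seq_len(length(maxima) - 1), function(k) {
    seg <- maxima[k]:maxima[k + 1]
    seg[which.min(lod[seg])]
  }, integer(1)), n + 1L)
  purrr::map(seq_along(maxima), function(k) {
    pk <- maxima[k]
    lo <- pk
    while (lo - 1 > bounds[k] && lod[lo - 1] >= lod[pk] - drop) lo <- lo - 1
    hi <- pk
    while (hi + 1 < bounds[k + 1] && lod[hi + 1] >= lod[pk] - drop) hi <- hi + 1
    tibble::tibble(peak_idx = pk, peak_bp = pos[pk], lod = lod[pk],
                   ci_lo_bp = pos[lo], ci_hi_bp = pos[hi])
  }) |> purrr::list_rbind()
}

# --- local eQTL and cross-method matching ------------------------------------

#' Flag and select local eQTL
#'
#' A peak is local when it lies on the gene's chromosome within `max_dist`
#' of the gene midpoint (inclusive). Per gene, the local peak closest to
#' the midpoint is marked `selected` for cross-method comparison.
#'
#' @param peaks an `eqtl_peaks` tibble
#' @param gene_midpoints tibble with `gene`, `chrom`, `midpoint_bp`
#' @param max_dist locality radius in bp (default 2 Mb)
#' @return `peaks` with added `midpoint_bp`, `dist_bp`, `is_local`,
#'   `selected`
#' @export
local_eqtl <- function(peaks, gene_midpoints, max_dist = 2e6) {
  res <- peaks |>
    dplyr::left_join(dplyr::rename(gene_midpoints, gene_chrom = chrom),
                     by = "gene") |>
    dplyr::mutate(dist_bp = abs(peak_bp - midpoint_bp),
                  is_local = !is.na(midpoint_bp) &
                    chrom == gene_chrom & dist_bp <= max_dist)
  res |>
    dplyr::group_by(gene) |>
    dplyr::mutate(selected = is_local &
                    dplyr::row_number() == ifelse(any(is_local),
                                                  which.min(ifelse(is_local, dist_bp, Inf)),
                                                  0L)) |>
    dplyr::ungroup() |>
    dplyr::select(-gene_chrom)
}

#' Match local eQTL catalogs one-to-one across methods
#'
#' Pairs the selected local eQTL of the same gene in two catalogs when
#' their support intervals overlap by at least 1 bp (on the same
#' chromosome), and reports per-pair differences.
#'
#' @param catalog_a,catalog_b tibbles of selected local eQTL (one row per
#'   gene; columns as from [local_eqtl()] with `selected = TRUE` rows)
#' @return list with `matched` (tibble: gene, lod_a, lod_b, delta_lod,
#'   delta_peak_bp, delta_width_bp), `unmatched_a`, `unmatched_b`
#'   (character vectors of gene ids)
#' @export
match_eqtl <- function(catalog_a, catalog_b) {
  for (cat in list(catalog_a, catalog_b)) {
    if (anyDuplicated(cat$gene)) stop("duplicate gene entries within a catalog")
  }
  j <- dplyr::inner_join(catalog_a, catalog_b, by = "gene",
                         suffix = c("_a", "_b"))
  overlap <- j$chrom_a == j$chrom_b &
    pmin(j$ci_hi_bp_a, j$ci_hi_bp_b) >= pmax(j$ci_lo_bp_a, j$ci_lo_bp_b)
  matched <- j[overlap, , drop = FALSE]
  list(
    matched = tibble::tibble(
      gene = matched$gene,
      lod_a = matched$lod_a, lod_b = matched$lod_b,
      delta_lod = matched$lod_b - matched$lod_a,
      delta_peak_bp = matched$peak_bp_b - matched$peak_bp_a,
      delta_width_bp = (matched$ci_hi_bp_b - matched$ci_lo_bp_b) -
        (matched$ci_hi_bp_a - matched$ci_lo_bp_a)
    ),
    unmatched_a = setdiff(catalog_a$gene, matched$gene),
    unmatched_b = setdiff(catalog_b$gene, matched$gene)
  )
}

#' Additive founder allele effects at a peak marker
#'
#' Regresses the trait on the 8 founder allele probabilities plus
#' covariates (no intercept; the probabilities sum to 1 and absorb it) and
#' returns the founder coefficients centered to sum to zero. Cross-method
#' effect similarity is [cosine_similarity()] applied to two such vectors.
#'
#' @param trait numeric vector (rank-Z scale)
#' @param probs_at_peak samples x 8 allele-probability matrix at the peak
#' @param covariates tibble with `sex`, `generation` (or `NULL`)
#' @return named length-8 vector of centered allele effects
#' @export
allele_effects <- function(trait, probs_at_peak, covariates = NULL) {
  n <- length(trait)
  stopifnot(nrow(probs_at_peak) == n, ncol(probs_at_peak) == 8)
  Xc <- if (is.null(covariates)) NULL else {
    cbind(sex = as.numeric(covariates$sex),
          generation = as.numeric(covariates$generation))
  }
  X <- cbind(probs_at_peak, Xc)
  q <- qr(X)
  if (q$rank < ncol(X)) stop("collinear allele probabilities at the peak marker")
  beta <- qr.coef(q, trait)[1:8]
  beta <- beta - mean(beta)
  names(beta) <- do_founders()
  beta
}
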