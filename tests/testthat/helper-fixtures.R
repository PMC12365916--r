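# deterministic hand-built panel: alternating allele patterns, exact map
make_test_panel <- function(n_markers = 100, chrom_length_bp = 1e6,
                            cM_per_Mb = 50) {
  pos <- as.integer(seq(1e4, chrom_length_bp - 1e4, length.out = n_markers))
  alleles <- matrix(0L, n_markers, 8, dimnames = list(NULL, LETTERS[1:8]))
  for (m in seq_len(n_markers)) {
    alleles[m, seq_len(1 + (m %% 6))] <- 1L  # 1..7 alt carriers, varies by marker
  }
  structure(list(
    chrom = "1",
    map = tibble::tibble(marker = paste0("m", seq_len(n_markers)),
                         pos_bp = pos, cM = pos / 1e6 * cM_per_Mb),
    alleles = alleles,
    ibd_truth = tibble::tibble(founder1 = character(), founder2 = character(),
                               start_bp = numeric(), end_bp = numeric()),
    chrom_length_bp = chrom_length_bp
  ), class = "founder_panel")
}

# hand-built mosaic with given homolog segment tables
make_mosaic <- function(h1, h2, n_gen = 41) {
  structure(list(h1, h2), class = "do_mosaic", n_gen = n_gen)
}

full_span_homolog <- function(founder, len) {
  tibble::tibble(start_bp = 1, end_bp = len, founder = founder)
}

# exhaustive path-sum posterior oracle over an explicit state support set,
# using the full 36x36 transition matrices (paths outside the support have
# zero emission and contribute nothing)
brute_posterior_support <- function(emissions, map, n_gen, support) {
  M <- nrow(emissions)
  trans <- lapply(diff(map$cM), dohaplo::transition_matrix, n_gen = n_gen)
  paths <- as.matrix(expand.grid(rep(list(support), M)))
  w <- apply(paths, 1, function(p) {
    pr <- (1 / 36) * emissions[1, p[1]]
    if (M > 1) {
      for (m in 2:M) pr <- pr * trans[[m - 1]][p[m - 1], p[m]] * emissions[m, p[m]]
    }
    pr
  })
  post <- matrix(0, M, 36)
  for (m in seq_len(M)) {
    for (s in support) post[m, s] <- sum(w[paths[, m] == s])
  }
  post / rowSums(post)
}

# O(n^2) best-scoring contiguous subinterval (exhaustive oracle)
brute_best_subinterval <- function(scores) {
  best <- -Inf
  n <- length(scores)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in i:n) {
      acc <- acc + scores[j]
      if (acc > best) best <- acc
    }
  }
  best
}

# truth-probability "reconstruction" stand-in usable by scan1()
truth_recon <- function(mosaics, panel) {
  n_s <- length(mosaics)
  ap <- array(NA_real_, c(n_s, nrow(panel$map), 8))
  for (i in seq_len(n_s)) ap[i, , ] <- mosaic_alleleprobs(mosaics[[i]], panel)
  dimnames(ap) <- list(sprintf("S%03d", seq_len(n_s)), panel$map$marker,
                       LETTERS[1:8])
  list(alleleprob = ap, map = panel$map)
}
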