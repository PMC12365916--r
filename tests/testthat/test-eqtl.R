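test_that("gene filters apply the total-count and uniqueness rules", {
  set.seed(1)
  counts <- cbind(
    g1 = rep(2999 / 10, 10),           # total 2999: dropped (strict >)
    g2 = c(rep(1000, 9), 1001),        # huge total but 2 unique: dropped
    g3 = sample(1000, 10) + 300        # passes both at relaxed thresholds
  )
  keep <- filter_genes(counts, min_total = 3000, min_unique = 3)
  expect_identical(as.vector(keep), "g3")

  # brute-force oracle on a random fixture
  m <- matrix(rpois(10 * 20, 50), 20, 10,
              dimnames = list(NULL, paste0("G", 1:10)))
  keep2 <- filter_genes(m, min_total = 1000, min_unique = 15)
  oracle <- colnames(m)[colSums(m) > 1000 &
                          apply(m, 2, function(x) length(unique(x))) >= 15]
  expect_identical(as.vector(keep2), oracle)
  expect_error(filter_genes(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("rank-Z maps values to exact normal quantiles", {
  out <- rankz(c(5, 1, 3))
  expect_equal(sort(out), qnorm(c(1, 3, 5) / 6))
  expect_equal(out[2], qnorm(1 / 6))  # smallest value -> lowest quantile

  x <- rnorm(101)
  expect_lt(abs(mean(rankz(x))), 1e-12)
  expect_true(all(diff(rankz(sort(x))) > 0))  # monotone in, monotone out
  expect_error(rankz(rep(1, 10)), "constant")
  expect_error(rankz(1:2), "at least 3")
})

test_that("LOCO kinship satisfies the decomposition and symmetry identities", {
  pan1 <- simulate_founder_panel(200, 10e6, chrom = "1", seed = 61)
  pan2 <- simulate_founder_panel(300, 15e6, chrom = "2", seed = 62)
  mos1 <- simulate_do_diplotypes(pan1, 41, 6, seed = 63)
  mos2 <- simulate_do_diplotypes(pan2, 41, 6, seed = 64)
  # duplicate sample 1 into slot 6
  mos1[[6]] <- mos1[[1]]
  mos2[[6]] <- mos2[[1]]
  recs <- list(`1` = truth_recon(mos1, pan1), `2` = truth_recon(mos2, pan2))
  ks <- loco_kinship(recs)
  expect_named(ks, c("1", "2"))
  for (K in ks) {
    expect_lt(max(abs(K - t(K))), 1e-12)
    # duplicated genomes: cross-entry equals self-entry
    expect_equal(K[1, 6], K[1, 1], tolerance = 1e-12)
  }
  # LOCO matrices are single-chromosome kinships here (2 chromosomes), and
  # their marker-weighted average equals the all-marker kinship
  all_k <- (ks[["2"]] * 200 + ks[["1"]] * 300) / 500
  direct <- Reduce(`+`, lapply(recs, function(r) {
    acc <- matrix(0, 6, 6)
    for (m in seq_len(dim(r$alleleprob)[2])) {
      acc <- acc + tcrossprod(matrix(r$alleleprob[, m, ], 6, 8))
    }
    acc
  })) / 500
  expect_lt(max(abs(all_k - direct)), 1e-10)

  expect_error(loco_kinship(recs[1]), "chromosome")
})

test_that("scan LOD matches the closed-form regression on a toy instance", {
  # 6 samples, 2 markers, known probabilities
  probs <- array(0, c(6, 2, 8))
  probs[, 1, 1] <- c(1, 1, 0.5, 0.5, 0, 0)
  probs[, 1, 2] <- 1 - probs[, 1, 1]
  probs[, 2, 3] <- c(0, 0.5, 1, 0, 0.5, 1)
  probs[, 2, 4] <- 1 - probs[, 2, 3]
  map <- tibble::tibble(marker = c("m1", "m2"), pos_bp = c(1e6, 2e6),
                        cM = c(0.5, 1.0))
  rec <- list(alleleprob = probs, map = map)
  y <- c(0.3, -1.2, 0.5, 1.4, -0.7, 0.1)
  covar <- tibble::tibble(sex = c(0, 1, 0, 1, 0, 1),
                          generation = c(40, 41, 42, 40, 41, 42))
  sc <- scan1(matrix(y, dimnames = list(NULL, "t")), rec, covar)
  # closed-form oracle via lm(): LOD = (n/2) log10(RSS0/RSS1)
  X0 <- cbind(1, covar$sex, covar$generation)
  rss0 <- sum(resid(lm(y ~ X0 - 1))^2)
  for (m in 1:2) {
    X1 <- cbind(X0, probs[, m, 1:7])
    rss1 <- sum(resid(lm(y ~ X1 - 1))^2)
    expect_equal(sc$lod[m, 1], 3 * log10(rss0 / rss1), tolerance = 1e-8)
  }

  # LOD is invariant to trait location/scale
  sc2 <- scan1(matrix(5 * y + 7, dimnames = list(NULL, "t")), rec, covar)
  expect_equal(sc$lod, sc2$lod, tolerance = 1e-8)

  # a perfect genetic signal saturates the LOD
  y_perfect <- 2 * probs[, 1, 1]
  sc3 <- scan1(matrix(y_perfect, dimnames = list(NULL, "t")), rec,
               covariates = NULL)
  expect_gt(sc3$lod[1, 1], 50)

  expect_error(scan1(matrix(y, dimnames = list(NULL, "t")), rec,
                     tibble::tibble(sex = rep(1, 6), generation = rep(41, 6))),
               "rank-deficient")
})

test_that("null traits rarely reach the detection threshold", {
  set.seed(71)
  pan <- simulate_founder_panel(400, 60e6, seed = 72)
  mos <- simulate_do_diplotypes(pan, 41, 100, seed = 73)
  rec <- truth_recon(mos, pan)
  y <- matrix(rnorm(100 * 60), 100, 60, dimnames = list(NULL, paste0("n", 1:60)))
  covar <- tibble::tibble(sex = rep(0:1, 50), generation = rep(40:44, 20))
  sc <- scan1(y, rec, covar)
  max_lod <- apply(sc$lod, 2, max)
  expect_gt(mean(max_lod < 8), 0.95)
})

test_that("kinship-adjusted scans stay close to OLS under no relatedness structure", {
  pan1 <- simulate_founder_panel(150, 10e6, chrom = "1", seed = 81)
  pan2 <- simulate_founder_panel(150, 10e6, chrom = "2", seed = 82)
  mos1 <- simulate_do_diplotypes(pan1, 41, 40, seed = 83)
  mos2 <- simulate_do_diplotypes(pan2, 41, 40, seed = 84)
  recs <- list(`1` = truth_recon(mos1, pan1), `2` = truth_recon(mos2, pan2))
  set.seed(85)
  y <- matrix(2 * recs[["1"]]$alleleprob[, 75, 1] + rnorm(40, 0, 0.3),
              dimnames = list(NULL, "g"))
  covar <- tibble::tibble(sex = rep(0:1, 20), generation = rep(40:43, 10))
  ks <- loco_kinship(recs)
  sc_ols <- scan1(y, recs, covar)
  sc_lmm <- scan1(y, recs, covar, kinship = ks)
  expect_equal(dim(sc_lmm$lod), dim(sc_ols$lod))
  expect_true(all(is.finite(sc_lmm$lod)))
  # both localize the planted signal to the same neighbourhood
  pos_lmm <- sc_lmm$map$pos_bp[which.max(sc_lmm$lod[, 1])]
  pos_ols <- sc_ols$map$pos_bp[which.max(sc_ols$lod[, 1])]
  expect_lt(abs(pos_lmm - pos_ols), 5e5)
  expect_equal(sc_lmm$map$chrom[which.max(sc_lmm$lod[, 1])], "1")
  expect_gt(max(sc_lmm$lod[, 1]), 8)
})

test_that("peak calling follows the threshold, peakdrop and interval rules", {
  map <- tibble::tibble(chrom = "1", marker = paste0("m", 1:7),
                        pos_bp = (1:7) * 1e6)
  mk <- function(lods) {
    structure(list(lod = matrix(lods, ncol = 1,
                                dimnames = list(map$marker, "g")),
                   map = map, n = 100), class = "do_scan1")
  }
  expect_equal(nrow(find_peaks(mk(rep(3, 7)))), 0L)

  one <- find_peaks(mk(c(2, 2, 9, 8, 2, 2, 2)))
  expect_equal(one$peak_bp, 3e6)
  expect_equal(c(one$ci_lo_bp, one$ci_hi_bp), c(3e6, 4e6))

  twin_shallow <- find_peaks(mk(c(2, 10, 6, 10, 2, 2, 2)))
  expect_equal(nrow(twin_shallow), 1L)  # valley drop 4 < peakdrop 5

  twin_deep <- find_peaks(mk(c(2, 10, 4, 10, 2, 2, 2)))
  expect_equal(nrow(twin_deep), 2L)     # valley drop 6 >= 5 splits
  expect_equal(twin_deep$peak_bp, c(2e6, 4e6))
})

test_that("local-eQTL selection and catalog matching are interval-exact", {
  peaks <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g3"),
    chrom = c("1", "1", "1", "2"),
    peak_marker = paste0("p", 1:4),
    peak_bp = c(10.5e6, 11.5e6, 30e6, 5e6),
    lod = c(12, 9, 10, 11),
    ci_lo_bp = c(10e6, 11e6, 29e6, 4e6),
    ci_hi_bp = c(11e6, 12e6, 31e6, 6e6)
  )
  mids <- tibble::tibble(gene = c("g1", "g2", "g3"), chrom = c("1", "1", "1"),
                         midpoint_bp = c(10e6, 28e6, 5e6))
  loc <- local_eqtl(peaks, mids)
  # 2 Mb is inclusive: g2 peak exactly 2 Mb away is local
  expect_true(loc$is_local[loc$gene == "g2"])
  # wrong chromosome is never local
  expect_false(loc$is_local[loc$gene == "g3"])
  # nearest of two local peaks is selected
  sel_g1 <- loc[loc$gene == "g1" & loc$selected, ]
  expect_equal(sel_g1$peak_bp, 10.5e6)

  cat_a <- loc[loc$selected, ]
  # self-match: everything pairs with zero deltas
  mm <- match_eqtl(cat_a, cat_a)
  expect_equal(nrow(mm$matched), nrow(cat_a))
  expect_true(all(mm$matched$delta_lod == 0 & mm$matched$delta_peak_bp == 0))

  # disjoint intervals for the same gene do not match
  cat_b <- dplyr::mutate(cat_a, ci_lo_bp = ci_hi_bp + 5e6,
                         ci_hi_bp = ci_hi_bp + 6e6)
  mm2 <- match_eqtl(cat_a, cat_b)
  expect_equal(nrow(mm2$matched), 0L)
  expect_setequal(mm2$unmatched_a, cat_a$gene)

  # brute-force interval-overlap oracle on a designed fixture
  a <- tibble::tibble(gene = paste0("x", 1:5), chrom = "1",
                      peak_bp = (1:5) * 1e6, lod = 10,
                      ci_lo_bp = c(1, 3, 5, 7, 9) * 1e6,
                      ci_hi_bp = c(2, 4, 6, 8, 10) * 1e6)
  b <- tibble::tibble(gene = paste0("x", 1:5), chrom = "1",
                      peak_bp = (1:5) * 1e6 + 5e5, lod = 9,
                      ci_lo_bp = c(2, 4.5, 5.5, 9, 11) * 1e6,
                      ci_hi_bp = c(3, 4.8, 6.5, 9.5, 12) * 1e6)
  mm3 <- match_eqtl(a, b)
  oracle <- a$gene[b$ci_lo_bp <= a$ci_hi_bp & b$ci_hi_bp >= a$ci_lo_bp]
  expect_setequal(mm3$matched$gene, oracle)

  expect_error(match_eqtl(dplyr::bind_rows(cat_a, cat_a), cat_a), "duplicate")
})

test_that("allele effects recover planted founder contrasts", {
  set.seed(91)
  pan <- simulate_founder_panel(50, 5e6, seed = 92)
  mos <- simulate_do_diplotypes(pan, 41, 120, seed = 93)
  rec <- truth_recon(mos, pan)
  probs <- matrix(rec$alleleprob[, 25, ], ncol = 8)
  y <- 2 * probs[, 1]
  eff <- allele_effects(y, probs)
  expect_equal(which.max(eff), 1L, ignore_attr = TRUE)
  # centered effects of a pure founder-A trait: A carries the signal
  expect_gt(eff["A"] - max(eff[-1]), 0.5)

  # identical genotypes give identical (cosine 1) effect estimates
  covar <- tibble::tibble(sex = rep(0:1, 60), generation = rep(40:45, 20))
  y2 <- y + rnorm(120, 0, 0.3)
  e1 <- allele_effects(y2, probs, covar)
  e2 <- allele_effects(y2, probs, covar)
  expect_equal(cosine_similarity(e1, e2), 1, tolerance = 1e-10)

  # collinear probability columns are rejected
  bad <- probs; bad[, 2] <- bad[, 1]
  bad[, 3:8] <- 0
  expect_error(allele_effects(y, bad), "collinear")
})

test_that("expression simulation respects the null and determinism contracts", {
  pan <- simulate_founder_panel(300, 40e6, seed = 95)
  mos <- simulate_do_diplotypes(pan, 41, 50, seed = 96)
  tr <- make_expression_truth(pan, 8, 4, seed = 97)
  expect_equal(sum(tr$causal), 4L)
  beta <- as.matrix(tr[, paste0("beta_", LETTERS[1:8])])
  expect_true(all(beta[!tr$causal, ] == 0))  # non-causal: zero effects
  expect_true(all(rowSums(beta != 0)[tr$causal] == 2))

  ex1 <- simulate_expression(mos, pan, tr, seed = 98)
  ex2 <- simulate_expression(mos, pan, tr, seed = 98)
  expect_identical(ex1$counts, ex2$counts)
  expect_equal(dim(ex1$counts), c(50L, 8L))

  expect_error(make_expression_truth(pan, 5, 2, dispersion = 0), "dispersion")
})
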