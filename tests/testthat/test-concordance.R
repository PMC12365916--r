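test_that("cosine similarity reproduces the canonical threshold scenario", {
  g <- c(0, 0, 0, 0, 0, 0, 0.5, 0.5)
  q <- c(0, 0, 0, 0, 0, 0.25, 0.25, 0.5)
  expect_equal(cosine_similarity(g, q), 0.8660254, tolerance = 1e-7)
  expect_equal(round(cosine_similarity(g, q), 2), 0.87)

  expect_equal(cosine_similarity(q, q), 1)
  expect_equal(cosine_similarity(c(1, rep(0, 7)), c(0, 1, rep(0, 6))), 0)
  expect_error(cosine_similarity(rep(0, 8), q), "zero")
})

test_that("map interpolation is linear in bp with row renormalization", {
  from_map <- tibble::tibble(marker = c("a", "b"), pos_bp = c(100, 300))
  probs <- rbind(c(1, 0, rep(0, 6)), c(0, 1, rep(0, 6)))

  # coincident target returns the identical row
  at_a <- interpolate_probs(probs, from_map,
                            tibble::tibble(marker = "x", pos_bp = 100))
  expect_equal(as.vector(at_a), probs[1, ])

  # midpoint of opposing unit rows -> (0.5, 0.5) after renormalization
  mid <- interpolate_probs(probs, from_map,
                           tibble::tibble(marker = "x", pos_bp = 200))
  expect_equal(as.vector(mid), c(0.5, 0.5, rep(0, 6)))

  # midpoint of two identical rows -> that row
  same <- rbind(c(0.25, 0.75, rep(0, 6)), c(0.25, 0.75, rep(0, 6)))
  mid2 <- interpolate_probs(same, from_map,
                            tibble::tibble(marker = "x", pos_bp = 150))
  expect_equal(as.vector(mid2), same[1, ])

  # outside the span: nearest end row
  out <- interpolate_probs(probs, from_map,
                           tibble::tibble(marker = c("l", "r"),
                                          pos_bp = c(10, 900)))
  expect_equal(out[1, ], probs[1, ], ignore_attr = TRUE)
  expect_equal(out[2, ], probs[2, ], ignore_attr = TRUE)

  # step dialect carries the previous row forward
  stp <- interpolate_probs(probs, from_map,
                           tibble::tibble(marker = "x", pos_bp = 299),
                           method = "step")
  expect_equal(as.vector(stp), probs[1, ])

  expect_error(interpolate_probs(probs[0, , drop = FALSE],
                                 from_map[0, ], from_map), "empty")
})

test_that("discordant regions are maximal sub-threshold runs", {
  map <- tibble::tibble(marker = paste0("m", 1:4), pos_bp = c(10, 20, 30, 40))
  track <- tibble::tibble(marker = map$marker, pos_bp = map$pos_bp,
                          cosine = c(0.99, 0.5, 0.5, 0.99))
  reg <- flag_discordant_regions(track, threshold = 0.87)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start_bp, 20)
  expect_equal(reg$end_bp, 30)
  expect_equal(reg$n_markers, 2L)
  expect_equal(reg$mean_cosine, 0.5)

  # all concordant -> empty
  ok <- tibble::tibble(pos_bp = map$pos_bp, cosine = rep(0.95, 4))
  expect_equal(nrow(flag_discordant_regions(ok)), 0L)

  # a single sub-threshold marker is a single-point region
  single <- tibble::tibble(pos_bp = map$pos_bp, cosine = c(0.9, 0.9, 0.3, 0.9))
  reg2 <- flag_discordant_regions(single)
  expect_equal(reg2$start_bp, reg2$end_bp)
  expect_equal(reg2$start_bp, 30)
})

test_that("IBD classification requires a qualifying overlap and founder pattern", {
  # region over markers 1-3 spanning 1-30 kb; G sees {B}, Q sees {B, C}
  probs_g <- matrix(0, 3, 8, dimnames = list(NULL, LETTERS[1:8]))
  probs_g[, "B"] <- 1
  probs_q <- probs_g / 2
  probs_q[, "C"] <- 0.5
  regions <- tibble::tibble(start_bp = 1000, end_bp = 30000, n_markers = 3L,
                            mean_cosine = 0.7, start_idx = 1L, end_idx = 3L)
  ibd_bc <- tibble::tibble(founder1 = "B", founder2 = "C", chrom = "1",
                           start_bp = 1, end_bp = 50000, lod = 20,
                           n_markers = 100L)
  cls <- classify_discordance_ibd(regions, ibd_bc, probs_g, probs_q)
  expect_true(cls$ibd_explained)
  expect_equal(cls$sharing_category, "classical-only")
  expect_equal(cls$founders_g, "B")
  expect_equal(cls$founders_q, "B,C")

  # no overlapping IBD segment
  far <- dplyr::mutate(ibd_bc, start_bp = 9e6, end_bp = 10e6)
  cls2 <- classify_discordance_ibd(regions, far, probs_g, probs_q)
  expect_false(cls2$ibd_explained)
  expect_equal(cls2$sharing_category, "none")

  # 9,999-base overlap misses the 10 kb floor; 10,000 makes it
  reg10 <- tibble::tibble(start_bp = 1, end_bp = 30000, n_markers = 3L,
                          mean_cosine = 0.7, start_idx = 1L, end_idx = 3L)
  ibd_short <- dplyr::mutate(ibd_bc, start_bp = 1, end_bp = 9999)
  expect_false(classify_discordance_ibd(reg10, ibd_short, probs_g,
                                        probs_q)$ibd_explained)
  ibd_exact <- dplyr::mutate(ibd_bc, start_bp = 1, end_bp = 10000)
  expect_true(classify_discordance_ibd(reg10, ibd_exact, probs_g,
                                       probs_q)$ibd_explained)

  # wild-derived pair F-G labels as PWK-CAST
  probs_g2 <- matrix(0, 3, 8); probs_g2[, 6] <- 1
  probs_q2 <- matrix(0, 3, 8); probs_q2[, 7] <- 1
  ibd_fg <- tibble::tibble(founder1 = "F", founder2 = "G", chrom = "1",
                           start_bp = 1, end_bp = 50000, lod = 15,
                           n_markers = 50L)
  cls3 <- classify_discordance_ibd(regions, ibd_fg, probs_g2, probs_q2)
  expect_equal(cls3$sharing_category, "PWK-CAST")

  expect_error(classify_discordance_ibd(regions, ibd_bc, probs_g, probs_q,
                                        prob_floor = 1), "prob_floor")
})

test_that("two reconstructions of the same error-free dense data agree perfectly", {
  pan <- simulate_founder_panel(600, 20e6, seed = 55)
  mos <- simulate_do_diplotypes(pan, 41, 2, seed = 56)
  truth <- t(vapply(mos, mosaic_doses, integer(600), panel = pan))
  # same underlying error-free genotypes fed through the sequencing route
  # (constant depth 40) and the array route (noiseless hard calls)
  alt <- matrix(as.integer(truth / 2 * 40), 2, 600,
                dimnames = list(c("S001", "S002"), pan$map$marker))
  dep <- dohaplo:::new_allele_depths(40L - alt, alt, pan$map, 40)
  rec_seq <- reconstruct_cohort(dep, pan, 41)
  calls <- structure(list(calls = truth, map = pan$map,
                          marker_indices = seq_len(600)),
                     class = "genotype_calls")
  rec_arr <- reconstruct_cohort(calls, pan, 41, array_error = 1e-6)
  for (i in 1:2) {
    tr <- concordance_track(matrix(rec_seq$alleleprob[i, , ], ncol = 8),
                            matrix(rec_arr$alleleprob[i, , ], ncol = 8),
                            pan$map)
    expect_gt(attr(tr, "mean_cosine"), 1 - 1e-6)
  }
})
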