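test_that("transition matrices have the right limits and stay stochastic", {
  expect_equal(transition_matrix(0, 41), diag(36), ignore_attr = TRUE)

  # d -> infinity: every row converges to the stationary diplotype
  # distribution of two independent uniform homologs (hom 1/64, het 2/64)
  st <- diplotype_states()
  stationary <- ifelse(st[, 1] == st[, 2], 1 / 64, 2 / 64)
  Tinf <- transition_matrix(1e7, 5)
  expect_equal(unname(t(Tinf)), matrix(stationary, 36, 36), tolerance = 1e-9)

  for (d in c(0.01, 0.5, 2, 37)) {
    expect_equal(rowSums(transition_matrix(d, 41)), rep(1, 36),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(transition_matrix(1, 0), "n_gen")
})

test_that("stationary distribution matches brute-force two-homolog enumeration", {
  # enumerate ordered homolog pairs under the per-homolog switch kernel and
  # collapse to unordered diplotypes
  d <- 3; n_gen <- 41
  r <- n_gen * d / 100
  T8 <- matrix((1 - exp(-r)) / 8, 8, 8)
  diag(T8) <- exp(-r) + (1 - exp(-r)) / 8
  st <- diplotype_states()
  T36 <- transition_matrix(d, n_gen)
  for (s in c(1, 9, 36, 17)) {
    a <- st[s, 1]; b <- st[s, 2]
    for (t in c(2, 9, 30, 36)) {
      c_ <- st[t, 1]; d_ <- st[t, 2]
      expected <- if (c_ == d_) T8[a, c_] * T8[b, d_] else {
        T8[a, c_] * T8[b, d_] + T8[a, d_] * T8[b, c_]
      }
      expect_equal(T36[s, t], expected)
    }
  }
})

test_that("emissions map observations through state doses", {
  panel_row <- c(1, 0, 0, 0, 0, 0, 0, 1)  # founders A and H carry alt
  e_flat <- emission_probs(c(1, 1, 1), panel_row, "sequencing")
  expect_equal(e_flat, rep(1, 36))

  e_arr <- emission_probs(2, panel_row, "array", error = 0)
  st <- diplotype_states()
  dose <- panel_row[st[, 1]] + panel_row[st[, 2]]
  expect_true(all(e_arr[dose == 2] == 1) && all(e_arr[dose != 2] == 0))

  # binomial likelihood-ratio oracle for ref=10, alt=0
  err <- 0.01
  gl <- dbinom(0, 10, c(err, 0.5, 1 - err))
  e_seq <- emission_probs(gl, panel_row, "sequencing")
  ratio <- e_seq[dose == 0][1] / e_seq[dose == 2][1]
  expect_equal(ratio, ((1 - err) / err)^10, tolerance = 1e-9)

  expect_error(emission_probs(c(1, 1, 1), panel_row, "banana"))
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(11)
  # 3 markers, emissions supported on 3 founders (6 diplotype states)
  support <- dohaplo::diplotype_state_index(c(1, 1, 1, 2, 2, 3), c(1, 2, 3, 2, 3, 3))
  map3 <- tibble::tibble(marker = c("a", "b", "c"), pos_bp = c(1, 2, 3) * 1e6,
                         cM = c(0, 0.8, 2.2))
  emis <- matrix(0, 3, 36)
  emis[, support] <- runif(18, 0.05, 1)
  post <- diplotype_posteriors(emis, map3, n_gen = 12)
  oracle <- brute_posterior_support(emis, map3, 12, support)
  expect_lt(max(abs(post - oracle)), 1e-10)

  # 4 markers, 2 founders (3 states)
  support2 <- dohaplo::diplotype_state_index(c(1, 1, 2), c(1, 2, 2))
  map4 <- tibble::tibble(marker = paste0("m", 1:4), pos_bp = (1:4) * 1e6,
                         cM = c(0, 0.5, 0.9, 2.0))
  emis4 <- matrix(0, 4, 36)
  emis4[, support2] <- runif(12, 0.05, 1)
  post4 <- diplotype_posteriors(emis4, map4, n_gen = 41)
  oracle4 <- brute_posterior_support(emis4, map4, 41, support2)
  expect_lt(max(abs(post4 - oracle4)), 1e-10)

  # prior only: single flat marker
  p1 <- diplotype_posteriors(matrix(1, 1, 36), map3[1, ], 41)
  expect_equal(as.vector(p1), rep(1 / 36, 36))

  expect_error(diplotype_posteriors(matrix(c(1, NA), 1, 36), map3[1, ], 41),
               "finite")
})

test_that("high-depth error-free data pins the posterior on the true state", {
  # founders kept mutually distinguishable (high-MAF markers); posterior
  # concentration is assessed away from true junctions, where the state is
  # unambiguous
  pan <- simulate_founder_panel(800, 30e6, maf_range = c(0.4, 0.5), seed = 21)
  mos <- simulate_do_diplotypes(pan, 41, 3, seed = 22)
  dep <- simulate_reads(mos, pan, coverage = 30, base_error = 0, seed = 23)
  rec <- reconstruct_cohort(dep, pan, 41, keep_diplotype = TRUE)
  hit <- tot <- 0
  for (i in 1:3) {
    truth <- dohaplo:::mosaic_states(mos[[i]], pan)
    junc <- sort(unique(unlist(lapply(mos[[i]], function(h) {
      h$end_bp[-nrow(h)]
    }))))
    dj <- vapply(pan$map$pos_bp, function(p) {
      if (length(junc)) min(abs(p - junc)) else Inf
    }, numeric(1))
    pmax_true <- vapply(seq_along(truth), function(m) {
      rec$diplotype[i, m, truth[m]]
    }, numeric(1))
    away <- dj > 5e5
    hit <- hit + sum(pmax_true[away] >= 0.999)
    tot <- tot + sum(away)
  }
  expect_gt(hit / tot, 0.97)
})

test_that("condensation conserves probability and handles pure states", {
  hom <- matrix(0, 1, 36); hom[1, 1] <- 1  # state AA
  expect_equal(as.vector(genoprob_to_alleleprob(hom)),
               c(1, 0, 0, 0, 0, 0, 0, 0))
  het <- matrix(0, 1, 36); het[1, 2] <- 1  # state AB
  expect_equal(as.vector(genoprob_to_alleleprob(het)),
               c(0.5, 0.5, 0, 0, 0, 0, 0, 0))
  unif <- matrix(1 / 36, 5, 36)
  expect_equal(unname(genoprob_to_alleleprob(unif)),
               matrix(1 / 8, 5, 8))
  rand <- matrix(runif(360), 10, 36)
  rand <- rand / rowSums(rand)
  expect_equal(rowSums(genoprob_to_alleleprob(rand)), rep(1, 10))
})

test_that("maximum-marginal calls respect the probability floor", {
  p <- matrix(1 / 36, 2, 36)
  expect_true(all(is.na(maxmarg_path(p))))

  point <- diag(36)[c(5, 17, 30), ]
  expect_equal(maxmarg_path(point), c(5L, 17L, 30L))

  row <- matrix(c(0.94, rep(0.06 / 35, 35)), 1, 36)
  expect_true(is.na(maxmarg_path(row, minprob = 0.95)))
  expect_equal(maxmarg_path(row, minprob = 0.90), 1L)

  # ties break to the lowest state index
  tie <- matrix(0, 1, 36); tie[1, c(3, 7)] <- 0.5
  expect_equal(maxmarg_path(tie, minprob = 0.51), NA_integer_)
  tie2 <- matrix(0, 1, 36); tie2[1, c(3, 7)] <- c(0.5, 0.5)
  expect_equal(maxmarg_path(tie2, minprob = 0.5 + 1e-9), NA_integer_)
  expect_error(maxmarg_path(p, minprob = 0.4), "minprob")
})

test_that("crossover location counts founder multiset changes", {
  map <- tibble::tibble(marker = paste0("m", 1:5), pos_bp = (1:5) * 1e6,
                        cM = (1:5) * 0.5)
  sAA <- diplotype_state_index(1, 1)
  sAB <- diplotype_state_index(1, 2)
  sCD <- diplotype_state_index(3, 4)
  sBC <- diplotype_state_index(2, 3)

  const <- locate_crossovers(rep(sAA, 5), map)
  expect_equal(const$n_crossovers, 0L)
  expect_equal(nrow(const$blocks), 1L)
  expect_equal(const$blocks$length_bp, 4e6)

  one <- locate_crossovers(c(sAA, sAA, sAB, sAB, sAB), map)
  expect_equal(one$n_crossovers, 1L)
  expect_equal(one$crossovers$left_bp, 2e6)
  expect_equal(one$crossovers$right_bp, 3e6)

  two <- locate_crossovers(c(sAB, sAB, sCD, sCD, sCD), map)
  expect_equal(two$n_crossovers, 2L)
  expect_equal(two$crossovers$n_changes, 2L)

  shared <- locate_crossovers(c(sAB, sBC, sBC, sBC, sBC), map)
  expect_equal(shared$n_crossovers, 1L)  # B shared between AB and BC

  # missing calls are bridged by the nearest called flanks
  bridged <- locate_crossovers(c(sAA, NA, NA, sAB, sAB), map)
  expect_equal(bridged$n_crossovers, 1L)
  expect_equal(bridged$crossovers$left_bp, 1e6)
  expect_equal(bridged$crossovers$right_bp, 4e6)

  # blocks always tile the marker span
  expect_equal(sum(two$blocks$length_bp), 4e6)
  expect_warning(empty <- locate_crossovers(rep(NA_integer_, 5), map), "uncalled")
  expect_equal(empty$n_crossovers, 0L)
})
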