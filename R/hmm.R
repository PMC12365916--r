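# --- 36-state founder diplotype HMM -----------------------------------------
#
# States are unordered founder pairs (8 homozygous + 28 heterozygous).
# Transitions treat the two homologs as independent founder-switch processes
# with rate proportional to genetic distance and outbreeding generation;
# emissions come from genotype likelihoods (sequencing) or hard calls
# (array) through the alternate-allele dose implied by each state.

# cached structural index matrices for building 36x36 transitions from an
# 8x8 homolog matrix
.hmm_cache <- new.env(parent = emptyenv())

transition_indices <- function() {
  if (!is.null(.hmm_cache$ti)) return(.hmm_cache$ti)
  st <- diplotype_states()
  A <- st[, 1]; B <- st[, 2]
  ti <- list(
    ac = outer(A, A, function(a, c) (c - 1L) * 8L + a),
    bd = outer(B, B, function(b, d) (d - 1L) * 8L + b),
    ad = outer(A, B, function(a, d) (d - 1L) * 8L + a),
    bc = outer(B, A, function(b, c) (c - 1L) * 8L + b),
    het = matrix(A != B, 36, 36, byrow = TRUE)
  )
  .hmm_cache$ti <- ti
  ti
}

#' Diplotype transition matrix over a genetic map interval
#'
#' Each homolog independently retains its founder with probability
#' `exp(-r) + (1 - exp(-r)) / 8` and switches to any specific other founder
#' with probability `(1 - exp(-r)) / 8`, where `r = n_gen * d_cM / 100`
#' scales the per-interval switch rate by the outbreeding generation.
#' Diplotype (unordered pair) transitions are the symmetrized product of
#' the two homolog processes.
#'
#' @param d_cM genetic distance of the interval in centiMorgans (>= 0)
#' @param n_gen outbreeding generation (>= 1); larger values put more
#'   recombinations per interval
#' @return 36 x 36 row-stochastic matrix in diplotype state order
#' @examples
#' T1 <- transition_matrix(1, 41)
#' range(rowSums(T1))
#' @export
transition_matrix <- function(d_cM, n_gen) {
  if (n_gen < 1) stop("`n_gen` must be >= 1")
  if (d_cM < 0) stop("`d_cM` must be >= 0")
  r <- n_gen * d_cM / 100
  er <- exp(-r)
  p_switch <- (1 - er) / 8
  p_stay <- er + p_switch
  T8 <- matrix(p_switch, 8, 8)
  diag(T8) <- p_stay
  ti <- transition_indices()
  T36 <- T8[ti$ac] * T8[ti$bd] + ti$het * (T8[ti$ad] * T8[ti$bc])
  dim(T36) <- c(36L, 36L)
  dimnames(T36) <- list(rownames(diplotype_states()), rownames(diplotype_states()))
  T36
}

#' Per-state emission probabilities at one marker
#'
#' Maps an observation to a likelihood per diplotype state through the
#' alternate-allele dose each state implies at the marker. For
#' `model = "sequencing"` the observation is a genotype-likelihood triple
#' (doses 0, 1, 2; any positive scale); for `model = "array"` it is a hard
#' call in {0, 1, 2} (or `NA` for missing), observed correctly with
#' probability `1 - error` and as either other dose with probability
#' `error / 2`.
#'
#' @param observation length-3 likelihood triple, or a single hard call
#' @param panel_row length-8 binary founder allele vector at the marker
#' @param model `"sequencing"` or `"array"`
#' @param error array call error probability (ignored for sequencing)
#' @return length-36 emission vector
#' @export
emission_probs <- function(observation, panel_row, model = c("sequencing", "array"),
                           error = 0.002) {
  model <- match.arg(model)
  st <- diplotype_states()
  dose <- panel_row[st[, 1]] + panel_row[st[, 2]]
  if (model == "sequencing") {
    stopifnot(length(observation) == 3)
    as.numeric(observation[dose + 1L])
  } else {
    if (length(observation) != 1) stop("array model expects a single hard call")
    if (is.na(observation)) return(rep(1, 36))
    lik <- rep(error / 2, 3)
    lik[observation + 1L] <- 1 - error
    lik[dose + 1L]
  }
}

#' Forward-backward posterior over diplotype states
#'
#' Runs the scaled forward-backward algorithm for one sample over a
#' chromosome, with a uniform initial distribution over the 36 states and
#' transitions built per inter-marker interval from the genetic map.
#'
#' @param emissions markers x 36 matrix of per-state emission likelihoods
#'   (any positive scale per row)
#' @param map tibble with at least a `cM` column (one row per marker)
#' @param n_gen outbreeding generation passed to [transition_matrix()]
#' @return markers x 36 matrix of posterior probabilities (rows sum to 1),
#'   with attribute `loglik` (natural-log marginal likelihood)
#' @export
diplotype_posteriors <- function(emissions, map, n_gen) {
  emissions <- as.matrix(emissions)
  if (!nrow(emissions)) stop("need at least one marker")
  if (!all(is.finite(emissions)) || any(emissions < 0)) {
    stop("emissions must be finite and non-negative")
  }
  trans <- interval_transitions(map, n_gen)
  res <- forward_backward_cohort(array(t(emissions), c(36L, 1L, nrow(emissions))), trans)
  post <- t(res$posterior[, 1, ])
  dimnames(post) <- list(map$marker, rownames(diplotype_states()))
  attr(post, "loglik") <- res$loglik[1]
  post
}

interval_transitions <- function(map, n_gen) {
  d <- diff(map$cM)
  if (any(d < 0)) stop("genetic map must be non-decreasing")
  lapply(d, transition_matrix, n_gen = n_gen)
}

# emissions: 36 x S x M array; trans: list of M-1 36x36 matrices
# returns posterior 36 x S x M and per-sample log-likelihood
forward_backward_cohort <- function(emissions, trans) {
  M <- dim(emissions)[3]
  S <- dim(emissions)[2]
  alpha <- array(NA_real_, c(S, 36L, M))
  loglik <- numeric(S)
  a <- t(matrix(emissions[, , 1], 36L, S)) / 36
  sc <- rowSums(a)
  if (any(sc <= 0)) stop("zero forward probability (inconsistent emissions)")
  a <- a / sc
  loglik <- log(sc)
  alpha[, , 1] <- a
  for (m in seq_len(M - 1)) {
    e <- t(matrix(emissions[, , m + 1], 36L, S))
    a <- (a %*% trans[[m]]) * e
    sc <- rowSums(a)
    if (any(sc <= 0)) stop("zero forward probability at marker ", m + 1)
    a <- a / sc
    loglik <- loglik + log(sc)
    alpha[, , m + 1] <- a
  }
  post <- array(NA_real_, c(36L, S, M))
  b <- matrix(1, S, 36)
  p <- matrix(alpha[, , M], S, 36)
  post[, , M] <- t(p / rowSums(p))
  for (m in rev(seq_len(M - 1))) {
    e <- t(matrix(emissions[, , m + 1], 36L, S))
    b <- (b * e) %*% t(trans[[m]])
    b <- b / rowSums(b)
    am <- matrix(alpha[, , m], S, 36)
    p <- am * b
    post[, , m] <- t(p / rowSums(p))
  }
  list(posterior = post, loglik = loglik)
}

#' Condense diplotype probabilities to founder allele probabilities
#'
#' The probability a sample carries founder i's haplotype at a locus is the
#' homozygous-state probability plus half of every heterozygous state
#' involving i, so allele-probability rows sum to 1 whenever the diplotype
#' rows do.
#'
#' @param diplotype_probs markers x 36 matrix (or samples x markers x 36
#'   array) of diplotype posteriors
#' @return markers x 8 matrix (or samples x markers x 8 array) of founder
#'   allele probabilities
#' @export
genoprob_to_alleleprob <- function(diplotype_probs) {
  K <- condensation_matrix()
  if (is.matrix(diplotype_probs)) {
    out <- diplotype_probs %*% K
    rownames(out) <- rownames(diplotype_probs)
    return(out)
  }
  stopifnot(length(dim(diplotype_probs)) == 3, dim(diplotype_probs)[3] == 36)
  d <- dim(diplotype_probs)
  flat <- matrix(diplotype_probs, d[1] * d[2], 36) %*% K
  array(flat, c(d[1], d[2], 8L),
        dimnames = c(dimnames(diplotype_probs)[1:2], list(do_founders())))
}

condensation_matrix <- function() {
  if (!is.null(.hmm_cache$K)) return(.hmm_cache$K)
  st <- diplotype_states()
  K <- matrix(0, 36, 8, dimnames = list(rownames(st), do_founders()))
  for (s in 1:36) {
    K[s, st[s, 1]] <- K[s, st[s, 1]] + 0.5
    K[s, st[s, 2]] <- K[s, st[s, 2]] + 0.5
  }
  .hmm_cache$K <- K
  K
}

#' Maximum-marginal diplotype path
#'
#' Calls the maximal-posterior state at each marker when that posterior
#' reaches `minprob`, otherwise leaves the marker uncalled (`NA`). Ties are
#' broken toward the lowest state index.
#'
#' @param diplotype_probs markers x 36 posterior matrix
#' @param minprob minimum posterior to call a state (in (0.5, 1])
#' @return integer vector of state indices (1--36) with `NA` where uncertain
#' @export
maxmarg_path <- function(diplotype_probs, minprob = 0.95) {
  if (minprob <= 0.5 || minprob > 1) stop("`minprob` must be in (0.5, 1]")
  diplotype_probs <- as.matrix(diplotype_probs)
  idx <- max.col(diplotype_probs, ties.method = "first")
  mx <- diplotype_probs[cbind(seq_along(idx), idx)]
  idx[mx < minprob] <- NA_integer_
  idx
}

#' Locate crossovers along a called diplotype path
#'
#' Walks adjacent called markers (uncalled markers are bridged by comparing
#' the nearest called flanks) and counts founder changes at each state
#' switch: states sharing one founder are a single crossover, disjoint
#' founder pairs are two. Each crossover is localized to the bp interval
#' between its flanking called markers; haplotype block lengths are
#' measured between successive boundary midpoints over the marker span.
#'
#' @param path integer state path from [maxmarg_path()] (may contain `NA`)
#' @param map tibble with `pos_bp` per marker
#' @return a list of class `crossover_set`: `crossovers` tibble
#'   (`left_bp`, `right_bp`, `n_changes`), `n_crossovers`, and `blocks`
#'   tibble (`start_bp`, `end_bp`, `length_bp`)
#' @export
locate_crossovers <- function(path, map) {
  stopifnot(length(path) == nrow(map), length(path) >= 2)
  called <- which(!is.na(path))
  if (!length(called)) {
    warning("all markers uncalled; empty crossover set")
    return(structure(list(
      crossovers = tibble::tibble(left_bp = numeric(), right_bp = numeric(),
                                  n_changes = integer()),
      n_crossovers = 0L,
      blocks = tibble::tibble(start_bp = numeric(), end_bp = numeric(),
                              length_bp = numeric())
    ), class = "crossover_set"))
  }
  st <- diplotype_states()
  s <- path[called]
  chg <- which(s[-1] != s[-length(s)])
  n_changes <- vapply(chg, function(k) {
    f_prev <- st[s[k], ]
    f_next <- st[s[k + 1], ]
    # multiset difference between founder pairs
    shared <- 0L
    rem <- f_next
    for (f in f_prev) {
      hit <- match(f, rem)
      if (!is.na(hit)) {
        shared <- shared + 1L
        rem <- rem[-hit]
      }
    }
    2L - shared
  }, integer(1))
  left <- map$pos_bp[called[chg]]
  right <- map$pos_bp[called[chg + 1]]
  span <- range(map$pos_bp)
  mids <- (left + right) / 2
  bounds <- c(span[1], mids, span[2])
  structure(list(
    crossovers = tibble::tibble(left_bp = left, right_bp = right,
                                n_changes = n_changes),
    n_crossovers = as.integer(sum(n_changes)),
    blocks = tibble::tibble(start_bp = bounds[-length(bounds)],
                            end_bp = bounds[-1],
                            length_bp = diff(bounds))
  ), class = "crossover_set")
}

#' @export
print.crossover_set <- function(x, ...) {
  cat(sprintf("<crossover_set> %d crossover(s) across %d boundary interval(s); %d block(s)\n",
              x$n_crossovers, nrow(x$crossovers), nrow(x$blocks)))
  invisible(x)
}
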