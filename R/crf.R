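# Linear-chain CRF: log-partition by the forward algorithm, gold-path
# scoring, Viterbi decoding, and the batched forward-backward recursions
# that supply gradients for training.
#
# Conventions: `emissions` is an L x K matrix of per-token tag scores; a CRF
# parameter set is list(transitions = K x K matrix with [i, j] the score of
# moving from tag i to tag j, start = K vector, end = K vector). The score
# of a tag path y is
#   start[y1] + sum_t emissions[t, yt] + sum_t transitions[y_{t-1}, yt] + end[yL],
# and the partition function sums exp(score) over all K^L paths. All
# computation is in log space with max-shifting, so emission magnitudes up
# to ~1e3 are safe.

#' Construct a CRF parameter set
#'
#' @param n_tags number of tags.
#' @param init `"zero"` (default) or `"uniform"` (small uniform noise).
#' @param seed RNG seed for `"uniform"` init.
#' @return list with `transitions`, `start`, `end`.
#' @export
crf_params <- function(n_tags, init = c("zero", "uniform"), seed = 1L) {
  init <- match.arg(init)
  if (init == "zero") {
    list(transitions = matrix(0, n_tags, n_tags),
         start = numeric(n_tags), end = numeric(n_tags))
  } else {
    with_seed(seed, list(
      transitions = matrix(stats::runif(n_tags^2, -0.1, 0.1), n_tags, n_tags),
      start = stats::runif(n_tags, -0.1, 0.1),
      end = stats::runif(n_tags, -0.1, 0.1)))
  }
}

#' Log-partition function of a linear-chain CRF
#'
#' `log sum over all tag paths of exp(path score)`, computed by the forward
#' algorithm in log space.
#'
#' @param emissions L x K matrix of per-token tag scores (L >= 1).
#' @param crf CRF parameter list (see [crf_params()]).
#' @return scalar log-partition value.
#' @export
crf_log_partition <- function(emissions, crf) {
  emissions <- rbind(emissions)
  L <- nrow(emissions)
  stopifnot(L >= 1L, ncol(emissions) == length(crf$start))
  alpha <- crf$start + emissions[1L, ]
  if (L > 1L) for (t in 2:L) {
    alpha <- col_logsumexp(alpha + crf$transitions) + emissions[t, ]
  }
  logsumexp(alpha + crf$end)
}

#' Score of one tag path under a linear-chain CRF
#'
#' @inheritParams crf_log_partition
#' @param tags integer vector of tag indices (length L).
#' @return scalar path score; always `<=` [crf_log_partition()].
#' @export
crf_path_score <- function(emissions, crf, tags) {
  emissions <- rbind(emissions)
  L <- nrow(emissions)
  stopifnot(length(tags) == L)
  s <- crf$start[tags[1L]] + crf$end[tags[L]] +
    sum(emissions[cbind(seq_len(L), tags)])
  if (L > 1L) s <- s + sum(crf$transitions[cbind(tags[-L], tags[-1L])])
  s
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Highest-scoring tag path and its score. Ties break toward the lower tag
#' index at every backtracking step.
#'
#' @inheritParams crf_log_partition
#' @return list with `tags` (integer path) and `score`.
#' @export
viterbi_decode <- function(emissions, crf) {
  emissions <- rbind(emissions)
  L <- nrow(emissions); K <- ncol(emissions)
  delta <- crf$start + emissions[1L, ]
  ptr <- matrix(0L, L, K)
  if (L > 1L) for (t in 2:L) {
    m <- delta + crf$transitions          # [i, j]: from i to j
    best <- apply(m, 2L, which.max)       # first max = lowest index
    delta <- m[cbind(best, seq_len(K))] + emissions[t, ]
    ptr[t, ] <- best
  }
  fin <- delta + crf$end
  path <- integer(L)
  path[L] <- which.max(fin)
  if (L > 1L) for (t in L:2) path[t - 1L] <- ptr[t, path[t]]
  list(tags = path, score = max(fin))
}

# ---- batched internals (training path) -------------------------------------
#
# emissions: list over t = 1..T of B x K matrices; mask: B x T 0/1;
# lengths: B integer vector. Only positions with mask 1 exist.

# Batched forward pass. Returns list(alphas = list of B x K, logZ = B vector).
crf_forward_batch <- function(emissions, crf, lengths) {
  Tm <- length(emissions)
  B <- nrow(emissions[[1L]]); K <- ncol(emissions[[1L]])
  alphas <- vector("list", Tm)
  alpha <- matrix(crf$start, B, K, byrow = TRUE) + emissions[[1L]]
  alphas[[1L]] <- alpha
  if (Tm > 1L) {
    cshift <- apply(crf$transitions, 2L, max)
    eT <- exp(sweep(crf$transitions, 2L, cshift, "-"))
    for (t in 2:Tm) {
      a <- apply(alpha, 1L, max)
      newa <- a + log(exp(alpha - a) %*% eT)
      newa <- sweep(newa, 2L, cshift, "+") + emissions[[t]]
      act <- as.numeric(lengths >= t)
      alpha <- newa * act + alpha * (1 - act)
      alphas[[t]] <- alpha
    }
  }
  fin <- alpha + matrix(crf$end, B, K, byrow = TRUE)
  m <- apply(fin, 1L, max)
  list(alphas = alphas, logZ = m + log(rowSums(exp(fin - m))))
}

# Batched backward pass. beta[[t]][b, i] = log sum over continuations from
# tag i at position t (excluding emission at t, including end scores).
crf_backward_batch <- function(emissions, crf, lengths) {
  Tm <- length(emissions)
  B <- nrow(emissions[[1L]]); K <- ncol(emissions[[1L]])
  betas <- vector("list", Tm)
  endrow <- matrix(crf$end, B, K, byrow = TRUE)
  beta <- endrow  # for sequences ending at Tm
  betas[[Tm]] <- beta
  if (Tm > 1L) {
    rshift <- apply(crf$transitions, 1L, max)
    eTt <- exp(crf$transitions - rshift)  # rows shifted; [i, j]
    for (t in (Tm - 1L):1L) {
      x <- emissions[[t + 1L]] + beta
      m <- apply(x, 1L, max)
      newb <- m + log(exp(x - m) %*% t(eTt))
      newb <- sweep(newb, 2L, rshift, "+")
      is_last <- as.numeric(lengths == t)
      act <- as.numeric(lengths > t)
      # positions with t > length are never read; keep finite zeros there
      beta <- newb * act + endrow * is_last
      betas[[t]] <- beta
    }
  }
  betas
}

# Gold path scores for a batch. gold: B x T integer matrix (indices valid
# where mask is 1).
crf_gold_score_batch <- function(emissions, crf, gold, lengths) {
  Tm <- length(emissions)
  B <- nrow(emissions[[1L]])
  s <- crf$start[gold[, 1L]] + emissions[[1L]][cbind(seq_len(B), gold[, 1L])]
  if (Tm > 1L) for (t in 2:Tm) {
    act <- lengths >= t
    if (!any(act)) break
    b <- which(act)
    s[b] <- s[b] + crf$transitions[cbind(gold[b, t - 1L], gold[b, t])] +
      emissions[[t]][cbind(b, gold[b, t])]
  }
  s + crf$end[gold[cbind(seq_len(B), lengths)]]
}

# Full CRF NLL gradient pass for one batch.
# Returns list(loss, d_emissions = list of B x K, d_trans, d_start, d_end).
# Loss is mean over the B sequences of (logZ - gold score); gradients are
# of that mean.
crf_nll_batch <- function(emissions, crf, gold, lengths) {
  Tm <- length(emissions)
  B <- nrow(emissions[[1L]]); K <- ncol(emissions[[1L]])
  fw <- crf_forward_batch(emissions, crf, lengths)
  betas <- crf_backward_batch(emissions, crf, lengths)
  gold_s <- crf_gold_score_batch(emissions, crf, gold, lengths)
  loss <- mean(fw$logZ - gold_s)

  d_emissions <- vector("list", Tm)
  d_trans <- matrix(0, K, K)
  d_start <- numeric(K)
  d_end <- numeric(K)
  expT <- exp(crf$transitions)
  for (t in seq_len(Tm)) {
    act <- lengths >= t
    gamma <- exp(fw$alphas[[t]] + betas[[t]] - fw$logZ)  # B x K marginals
    gamma[!act, ] <- 0
    ind <- matrix(0, B, K)
    b <- which(act)
    ind[cbind(b, gold[b, t])] <- 1
    d_emissions[[t]] <- (gamma - ind) / B
    if (t == 1L) d_start <- colSums(gamma - ind) / B
    # end-score gradient at each sequence's last position
    lastb <- which(lengths == t)
    if (length(lastb)) {
      al <- fw$alphas[[t]][lastb, , drop = FALSE]
      pe <- exp(al + matrix(crf$end, length(lastb), K, byrow = TRUE) -
                  fw$logZ[lastb])
      indl <- matrix(0, length(lastb), K)
      indl[cbind(seq_along(lastb), gold[cbind(lastb, t)])] <- 1
      d_end <- d_end + colSums(pe - indl) / B
    }
    if (t < Tm) {
      act2 <- which(lengths >= t + 1L)
      if (length(act2)) {
        # expected transition counts: exp(T)[i,j] * sum_b P[b,i] Q[b,j]
        al <- fw$alphas[[t]][act2, , drop = FALSE]
        u <- apply(al, 1L, max)
        nx <- emissions[[t + 1L]][act2, , drop = FALSE] +
          betas[[t + 1L]][act2, , drop = FALSE]
        v <- apply(nx, 1L, max)
        P <- exp(al - u) * exp(u + v - fw$logZ[act2])
        Q <- exp(nx - v)
        d_trans <- d_trans + expT * crossprod(P, Q)
        g2 <- gold[act2, c(t, t + 1L), drop = FALSE]
        tc <- tabulate((g2[, 1L] - 1L) * K + g2[, 2L], nbins = K * K)
        d_trans <- d_trans - matrix(tc, K, K, byrow = TRUE)
      }
    }
  }
  list(loss = loss, d_emissions = d_emissions,
       d_trans = d_trans / B, d_start = d_start, d_end = d_end)
}
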