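# Bidirectional LSTM encoder over trainable word embeddings, producing
# per-token tag emission scores for the CRF. Forward pass and
# backpropagation-through-time are written against BLAS-backed matrix ops;
# batches are time-step-major (a list over t of B x dim matrices).
#
# Gate layout in the concatenated 4H dimension: input (i), forget (f),
# cell candidate (g), output (o).

sigmoid <- function(x) 1 / (1 + exp(-x))

# Initialize all tagger parameters.
# embedding rows start at zero by default (embeddings are learned from
# scratch; rows differentiate through word-specific gradients); LSTM and
# projection weights use the customary U(-1/sqrt(H), 1/sqrt(H)).
init_params <- function(vocab_size, n_tags, config) {
  D <- config$embedding_dim; H <- config$hidden_dim
  r <- 1 / sqrt(H)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  with_seed(config$seed, {
    E <- if (config$embedding_init == "zero") matrix(0, vocab_size, D)
         else matrix(stats::runif(vocab_size * D, -r, r), vocab_size, D)
    list(
      E = E,
      Wf = u(D, 4 * H), Uf = u(H, 4 * H), bf = stats::runif(4 * H, -r, r),
      Wb = u(D, 4 * H), Ub = u(H, 4 * H), bb = stats::runif(4 * H, -r, r),
      Wo = matrix(stats::runif(2 * H * n_tags, -1 / sqrt(2 * H), 1 / sqrt(2 * H)),
                  2 * H, n_tags),
      bo = numeric(n_tags),
      trans = matrix(0, n_tags, n_tags),
      start = numeric(n_tags),
      end = numeric(n_tags)
    )
  })
}

# One-direction LSTM forward over a padded batch.
# Xe: list over t of B x D embedded inputs; mask: B x T.
# Padded positions carry hidden/cell state through unchanged, which makes
# per-batch padding equivalent to any global padding length.
lstm_forward_dir <- function(Xe, W, U, b, mask, reverse = FALSE) {
  Tm <- length(Xe); B <- nrow(Xe[[1L]]); H <- nrow(U)  # U is H x 4H
  steps <- if (reverse) Tm:1L else 1:Tm
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", Tm)
  brow <- matrix(b, B, 4L * H, byrow = TRUE)
  for (t in steps) {
    m <- mask[, t]
    hp <- h; cp <- cc
    z <- Xe[[t]] %*% W + hp %*% U + brow
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1L):(2L * H), drop = FALSE])
    g <- tanh(z[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigmoid(z[, (3L * H + 1L):(4L * H), drop = FALSE])
    cn <- f * cp + i * g
    hn <- o * tanh(cn)
    cc <- cn * m + cp * (1 - m)
    h <- hn * m + hp * (1 - m)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, cn = cn,
                       hp = hp, cp = cp, h = h)
  }
  cache
}

# BPTT for one direction. dH: list over t of B x H gradients w.r.t. the
# direction's hidden output h_t. Returns dW, dU, db and dX (list over t).
lstm_backward_dir <- function(Xe, W, U, cache, mask, dH, reverse = FALSE) {
  Tm <- length(Xe); B <- nrow(Xe[[1L]]); H <- nrow(U)
  steps <- if (reverse) 1:Tm else Tm:1L  # reverse of the forward order
  dW <- matrix(0, nrow(W), ncol(W)); dU <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- vector("list", Tm)
  dh_carry <- matrix(0, B, H); dc_carry <- matrix(0, B, H)
  for (t in steps) {
    s <- cache[[t]]
    m <- mask[, t]
    dh <- dH[[t]] + dh_carry
    dhn <- dh * m; dh_pass <- dh * (1 - m)
    dcn <- dc_carry * m; dc_pass <- dc_carry * (1 - m)
    tanc <- tanh(s$cn)
    do_ <- dhn * tanc
    dct <- dhn * s$o * (1 - tanc^2) + dcn
    di <- dct * s$g
    dg <- dct * s$i
    df <- dct * s$cp
    G <- cbind(di * s$i * (1 - s$i),
               df * s$f * (1 - s$f),
               dg * (1 - s$g^2),
               do_ * s$o * (1 - s$o))
    dW <- dW + crossprod(Xe[[t]], G)
    dU <- dU + crossprod(s$hp, G)
    db <- db + colSums(G)
    dX[[t]] <- tcrossprod(G, W)
    dh_carry <- tcrossprod(G, U) + dh_pass
    dc_carry <- dct * s$f + dc_pass
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# Full encoder forward: embeddings -> BiLSTM -> linear projection.
# idx: B x T integer matrix of vocab indices; mask: B x T.
# Returns emissions (list over t of B x K) and, if want_cache, everything
# the backward pass needs.
tagger_forward <- function(params, idx, mask, want_cache = FALSE) {
  Tm <- ncol(idx); B <- nrow(idx); H <- nrow(params$Uf)
  Xe <- lapply(seq_len(Tm), function(t) params$E[idx[, t], , drop = FALSE])
  cf <- lstm_forward_dir(Xe, params$Wf, params$Uf, params$bf, mask, reverse = FALSE)
  cb <- lstm_forward_dir(Xe, params$Wb, params$Ub, params$bb, mask, reverse = TRUE)
  born <- matrix(params$bo, B, length(params$bo), byrow = TRUE)
  emissions <- lapply(seq_len(Tm), function(t) {
    cbind(cf[[t]]$h, cb[[t]]$h) %*% params$Wo + born
  })
  if (!want_cache) return(list(emissions = emissions))
  list(emissions = emissions, Xe = Xe, cf = cf, cb = cb)
}

# Backward through projection, both LSTM directions and the embedding
# lookup. d_emissions: list over t of B x K. Returns gradient list matching
# the parameter layout (without CRF parts).
tagger_backward <- function(params, idx, mask, fwd, d_emissions) {
  Tm <- ncol(idx); B <- nrow(idx); H <- nrow(params$Uf)
  K <- ncol(params$Wo)
  dWo <- matrix(0, 2L * H, K); dbo <- numeric(K)
  dHf <- vector("list", Tm); dHb <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    de <- d_emissions[[t]]
    hcat <- cbind(fwd$cf[[t]]$h, fwd$cb[[t]]$h)
    dWo <- dWo + crossprod(hcat, de)
    dbo <- dbo + colSums(de)
    dh <- tcrossprod(de, params$Wo)
    dHf[[t]] <- dh[, 1:H, drop = FALSE]
    dHb[[t]] <- dh[, (H + 1L):(2L * H), drop = FALSE]
  }
  gf <- lstm_backward_dir(fwd$Xe, params$Wf, params$Uf, fwd$cf, mask, dHf,
                          reverse = FALSE)
  gb <- lstm_backward_dir(fwd$Xe, params$Wb, params$Ub, fwd$cb, mask, dHb,
                          reverse = TRUE)
  # embedding gradient: scatter-add token gradients by vocab index
  dXall <- do.call(rbind, lapply(seq_len(Tm), function(t) gf$dX[[t]] + gb$dX[[t]]))
  idxall <- as.vector(idx)
  dEcomp <- rowsum(dXall, group = idxall)
  dE <- matrix(0, nrow(params$E), ncol(params$E))
  dE[as.integer(rownames(dEcomp)), ] <- dEcomp
  list(E = dE, Wf = gf$dW, Uf = gf$dU, bf = gf$db,
       Wb = gb$dW, Ub = gb$dU, bb = gb$db, Wo = dWo, bo = dbo)
}

#' Emission scores for one report
#'
#' Runs the trained encoder (embeddings, BiLSTM, projection) on a single
#' tokenized report. Deterministic in evaluation mode (the model has no
#' stochastic layers).
#'
#' @param model an `ems_tagger` (see [train_tagger()]).
#' @param tokens character vector of normalized tokens.
#' @return length(tokens) x n_tags matrix of emission scores.
#' @export
tagger_emissions <- function(model, tokens) {
  stopifnot(length(tokens) >= 1L)
  idx <- matrix(encode_tokens(tokens, model$vocab), nrow = 1L)
  msk <- matrix(1, 1L, length(tokens))
  em <- tagger_forward(model$params, idx, msk)$emissions
  out <- do.call(rbind, lapply(em, function(e) e[1L, ]))
  colnames(out) <- model$tags
  out
}
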