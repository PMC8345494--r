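# Training loop for the BiLSTM-CRF tagger: Adam optimization of the CRF
# negative log-likelihood, per-epoch shuffling, dev-loss early stopping with
# best-epoch parameter restoration, and Viterbi prediction.

#' Tagger hyperparameter configuration
#'
#' Defaults are the reference configuration of the audit model: 100-d
#' trainable embeddings initialized at zero, 64 hidden units per direction
#' (the concatenated encoder output is 128-d), Adam at learning rate 0.001,
#' batch size 512, early stopping with patience 5 on the development loss,
#' and at most 300 epochs.
#'
#' @param embedding_dim word embedding dimension.
#' @param hidden_dim LSTM hidden units per direction.
#' @param batch_size reports per gradient step.
#' @param learning_rate Adam learning rate.
#' @param patience epochs without a new best dev loss before stopping.
#' @param max_epochs epoch cap.
#' @param seed RNG seed governing initialization and shuffling.
#' @param embedding_init `"zero"` (default) or `"uniform"`; zero is the
#'   reference behaviour, uniform speeds up early learning.
#' @param max_len truncation length for over-long reports (default 300).
#' @param stop_rule `"running_min"` (default): patience counts epochs since
#'   the best dev loss so far; `"previous"`: counts consecutive epochs whose
#'   loss did not improve on the immediately preceding epoch.
#' @return list of class `tagger_config`.
#' @export
tagger_config <- function(embedding_dim = 100L, hidden_dim = 64L,
                          batch_size = 512L, learning_rate = 0.001,
                          patience = 5L, max_epochs = 300L, seed = 42L,
                          embedding_init = c("zero", "uniform"),
                          max_len = 300L,
                          stop_rule = c("running_min", "previous")) {
  cfg <- list(embedding_dim = as.integer(embedding_dim),
              hidden_dim = as.integer(hidden_dim),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              patience = as.integer(patience),
              max_epochs = as.integer(max_epochs),
              seed = as.integer(seed),
              embedding_init = match.arg(embedding_init),
              max_len = as.integer(max_len),
              stop_rule = match.arg(stop_rule))
  stopifnot(cfg$embedding_dim > 0, cfg$hidden_dim > 0, cfg$batch_size > 0,
            cfg$learning_rate > 0, cfg$patience > 0, cfg$max_epochs > 0)
  structure(cfg, class = "tagger_config")
}

# Adam with bias correction; state holds first/second moment per parameter.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Early-stopping bookkeeping over a dev-loss trajectory
#'
#' Pure helper implementing the stopping rule: training stops after the
#' first epoch at which the dev loss has failed to make a new minimum for
#' `patience` consecutive epochs, and the parameters of the best epoch are
#' restored.
#'
#' @param dev_losses numeric vector of per-epoch dev losses.
#' @param patience non-improving epochs tolerated.
#' @param rule `"running_min"` or `"previous"` (see [tagger_config()]).
#' @return list with `stop_after` (epoch index at which training stops, or
#'   `length(dev_losses)` if never triggered) and `best` (epoch whose
#'   parameters are kept).
#' @export
early_stop_epoch <- function(dev_losses, patience, rule = "running_min") {
  best <- 1L; wait <- 0L
  for (e in seq_along(dev_losses)) {
    improved <- if (rule == "running_min") {
      e == 1L || dev_losses[e] < dev_losses[best]
    } else {
      e == 1L || dev_losses[e] < dev_losses[e - 1L]
    }
    if (improved) {
      wait <- 0L
      if (e == 1L || dev_losses[e] < dev_losses[best]) best <- e
    } else {
      wait <- wait + 1L
    }
    if (wait >= patience) return(list(stop_after = e, best = best))
  }
  list(stop_after = length(dev_losses), best = best)
}

# Encode a tagged corpus into index/tag-index vectors.
encode_corpus <- function(corpus, vocab, tags) {
  lapply(corpus, function(r) {
    ti <- match(r$tags %||% rep("O", length(r$tokens)), tags)
    if (anyNA(ti)) stop("report ", r$report_id, ": tag outside tag vocabulary")
    list(x = encode_tokens(r$tokens, vocab), y = ti)
  })
}

# Group encoded reports into length-sorted padded batches.
make_batches <- function(enc, batch_size, max_len) {
  ord <- order(lengths(lapply(enc, `[[`, "x")))
  chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
  lapply(chunks, function(ix) {
    xs <- lapply(enc[ix], `[[`, "x")
    ys <- lapply(enc[ix], `[[`, "y")
    pb <- pad_batch(xs, max_len = min(max(lengths(xs)), max_len))
    Tm <- ncol(pb$indices)
    gold <- matrix(1L, length(ix), Tm)
    for (i in seq_along(ys)) {
      l <- min(length(ys[[i]]), Tm)
      gold[i, seq_len(l)] <- ys[[i]][seq_len(l)]
    }
    list(idx = pb$indices, mask = pb$mask, gold = gold,
         lengths = pb$lengths, n = length(ix))
  })
}

# Mean CRF NLL of one padded batch under given parameters.
batch_loss <- function(params, batch) {
  fwd <- tagger_forward(params, batch$idx, batch$mask)
  crf <- list(transitions = params$trans, start = params$start, end = params$end)
  fw <- crf_forward_batch(fwd$emissions, crf, batch$lengths)
  gs <- crf_gold_score_batch(fwd$emissions, crf, batch$gold, batch$lengths)
  mean(fw$logZ - gs)
}

# Loss and full gradient for one batch.
batch_loss_grad <- function(params, batch) {
  fwd <- tagger_forward(params, batch$idx, batch$mask, want_cache = TRUE)
  crf <- list(transitions = params$trans, start = params$start, end = params$end)
  nb <- crf_nll_batch(fwd$emissions, crf, batch$gold, batch$lengths)
  enc_g <- tagger_backward(params, batch$idx, batch$mask, fwd, nb$d_emissions)
  grads <- c(enc_g, list(trans = nb$d_trans, start = nb$d_start, end = nb$d_end))
  list(loss = nb$loss, grads = grads)
}

# Report-weighted mean loss over a list of batches.
corpus_loss <- function(params, batches) {
  tot <- sum(vapply(batches, `[[`, 0L, "n"))
  sum(vapply(batches, function(b) batch_loss(params, b) * b$n, 0)) / tot
}

#' Train the BiLSTM-CRF tagger
#'
#' Builds the vocabulary from the training split only, optimizes the CRF
#' negative log-likelihood with Adam over length-bucketed padded batches,
#' evaluates the dev loss after every epoch, and stops early when the dev
#' loss has not reached a new minimum for `config$patience` consecutive
#' epochs (capped at `config$max_epochs`). The returned model carries the
#' parameters of the best-dev-loss epoch. Fully reproducible under
#' `config$seed`.
#'
#' @param train_corpus tagged [ems_corpus] (pseudo-labels or gold).
#' @param dev_corpus tagged [ems_corpus] used for early stopping.
#' @param config a [tagger_config()].
#' @param quiet suppress per-epoch messages (default `TRUE`).
#' @return an `ems_tagger`: list with `params`, `vocab`, `tags`, `config`
#'   and `history` (per-epoch train/dev loss data.frame).
#' @export
train_tagger <- function(train_corpus, dev_corpus, config = tagger_config(),
                         quiet = TRUE) {
  if (!length(train_corpus)) stop("empty training corpus")
  vocab <- build_vocab(train_corpus)
  tags <- tag_vocabulary()
  enc_tr <- encode_corpus(train_corpus, vocab, tags)
  enc_dv <- encode_corpus(dev_corpus, vocab, tags)
  tr_batches <- make_batches(enc_tr, config$batch_size, config$max_len)
  dv_batches <- make_batches(enc_dv, config$batch_size, config$max_len)
  params <- init_params(length(vocab), length(tags), config)
  state <- adam_init(params)
  best_params <- params
  best_loss <- Inf; best_epoch <- 0L; wait <- 0L; prev_loss <- Inf
  hist <- list()
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      tr_loss <- 0
      for (bi in sample(length(tr_batches))) {
        lg <- batch_loss_grad(params, tr_batches[[bi]])
        st <- adam_step(params, lg$grads, state, config$learning_rate)
        params <- st$params; state <- st$state
        tr_loss <- tr_loss + lg$loss * tr_batches[[bi]]$n
      }
      tr_loss <- tr_loss / length(enc_tr)
      dv_loss <- corpus_loss(params, dv_batches)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                  dev_loss = dv_loss)
      if (!quiet)
        message(sprintf("epoch %3d  train %.4f  dev %.4f", epoch, tr_loss, dv_loss))
      improved_best <- dv_loss < best_loss
      if (improved_best) {
        best_loss <- dv_loss; best_epoch <- epoch; best_params <- params
      }
      improved <- if (config$stop_rule == "running_min") improved_best
                  else dv_loss < prev_loss
      prev_loss <- dv_loss
      wait <- if (improved) 0L else wait + 1L
      if (wait >= config$patience) break
    }
  })
  structure(list(params = best_params, vocab = vocab, tags = tags,
                 config = config,
                 best_epoch = best_epoch,
                 history = do.call(rbind, hist)),
            class = "ems_tagger")
}

#' @export
print.ems_tagger <- function(x, ...) {
  cat("<ems_tagger> vocab ", length(x$vocab), ", tags ", length(x$tags),
      ", emb ", x$config$embedding_dim, ", hidden ", x$config$hidden_dim,
      "/direction, best epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Predict mentions for one tokenized report
#'
#' Encoder emissions are decoded with Viterbi; the tag path is converted to
#' mentions with stray-`I` repair (see [iob2_to_mentions()]).
#'
#' @param model an `ems_tagger`.
#' @param tokens character vector of normalized tokens.
#' @return list with `tags` (character IOB2) and `mentions` (data.frame,
#'   `source = "predicted"`); empty input yields an empty mention set.
#' @export
predict_mentions <- function(model, tokens) {
  if (!length(tokens))
    return(list(tags = character(0), mentions = mention_frame()))
  em <- tagger_emissions(model, tokens)
  crf <- list(transitions = model$params$trans, start = model$params$start,
              end = model$params$end)
  path <- viterbi_decode(em, crf)$tags
  tags <- model$tags[path]
  list(tags = tags, mentions = iob2_to_mentions(tags, source = "predicted"))
}

#' Predict IOB2 tags for every report in a corpus
#'
#' Batched Viterbi prediction.
#'
#' @param model an `ems_tagger`.
#' @param corpus an [ems_corpus].
#' @return the corpus with predicted `tags` on every report.
#' @export
predict_corpus <- function(model, corpus) {
  enc <- lapply(corpus, function(r) encode_tokens(r$tokens, model$vocab))
  ord <- order(lengths(enc))
  crf <- list(transitions = model$params$trans, start = model$params$start,
              end = model$params$end)
  out <- unclass(corpus)
  bs <- model$config$batch_size
  for (chunk in split(ord, ceiling(seq_along(ord) / bs))) {
    pb <- pad_batch(enc[chunk], max_len = max(lengths(enc[chunk])))
    em <- tagger_forward(model$params, pb$indices, pb$mask)$emissions
    for (i in seq_along(chunk)) {
      L <- pb$lengths[i]
      emi <- do.call(rbind, lapply(em[seq_len(L)], function(e) e[i, ]))
      path <- viterbi_decode(emi, crf)$tags
      out[[chunk[i]]]$tags <- model$tags[path]
    }
  }
  ems_corpus(out)
}

#' Mean CRF negative log-likelihood of a tagged corpus
#'
#' Always non-negative: the partition function dominates any single path
#' score. Useful for monitoring and testing; the training loop uses the
#' same computation internally.
#'
#' @param model an `ems_tagger`.
#' @param corpus tagged [ems_corpus].
#' @return mean per-report negative log-likelihood.
#' @export
tagger_loss <- function(model, corpus) {
  enc <- encode_corpus(corpus, model$vocab, model$tags)
  corpus_loss(model$params, make_batches(enc, model$config$batch_size,
                                         model$config$max_len))
}

#' Save / load a trained tagger
#'
#' A self-describing JSON checkpoint (format id `emsner-tagger-v1`) holding
#' the configuration, vocabulary, tag set and all parameter matrices.
#'
#' @param model an `ems_tagger`.
#' @param path file path.
#' @return `load_tagger()` returns the restored `ems_tagger`.
#' @export
save_tagger <- function(model, path) {
  obj <- list(format = "emsner-tagger-v1",
              config = unclass(model$config),
              vocab = names(model$vocab),
              tags = model$tags,
              best_epoch = model$best_epoch,
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                else list(dim = length(p), data = as.vector(p))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "emsner-tagger-v1"))
    stop("not an emsner tagger checkpoint: ", path)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L]) else p$data
  })
  vocab <- stats::setNames(seq_along(obj$vocab), obj$vocab)
  class(vocab) <- "ems_vocab"
  cfg <- obj$config
  cfg$embedding_init <- cfg$embedding_init %||% "zero"
  cfg <- do.call(tagger_config, cfg)
  structure(list(params = params, vocab = vocab, tags = obj$tags,
                 config = cfg, best_epoch = obj$best_epoch, history = NULL),
            class = "ems_tagger")
}
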