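# BiLSTM encoder contracts and the training loop.

tiny_corpus <- function(n = 30, seed = 5, misspell = 0) {
  g <- generate_corpus(generator_config(n_reports = n, misspell_prob = misspell,
                                        report_len = c(8L, 20L), seed = seed))
  label_corpus(g$corpus, default_lexicon())
}

tiny_config <- function(max_epochs = 3, patience = 2, ...) {
  tagger_config(embedding_dim = 12, hidden_dim = 8, batch_size = 16,
                embedding_init = "uniform", learning_rate = 0.01,
                max_epochs = max_epochs, patience = patience, seed = 7, ...)
}

test_that("encoder emissions have the contracted shape and determinism", {
  corp <- tiny_corpus()
  m <- train_tagger(corp[1:20], corp[21:25], tiny_config(max_epochs = 1))
  em1 <- tagger_emissions(m, c("pt", "alert"))
  expect_identical(dim(em1), c(2L, 35L))
  expect_true(all(is.finite(em1)))
  expect_identical(colnames(em1), tag_vocabulary())
  expect_identical(em1, tagger_emissions(m, c("pt", "alert")))
  # single token
  expect_identical(dim(tagger_emissions(m, "ecg")), c(1L, 35L))
  # permuting two distinct tokens changes the emissions
  a <- tagger_emissions(m, c("ecg", "aspirin", "given"))
  b <- tagger_emissions(m, c("aspirin", "ecg", "given"))
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("masked padding positions influence neither loss nor gradients", {
  corp <- tiny_corpus()
  m <- train_tagger(corp[1:20], corp[21:25], tiny_config(max_epochs = 1))
  enc <- emsner:::encode_corpus(corp[1:8], m$vocab, m$tags)
  batch <- emsner:::make_batches(enc, 8L, 300L)[[1]]
  base <- emsner:::batch_loss(m$params, batch)
  # randomize gold tags at masked positions: loss must be unchanged
  set.seed(1)
  pert <- batch
  masked <- which(pert$mask == 0)
  expect_gt(length(masked), 0)
  pert$gold[masked] <- sample.int(35L, length(masked), replace = TRUE)
  expect_identical(emsner:::batch_loss(m$params, pert), base)
  # padding to a longer length leaves the loss unchanged too
  pb <- pad_batch(lapply(enc[order(lengths(lapply(enc, `[[`, "x")))],
                         `[[`, "x"),
                  max_len = max(lengths(lapply(enc, `[[`, "x"))) + 7L)
  gold2 <- cbind(batch$gold,
                 matrix(1L, nrow(batch$gold), ncol(pb$indices) - ncol(batch$gold)))
  batch2 <- list(idx = pb$indices, mask = pb$mask, gold = gold2,
                 lengths = pb$lengths, n = batch$n)
  expect_equal(emsner:::batch_loss(m$params, batch2), base, tolerance = 1e-12)
})

test_that("the early-stopping rule stops and restores as specified", {
  # dev losses 5,4,4,4,4,4,4 with patience 5: stop after epoch 7, keep epoch 2
  r <- early_stop_epoch(c(5, 4, 4, 4, 4, 4, 4), patience = 5)
  expect_identical(r$stop_after, 7L)
  expect_identical(r$best, 2L)
  # a new minimum resets the counter
  r2 <- early_stop_epoch(c(5, 4, 4, 3, 3, 3, 3, 3), patience = 4)
  expect_identical(r2$stop_after, 8L)
  expect_identical(r2$best, 4L)
  # never triggered
  r3 <- early_stop_epoch(c(3, 2, 1), patience = 5)
  expect_identical(r3$stop_after, 3L)
  expect_identical(r3$best, 3L)
  # "previous" rule: a plateau below the minimum still counts as no decrease
  r4 <- early_stop_epoch(c(5, 4, 4, 4), patience = 3, rule = "previous")
  expect_identical(r4$stop_after, 4L)
  expect_identical(r4$best, 2L)
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  corp <- tiny_corpus(40)
  tr <- corp[1:32]; dv <- corp[33:40]
  cfg <- tiny_config(max_epochs = 6, patience = 6)
  m1 <- train_tagger(tr, dv, cfg)
  # monotone decrease over the first epochs of an easy fit
  expect_true(all(diff(m1$history$train_loss[1:4]) < 0))
  expect_lt(m1$history$train_loss[6], m1$history$train_loss[1])
  expect_lte(nrow(m1$history), cfg$max_epochs)
  m2 <- train_tagger(tr, dv, cfg)
  expect_identical(m1$history$dev_loss, m2$history$dev_loss)
  expect_identical(m1$params$Wo, m2$params$Wo)
  expect_error(train_tagger(ems_corpus(list()), dv, cfg), "empty")
})

test_that("the loss of a single-path problem is the CRF identity", {
  # one tag: partition equals the only path score, so the NLL is zero
  crf <- list(transitions = matrix(0, 1, 1), start = 0.7, end = -0.2)
  em <- matrix(2.5, 3, 1)
  expect_equal(crf_log_partition(em, crf),
               crf_path_score(em, crf, c(1L, 1L, 1L)))
})

test_that("a modest model learns the lexicon task end to end", {
  g_tr <- generate_corpus(generator_config(n_reports = 260, misspell_prob = 0,
                                           report_len = c(8L, 25L), seed = 19))
  lab <- label_corpus(g_tr$corpus, default_lexicon())
  cfg <- tagger_config(embedding_dim = 24, hidden_dim = 16, batch_size = 32,
                       embedding_init = "uniform", learning_rate = 0.015,
                       max_epochs = 50, patience = 50, seed = 2)
  m <- train_tagger(lab[1:230], lab[231:260], cfg)
  g_te <- generate_corpus(generator_config(n_reports = 40, misspell_prob = 0,
                                           report_len = c(8L, 25L), seed = 20))
  ev <- evaluate_corpus(g_te$corpus, predict_corpus(m, g_te$corpus))
  expect_gt(ev$metrics$type$f1, 0.8)
  # single-surface-form report is recovered as exactly that mention
  pm <- predict_mentions(m, tokenize("vitals stable aspirin"))
  expect_identical(pm$mentions$entity, "Aspirin")
  expect_identical(pm$mentions$start, 3L)
  expect_identical(pm$mentions$end, 3L)
  # empty report
  expect_identical(nrow(predict_mentions(m, character(0))$mentions), 0L)
})

test_that("checkpoints round-trip through JSON", {
  corp <- tiny_corpus()
  m <- train_tagger(corp[1:20], corp[21:25], tiny_config(max_epochs = 1))
  f <- withr::local_tempfile(fileext = ".json")
  save_tagger(m, f)
  m2 <- load_tagger(f)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_identical(names(m2$vocab), names(m$vocab))
  toks <- c("pt", "given", "aspirin")
  expect_identical(predict_mentions(m2, toks)$tags,
                   predict_mentions(m, toks)$tags)
  expect_error(load_tagger(withr::local_tempfile(lines = "{}",
                                                 fileext = ".json")),
               "checkpoint")
})
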