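# End-to-end orchestration (synth -> preprocess -> weak-label -> split ->
# train -> predict -> evaluate) and a plain-text mention renderer.

#' Run the full weak-supervision pipeline
#'
#' Generates (or loads) a corpus, weak-labels the training portion against
#' the lexicon, splits, trains the BiLSTM-CRF on the pseudo-labels, predicts
#' on the held-out test split, and scores the predictions against the gold
#' annotations in both evaluation modes. Every intermediate artifact is
#' written under `out_dir` when given.
#'
#' @param gen_config a [generator_config()] for the synthetic corpus.
#' @param tagger_cfg a [tagger_config()].
#' @param lexicon an [ems_lexicon()].
#' @param fractions train/dev/test split fractions.
#' @param split_seed seed for the corpus split.
#' @param out_dir optional directory for artifacts (CoNLL files, model
#'   checkpoint, evaluation table).
#' @param quiet passed to [train_tagger()].
#' @return list with `model`, `evaluation` (an `ems_evaluation` on the test
#'   split, gold vs. predicted), `splits`, and `stats` (training-split
#'   [corpus_stats()]).
#' @export
run_pipeline <- function(gen_config = generator_config(),
                         tagger_cfg = tagger_config(),
                         lexicon = default_lexicon(),
                         fractions = c(0.95, 0.025, 0.025),
                         split_seed = 1L, out_dir = NULL, quiet = TRUE) {
  gen <- generate_corpus(gen_config, lexicon)
  splits <- split_corpus(gen$corpus, fractions, seed = split_seed)
  weak_train <- label_corpus(splits$train, lexicon)
  weak_dev <- label_corpus(splits$dev, lexicon)
  model <- train_tagger(weak_train, weak_dev, tagger_cfg, quiet = quiet)
  pred_test <- predict_corpus(model, splits$test)
  ev <- evaluate_corpus(splits$test, pred_test)
  stats <- corpus_stats(weak_train)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_conll(weak_train, file.path(out_dir, "train.conll"))
    write_conll(weak_dev, file.path(out_dir, "dev.conll"))
    write_conll(splits$test, file.path(out_dir, "test_gold.conll"))
    write_conll(pred_test, file.path(out_dir, "test_pred.conll"))
    save_tagger(model, file.path(out_dir, "model.json"))
    utils::write.csv(stats, file.path(out_dir, "train_stats.csv"),
                     row.names = FALSE)
  }
  list(model = model, evaluation = ev, splits = splits, stats = stats)
}

#' Render mentions as inline bracketed annotations
#'
#' `"given aspirin"` with an Aspirin mention on token 2 renders as
#' `"given [aspirin|Aspirin]"`. Lossless: [strip_annotations()] recovers the
#' space-joined token text exactly.
#'
#' @param tokens character vector of tokens.
#' @param mentions non-overlapping mention data.frame.
#' @return a single annotated string.
#' @export
render_annotations <- function(tokens, mentions) {
  if (nrow(mentions)) {
    stopifnot(all(mentions$start >= 1L), all(mentions$end <= length(tokens)))
    mentions <- mentions[order(mentions$start), , drop = FALSE]
  }
  out <- character(0)
  i <- 1L; mi <- 1L
  n <- length(tokens)
  while (i <= n) {
    if (mi <= nrow(mentions) && mentions$start[mi] == i) {
      span <- paste(tokens[i:mentions$end[mi]], collapse = " ")
      out <- c(out, paste0("[", span, "|", mentions$entity[mi], "]"))
      i <- mentions$end[mi] + 1L
      mi <- mi + 1L
    } else {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = " ")
}

#' @rdname render_annotations
#' @param text an annotated string produced by `render_annotations()`.
#' @export
strip_annotations <- function(text) {
  gsub("\\[([^]|]*)\\|[^]]*\\]", "\\1", text)
}
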