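# MUC-5 categorization, SemEval'13 metrics and token-level metrics.

gold1 <- function(...) data.frame(start = 1L, end = 3L, entity = "ECG",
                                  source = "gold", stringsAsFactors = FALSE)

test_that("MUC-5 categorization follows the per-prediction rules", {
  g <- gold1()
  exact <- data.frame(start = 1L, end = 3L, entity = "ECG", source = "predicted")
  for (mode in c("strict", "type")) {
    ct <- muc_align(g, exact, mode)
    expect_identical(c(ct$COR, ct$INC, ct$MIS, ct$SPU), c(1L, 0L, 0L, 0L))
  }
  # overlapping span, correct type: COR under type matching, INC under strict
  part <- data.frame(start = 2L, end = 3L, entity = "ECG", source = "predicted")
  expect_identical(muc_align(g, part, "type")$COR, 1L)
  expect_identical(muc_align(g, part, "strict")$INC, 1L)
  # overlapping span, wrong type: INC in both
  wrong <- data.frame(start = 2L, end = 3L, entity = "Aspirin", source = "predicted")
  expect_identical(muc_align(g, wrong, "type")$INC, 1L)
  expect_identical(muc_align(g, wrong, "strict")$INC, 1L)
  # disjoint prediction: SPU + untouched gold MIS
  far <- data.frame(start = 6L, end = 7L, entity = "Aspirin", source = "predicted")
  ct <- muc_align(g, far, "strict")
  expect_identical(c(ct$MIS, ct$SPU), c(1L, 1L))
  # one gold counted against two overlapping predictions: POS exceeds gold
  two <- data.frame(start = c(1L, 3L), end = c(1L, 3L), entity = "ECG",
                    source = "predicted")
  ct <- muc_align(g, two, "type")
  expect_identical(ct$COR, 2L)
  expect_identical(ct$POS, 2L)
  expect_gt(ct$POS, nrow(g))
})

test_that("SemEval metrics reproduce the published MUC-5 score table", {
  # rows: COR, INC, MIS, SPU -> POS, ACT, P, R, F1
  rows <- list(
    list(c(1336, 0, 25, 26), c(1361, 1362), c(0.981, 0.982, 0.981)),  # type, BiLSTM-CRF
    list(c(1343, 0, 20, 31), c(1363, 1374), c(0.977, 0.985, 0.981)),  # type, BERT-base
    list(c(1343, 0, 20, 30), c(1363, 1373), c(0.978, 0.985, 0.982)),  # type, Clinical-BERT
    list(c(1329, 7, 25, 26), c(1361, 1362), c(0.976, 0.976, 0.976)),  # strict, BiLSTM-CRF
    list(c(1335, 8, 20, 31), c(1363, 1374), c(0.972, 0.979, 0.976)),  # strict, BERT-base
    list(c(1334, 9, 20, 30), c(1363, 1373), c(0.972, 0.979, 0.975)))  # strict, Clinical-BERT
  for (r in rows) {
    ct <- muc_counts(COR = r[[1]][1], INC = r[[1]][2], MIS = r[[1]][3],
                     SPU = r[[1]][4])
    expect_identical(c(ct$POS, ct$ACT), r[[2]])
    met <- semeval_metrics(ct)
    expect_identical(unname(met$rounded), r[[3]])
  }
  # degenerate counts give zero metrics with a warning
  expect_warning(semeval_metrics(muc_counts(MIS = 2)), "no predictions")
  z <- suppressWarnings(semeval_metrics(muc_counts()))
  expect_identical(unname(z$rounded), c(0, 0, 0))
})

test_that("muc counts agree with an independent naive scorer", {
  set.seed(41)
  ents <- c("ECG", "Aspirin", "Bleeding")
  for (i in 1:100) {
    g <- random_mentions(20, sample(1:4, 1), ents)
    p <- random_mentions(20, sample(1:4, 1), ents)
    for (mode in c("strict", "type")) {
      ours <- muc_align(g, p, mode)
      ref <- naive_muc(g, p, mode)
      expect_identical(c(ours$COR, ours$INC, ours$MIS, ours$SPU,
                         ours$POS, ours$ACT),
                       c(ref$COR, ref$INC, ref$MIS, ref$SPU, ref$POS, ref$ACT))
      # count conservation with PAR = 0
      expect_identical(ours$POS, ours$COR + ours$INC + ours$MIS)
      expect_identical(ours$ACT, ours$COR + ours$INC + ours$SPU)
    }
    # mode dominance
    expect_gte(muc_align(g, p, "type")$COR, muc_align(g, p, "strict")$COR)
  }
})

test_that("swapping gold and prediction swaps MIS/SPU and transposes P/R", {
  set.seed(43)
  for (i in 1:20) {
    g <- random_mentions(30, 4, c("ECG", "Aspirin"))
    # one-to-one perturbation: shift each span end by at most one token
    p <- g
    if (nrow(p)) {
      p$end <- pmax(p$start, p$end - sample(0:1, nrow(p), replace = TRUE))
      drop <- sample(c(TRUE, FALSE), nrow(p), replace = TRUE, prob = c(.2, .8))
      p <- p[!drop, , drop = FALSE]
    }
    a <- muc_align(g, p, "type"); b <- muc_align(p, g, "type")
    expect_identical(a$MIS, b$SPU)
    expect_identical(a$SPU, b$MIS)
    ma <- suppressWarnings(semeval_metrics(a))
    mb <- suppressWarnings(semeval_metrics(b))
    expect_equal(ma$precision, mb$recall)
    expect_equal(ma$recall, mb$precision)
  }
})

test_that("token metrics weight per-class scores by gold support, excluding O", {
  # perfect prediction
  tm <- token_metrics(c("B-ECG", "O", "B-Aspirin"), c("B-ECG", "O", "B-Aspirin"))
  expect_equal(unname(tm$weighted), c(1, 1, 1))
  # all-O prediction: zero recall
  tm <- token_metrics(c("B-ECG", "O"), c("O", "O"))
  expect_equal(unname(tm$weighted[["recall"]]), 0)
  # hand-worked two-class confusion:
  # gold B-ECG x3 (pred: 2 correct, 1 as B-Aspirin), gold B-Aspirin x1
  # (pred correct), plus one O predicted as B-ECG
  gold <- c("B-ECG", "B-ECG", "B-ECG", "B-Aspirin", "O")
  pred <- c("B-ECG", "B-ECG", "B-Aspirin", "B-Aspirin", "B-ECG")
  tm <- token_metrics(gold, pred)
  ecg <- tm$per_class[tm$per_class$class == "B-ECG", ]
  asp <- tm$per_class[tm$per_class$class == "B-Aspirin", ]
  expect_equal(ecg$precision, 2 / 3)   # 2 TP, 1 FP (the O token)
  expect_equal(ecg$recall, 2 / 3)      # 2 of 3 gold
  expect_equal(asp$precision, 1 / 2)   # 1 TP, 1 FP
  expect_equal(asp$recall, 1)
  wP <- (3 * (2 / 3) + 1 * (1 / 2)) / 4
  wR <- (3 * (2 / 3) + 1 * 1) / 4
  expect_equal(unname(tm$weighted[["precision"]]), wP)
  expect_equal(unname(tm$weighted[["recall"]]), wR)
  # O never contributes to classes or weights
  expect_false("O" %in% tm$per_class$class)
  expect_error(token_metrics(c("O", "O"), "O"), "length")
})

test_that("corpus evaluation composes counts, metrics and breakdowns", {
  g <- generate_corpus(generator_config(n_reports = 40, misspell_prob = 0,
                                        seed = 29))
  # identity: gold vs gold is perfect in both modes
  ev <- evaluate_corpus(g$corpus, g$corpus)
  expect_equal(ev$metrics$strict$f1, 1)
  expect_equal(ev$metrics$type$f1, 1)
  expect_identical(ev$counts$strict$INC + ev$counts$strict$MIS +
                     ev$counts$strict$SPU, 0L)
  # truncating every multi-token mention: type matching stays perfect,
  # strict does not
  trunc <- ems_corpus(lapply(g$corpus, function(r) {
    m <- iob2_to_mentions(r$tags, "gold")
    if (nrow(m)) m$end <- pmax(m$start, m$end - 1L)
    r$tags <- mentions_to_iob2(m, length(r$tokens))
    r
  }))
  ev2 <- evaluate_corpus(g$corpus, trunc)
  expect_equal(ev2$metrics$type$f1, 1)
  expect_lt(ev2$metrics$strict$f1, 1)
  expect_gte(ev2$metrics$type$f1, ev2$metrics$strict$f1)
  # mismatched ids are reported
  bad <- g$corpus; bad[[1]]$report_id <- "intruder"
  expect_error(evaluate_corpus(g$corpus, bad), "intruder")
})
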