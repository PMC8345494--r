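# Entity-level evaluation: MUC-5 category counts (COR/INC/PAR/MIS/SPU)
# under the SemEval-2013 strict and entity-type-matching modes, the derived
# precision/recall/F1, and O-excluded weighted token-level metrics.
#
# Categorization is prediction-driven: every prediction is independently
# classified against the gold annotations, and a gold mention untouched by
# any prediction counts as missing. One gold mention overlapped by several
# predictions is counted against each of them, so POS = COR + INC + MIS can
# exceed the number of gold mentions.

#' Construct a MUC-5 count object
#'
#' @param COR,INC,PAR,MIS,SPU non-negative category counts. Both implemented
#'   modes never produce PAR; the slot exists for completeness.
#' @return list of class `muc_counts` with derived `POS = COR+INC+PAR+MIS`
#'   and `ACT = COR+INC+PAR+SPU`.
#' @export
muc_counts <- function(COR = 0L, INC = 0L, PAR = 0L, MIS = 0L, SPU = 0L) {
  x <- list(COR = COR, INC = INC, PAR = PAR, MIS = MIS, SPU = SPU)
  stopifnot(all(vapply(x, function(v) v >= 0, TRUE)))
  x$POS <- COR + INC + PAR + MIS
  x$ACT <- COR + INC + PAR + SPU
  structure(x, class = "muc_counts")
}

#' @export
print.muc_counts <- function(x, ...) {
  cat(sprintf("COR %d  INC %d  PAR %d  MIS %d  SPU %d  (POS %d, ACT %d)\n",
              x$COR, x$INC, x$PAR, x$MIS, x$SPU, x$POS, x$ACT))
  invisible(x)
}

#' @export
`+.muc_counts` <- function(a, b) {
  muc_counts(a$COR + b$COR, a$INC + b$INC, a$PAR + b$PAR,
             a$MIS + b$MIS, a$SPU + b$SPU)
}

spans_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

#' MUC-5 categorization of predictions against gold mentions
#'
#' Per prediction: an exact span-and-type match is COR in both modes; a
#' same-type prediction whose span merely overlaps a gold mention is COR
#' under entity-type matching but INC under strict evaluation; an
#' overlapping prediction of the wrong type is INC in both; a prediction
#' overlapping no gold mention is SPU. Per gold mention: MIS if no
#' prediction overlaps it. A prediction overlapping several gold mentions is
#' categorized against the first overlapping gold in span order.
#'
#' @param gold,pred mention data.frames for one report (`start`, `end`,
#'   `entity`).
#' @param mode `"strict"` or `"type"` (entity type matching).
#' @return a [muc_counts()].
#' @export
muc_align <- function(gold, pred, mode = c("strict", "type")) {
  mode <- match.arg(mode)
  gold <- gold[order(gold$start, gold$end), , drop = FALSE]
  COR <- INC <- SPU <- 0L
  touched <- rep(FALSE, nrow(gold))
  for (i in seq_len(nrow(pred))) {
    ps <- pred$start[i]; pe <- pred$end[i]; pent <- pred$entity[i]
    ov <- which(spans_overlap(gold$start, gold$end, ps, pe))
    if (!length(ov)) { SPU <- SPU + 1L; next }
    touched[ov] <- TRUE
    g <- ov[1L]
    exact <- gold$start[g] == ps && gold$end[g] == pe
    same_type <- gold$entity[g] == pent
    if (same_type && (exact || mode == "type")) COR <- COR + 1L
    else INC <- INC + 1L
  }
  muc_counts(COR = COR, INC = INC, MIS = sum(!touched), SPU = SPU)
}

#' SemEval'13 metrics from MUC-5 counts
#'
#' `P = COR/ACT`, `R = COR/POS`, `F1 = 2PR/(P+R)`. A zero denominator gives
#' a zero metric with a warning. Rounded values use half-up rounding to 3
#' decimals, matching how the metrics are conventionally printed.
#'
#' @param counts a [muc_counts()].
#' @return list of class `entity_metrics`: `precision`, `recall`, `f1`
#'   (exact) and `rounded` (named vector at 3 decimals).
#' @export
semeval_metrics <- function(counts) {
  stopifnot(inherits(counts, "muc_counts"))
  if (counts$ACT == 0) {
    warning("no predictions (ACT = 0); precision defined as 0")
    P <- 0
  } else P <- counts$COR / counts$ACT
  if (counts$POS == 0) {
    warning("no possible annotations (POS = 0); recall defined as 0")
    R <- 0
  } else R <- counts$COR / counts$POS
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(list(precision = P, recall = R, f1 = F1,
                 rounded = c(precision = round_half_up(P, 3),
                             recall = round_half_up(R, 3),
                             f1 = round_half_up(F1, 3)),
                 counts = counts),
            class = "entity_metrics")
}

#' @export
print.entity_metrics <- function(x, ...) {
  cat(sprintf("P %.3f  R %.3f  F1 %.3f\n", x$rounded["precision"],
              x$rounded["recall"], x$rounded["f1"]))
  invisible(x)
}

#' O-excluded weighted token-level metrics
#'
#' Precision, recall and F1 per token class from the token-level confusion,
#' averaged over all classes except `O` with weights equal to each class's
#' gold support. `O` contributes neither a class metric nor weight.
#'
#' @param gold_tags,pred_tags character vectors (or lists of per-report
#'   vectors) of IOB2 tags; lengths must agree.
#' @return list with `per_class` (data.frame: class, support, precision,
#'   recall, f1) and `weighted` (named vector).
#' @export
token_metrics <- function(gold_tags, pred_tags) {
  if (is.list(gold_tags)) gold_tags <- unlist(gold_tags)
  if (is.list(pred_tags)) pred_tags <- unlist(pred_tags)
  if (length(gold_tags) != length(pred_tags))
    stop("gold and predicted tag sequences differ in length")
  classes <- setdiff(sort(unique(gold_tags), method = "radix"), "O")
  rows <- lapply(classes, function(cl) {
    tp <- sum(gold_tags == cl & pred_tags == cl)
    fp <- sum(pred_tags == cl & gold_tags != cl)
    fn <- sum(gold_tags == cl & pred_tags != cl)
    P <- if (tp + fp > 0) tp / (tp + fp) else 0
    R <- if (tp + fn > 0) tp / (tp + fn) else 0
    data.frame(class = cl, support = tp + fn, precision = P, recall = R,
               f1 = if (P + R > 0) 2 * P * R / (P + R) else 0,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows) %||%
    data.frame(class = character(0), support = integer(0),
               precision = numeric(0), recall = numeric(0), f1 = numeric(0))
  w <- per_class$support
  weighted <- if (length(w) && sum(w) > 0) {
    c(precision = sum(per_class$precision * w) / sum(w),
      recall = sum(per_class$recall * w) / sum(w),
      f1 = sum(per_class$f1 * w) / sum(w))
  } else c(precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  list(per_class = per_class, weighted = weighted)
}

#' Evaluate a predicted corpus against a gold corpus
#'
#' Aligns reports by id, derives mentions from the IOB2 tags of both
#' corpora, accumulates MUC-5 counts in both evaluation modes, computes
#' SemEval'13 metrics, O-excluded weighted token metrics, and a per-entity
#' breakdown under entity-type matching.
#'
#' @param gold_corpus,pred_corpus tagged [ems_corpus] objects with matching
#'   report ids.
#' @return list of class `ems_evaluation`: `counts` and `metrics` (one per
#'   mode), `token`, `per_entity`.
#' @export
evaluate_corpus <- function(gold_corpus, pred_corpus) {
  gids <- vapply(gold_corpus, `[[`, "", "report_id")
  pids <- vapply(pred_corpus, `[[`, "", "report_id")
  if (!identical(sort(gids), sort(pids))) {
    off <- union(setdiff(gids, pids), setdiff(pids, gids))
    stop("report id mismatch between gold and predicted corpora: ",
         paste(utils::head(off, 10L), collapse = ", "))
  }
  pred_corpus <- pred_corpus[match(gids, pids)]
  gm <- lapply(gold_corpus, function(r) iob2_to_mentions(r$tags, source = "gold"))
  pm <- lapply(pred_corpus, function(r) iob2_to_mentions(r$tags))
  counts <- list()
  metrics <- list()
  for (mode in c("strict", "type")) {
    cl <- mapply(function(g, p) muc_align(g, p, mode = mode), gm, pm,
                 SIMPLIFY = FALSE)
    tot <- Reduce(`+`, cl, muc_counts())
    counts[[mode]] <- tot
    metrics[[mode]] <- semeval_metrics(tot)
  }
  ents <- entity_schema()$entity
  per_entity <- do.call(rbind, lapply(ents, function(e) {
    cl <- mapply(function(g, p)
      muc_align(g[g$entity == e, , drop = FALSE],
                p[p$entity == e, , drop = FALSE], mode = "type"),
      gm, pm, SIMPLIFY = FALSE)
    tot <- Reduce(`+`, cl, muc_counts())
    if (tot$POS == 0 && tot$ACT == 0) return(NULL)
    met <- suppressWarnings(semeval_metrics(tot))
    data.frame(entity = e, COR = tot$COR, INC = tot$INC, MIS = tot$MIS,
               SPU = tot$SPU, POS = tot$POS, ACT = tot$ACT,
               precision = met$rounded["precision"],
               recall = met$rounded["recall"], f1 = met$rounded["f1"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(counts = counts, metrics = metrics,
                 token = token_metrics(lapply(gold_corpus, `[[`, "tags"),
                                       lapply(pred_corpus, `[[`, "tags")),
                 per_entity = per_entity),
            class = "ems_evaluation")
}

#' @export
print.ems_evaluation <- function(x, ...) {
  tab <- do.call(rbind, lapply(c("type", "strict"), function(m) {
    ct <- x$counts[[m]]; mt <- x$metrics[[m]]
    data.frame(mode = if (m == "type") "Entity Type Matching" else "Strict Evaluation",
               COR = ct$COR, INC = ct$INC, MIS = ct$MIS, SPU = ct$SPU,
               POS = ct$POS, ACT = ct$ACT,
               precision = sprintf("%.3f", mt$rounded["precision"]),
               recall = sprintf("%.3f", mt$rounded["recall"]),
               f1 = sprintf("%.3f", mt$rounded["f1"]))
  }))
  print(tab, row.names = FALSE)
  if (!all(is.na(x$token$weighted)))
    cat(sprintf("token-level (O excluded, weighted): P %.3f  R %.3f  F1 %.3f\n",
                x$token$weighted["precision"], x$token$weighted["recall"],
                x$token$weighted["f1"]))
  invisible(x)
}
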