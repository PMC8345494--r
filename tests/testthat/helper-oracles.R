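# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: path enumeration for the CRF, adist() edit
# operations for the fuzzy matcher, and a naive re-implementation of the
# MUC-5 categorization for cross-checking.

# Brute-force CRF quantities by enumerating all K^L tag paths.
enum_crf <- function(emissions, crf) {
  L <- nrow(emissions); K <- ncol(emissions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  scores <- apply(paths, 1L, function(p) {
    s <- crf$start[p[1L]] + crf$end[p[L]] +
      sum(emissions[cbind(seq_len(L), p)])
    if (L > 1L) s <- s + sum(crf$transitions[cbind(p[-L], p[-1L])])
    s
  })
  m <- max(scores)
  list(log_partition = m + log(sum(exp(scores - m))),
       best_score = m,
       best_path = as.integer(paths[which.max(scores), ]))
}

# Edit operations between two strings via base R's adist.
edit_ops <- function(from, to) {
  d <- utils::adist(from, to, counts = TRUE)
  cnt <- attr(d, "counts")[1, 1, ]
  list(distance = as.integer(d), ins = as.integer(cnt[["ins"]]),
       del = as.integer(cnt[["del"]]), sub = as.integer(cnt[["sub"]]))
}

# Naive per-report MUC-5 categorization, written set-style and
# independently of muc_align(). Returns a plain list of counts.
naive_muc <- function(gold, pred, mode) {
  cor <- inc <- spu <- 0L
  overlapped <- rep(FALSE, nrow(gold))
  for (i in seq_len(nrow(pred))) {
    hits <- c()
    for (j in seq_len(nrow(gold))) {
      shared <- intersect(seq(pred$start[i], pred$end[i]),
                          seq(gold$start[j], gold$end[j]))
      if (length(shared)) hits <- c(hits, j)
    }
    if (!length(hits)) { spu <- spu + 1L; next }
    overlapped[hits] <- TRUE
    j <- hits[order(gold$start[hits], gold$end[hits])][1]
    span_eq <- gold$start[j] == pred$start[i] && gold$end[j] == pred$end[i]
    type_eq <- gold$entity[j] == pred$entity[i]
    ok <- if (mode == "strict") span_eq && type_eq else type_eq
    if (ok) cor <- cor + 1L else inc <- inc + 1L
  }
  mis <- sum(!overlapped)
  list(COR = cor, INC = inc, MIS = mis, SPU = spu,
       POS = cor + inc + mis, ACT = cor + inc + spu)
}

# Random non-overlapping mention set over n tokens (for property tests).
random_mentions <- function(n_tokens, n_mentions, entities) {
  starts <- integer(0); ends <- integer(0); ents <- character(0)
  pos <- 1L
  for (i in seq_len(n_mentions)) {
    if (pos > n_tokens) break
    s <- pos + sample.int(3L, 1L) - 1L
    e <- s + sample.int(3L, 1L) - 1L
    if (e > n_tokens) break
    starts <- c(starts, s); ends <- c(ends, e)
    ents <- c(ents, sample(entities, 1L))
    pos <- e + 2L
  }
  data.frame(start = starts, end = ends, entity = ents,
             source = rep("gold", length(starts)), stringsAsFactors = FALSE)
}

# Tiny lexicon used by matcher unit tests.
toy_lexicon <- function() {
  ems_lexicon(data.frame(
    entity = c("ECG", "ECG", "Aspirin", "Nitroglycerin (GTN)",
               "Nitroglycerin (GTN)", "Stroke Assessment"),
    phrase = c("ecg", "12 lead ecg", "aspirin", "gtn", "gtn spray",
               "facial droop"),
    exact_only = FALSE,
    stringsAsFactors = FALSE))
}
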