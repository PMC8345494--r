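# Gazetteer pseudo-labeling: exact and one-deletion fuzzy phrase matching,
# overlap resolution, and IOB2 <-> mention conversion.
#
# Token spans are 1-based and inclusive on both ends throughout the package:
# a mention covering tokens 3..5 has start = 3, end = 5.

# Empty mention table with canonical columns
mention_frame <- function() {
  data.frame(start = integer(0), end = integer(0),
             entity = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

span_frame <- function(starts, ends) {
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Exact phrase occurrences in a token sequence
#'
#' All (possibly overlapping) windows whose tokens equal the phrase.
#'
#' @param tokens character vector of normalized tokens.
#' @param phrase character vector of phrase tokens (non-empty).
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @examples
#' match_exact(c("12", "lead", "ecg", "done"), c("12", "lead", "ecg"))
#' @export
match_exact <- function(tokens, phrase) {
  starts <- exact_starts(tokens, phrase)
  span_frame(starts, starts + length(phrase) - 1L)
}

# integer-level worker: starts of exact phrase occurrences
exact_starts <- function(tokens, phrase) {
  k <- length(phrase)
  n <- length(tokens)
  stopifnot(k >= 1L)
  if (n < k) return(integer(0))
  starts <- which(tokens == phrase[1L])
  starts <- starts[starts <= n - k + 1L]
  if (k > 1L && length(starts)) {
    ok <- vapply(starts, function(s) all(tokens[s:(s + k - 1L)] == phrase), TRUE)
    starts <- starts[ok]
  }
  starts
}

# TRUE iff `short` equals `long` with exactly one character deleted
is_one_deletion <- function(long, short) {
  if (nchar(long) != nchar(short) + 1L) return(FALSE)
  a <- strsplit(long, "")[[1L]]
  b <- strsplit(short, "")[[1L]]
  i <- 1L
  nb <- length(b)
  while (i <= nb && a[i] == b[i]) i <- i + 1L
  identical(a[-i], b)
}

#' Fuzzy phrase occurrences tolerating one missing character
#'
#' Finds token windows whose single-space join equals the joined phrase, or
#' equals it with exactly one character deleted (the text is missing one
#' character relative to the synonym). Matches are token-boundary aligned; a
#' deleted boundary space merges two tokens, so for a k-token phrase both
#' k-token and (k-1)-token windows are candidates. Only phrases whose joined
#' form has at least 5 characters may be fuzzy-matched; shorter phrases would
#' produce high false-positive rates and must use [match_exact()].
#'
#' @param tokens character vector of normalized tokens.
#' @param phrase character vector of phrase tokens; joined length must be >= 5.
#' @param mode `"deletion"` (default): exactly one missing character, no
#'   insertions or substitutions. `"lev1"`: any Levenshtein distance <= 1
#'   (uses [utils::adist()]), provided for experimentation.
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @examples
#' match_fuzzy(c("given", "asprin"), "aspirin")
#' match_fuzzy(c("facial", "drop"), c("facial", "droop"))
#' @export
match_fuzzy <- function(tokens, phrase, mode = c("deletion", "lev1")) {
  mode <- match.arg(mode)
  joined <- paste(phrase, collapse = " ")
  if (nchar(joined) < 5L)
    stop("fuzzy matching requires a joined phrase of >= 5 characters (got \"",
         joined, "\"); flag this phrase for exact matching instead")
  cum <- c(0L, cumsum(nchar(tokens)))
  m <- fuzzy_spans(tokens, cum, phrase, joined, mode)
  out <- span_frame(m[, 1L], m[, 2L])
  out[order(out$start, out$end), , drop = FALSE]
}

# integer-level worker: (start, end) matrix of fuzzy occurrences; `cum` is
# the zero-prefixed cumulative token nchar, precomputed once per report
fuzzy_spans <- function(tokens, cum, phrase, joined, mode = "deletion") {
  k <- length(phrase)
  n <- length(tokens)
  target <- nchar(joined)
  win_lens <- if (mode == "deletion") c(target, target - 1L) else
    c(target - 1L, target, target + 1L)
  kws <- if (mode == "deletion") c(k, k - 1L) else c(k - 1L, k, k + 1L)
  res <- matrix(integer(0), 0L, 2L)
  for (kw in unique(pmax(kws, 1L))) {
    if (kw > n) next
    starts <- seq_len(n - kw + 1L)
    jlens <- cum[starts + kw] - cum[starts] + (kw - 1L)
    starts <- starts[jlens %in% win_lens]
    if (!length(starts)) next
    hit <- vapply(starts, function(s) {
      w <- paste(tokens[s:(s + kw - 1L)], collapse = " ")
      if (mode == "deletion") w == joined || is_one_deletion(joined, w)
      else utils::adist(joined, w) <= 1L
    }, TRUE)
    starts <- starts[hit]
    if (length(starts)) res <- rbind(res, cbind(starts, starts + kw - 1L))
  }
  res
}

#' Resolve overlapping candidate matches into a non-overlapping mention set
#'
#' Deterministic greedy selection: candidates are ranked by longer span
#' first, then exact before fuzzy, then smaller start, then lexicographically
#' smaller entity name; each candidate is accepted iff it overlaps no
#' already-accepted mention. The ranking is a total order, so resolution is
#' reproducible regardless of input order.
#'
#' @param matches data.frame with columns `start`, `end`, `entity`, `source`.
#' @return mention data.frame sorted by `start`.
#' @export
resolve_overlaps <- function(matches) {
  if (!nrow(matches)) return(mention_frame())
  len <- matches$end - matches$start + 1L
  src_rank <- match(matches$source, c("exact", "fuzzy", "gold", "predicted"))
  ord <- order(-len, src_rank, matches$start, matches$entity, method = "radix")
  matches <- matches[ord, , drop = FALSE]
  taken_end <- integer(0)
  taken_start <- integer(0)
  keep <- logical(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    s <- matches$start[i]; e <- matches$end[i]
    if (!any(s <= taken_end & taken_start <= e)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  out <- matches[keep, c("start", "end", "entity", "source"), drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a non-overlapping mention set to IOB2 tags
#'
#' @param mentions mention data.frame (`start`, `end`, `entity`); spans must
#'   be non-overlapping and within `1..n_tokens`.
#' @param n_tokens number of tokens in the report.
#' @return character vector of `n_tokens` IOB2 tags.
#' @examples
#' mentions_to_iob2(data.frame(start = 3, end = 5, entity = "ECG"), 6)
#' @export
mentions_to_iob2 <- function(mentions, n_tokens) {
  tags <- rep("O", n_tokens)
  if (!nrow(mentions)) return(tags)
  stopifnot(all(mentions$start >= 1L), all(mentions$end <= n_tokens),
            all(mentions$start <= mentions$end))
  ord <- order(mentions$start)
  ends <- mentions$end[ord]
  starts <- mentions$start[ord]
  if (any(starts[-1L] <= ends[-length(ends)]))
    stop("overlapping mentions passed to mentions_to_iob2()")
  for (i in seq_len(nrow(mentions))) {
    s <- mentions$start[i]; e <- mentions$end[i]; ent <- mentions$entity[i]
    tags[s] <- paste0("B-", ent)
    if (e > s) tags[(s + 1L):e] <- paste0("I-", ent)
  }
  tags
}

#' Recover mentions from an IOB2 tag sequence
#'
#' Exact inverse of [mentions_to_iob2()] on valid input. Model output need
#' not be IOB2-valid: a stray `I-e` whose predecessor is not `B-e`/`I-e` of
#' the same entity opens a new mention (treated as `B-e`).
#'
#' @param tags character vector of IOB2 tags.
#' @param source source label for the recovered mentions (default
#'   `"predicted"`).
#' @return mention data.frame.
#' @export
iob2_to_mentions <- function(tags, source = "predicted") {
  n <- length(tags)
  starts <- integer(0); ends <- integer(0); ents <- character(0)
  cur_ent <- NULL; cur_start <- 0L
  flush <- function(i) {
    if (!is.null(cur_ent)) {
      starts <<- c(starts, cur_start); ends <<- c(ends, i)
      ents <<- c(ents, cur_ent)
    }
  }
  for (i in seq_len(n)) {
    t <- tags[i]
    if (t == "O") { flush(i - 1L); cur_ent <- NULL; next }
    pre <- substr(t, 1L, 2L)
    ent <- substring(t, 3L)
    if (pre == "B-" || is.null(cur_ent) || ent != cur_ent) {
      flush(i - 1L)
      cur_ent <- ent; cur_start <- i
    }
    # I- matching the open entity: continue
  }
  flush(n)
  data.frame(start = starts, end = ends, entity = ents,
             source = rep(source, length(starts)), stringsAsFactors = FALSE)
}

#' Pseudo-label one tokenized report against a lexicon
#'
#' Runs [match_exact()] for every phrase, plus [match_fuzzy()] for phrases
#' that are fuzzy-eligible (joined length >= `fuzzy_min_chars` and not
#' flagged `exact_only`), resolves overlaps, and emits IOB2 tags.
#'
#' @param tokens character vector of normalized tokens (or a single report
#'   list with a `tokens` element).
#' @param lexicon an [ems_lexicon()].
#' @param fuzzy enable fuzzy matching (default `TRUE`).
#' @param fuzzy_min_chars minimum joined phrase length for fuzzy matching
#'   (default 5).
#' @param fuzzy_mode passed to [match_fuzzy()].
#' @return list with `tags` (IOB2 character vector) and `mentions`
#'   (data.frame with `source` `"exact"` or `"fuzzy"`).
#' @export
weak_label <- function(tokens, lexicon, fuzzy = TRUE, fuzzy_min_chars = 5L,
                       fuzzy_mode = "deletion") {
  if (is.list(tokens) && !is.null(tokens$tokens)) tokens <- tokens$tokens
  n <- length(tokens)
  cum <- c(0L, cumsum(nchar(tokens)))
  starts <- integer(0); ends <- integer(0)
  ents <- character(0); srcs <- character(0)
  for (i in seq_len(nrow(lexicon))) {
    ptoks <- strsplit(lexicon$phrase[i], " ", fixed = TRUE)[[1L]]
    ent <- lexicon$entity[i]
    ex <- exact_starts(tokens, ptoks)
    if (length(ex)) {
      starts <- c(starts, ex); ends <- c(ends, ex + length(ptoks) - 1L)
      ents <- c(ents, rep(ent, length(ex)))
      srcs <- c(srcs, rep("exact", length(ex)))
    }
    if (fuzzy && !lexicon$exact_only[i] &&
        nchar(lexicon$phrase[i]) >= fuzzy_min_chars) {
      fz <- fuzzy_spans(tokens, cum, ptoks, lexicon$phrase[i], fuzzy_mode)
      if (nrow(fz)) {
        starts <- c(starts, fz[, 1L]); ends <- c(ends, fz[, 2L])
        ents <- c(ents, rep(ent, nrow(fz)))
        srcs <- c(srcs, rep("fuzzy", nrow(fz)))
      }
    }
  }
  cands <- data.frame(start = starts, end = ends, entity = ents,
                      source = srcs, stringsAsFactors = FALSE)
  mentions <- resolve_overlaps(cands)
  list(tags = mentions_to_iob2(mentions, n), mentions = mentions)
}

#' Pseudo-label every report in a corpus
#'
#' @param corpus an [ems_corpus].
#' @inheritParams weak_label
#' @return the corpus with IOB2 `tags` attached to every report.
#' @export
label_corpus <- function(corpus, lexicon, fuzzy = TRUE, fuzzy_min_chars = 5L,
                         fuzzy_mode = "deletion") {
  out <- lapply(corpus, function(r) {
    r$tags <- weak_label(r$tokens, lexicon, fuzzy = fuzzy,
                         fuzzy_min_chars = fuzzy_min_chars,
                         fuzzy_mode = fuzzy_mode)$tags
    r
  })
  ems_corpus(out)
}
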