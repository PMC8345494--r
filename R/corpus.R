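# Corpus management: container, CoNLL-style I/O, deterministic splits,
# corpus statistics, vocabulary, batch padding, subtoken tag aggregation.

#' Corpus of tokenized (optionally tagged) reports
#'
#' A light list container. Each element is a report:
#' `list(report_id, tokens, tags)` where `tags` is `NULL` or a character
#' vector of IOB2 tags the same length as `tokens`.
#'
#' @param reports list of report lists.
#' @return the list with class `ems_corpus`.
#' @export
ems_corpus <- function(reports) {
  for (r in reports) {
    stopifnot(is.character(r$report_id), length(r$report_id) == 1L,
              is.character(r$tokens))
    if (!is.null(r$tags) && length(r$tags) != length(r$tokens))
      stop("report ", r$report_id, ": tags length != token length")
  }
  structure(reports, class = "ems_corpus")
}

#' @export
print.ems_corpus <- function(x, ...) {
  nt <- sum(vapply(x, function(r) length(r$tokens), 0L))
  tagged <- sum(vapply(x, function(r) !is.null(r$tags), TRUE))
  cat("<ems_corpus> ", length(x), " reports, ", nt, " tokens (",
      tagged, " tagged)\n", sep = "")
  invisible(x)
}

#' @export
`[.ems_corpus` <- function(x, i) ems_corpus(unclass(x)[i])

#' Write a corpus in CoNLL-style token-per-line format
#'
#' Two tab-separated columns (`token<TAB>tag`), a blank line between
#' reports, and a `# id = <report_id>` comment line before each report so
#' identifiers round-trip. Untagged reports are written with tag `O`.
#'
#' @param corpus an [ems_corpus].
#' @param path output file path.
#' @param ids write `# id =` comment lines (default `TRUE`).
#' @export
write_conll <- function(corpus, path, ids = TRUE) {
  chunks <- lapply(corpus, function(r) {
    tags <- r$tags %||% rep("O", length(r$tokens))
    c(if (ids) paste0("# id = ", r$report_id),
      paste(r$tokens, tags, sep = "\t"), "")
  })
  lines <- unlist(chunks)
  writeLines(lines[-length(lines)], path, useBytes = TRUE)  # no trailing blank
}

#' Read a CoNLL-style corpus file
#'
#' Accepts the format written by [write_conll()]; files without `# id =`
#' comments get generated identifiers.
#'
#' @param path file path.
#' @return an [ems_corpus] with tags.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  reports <- list()
  cur_id <- NULL; toks <- character(0); tags <- character(0)
  flush <- function() {
    if (length(toks)) {
      id <- cur_id %||% sprintf("report-%05d", length(reports) + 1L)
      reports[[length(reports) + 1L]] <<-
        list(report_id = id, tokens = toks, tags = tags)
    }
    cur_id <<- NULL; toks <<- character(0); tags <<- character(0)
  }
  for (ln in lines) {
    if (!nzchar(ln)) { flush(); next }
    if (startsWith(ln, "# id = ")) { cur_id <- substring(ln, 8L); next }
    parts <- regmatches(ln, regexpr("\t", ln, fixed = TRUE), invert = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed CoNLL line: ", ln)
    toks <- c(toks, parts[1L]); tags <- c(tags, parts[2L])
  }
  flush()
  ems_corpus(reports)
}

#' Split sizes under cumulative half-up rounding
#'
#' The development size is `round(n * f_dev)` and the development+test size
#' is `round(n * (f_dev + f_test))` (both half-up); the remainder goes to
#' training. For n = 44,211 and fractions (0.95, 0.025, 0.025) this gives
#' 42,000 / 1105 / 1106.
#'
#' @param n number of reports.
#' @param fractions numeric length-3 vector `(train, dev, test)` summing to 1.
#' @return named integer vector `c(train, dev, test)`.
#' @export
split_sizes <- function(n, fractions = c(0.95, 0.025, 0.025)) {
  stopifnot(length(fractions) == 3L, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n_dev <- round_half_up(n * fractions[2L])
  n_test <- round_half_up(n * (fractions[2L] + fractions[3L])) - n_dev
  c(train = as.integer(n - n_dev - n_test),
    dev = as.integer(n_dev), test = as.integer(n_test))
}

#' Randomly split a corpus into train/dev/test
#'
#' A random permutation under the given seed; sizes from [split_sizes()].
#' Deterministic, disjoint and exhaustive.
#'
#' @param corpus an [ems_corpus].
#' @param fractions `(train, dev, test)` fractions summing to 1.
#' @param seed integer RNG seed.
#' @return named list of three corpora (`train`, `dev`, `test`).
#' @export
split_corpus <- function(corpus, fractions = c(0.95, 0.025, 0.025), seed = 1L) {
  n <- length(corpus)
  sizes <- split_sizes(n, fractions)
  perm <- with_seed(seed, sample.int(n))
  idx <- list(train = perm[seq_len(sizes["train"])],
              dev = perm[sizes["train"] + seq_len(sizes["dev"])],
              test = perm[sizes["train"] + sizes["dev"] + seq_len(sizes["test"])])
  lapply(idx, function(i) corpus[sort(i)])
}

#' Average tokens per entity, as printed
#' @param tokens total entity tokens.
#' @param mentions number of mentions.
#' @return tokens/mentions rounded half-up to 2 decimals; `NA` if no mentions.
#' @export
ate <- function(tokens, mentions) {
  ifelse(mentions > 0, round_half_up(tokens / mentions, 2), NA_real_)
}

#' Percentage share, as printed
#' @param count per-entity count.
#' @param total overall count.
#' @return `100 * count / total` rounded half-up to 1 decimal.
#' @export
share_pct <- function(count, total) round_half_up(100 * count / total, 1)

#' Per-entity corpus statistics
#'
#' Mention counts, entity token counts, average tokens per entity (ATE) and
#' share of total mentions, per entity and overall, in the shape of the
#' standard corpus overview table.
#'
#' @param corpus a tagged [ems_corpus].
#' @return data.frame with columns `category`, `entity`, `mentions`,
#'   `share_pct`, `tokens`, `ate`; attributes `total_mentions`,
#'   `entity_tokens`, `total_tokens`, `entity_token_pct`.
#' @export
corpus_stats <- function(corpus) {
  schema <- entity_schema()
  mcount <- stats::setNames(rep(0L, nrow(schema)), schema$entity)
  tcount <- mcount
  total_tokens <- 0L
  for (r in corpus) {
    total_tokens <- total_tokens + length(r$tokens)
    if (is.null(r$tags)) next
    m <- iob2_to_mentions(r$tags)
    if (!nrow(m)) next
    mt <- table(factor(m$entity, levels = schema$entity))
    tt <- tapply(m$end - m$start + 1L, factor(m$entity, levels = schema$entity),
                 sum, default = 0L)
    mcount <- mcount + as.integer(mt)
    tcount <- tcount + as.integer(tt)
  }
  total_m <- sum(mcount)
  out <- data.frame(
    category = schema$category,
    entity = schema$entity,
    mentions = as.integer(mcount),
    share_pct = if (total_m > 0) share_pct(mcount, total_m) else rep(NA_real_, nrow(schema)),
    tokens = as.integer(tcount),
    ate = ate(tcount, mcount),
    stringsAsFactors = FALSE
  )
  attr(out, "total_mentions") <- total_m
  attr(out, "entity_tokens") <- sum(tcount)
  attr(out, "total_tokens") <- total_tokens
  attr(out, "entity_token_pct") <- if (total_tokens > 0)
    round_half_up(100 * sum(tcount) / total_tokens, 2) else NA_real_
  out
}

#' Build a token vocabulary from a training corpus
#'
#' Index 1 is reserved for padding (`"<pad>"`) and index 2 for unknown
#' tokens (`"<unk>"`); out-of-vocabulary tokens map to the unknown index at
#' encode time, the standard treatment for words unseen in training. Build
#' the vocabulary from the training split only to avoid dev/test leakage.
#'
#' @param corpus an [ems_corpus] (training split).
#' @param min_count minimum token frequency to be included (default 1).
#' @return named integer vector (token -> index) with class `ems_vocab`.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  freq <- table(unlist(lapply(corpus, `[[`, "tokens")))
  toks <- names(freq)[freq >= min_count]
  toks <- setdiff(sort(toks, method = "radix"), c("<pad>", "<unk>"))
  v <- stats::setNames(seq_len(length(toks) + 2L), c("<pad>", "<unk>", toks))
  class(v) <- "ems_vocab"
  v
}

#' Encode tokens as vocabulary indices
#' @param tokens character vector.
#' @param vocab an `ems_vocab`.
#' @return integer vector; unknown tokens get index 2.
#' @export
encode_tokens <- function(tokens, vocab) {
  i <- unclass(vocab)[tokens]
  i[is.na(i)] <- 2L
  unname(i)
}

#' Pad encoded reports into a fixed-shape batch with a mask
#'
#' @param encoded list of integer vectors (encoded reports, all non-empty).
#' @param max_len pad/truncate length; default the longest report in the
#'   batch. Longer reports are truncated with a warning.
#' @param pad_index index used for padding positions (default 1).
#' @return list with `indices` (n x max_len integer matrix), `mask`
#'   (n x max_len 0/1 matrix) and `lengths` (after truncation). Masked
#'   positions are never read by the loss or the metrics.
#' @export
pad_batch <- function(encoded, max_len = NULL, pad_index = 1L) {
  stopifnot(length(encoded) > 0, all(lengths(encoded) > 0))
  lens <- lengths(encoded)
  if (is.null(max_len)) max_len <- max(lens)
  if (any(lens > max_len)) {
    warning(sum(lens > max_len), " report(s) longer than ", max_len,
            " tokens truncated")
    encoded <- lapply(encoded, function(x) x[seq_len(min(length(x), max_len))])
    lens <- lengths(encoded)
  }
  n <- length(encoded)
  idx <- matrix(pad_index, n, max_len)
  msk <- matrix(0, n, max_len)
  for (i in seq_len(n)) {
    idx[i, seq_len(lens[i])] <- encoded[[i]]
    msk[i, seq_len(lens[i])] <- 1
  }
  list(indices = idx, mask = msk, lengths = as.integer(lens))
}

#' Aggregate subtoken tag predictions into one word-level tag
#'
#' Majority vote over the non-`O` tags; if every subtoken is `O` the word is
#' `O`; ties break toward the tag occurring first in the subtoken sequence.
#' With `level = "type"` the vote pools `B-`/`I-` variants of the same
#' entity before voting and returns the first original tag of the winning
#' entity.
#'
#' @param subtoken_tags character vector of tags for one word's subtokens.
#' @param level `"tag"` (default) or `"type"`.
#' @return a single tag.
#' @export
aggregate_subtoken_tags <- function(subtoken_tags, level = c("tag", "type")) {
  level <- match.arg(level)
  stopifnot(length(subtoken_tags) >= 1L)
  nz <- subtoken_tags[subtoken_tags != "O"]
  if (!length(nz)) return("O")
  key <- if (level == "tag") nz else substring(nz, 3L)
  cnt <- table(factor(key, levels = unique(key)))  # first-occurrence order
  win <- names(cnt)[which.max(cnt)]
  if (level == "tag") win else nz[substring(nz, 3L) == win][1L]
}
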