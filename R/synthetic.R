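# Synthetic paramedic-report generator.
#
# The restricted source corpus cannot be redistributed, so end-to-end
# validation runs on generated reports that emulate its salient features:
# short telegraphic narratives of normalized shorthand, entity mentions
# drawn from the lexicon's surface forms at controllable relative
# frequencies, and occasional single-character-deletion misspellings --
# exactly the error family the fuzzy matcher models. Gold spans are known
# by construction, and filler phrases share no token with any lexicon
# phrase, so the gold annotation is exhaustive: whatever the labeler or the
# tagger finds can be scored against it without unlabeled-entity ambiguity.

#' Default generator configuration
#'
#' Defaults mirror the reference corpus overview: entity weights follow the
#' training-split mention shares (ECG 50.6%, Bleeding 14.1%, Stroke
#' Assessment 12.5%, ...), mentions per report are 0-4 with mean ~1.2
#' (which lands near the ~2.7% entity-token share), 5% of eligible mentions
#' carry one deleted character, and report lengths are uniform on 30-120
#' tokens.
#'
#' @param n_reports number of reports to generate.
#' @param entity_weights named non-negative vector of relative mention
#'   frequencies (normalized internally).
#' @param mentions_per_report probability vector for 0..k mentions.
#' @param misspell_prob per-mention probability of a single character
#'   deletion (applied only to surface forms of joined length >= 5).
#' @param misspell_mode `"deletion"` (default) or `"substitution"`; the
#'   substitution mode emulates the residual error family that a
#'   deletion-only fuzzy matcher is expected to miss.
#' @param report_len length-2 integer range of report lengths in tokens.
#' @param filler_bank character vector of entity-free filler phrases.
#' @param seed integer seed; generation is byte-identical under a fixed seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_reports = 2000L,
                             entity_weights = default_entity_weights(),
                             mentions_per_report = c(`0` = 0.30, `1` = 0.35,
                                                     `2` = 0.22, `3` = 0.09,
                                                     `4` = 0.04),
                             misspell_prob = 0.05,
                             misspell_mode = c("deletion", "substitution"),
                             report_len = c(30L, 120L),
                             filler_bank = default_fillers(),
                             seed = 1L) {
  stopifnot(n_reports >= 1, all(entity_weights >= 0), sum(entity_weights) > 0,
            all(mentions_per_report >= 0), misspell_prob >= 0, misspell_prob <= 1,
            length(report_len) == 2L, report_len[1L] >= 2L,
            report_len[2L] >= report_len[1L], length(filler_bank) >= 5L)
  structure(list(n_reports = as.integer(n_reports),
                 entity_weights = entity_weights / sum(entity_weights),
                 mentions_per_report = mentions_per_report / sum(mentions_per_report),
                 misspell_prob = misspell_prob,
                 misspell_mode = match.arg(misspell_mode),
                 report_len = as.integer(report_len),
                 filler_bank = filler_bank,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Training-split entity mention shares used as default generator weights
#' @return named numeric vector over the 17 schema entities (percent).
#' @export
default_entity_weights <- function() {
  c("ECG" = 50.6, "Stroke Assessment" = 12.5, "Intravenous Cannulation" = 3.9,
    "Burns Cooling" = 0.1, "Valsalva Maneuver" = 0.1,
    "Bleeding" = 14.1, "Signs Of Obvious Death" = 0.6,
    "Nitroglycerin (GTN)" = 5.0, "Aspirin" = 3.1, "Normal Saline" = 2.6,
    "Penthrox" = 1.1, "Dextrose/Glucose" = 0.8, "Adrenaline" = 0.8,
    "Diazepam" = 0.7, "Salbutamol" = 3.4, "Tramadol" = 0.6,
    "Syntometrine" = 0.1)
}

#' Entity-free filler phrases
#'
#' Telegraphic connective material in the register of paramedic shorthand.
#' No filler token occurs in any phrase of [default_lexicon()] (see
#' [validate_fillers()]), so filler text can never spell out an entity.
#'
#' @return character vector of normalized phrases.
#' @export
default_fillers <- function() {
  c("hx from pt", "c o chest pain", "o a pt sitting alert",
    "conscious and alert", "o e pt appears well", "no trauma", "no fall noted",
    "pt ambulant at scene", "denies sob", "no giddiness", "afebrile",
    "gcs 15", "bp 115 57", "hr 88", "spo2 98% on room air", "rr 18",
    "pt escorted to hospital", "handover done at a&e", "nkda",
    "no known drug allergy", "pmhx htn dm", "on long term meds",
    "pain score 3", "vitals stable", "pt lying on sofa",
    "family present at scene", "nil else to note", "case referred",
    "secondary survey unremarkable", "pt transferred onto stretcher",
    "monitored en route", "no distress observed", "pt denies any complaint",
    "witnessed by family", "nil per mouth since morning",
    "skin warm and dry", "no deformity seen", "pupils equal reactive",
    "talking in full sentences",
    "pt able to ambulate", "no chest discomfort en route")
}

#' Check that fillers cannot collide with lexicon phrases
#'
#' Enforces token-level disjointness: no filler token may appear in any
#' lexicon phrase. This is the precondition for treating generated gold
#' spans as exhaustive ground truth.
#'
#' @param fillers character vector of filler phrases.
#' @param lexicon an [ems_lexicon()].
#' @return invisibly `TRUE`; errors listing offending tokens otherwise.
#' @export
validate_fillers <- function(fillers, lexicon) {
  ftoks <- unique(unlist(strsplit(fillers, " ", fixed = TRUE)))
  bad <- intersect(ftoks, lexicon_phrase_tokens(lexicon))
  if (length(bad))
    stop("filler tokens collide with lexicon phrases: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Delete one character from an entity surface form
#'
#' Applies a single character deletion at a position drawn uniformly from
#' the "safe" positions of the single-space-joined surface: any space (the
#' two adjacent tokens merge) or any character of a token with at least two
#' characters. Deleting the only character of a one-letter token would
#' collapse two separators and amount to a second deletion, so such
#' positions are excluded. Surfaces of joined length < 5 are returned
#' unchanged, mirroring the fuzzy matcher's eligibility gate.
#'
#' @param tokens character vector: one mention's surface form.
#' @return list with `tokens` (possibly misspelled, re-tokenized) and
#'   `position` (deleted character index in the joined string, or `NA`).
#' @export
inject_misspelling <- function(tokens) {
  joined <- paste(tokens, collapse = " ")
  if (nchar(joined) < 5L) return(list(tokens = tokens, position = NA_integer_))
  chars <- strsplit(joined, "")[[1L]]
  tok_len <- nchar(tokens)
  # label each character (token chars plus the following space) with its token
  lab <- rep(seq_along(tokens),
             times = tok_len + c(rep(1L, length(tokens) - 1L), 0L))
  safe <- which(chars == " " | tok_len[lab] >= 2L)
  pos <- if (length(safe) == 1L) safe else sample(safe, 1L)
  out <- paste(chars[-pos], collapse = "")
  list(tokens = strsplit(out, " ", fixed = TRUE)[[1L]], position = pos)
}

# Substitute one character (never a space) with a random other letter;
# produces the error family a deletion-only matcher cannot recover.
inject_substitution <- function(tokens) {
  joined <- paste(tokens, collapse = " ")
  if (nchar(joined) < 5L) return(list(tokens = tokens, position = NA_integer_))
  chars <- strsplit(joined, "")[[1L]]
  cand <- which(chars != " ")
  pos <- if (length(cand) == 1L) cand else sample(cand, 1L)
  repl <- sample(setdiff(letters, chars[pos]), 1L)
  chars[pos] <- repl
  list(tokens = strsplit(paste(chars, collapse = ""), " ", fixed = TRUE)[[1L]],
       position = pos)
}

#' Generate one synthetic report
#'
#' Samples a mention count, entity types and surface forms, optionally
#' misspells eligible surfaces, and interleaves them with filler phrases so
#' that no two mentions are adjacent. Uses the current RNG state.
#'
#' @param lexicon an [ems_lexicon()].
#' @param config a [generator_config()].
#' @param report_id identifier for the report.
#' @return list with `report_id`, `tokens`, `tags` (gold IOB2), `mentions`
#'   (gold mention data.frame) and `provenance` (entity, phrase, misspelled,
#'   position per mention).
#' @export
sample_report <- function(lexicon, config, report_id = "synth-00001") {
  wts <- config$entity_weights[config$entity_weights > 0]
  m_counts <- if (is.null(names(config$mentions_per_report)))
    seq_along(config$mentions_per_report) - 1L
  else as.integer(names(config$mentions_per_report))
  n_m <- sample(m_counts, 1L, prob = config$mentions_per_report)
  ments <- list()
  if (n_m > 0L) for (j in seq_len(n_m)) {
    ent <- sample(names(wts), 1L, prob = wts)
    rows <- which(lexicon$entity == ent)
    row <- if (length(rows) == 1L) rows else sample(rows, 1L)
    phr <- lexicon$phrase[row]
    toks <- strsplit(phr, " ", fixed = TRUE)[[1L]]
    mis <- FALSE; pos <- NA_integer_
    # exact-only phrases opted out of fuzzy matching, so the deletion error
    # model never applies to them
    if (config$misspell_prob > 0 && !lexicon$exact_only[row] &&
        stats::runif(1L) < config$misspell_prob) {
      r <- if (config$misspell_mode == "deletion") inject_misspelling(toks)
           else inject_substitution(toks)
      mis <- !is.na(r$position); pos <- r$position; toks <- r$tokens
    }
    ments[[j]] <- list(entity = ent, phrase = phr, tokens = toks,
                       misspelled = mis, position = pos)
  }
  target_len <- sample(config$report_len[1L]:config$report_len[2L], 1L)
  fillers <- character(0)
  while (sum(lengths(strsplit(fillers, " ", fixed = TRUE))) < target_len ||
         length(fillers) < length(ments) + 1L) {
    fillers <- c(fillers, sample(config$filler_bank, 1L))
  }
  # one mention at most per gap between fillers; gaps 0..length(fillers)
  gaps <- sort(sample.int(length(fillers) + 1L, length(ments)) - 1L)
  tokens <- character(0)
  starts <- integer(0); ends <- integer(0); ents <- character(0)
  mi <- 1L
  for (g in 0:length(fillers)) {
    while (mi <= length(ments) && gaps[mi] == g) {
      mt <- ments[[mi]]$tokens
      starts <- c(starts, length(tokens) + 1L)
      tokens <- c(tokens, mt)
      ends <- c(ends, length(tokens))
      ents <- c(ents, ments[[mi]]$entity)
      mi <- mi + 1L
    }
    if (g < length(fillers))
      tokens <- c(tokens, strsplit(fillers[g + 1L], " ", fixed = TRUE)[[1L]])
  }
  mentions <- data.frame(start = starts, end = ends, entity = ents,
                         source = rep("gold", length(starts)),
                         stringsAsFactors = FALSE)
  prov <- data.frame(
    report_id = rep(report_id, length(ments)),
    entity = vapply(ments, `[[`, "", "entity"),
    phrase = vapply(ments, `[[`, "", "phrase"),
    misspelled = vapply(ments, `[[`, TRUE, "misspelled"),
    position = vapply(ments, `[[`, 1L, "position"),
    stringsAsFactors = FALSE)
  list(report_id = report_id, tokens = tokens,
       tags = mentions_to_iob2(mentions, length(tokens)),
       mentions = mentions, provenance = prov)
}

#' Generate a synthetic corpus with gold annotations
#'
#' @param config a [generator_config()].
#' @param lexicon an [ems_lexicon()] (default [default_lexicon()]); fillers
#'   are validated against it first.
#' @return list with `corpus` (tagged [ems_corpus], tags = gold IOB2),
#'   `mentions` (named list of gold mention data.frames) and `provenance`
#'   (one data.frame across reports).
#' @export
generate_corpus <- function(config = generator_config(),
                            lexicon = default_lexicon()) {
  validate_fillers(config$filler_bank, lexicon)
  missing <- setdiff(names(config$entity_weights[config$entity_weights > 0]),
                     unique(lexicon$entity))
  if (length(missing))
    stop("entity weights refer to entities with no synonyms: ",
         paste(missing, collapse = ", "))
  with_seed(config$seed, {
    reps <- lapply(seq_len(config$n_reports), function(i)
      sample_report(lexicon, config, sprintf("synth-%05d", i)))
  })
  corpus <- ems_corpus(lapply(reps, `[`, c("report_id", "tokens", "tags")))
  mentions <- stats::setNames(lapply(reps, `[[`, "mentions"),
                              vapply(reps, `[[`, "", "report_id"))
  list(corpus = corpus, mentions = mentions,
       provenance = do.call(rbind, lapply(reps, `[[`, "provenance")))
}
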