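# Exact/fuzzy gazetteer matching, overlap resolution and IOB2 conversion.

test_that("exact matching finds all (including overlapping) occurrences", {
  expect_identical(match_exact(c("12", "lead", "ecg", "done"),
                               c("12", "lead", "ecg")),
                   data.frame(start = 1L, end = 3L))
  expect_identical(match_exact(c("ecg", "ecg"), "ecg"),
                   data.frame(start = 1:2, end = 1:2))
  expect_identical(nrow(match_exact("aspirin", "gtn")), 0L)
})

test_that("fuzzy matching accepts exactly one missing character", {
  expect_identical(match_fuzzy(c("given", "asprin"), "aspirin"),
                   data.frame(start = 2L, end = 2L))
  # the misspelling family discussed for stroke screening shorthand
  expect_identical(match_fuzzy(c("facial", "drop"), c("facial", "droop")),
                   data.frame(start = 1L, end = 2L))
  # an extra character is not a missing character
  expect_identical(nrow(match_fuzzy("aspirinn", "aspirin")), 0L)
  # a substitution is not a missing character (cross-checked below)
  expect_identical(nrow(match_fuzzy("aspirim", "aspirin")), 0L)
  ops <- edit_ops("aspirin", "aspirim")
  expect_identical(ops$distance, 1L)
  expect_identical(ops$sub, 1L)  # adist confirms: substitution, not deletion
  # a deleted boundary space merges tokens: matched via the k-1 window
  expect_identical(match_fuzzy(c("iv", "plug", "gtnspray"), c("gtn", "spray")),
                   data.frame(start = 3L, end = 3L))
  # exact occurrences are also reported by the fuzzy matcher
  expect_identical(nrow(match_fuzzy(c("gtn", "spray"), c("gtn", "spray"))), 1L)
})

test_that("fuzzy matching agrees with an edit-operations oracle", {
  set.seed(11)
  phrase <- "salbutamol"
  chars <- strsplit(phrase, "")[[1]]
  for (i in seq_along(chars)) {
    deleted <- paste(chars[-i], collapse = "")
    expect_identical(nrow(match_fuzzy(deleted, phrase)), 1L)
    ops <- edit_ops(phrase, deleted)
    expect_identical(ops$del, 1L)
  }
  # random single substitutions never match in deletion mode, always in lev1
  for (r in 1:20) {
    i <- sample(nchar(phrase), 1)
    repl <- sample(setdiff(letters, chars[i]), 1)
    mutated <- paste(replace(chars, i, repl), collapse = "")
    expect_identical(nrow(match_fuzzy(mutated, phrase)), 0L)
    expect_identical(nrow(match_fuzzy(mutated, phrase, mode = "lev1")), 1L)
  }
})

test_that("the 5-character eligibility gate is enforced", {
  expect_error(match_fuzzy("gtnn", "gtn"), "5 characters")
  # joined length counts the boundary space: "a bc" has 4 characters
  expect_error(match_fuzzy(c("a", "bc"), c("a", "bc")), "5 characters")
  # every single deletion of a 5-character phrase is caught
  chars <- strsplit("abcde", "")[[1]]
  for (i in 1:5) {
    expect_identical(nrow(match_fuzzy(paste(chars[-i], collapse = ""),
                                      "abcde")), 1L)
  }
})

test_that("overlap resolution is longest-first, exact-first, leftmost", {
  m <- data.frame(start = c(1L, 3L), end = c(3L, 3L),
                  entity = "ECG", source = "exact")
  expect_identical(resolve_overlaps(m)$start, 1L)
  m <- data.frame(start = 1L, end = 2L, entity = "Nitroglycerin (GTN)",
                  source = c("fuzzy", "exact"))
  expect_identical(resolve_overlaps(m)$source, "exact")
  m <- data.frame(start = c(1L, 2L), end = c(1L, 2L),
                  entity = c("Aspirin", "Bleeding"), source = "exact")
  expect_identical(nrow(resolve_overlaps(m)), 2L)
  # equal span and source: lexicographically smaller entity wins
  m <- data.frame(start = 1L, end = 1L, entity = c("ECG", "Aspirin"),
                  source = "exact")
  expect_identical(resolve_overlaps(m)$entity, "Aspirin")
})

test_that("IOB2 conversion matches its definition and round-trips", {
  expect_identical(mentions_to_iob2(data.frame(start = 3, end = 5,
                                               entity = "ECG"), 6),
                   c("O", "O", "B-ECG", "I-ECG", "I-ECG", "O"))
  expect_identical(mentions_to_iob2(data.frame(start = 1, end = 1,
                                               entity = "Aspirin"), 1),
                   "B-Aspirin")
  expect_identical(mentions_to_iob2(mention_frame()[0, ], 3), rep("O", 3))
  expect_error(mentions_to_iob2(data.frame(start = c(1, 2), end = c(2, 3),
                                           entity = "ECG"), 4), "overlapping")
  # stray-I repair and adjacent singletons
  expect_identical(iob2_to_mentions(c("I-ECG", "I-ECG"))[, 1:2],
                   data.frame(start = 1L, end = 2L))
  expect_identical(iob2_to_mentions(c("B-ECG", "B-ECG"))$start, 1:2)
  expect_identical(iob2_to_mentions(c("O", "B-ECG", "I-ECG"))[, c("start", "end")],
                   data.frame(start = 2L, end = 3L))
  # round-trip over random non-overlapping mention sets
  set.seed(5)
  ents <- entity_schema()$entity
  for (i in 1:40) {
    m <- random_mentions(30, sample(0:5, 1), ents)
    tags <- mentions_to_iob2(m, 30)
    back <- iob2_to_mentions(tags, source = "gold")
    expect_identical(back[c("start", "end", "entity")],
                     m[c("start", "end", "entity")])
  }
})

test_that("weak labeling composes matching, resolution and IOB2", {
  lx <- toy_lexicon()
  toks <- tokenize(normalize_text(
    "pt was gtn 1 tab by sn. given 300 mg aspirin stat dose & 1 gtn spray. 12 lead ecg done"))
  wl <- weak_label(toks, lx)
  got <- wl$mentions
  surf <- vapply(seq_len(nrow(got)),
                 function(i) paste(toks[got$start[i]:got$end[i]], collapse = " "), "")
  expect_setequal(surf, c("gtn", "aspirin", "gtn spray", "12 lead ecg"))
  expect_identical(got$entity[surf == "aspirin"], "Aspirin")
  expect_identical(got$entity[surf == "12 lead ecg"], "ECG")
  expect_true(all(wl$tags[setdiff(seq_along(toks), unlist(mapply(seq, got$start, got$end)))] == "O"))
  # empty lexicon: all O
  empty <- ems_lexicon(data.frame(entity = character(0), phrase = character(0)))
  expect_identical(weak_label(toks, empty)$tags, rep("O", length(toks)))
  # misspelled surface recovered through the fuzzy path
  wl2 <- weak_label(c("given", "asprin"), lx)
  expect_identical(wl2$mentions$entity, "Aspirin")
  expect_identical(wl2$mentions$source, "fuzzy")
  expect_identical(wl2$tags, c("O", "B-Aspirin"))
})

test_that("weak label output is IOB2-valid and sound against a re-scan", {
  g <- generate_corpus(generator_config(n_reports = 60, misspell_prob = 0.2,
                                        seed = 13))
  lx <- default_lexicon()
  lab <- label_corpus(g$corpus, lx)
  for (r in lab) {
    # validity: every I- is preceded by B-/I- of the same entity
    for (i in seq_along(r$tags)) {
      if (startsWith(r$tags[i], "I-")) {
        expect_true(i > 1)
        expect_identical(substring(r$tags[i - 1], 3), substring(r$tags[i], 3))
      }
    }
    # soundness: every labeled surface is a phrase or one deletion away
    m <- iob2_to_mentions(r$tags)
    for (j in seq_len(nrow(m))) {
      surf <- paste(r$tokens[m$start[j]:m$end[j]], collapse = " ")
      phrases <- lx$phrase[lx$entity == m$entity[j]]
      ok <- any(vapply(phrases, function(p) {
        if (p == surf) return(TRUE)
        ops <- edit_ops(p, surf)
        ops$distance == 1 && ops$del == 1
      }, TRUE))
      expect_true(ok, info = paste("unsound span:", surf, "->", m$entity[j]))
    }
  }
})
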