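# Entity schema and synonym lexicon.
#
# The schema fixes 17 clinical entities in 3 categories (procedures,
# findings, medications) chosen for EMS audit relevance. The lexicon maps
# each entity to normalized synonym phrases; a per-phrase `exact_only` flag
# opts a phrase out of fuzzy matching (used for short or collision-prone
# surface forms).

#' The 17-entity, 3-category clinical entity schema
#'
#' @return data.frame with columns `entity` and `category`
#'   (`"Clinical Procedure"`, `"Clinical Finding"` or `"Medication"`).
#' @export
entity_schema <- function() {
  data.frame(
    entity = c("ECG", "Stroke Assessment", "Intravenous Cannulation",
               "Burns Cooling", "Valsalva Maneuver",
               "Bleeding", "Signs Of Obvious Death",
               "Nitroglycerin (GTN)", "Aspirin", "Normal Saline", "Penthrox",
               "Dextrose/Glucose", "Adrenaline", "Diazepam", "Salbutamol",
               "Tramadol", "Syntometrine"),
    category = c(rep("Clinical Procedure", 5L),
                 rep("Clinical Finding", 2L),
                 rep("Medication", 10L)),
    stringsAsFactors = FALSE
  )
}

#' The full IOB2 tag vocabulary
#'
#' `"O"` plus `B-`/`I-` tags for every schema entity: 35 tags. The tag set is
#' fixed regardless of which entities occur in a given split, so model output
#' layers always have the same width.
#'
#' @param schema entity schema (default [entity_schema()]).
#' @return character vector of 35 tags, `"O"` first.
#' @export
tag_vocabulary <- function(schema = entity_schema()) {
  c("O", as.vector(rbind(paste0("B-", schema$entity), paste0("I-", schema$entity))))
}

#' Construct and validate a synonym lexicon
#'
#' Every phrase must be non-empty, pre-normalized (it survives
#' [normalize_text()] unchanged) and unique within its entity; every entity
#' must belong to the schema.
#'
#' @param entries data.frame with columns `entity`, `phrase` and optionally
#'   `category` and `exact_only` (logical, default `FALSE`).
#' @param complete require every schema entity to have at least one phrase
#'   (default `FALSE`, so partial lexicons can be built programmatically).
#' @return the validated data.frame with class `ems_lexicon`.
#' @export
ems_lexicon <- function(entries, complete = FALSE) {
  stopifnot(is.data.frame(entries), all(c("entity", "phrase") %in% names(entries)))
  schema <- entity_schema()
  entries$entity <- as.character(entries$entity)
  entries$phrase <- as.character(entries$phrase)
  if (is.null(entries$exact_only))
    entries$exact_only <- rep(FALSE, nrow(entries))
  entries$exact_only <- as.logical(entries$exact_only)
  entries$category <- schema$category[match(entries$entity, schema$entity)]
  bad <- setdiff(unique(entries$entity), schema$entity)
  if (length(bad)) stop("unknown entities: ", paste(bad, collapse = ", "))
  if (any(!nzchar(entries$phrase))) stop("empty phrase in lexicon")
  notnorm <- entries$phrase[normalize_text(entries$phrase) != entries$phrase]
  if (length(notnorm))
    stop("phrases not in normalized form: ", paste(unique(notnorm), collapse = ", "))
  if (anyDuplicated(entries[c("entity", "phrase")]))
    stop("duplicate (entity, phrase) pairs in lexicon")
  if (complete) {
    missing <- setdiff(schema$entity, entries$entity)
    if (length(missing))
      stop("entities with no synonyms: ", paste(missing, collapse = ", "))
  }
  entries <- entries[c("entity", "category", "phrase", "exact_only")]
  rownames(entries) <- NULL
  class(entries) <- c("ems_lexicon", "data.frame")
  entries
}

#' Starter synonym lexicon
#'
#' A compact lexicon seeded from surface forms typical of EMS shorthand
#' ("12 lead ecg", "gtn spray", "i v n s", "facial droop", ...). The lexicon
#' the original audit system used is unpublished; in practice users curate
#' their own file per EMS system and load it with [read_lexicon()].
#'
#' @return an [ems_lexicon()] covering all 17 entities.
#' @export
default_lexicon <- function() {
  e <- function(entity, phrases, exact = FALSE)
    data.frame(entity = entity, phrase = phrases,
               exact_only = rep_len(exact, length(phrases)),
               stringsAsFactors = FALSE)
  ems_lexicon(rbind(
    e("ECG", c("ecg", "ekg", "12 lead ecg", "ecg 12 leads", "ecg 4 leads",
               "electrocardiogram")),
    e("Stroke Assessment", c("facial droop", "slurred speech",
                             "stroke assessment", "arm drift",
                             "fast assessment")),
    e("Intravenous Cannulation", c("iv cannulation", "intravenous cannulation",
                                   "iv access")),
    e("Intravenous Cannulation", "iv plug", exact = TRUE),
    e("Burns Cooling", c("burns cooling", "burn cooling")),
    e("Valsalva Maneuver", c("valsalva", "valsalva maneuver",
                             "valsalva manoeuvre")),
    e("Bleeding", c("bleeding", "active bleeding", "bleeding wound",
                    "haemorrhage", "hemorrhage", "epistaxis")),
    e("Signs Of Obvious Death", c("signs of obvious death", "obvious death",
                                  "rigor mortis", "livor mortis")),
    e("Nitroglycerin (GTN)", c("gtn", "gtn spray", "s l gtn", "sublingual gtn",
                               "nitroglycerin", "glyceryl trinitrate")),
    e("Aspirin", c("aspirin", "acetylsalicylic acid")),
    e("Normal Saline", c("normal saline", "i v n s", "i v n s 0 9%",
                         "iv ns 0 9%", "ns 0 9%", "sodium chloride 0 9%")),
    e("Penthrox", c("penthrox", "penthrox inhaler", "methoxyflurane")),
    e("Dextrose/Glucose", c("dextrose", "dextrose 50%", "glucose",
                            "oral glucose")),
    e("Adrenaline", c("adrenaline", "epinephrine", "i m adrenaline")),
    e("Diazepam", c("diazepam", "valium")),
    e("Salbutamol", c("salbutamol", "salbutamol neb", "neb salbutamol",
                      "ventolin")),
    e("Tramadol", c("tramadol", "i m tramadol")),
    e("Syntometrine", "syntometrine")
  ), complete = TRUE)
}

#' Read a lexicon from a CSV file
#'
#' Expected columns: `entity`, `phrase`, optional `category` (ignored in
#' favour of the schema) and `exact_only` (logical).
#'
#' @param path CSV file path.
#' @param complete require full 17-entity coverage (default `TRUE` for
#'   files meant to drive a whole pipeline).
#' @return an `ems_lexicon`.
#' @export
read_lexicon <- function(path, complete = TRUE) {
  ems_lexicon(utils::read.csv(path, stringsAsFactors = FALSE), complete = complete)
}

#' Write a lexicon to CSV
#' @param lexicon an `ems_lexicon`.
#' @param path CSV file path.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.csv(as.data.frame(lexicon), path, row.names = FALSE, quote = TRUE)
}

# All distinct tokens appearing in any lexicon phrase (used by the synthetic
# generator to enforce filler/entity token disjointness).
lexicon_phrase_tokens <- function(lexicon) {
  unique(unlist(strsplit(lexicon$phrase, " ", fixed = TRUE)))
}
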