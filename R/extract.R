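# The automated feeding search algorithm: Rourke Baby Record detection and
# rule-based per-visit feeding classification from note text and structured
# fields. All matching runs through one vectorized engine so that the
# single-note operation and the corpus path are the same code.

# Compiled regexes for a lexicon, built once and cached on the object.
lexicon_regexes <- function(lexicon) {
  cached <- attr(lexicon, "compiled")
  if (!is.null(cached)) return(cached)
  list(
    rourke = vapply(lexicon$rourke_variants, phrase_regex, character(1)),
    breast = vapply(lexicon$breast_terms, phrase_regex, character(1)),
    formula = vapply(lexicon$formula_terms, phrase_regex, character(1)),
    mixed = vapply(lexicon$mixed_markers, phrase_regex, character(1)),
    excl = vapply(lexicon$exclusivity_markers, phrase_regex, character(1)),
    negation_any = paste0("\\b(?:",
                          paste(vapply(lexicon$negation_markers,
                                       function(p) gsub(" ", "\\\\s+",
                                                        escape_regex(p)),
                                       character(1)), collapse = "|"),
                          ")\\b"),
    historical = vapply(lexicon$historical_patterns,
                        compile_historical_pattern, character(1),
                        breast_terms = lexicon$breast_terms)
  )
}

#' Detect a Rourke Baby Record form name in note text
#'
#' Case-folded, whitespace-normalized, word-boundary-anchored search for any
#' of the lexicon's Rourke form-name variants ("Rourke", "Well Baby Visit",
#' "Well Baby Check Up", "Newborn Visit", "1 month visit", ...). The
#' earliest match in the text wins; ties go to the variant listed first.
#'
#' @param text a single note text (possibly empty or `NA`).
#' @param lexicon an [load_lexicon()] object.
#' @return list with `detected` (logical), `matched_variant` (the lexicon
#'   phrase, or `NULL`), and `char_span` (half-open `[start, end)` 1-based
#'   character offsets into `text`, or `NULL`).
#' @export
#' @examples
#' detect_rourke_record("Rourke completed, thriving", load_lexicon())
detect_rourke_record <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "ebf_lexicon"))
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(text)) {
    return(list(detected = FALSE, matched_variant = NULL, char_span = NULL))
  }
  rx <- lexicon_regexes(lexicon)
  best_start <- Inf
  best_len <- 0L
  best_variant <- NULL
  for (k in seq_along(rx$rourke)) {
    m <- regexpr(rx$rourke[k], text, perl = TRUE, ignore.case = TRUE)
    if (m > 0 && m < best_start) {
      best_start <- as.integer(m)
      best_len <- attr(m, "match.length")
      best_variant <- lexicon$rourke_variants[k]
    }
  }
  if (is.infinite(best_start)) {
    list(detected = FALSE, matched_variant = NULL, char_span = NULL)
  } else {
    list(detected = TRUE, matched_variant = best_variant,
         char_span = c(start = best_start, end = best_start + best_len))
  }
}

# A negation marker within 3 tokens before position `start`, with no
# intervening sentence punctuation, cancels the feeding term there.
is_negated <- function(norm, start, negation_markers) {
  prefix <- substr(norm, 1, start - 1)
  prefix <- sub(".*[,.;:]", "", prefix)  # negation scope stops at punctuation
  toks <- strsplit(trimws(prefix), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) return(FALSE)
  any(utils::tail(toks, 3) %in% negation_markers)
}

blank_spans <- function(norm, starts, ends) {
  chars <- strsplit(norm, "")[[1]]
  for (k in seq_along(starts)) {
    chars[seq(starts[k], min(ends[k] - 1, length(chars)))] <- " "
  }
  paste(chars, collapse = "")
}

# Vectorized matching of one phrase list over a text vector. Returns, per
# text, the surviving (non-negated) matched phrases.
match_category <- function(texts, phrases, regexes, lexicon, check_negation) {
  hits <- rep(list(character(0)), length(texts))
  live <- which(nzchar(texts))
  if (length(live) == 0) return(hits)
  for (k in seq_along(regexes)) {
    m <- gregexpr(regexes[k], texts[live], perl = TRUE)
    for (j in seq_along(live)) {
      starts <- m[[j]]
      if (starts[1] == -1) next
      i <- live[j]
      surviving <- if (check_negation[i]) {
        any(!vapply(as.integer(starts), is_negated, logical(1),
                    norm = texts[i],
                    negation_markers = lexicon$negation_markers))
      } else TRUE
      if (surviving) hits[[i]] <- c(hits[[i]], phrases[k])
    }
  }
  hits
}

# Historical (past-tense) duration statements per text: list of data.frames
# (start, end, duration).
match_historical <- function(texts, lexicon, rx) {
  out <- rep(list(NULL), length(texts))
  for (pat in rx$historical) {
    m <- gregexpr(pat, texts, perl = TRUE)
    for (i in seq_along(texts)) {
      mi <- m[[i]]
      if (mi[1] == -1) next
      cstarts <- attr(mi, "capture.start")
      clens <- attr(mi, "capture.length")
      lens <- attr(mi, "match.length")
      for (k in seq_along(mi)) {
        n_txt <- substr(texts[i], cstarts[k, 1],
                        cstarts[k, 1] + clens[k, 1] - 1)
        u_txt <- substr(texts[i], cstarts[k, 2],
                        cstarts[k, 2] + clens[k, 2] - 1)
        out[[i]] <- rbind(out[[i]], data.frame(
          start = as.integer(mi[k]), end = as.integer(mi[k]) + lens[k],
          duration = duration_to_days(as.integer(n_txt), u_txt)))
      }
    }
  }
  lapply(out, function(d) {
    if (is.null(d)) NULL else d[!duplicated(d$start), , drop = FALSE]
  })
}

# The vectorized extraction engine. Returns a list of per-note observation
# data.frames (current first, then historical companions).
extract_engine <- function(infant_id, age_days, texts, structured, lexicon) {
  rx <- lexicon_regexes(lexicon)
  n <- length(texts)
  texts[is.na(texts)] <- ""

  rourke_det <- rep(FALSE, n)
  for (k in seq_along(rx$rourke)) {
    rourke_det <- rourke_det |
      grepl(rx$rourke[k], texts, perl = TRUE, ignore.case = TRUE)
  }
  norm_all <- norm_text(texts)

  hist <- match_historical(norm_all, lexicon, rx)
  blanked <- norm_all
  for (i in which(!vapply(hist, is.null, logical(1)))) {
    blanked[i] <- blank_spans(norm_all[i], hist[[i]]$start, hist[[i]]$end)
  }

  # a structured Rourke feeding field overrides the free text
  feeding_val <- vapply(structured, function(sf) {
    keys <- intersect(c("feeding", "nutrition", "feeding_mode"),
                      tolower(names(sf)))
    if (length(keys) == 0) NA_character_ else as.character(sf[[keys[1]]])
  }, character(1))
  has_struct <- !is.na(feeding_val)
  class_text <- ifelse(has_struct, norm_text(feeding_val), blanked)
  source <- ifelse(has_struct, "rourke_structured",
                   ifelse(rourke_det, "rourke_freetext", "progress_note"))

  check_neg <- grepl(rx$negation_any, class_text, perl = TRUE)
  breast <- match_category(class_text, lexicon$breast_terms, rx$breast,
                           lexicon, check_neg)
  formula <- match_category(class_text, lexicon$formula_terms, rx$formula,
                            lexicon, check_neg)
  mixed <- match_category(class_text, lexicon$mixed_markers, rx$mixed,
                          lexicon, check_neg)
  excl <- match_category(class_text, lexicon$exclusivity_markers, rx$excl,
                         lexicon, rep(FALSE, n))

  has_breast <- lengths(breast) > 0
  has_formula <- lengths(formula) > 0
  has_mixed <- lengths(mixed) > 0
  has_excl <- lengths(excl) > 0
  # a mixed marker naming a feeding mode ("breast and formula", "mixed") is
  # self-sufficient; "both"/"supplementing" need a feeding term to co-occur
  self_mixed <- vapply(mixed, function(p) {
    any(grepl("breast|formula|milk", p) | p == "mixed")
  }, logical(1))

  status <- ifelse(
    (has_breast & (has_formula | has_mixed)) | self_mixed |
      (has_mixed & has_formula), "MIXED",
    ifelse(has_breast, "EBF",
           ifelse(has_formula, "FORMULA", "NONE_DOCUMENTED")))

  lapply(seq_len(n), function(i) {
    terms <- if (status[i] == "NONE_DOCUMENTED") character(0) else
      unique(c(breast[[i]], formula[[i]], mixed[[i]],
               if (has_breast[i]) excl[[i]]))
    rows <- data.frame(
      infant_id = infant_id[i], age_days = as.integer(age_days[i]),
      status = status[i], tense = "current",
      historical_duration = NA_real_, source = source[i],
      stringsAsFactors = FALSE)
    rows$matched_terms <- list(terms)
    h <- hist[[i]]
    if (!is.null(h) && nrow(h) > 0) {
      hrows <- data.frame(
        infant_id = infant_id[i], age_days = as.integer(age_days[i]),
        status = "EBF", tense = "historical",
        historical_duration = h$duration, source = source[i],
        stringsAsFactors = FALSE)
      hrows$matched_terms <- rep(list("historical_pattern"), nrow(h))
      rows <- rbind(rows, hrows)
    }
    rows
  })
}

#' Classify per-visit feeding status from one note
#'
#' Applies the rule-based feeding classifier to a single visit note. The
#' decision order is: (1) a structured Rourke feeding field, when present,
#' overrides the free text; (2) a breast term together with a formula term
#' or mixed marker gives MIXED; (3) a breast term with an exclusivity marker
#' and no formula term gives EBF; (4) a breast term alone (not negated)
#' gives EBF; (5) a formula term alone gives FORMULA; (6) no surviving
#' feeding terms give NONE_DOCUMENTED. A negation marker within three tokens
#' before a term (with no intervening punctuation) cancels it.
#'
#' Past-tense duration statements ("was exclusively breastfed until 4
#' months") are extracted first and reported as additional historical
#' observations with the stated duration converted to days (months x 30.44,
#' rounded half away from zero); the remaining text is then classified for
#' current status, so "..., now on formula" yields a current FORMULA
#' observation alongside the historical EBF one.
#'
#' @param note a one-row `ebf_notes` data.frame, or a list with fields
#'   `infant_id`, `age_days`, `text` and optionally `structured_fields`.
#' @param lexicon an [load_lexicon()] object.
#' @return data.frame of observations: `infant_id, age_days, status, tense,
#'   historical_duration, source` and a `matched_terms` list column. The
#'   first row is always the note's current-status observation.
#' @export
#' @examples
#' lex <- load_lexicon()
#' note <- list(infant_id = "A", age_days = 130,
#'              text = "was exclusively breastfed until 4 months, now on formula")
#' classify_feeding(note, lex)
classify_feeding <- function(note, lexicon) {
  stopifnot(inherits(lexicon, "ebf_lexicon"))
  if (is.data.frame(note)) {
    stopifnot(nrow(note) == 1)
    sf <- if ("structured_fields" %in% names(note))
      note$structured_fields[[1]] else list()
    note <- list(infant_id = note$infant_id, age_days = note$age_days,
                 text = note$text, structured_fields = sf)
  }
  extract_engine(note$infant_id, note$age_days, note$text %||% "",
                 list(note$structured_fields %||% list()), lexicon)[[1]]
}

#' Run the feeding search algorithm over a whole corpus
#'
#' Pure function of `(notes, lexicon)`: classifies every note, sorted per
#' infant by age. Duplicate (infant, visit date) notes are both processed
#' and flagged in the `duplicates` attribute.
#'
#' @param notes an `ebf_notes` data.frame (see [read_notes()]).
#' @param lexicon an [load_lexicon()] object.
#' @return data.frame of class `ebf_observations` with one current-status
#'   row per note plus any historical rows, sorted by infant and age; the
#'   attribute `rourke_detected` lists infants with any detected Rourke form.
#' @export
extract_all <- function(notes, lexicon = load_lexicon()) {
  stopifnot(inherits(lexicon, "ebf_lexicon"))
  if (nrow(notes) == 0) {
    out <- data.frame(infant_id = character(), age_days = integer(),
                      status = character(), tense = character(),
                      historical_duration = numeric(), source = character(),
                      stringsAsFactors = FALSE)
    out$matched_terms <- list()
    class(out) <- c("ebf_observations", "data.frame")
    return(out)
  }
  ord <- order(notes$infant_id, notes$age_days)
  notes <- notes[ord, , drop = FALSE]
  dup <- duplicated(notes[, c("infant_id", "visit_date")]) |
    duplicated(notes[, c("infant_id", "visit_date")], fromLast = TRUE)
  sf_col <- if ("structured_fields" %in% names(notes))
    notes$structured_fields else rep(list(list()), nrow(notes))

  obs <- extract_engine(notes$infant_id, notes$age_days, notes$text,
                        sf_col, lexicon)
  rourke <- rep(FALSE, nrow(notes))
  rx <- lexicon_regexes(lexicon)
  txt <- ifelse(is.na(notes$text), "", notes$text)
  for (k in seq_along(rx$rourke)) {
    rourke <- rourke | grepl(rx$rourke[k], txt, perl = TRUE,
                             ignore.case = TRUE)
  }
  out <- do.call(rbind, obs)
  rownames(out) <- NULL
  attr(out, "rourke_detected") <- unique(notes$infant_id[rourke])
  attr(out, "duplicates") <- unique(notes$infant_id[dup])
  class(out) <- c("ebf_observations", "data.frame")
  out
}

#' Write/read extracted observations as CSV
#'
#' The `matched_terms` list column is serialized as a `;`-joined string.
#'
#' @param observations an `ebf_observations` data.frame.
#' @param path CSV file path.
#' @return the path (write) or the observations data.frame (read).
#' @export
write_observations <- function(observations, path) {
  out <- as.data.frame(observations)
  out$matched_terms <- vapply(out$matched_terms, paste, character(1),
                              collapse = ";")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) io_error("observations file not found: %s", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(infant_id = "character"))
  out$matched_terms <- strsplit(out$matched_terms %||% "", ";", fixed = TRUE)
  class(out) <- c("ebf_observations", "data.frame")
  out
}
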