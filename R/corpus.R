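# Rendering of well-baby visit notes from latent trajectories, and the
# CSV/JSON-lines corpus readers and writers.

ebf_sentences <- c(
  "Exclusively breastfeeding, gaining well.",
  "Breast milk only.",
  "Exclusive breastfeeding, no concerns.",
  "Breastfeeding only, latching well."
)
mixed_sentences <- c(
  "Feeding both breast and formula.",
  "Breastfeeding, supplementing with formula.",
  "Mixed breast and formula feeding."
)
formula_sentences <- c(
  "Formula feeding, tolerating well.",
  "On formula, feeding q4h.",
  "Exclusively formula fed."
)
neutral_sentences <- c(
  "Seen in clinic today, thriving.",
  "Immunizations given as scheduled.",
  "Growth and development on track.",
  "Routine visit, doing well."
)

random_case <- function(x) {
  switch(sample(3, 1), x, toupper(x), tolower(x))
}

structured_feeding_value <- function(status) {
  switch(status,
    EBF = "exclusive breast milk",
    MIXED = "breast and formula",
    FORMULA = "formula")
}

# Past-tense sentence stating the true EBF duration; months granularity for
# longer durations, days below two months.
historical_sentence <- function(ebf_end) {
  d <- floor(ebf_end)
  if (d >= 60) {
    sprintf("Was exclusively breastfed until %d months, now on formula.",
            max(1, round_half_away(d / 30.44)))
  } else {
    sprintf("Was exclusively breastfed for %d days, now on formula.", d)
  }
}

#' Render the well-baby visit-note corpus
#'
#' Draws each infant's visits from the configured schedule (attendance
#' probability and Gaussian age jitter truncated at 0), then renders one
#' clinical note per visit whose feeding text is consistent with the
#' infant's ground-truth status at the visit age. With probability
#' `config$rourke_prob` an infant's notes carry a Rourke Baby Record form
#' name (variant sampled per infant, randomized case; recorded either as a
#' structured feeding field or free text). With probability
#' `config$undocumented_prob` an infant's notes carry no feeding terms at
#' all. Weaned infants may state their past exclusive-breastfeeding
#' duration in past tense (probability `config$historical_prob`).
#'
#' Deterministic given `config$seed` (seeds the RNG at `config$seed + 2`).
#'
#' @param registry output of [generate_birth_registry()].
#' @param trajectories output of [generate_feeding_trajectories()]; must
#'   cover every registry infant.
#' @param config an [sim_config()] object.
#' @param lexicon lexicon supplying the Rourke form-name variants.
#' @return data.frame of class `ebf_notes`: `infant_id, visit_date,
#'   age_days, text, structured_fields` (list column), `style`. The `style`
#'   column is a generator-side oracle label and is ignored by extraction.
#' @export
render_visit_corpus <- function(registry, trajectories, config,
                                lexicon = load_lexicon()) {
  stopifnot(inherits(config, "ebf_sim_config"))
  missing_tr <- setdiff(registry$infant_id, trajectories$infant_id)
  if (length(missing_tr) > 0) {
    data_error("no trajectory for infant(s): %s",
               paste(utils::head(missing_tr, 5), collapse = ", "))
  }
  set.seed(config$seed + 2L)
  tr <- trajectories[match(registry$infant_id, trajectories$infant_id), ]
  sched <- config$visit_schedule
  n <- nrow(registry)

  has_rourke <- stats::runif(n) < config$rourke_prob
  undocumented <- stats::runif(n) < config$undocumented_prob
  variants <- lexicon$rourke_variants

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    attended <- stats::runif(nrow(sched)) < sched$attend_prob
    if (!any(attended)) next  # pre-allocated element stays NULL
    ages <- pmax(0, round(sched$age[attended] +
                            stats::rnorm(sum(attended), 0,
                                         sched$jitter_sd[attended])))
    ages <- sort(unique(ages))
    variant <- if (has_rourke[i]) random_case(sample(variants, 1)) else NA
    notes <- lapply(ages, function(a) {
      status <- truth_status(tr[i, ], a)
      if (undocumented[i]) {
        txt <- paste(c(if (has_rourke[i]) paste0(variant, " completed."),
                       sample(neutral_sentences, 1)), collapse = " ")
        return(list(text = txt, structured = list(), style = "undocumented"))
      }
      historical <- status == "FORMULA" && tr$ebf_end_age[i] >= 1 &&
        a > tr$ebf_end_age[i] &&
        stats::runif(1) < config$historical_prob
      feeding_txt <- if (historical) {
        historical_sentence(tr$ebf_end_age[i])
      } else {
        switch(status,
               EBF = sample(ebf_sentences, 1),
               MIXED = sample(mixed_sentences, 1),
               FORMULA = sample(formula_sentences, 1))
      }
      if (has_rourke[i] && !historical &&
          stats::runif(1) < config$structured_prob) {
        list(text = paste0(variant, " completed. ",
                           sample(neutral_sentences, 1)),
             structured = list(feeding = structured_feeding_value(status)),
             style = "rourke_structured")
      } else if (has_rourke[i]) {
        list(text = paste0(variant, " done. ", feeding_txt),
             structured = list(), style = "rourke_freetext")
      } else {
        list(text = feeding_txt, structured = list(), style = "progress_note")
      }
    })
    rows[[i]] <- data.frame(
      infant_id = registry$infant_id[i],
      visit_date = registry$birth_date[i] + ages,
      age_days = as.integer(ages),
      text = vapply(notes, `[[`, character(1), "text"),
      style = vapply(notes, `[[`, character(1), "style"),
      stringsAsFactors = FALSE
    )
    rows[[i]]$structured_fields <- lapply(notes, `[[`, "structured")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("ebf_notes", "data.frame")
  out
}

# --- corpus I/O --------------------------------------------------------------

REGISTRY_COLUMNS <- c("infant_id", "maternal_age", "parity", "urban",
                      "immigrant", "income_quintile", "world_region",
                      "birth_date", "birthweight_g", "gestational_age_wk",
                      "infant_sex", "plurality")

#' Write a corpus to disk
#'
#' Serializes the registry as `registry.csv` (documented column order, the
#' unknown income quintile written as `"unknown"`) and the notes as
#' `notes.jsonl`, one JSON object per visit. Both round-trip losslessly
#' through [read_registry()] / [read_notes()].
#'
#' @param registry an `ebf_registry`.
#' @param notes an `ebf_notes` data.frame (may have zero rows).
#' @param out_dir output directory, created if needed.
#' @return named character vector of the two file paths.
#' @export
write_corpus <- function(registry, notes, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok) io_error("cannot create output directory: %s", out_dir)
  reg_path <- file.path(out_dir, "registry.csv")
  notes_path <- file.path(out_dir, "notes.jsonl")

  reg <- as.data.frame(registry)[, REGISTRY_COLUMNS]
  reg$income_quintile <- ifelse(is.na(reg$income_quintile), "unknown",
                                as.character(reg$income_quintile))
  reg$birth_date <- format(as.Date(reg$birth_date), "%Y-%m-%d")
  utils::write.csv(reg, reg_path, row.names = FALSE, quote = TRUE)

  lines <- vapply(seq_len(nrow(notes)), function(i) {
    obj <- list(
      infant_id = notes$infant_id[i],
      visit_date = format(as.Date(notes$visit_date[i]), "%Y-%m-%d"),
      age_days = notes$age_days[i],
      text = notes$text[i],
      structured_fields = notes$structured_fields[[i]],
      style = notes$style[i]
    )
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(lines, notes_path, useBytes = TRUE)
  c(registry = reg_path, notes = notes_path)
}

#' Read a birth registry CSV
#'
#' @param path path to a `registry.csv` written by [write_corpus()].
#' @return an `ebf_registry` data.frame (unknown income quintile as `NA`,
#'   `birth_year_band` re-derived).
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) io_error("registry file not found: %s", path)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(infant_id = "character"))
  missing <- setdiff(REGISTRY_COLUMNS, names(reg))
  if (length(missing) > 0) {
    data_error("registry is missing column(s): %s",
               paste(missing, collapse = ", "))
  }
  reg$income_quintile <- suppressWarnings(
    as.integer(ifelse(reg$income_quintile == "unknown", NA,
                      reg$income_quintile)))
  reg$birth_date <- as.Date(reg$birth_date)
  reg$urban <- as.logical(reg$urban)
  reg$immigrant <- as.logical(reg$immigrant)
  reg$birth_year_band <- birth_year_band(reg$birth_date)
  class(reg) <- c("ebf_registry", "data.frame")
  reg
}

#' Read a visit-note corpus (JSON lines)
#'
#' @param path path to a `notes.jsonl` written by [write_corpus()].
#' @return an `ebf_notes` data.frame; zero rows for an empty file.
#' @export
read_notes <- function(path) {
  if (!file.exists(path)) io_error("notes file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(infant_id = character(), visit_date = as.Date(character()),
                      age_days = integer(), text = character(),
                      style = character(), stringsAsFactors = FALSE)
    out$structured_fields <- list()
    class(out) <- c("ebf_notes", "data.frame")
    return(out)
  }
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  out <- data.frame(
    infant_id = vapply(objs, function(o) as.character(o$infant_id), ""),
    visit_date = as.Date(vapply(objs, function(o) o$visit_date, "")),
    age_days = vapply(objs, function(o) as.integer(o$age_days), 0L),
    text = vapply(objs, function(o) as.character(o$text %||% ""), ""),
    style = vapply(objs, function(o) as.character(o$style %||% NA), ""),
    stringsAsFactors = FALSE
  )
  out$structured_fields <- lapply(objs, function(o) {
    sf <- o$structured_fields
    if (is.null(sf) || length(sf) == 0) list() else as.list(sf)
  })
  class(out) <- c("ebf_notes", "data.frame")
  out
}
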