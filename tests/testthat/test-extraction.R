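lex <- load_lexicon()

test_that("Rourke form names are detected across case and spacing variants", {
  cases <- list(
    list(text = "Rourke completed, thriving", variant = "rourke"),
    list(text = "WELL BABY CHECK  UP today", variant = "well baby check up"),
    list(text = "newborn visit - feeding reviewed", variant = "newborn visit"),
    list(text = "1 month visit done", variant = "1 month visit")
  )
  for (cc in cases) {
    det <- detect_rourke_record(cc$text, lex)
    expect_true(det$detected, label = cc$text)
    expect_equal(det$matched_variant, cc$variant)
    # the span indexes real text positions
    span_text <- substr(cc$text, det$char_span["start"],
                        det$char_span["end"] - 1)
    expect_equal(norm_text <- gsub("\\s+", " ", tolower(span_text)),
                 cc$variant)
  }
  expect_false(detect_rourke_record("", lex)$detected)
  expect_false(detect_rourke_record("routine progress note", lex)$detected)
})

test_that("the earliest matching variant wins", {
  det <- detect_rourke_record("Newborn Visit; Rourke attached", lex)
  expect_equal(det$matched_variant, "newborn visit")
  expect_equal(unname(det$char_span["start"]), 1L)
})

test_that("feeding classification follows the rule cascade", {
  cases <- list(
    list(text = "exclusively breastfeeding, wt 5.6 kg", status = "EBF"),
    list(text = "feeding both breast and formula", status = "MIXED"),
    list(text = "breast milk only", status = "EBF"),
    list(text = "breastfeeding well", status = "EBF"),          # rule 4
    list(text = "on formula, 5 oz q4h", status = "FORMULA"),
    list(text = "exclusively formula fed", status = "FORMULA"),
    list(text = "breastfeeding, supplementing with formula", status = "MIXED"),
    list(text = "immunizations given, growing well", status = "NONE_DOCUMENTED"),
    # negation within three tokens cancels the term
    list(text = "no formula, breast milk only", status = "EBF"),
    list(text = "not breastfeeding, on formula", status = "FORMULA"),
    list(text = "stopped breastfeeding", status = "NONE_DOCUMENTED")
  )
  for (cc in cases) {
    obs <- classify_feeding(list(infant_id = "A", age_days = 60,
                                 text = cc$text), lex)
    cur <- obs[obs$tense == "current", ]
    expect_equal(nrow(cur), 1, info = cc$text)
    expect_equal(cur$status, cc$status, label = cc$text)
  }
})

test_that("NONE_DOCUMENTED observations carry no matched terms", {
  obs <- classify_feeding(list(infant_id = "A", age_days = 60,
                               text = "doing well, immunized"), lex)
  expect_equal(obs$status, "NONE_DOCUMENTED")
  expect_length(obs$matched_terms[[1]], 0)
})

test_that("historical statements yield a companion observation with duration", {
  obs <- classify_feeding(list(
    infant_id = "A", age_days = 200,
    text = "was exclusively breastfed until 4 months, now on formula"), lex)
  expect_equal(nrow(obs), 2)
  cur <- obs[obs$tense == "current", ]
  expect_equal(cur$status, "FORMULA")
  h <- obs[obs$tense == "historical", ]
  expect_equal(h$status, "EBF")
  expect_equal(h$historical_duration, 122)  # 4 x 30.44, rounded

  obs2 <- classify_feeding(list(
    infant_id = "A", age_days = 80,
    text = "was breastfed for 20 days, now on formula"), lex)
  expect_equal(obs2$historical_duration[obs2$tense == "historical"], 20)
})

test_that("a structured Rourke feeding field overrides the free text", {
  note <- list(infant_id = "A", age_days = 62,
               text = "Rourke completed. Growth on track.",
               structured_fields = list(feeding = "formula"))
  obs <- classify_feeding(note, lex)
  expect_equal(obs$status, "FORMULA")
  expect_equal(obs$source, "rourke_structured")
  # free text sources depend on Rourke detection
  obs2 <- classify_feeding(list(infant_id = "A", age_days = 62,
                                text = "Rourke done. Breast milk only."), lex)
  expect_equal(obs2$source, "rourke_freetext")
  obs3 <- classify_feeding(list(infant_id = "A", age_days = 62,
                                text = "Breast milk only."), lex)
  expect_equal(obs3$source, "progress_note")
})

test_that("extraction is a pure function of notes and lexicon", {
  cfg <- sim_config(n_infants = 60, seed = 13)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  notes <- render_visit_corpus(reg, tr, cfg)
  o1 <- extract_all(notes, lex)
  o2 <- extract_all(notes, lex)
  expect_identical(o1, o2)
  expect_equal(cohens_kappa(o1$status, o2$status), 1)
})

test_that("every note yields exactly one current-status observation", {
  cfg <- sim_config(n_infants = 80, seed = 21)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  notes <- render_visit_corpus(reg, tr, cfg)
  obs <- extract_all(notes, lex)
  cur <- obs[obs$tense == "current", ]
  expect_equal(nrow(cur), nrow(notes))
  expect_true(all(cur$status %in%
                    c("EBF", "MIXED", "FORMULA", "NONE_DOCUMENTED")))
  # historical rows always carry their parsed duration
  h <- obs[obs$tense == "historical", ]
  expect_true(all(!is.na(h$historical_duration)))
})

test_that("extraction recovers ground truth on a fully documented corpus", {
  cfg <- closure_config(250, seed = 17)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  notes <- render_visit_corpus(reg, tr, cfg)
  obs <- extract_all(notes, lex)
  cur <- obs[obs$tense == "current", ]
  # zero undocumented infants
  none_by_infant <- tapply(cur$status == "NONE_DOCUMENTED", cur$infant_id,
                           all)
  expect_equal(sum(none_by_infant), 0)
  # current status equals ground truth at every documented visit
  truth <- truth_status(tr[match(cur$infant_id, tr$infant_id), ],
                        cur$age_days)
  documented <- cur$status != "NONE_DOCUMENTED"
  expect_true(all(documented))
  expect_equal(mean(cur$status == truth), 1)
})

test_that("empty corpora and duplicate notes are handled", {
  cfg <- sim_config(n_infants = 5, seed = 2)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  notes <- render_visit_corpus(reg, tr, cfg)
  expect_equal(nrow(extract_all(notes[0, ], lex)), 0)
  dup <- rbind(notes[1, ], notes[1, ])
  obs <- extract_all(dup, lex)
  expect_equal(sum(obs$tense == "current"), 2)  # both processed
  expect_equal(attr(obs, "duplicates"), notes$infant_id[1])
})

test_that("observations round-trip through the CSV exporter", {
  cfg <- sim_config(n_infants = 30, seed = 19)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  obs <- extract_all(render_visit_corpus(reg, tr, cfg), lex)
  tmp <- tempfile(fileext = ".csv")
  write_observations(obs, tmp)
  obs2 <- read_observations(tmp)
  for (col in c("infant_id", "age_days", "status", "tense", "source")) {
    expect_equal(obs2[[col]], obs[[col]], label = col)
  }
  expect_equal(obs2$historical_duration, obs$historical_duration)
})
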