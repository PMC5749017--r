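test_that("identical config and seed give byte-identical corpora", {
  cfg <- sim_config(n_infants = 120, seed = 101)
  lex <- load_lexicon()
  reg1 <- generate_birth_registry(cfg)
  reg2 <- generate_birth_registry(cfg)
  expect_identical(reg1, reg2)
  tr1 <- generate_feeding_trajectories(reg1, cfg)
  tr2 <- generate_feeding_trajectories(reg2, cfg)
  expect_identical(tr1, tr2)
  expect_identical(render_visit_corpus(reg1, tr1, cfg, lex),
                   render_visit_corpus(reg2, tr2, cfg, lex))
})

test_that("registry records satisfy the domain invariants", {
  cfg <- sim_config(n_infants = 400, seed = 5)
  reg <- generate_birth_registry(cfg)
  expect_equal(nrow(reg), 400)
  expect_true(all(reg$maternal_age >= 12 & reg$maternal_age <= 55))
  expect_true(all(reg$parity >= 0))
  expect_true(all(reg$plurality == 1))
  expect_true(all(reg$gestational_age_wk >= 37 & reg$gestational_age_wk <= 44))
  expect_true(all(is.na(reg$income_quintile) |
                    reg$income_quintile %in% 1:5))
  expect_true(all(reg$birth_date >= cfg$study_start &
                    reg$birth_date <= cfg$study_end))
  expect_true(all(reg$birthweight_g > 0))
  # n = 1 edge
  reg1 <- generate_birth_registry(sim_config(n_infants = 1, seed = 2))
  expect_equal(nrow(reg1), 1)
})

test_that("marginal covariate frequencies match the binomial oracle", {
  n <- 8815
  p_urban <- 0.756
  reg <- generate_birth_registry(sim_config(n_infants = n, seed = 9))
  # 3 binomial SEs around n * p
  expect_lt(abs(sum(reg$urban) - n * p_urban),
            3 * sqrt(n * p_urban * (1 - p_urban)))
  p_imm <- 1 - 0.876
  expect_lt(abs(sum(reg$immigrant) - n * p_imm),
            3 * sqrt(n * p_imm * (1 - p_imm)))
})

test_that("trajectory survival is calibrated to the configured targets", {
  cfg <- sim_config(n_infants = 10, seed = 4, covariate_effects = NULL)
  set.seed(1234)
  ends <- draw_ebf_end(8000, cfg)
  targets <- c(0.395, 0.324, 0.251)
  ages <- c(60, 122, 182)
  for (k in 1:3) {
    se <- sqrt(targets[k] * (1 - targets[k]) / 8000)
    expect_lt(abs(mean(ends > ages[k]) - targets[k]), 3 * se,
              label = sprintf("survival at %d d", ages[k]))
  }
  # point mass of never-exclusively-breastfed infants
  se0 <- sqrt(0.145 * 0.855 / 8000)
  expect_lt(abs(mean(ends == 0) - 0.145), 3 * se0)
})

test_that("an all-zero hazard pushes every end age beyond the record limit", {
  cfg <- sim_config(n_infants = 10, seed = 4, p_never_ebf = 0,
                    ebf_survival_targets = c(1, 1, 1))
  set.seed(7)
  ends <- draw_ebf_end(500, cfg)
  expect_true(all(ends > 750))
})

test_that("trajectories respect ebf_end_age <= mixed_end_age", {
  cfg <- sim_config(n_infants = 2000, seed = 31)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  expect_true(all(tr$ebf_end_age <= tr$mixed_end_age))
  expect_true(all(tr$ebf_end_age >= 0))
  # single-record path draws valid trajectories too
  one <- generate_feeding_trajectory(reg[1, ], cfg)
  expect_true(one$ebf_end_age <= one$mixed_end_age)
})

test_that("invalid configurations raise configuration errors", {
  expect_error(sim_config(n_infants = 0, seed = 1),
               class = "ebf_config_error")
  expect_error(sim_config(n_infants = 10, seed = 1, rourke_prob = 1.2),
               class = "ebf_config_error")
  expect_error(sim_config(n_infants = 10, seed = 1,
                          ebf_survival_targets = c(0.3, 0.35, 0.2)),
               class = "ebf_config_error")
  expect_error(sim_config(n_infants = 10, seed = 1, p_never_ebf = 0.7),
               class = "ebf_config_error")
  expect_error(sim_config(n_infants = 10), class = "ebf_config_error")
})

test_that("undocumented infants occur at the configured binomial rate", {
  n <- 2000
  cfg <- sim_config(n_infants = n, seed = 77, undocumented_prob = 0.118)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  notes <- render_visit_corpus(reg, tr, cfg)
  undoc_flag <- tapply(notes$style == "undocumented", notes$infant_id, all)
  expect_lt(abs(sum(undoc_flag) - n * 0.118),
            3 * sqrt(n * 0.118 * 0.882))
})

test_that("notes rendered for ground-truth EBF honour the template contract", {
  cfg <- closure_config(150, seed = 12, structured_prob = 0)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  notes <- render_visit_corpus(reg, tr, cfg)
  lex <- load_lexicon()
  truth <- truth_status(tr[match(notes$infant_id, tr$infant_id), ],
                        notes$age_days)
  ebf_notes <- notes$text[truth == "EBF"]
  expect_gt(length(ebf_notes), 0)
  has_any <- function(text, phrases) {
    any(vapply(phrases, function(p) {
      grepl(paste0("\\b", gsub(" ", "\\\\s+", p), "\\b"),
            tolower(text), perl = TRUE)
    }, logical(1)))
  }
  for (txt in ebf_notes) {
    expect_true(has_any(txt, lex$breast_terms), label = txt)
    expect_true(has_any(txt, lex$exclusivity_markers), label = txt)
    expect_false(has_any(txt, lex$formula_terms), label = txt)
  }
})

test_that("a missing trajectory is a data-integrity error", {
  cfg <- sim_config(n_infants = 5, seed = 3)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  expect_error(render_visit_corpus(reg, tr[-1, ], cfg),
               class = "ebf_data_error")
})

test_that("corpus round-trips losslessly through the readers", {
  cfg <- sim_config(n_infants = 40, seed = 8)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  notes <- render_visit_corpus(reg, tr, cfg)
  reg$income_quintile[1] <- NA  # force an unknown-quintile sentinel
  dir <- tempfile()
  paths <- write_corpus(reg, notes, dir)
  reg2 <- read_registry(paths["registry"])
  notes2 <- read_notes(paths["notes"])
  cols <- c("infant_id", "maternal_age", "parity", "urban", "immigrant",
            "income_quintile", "world_region", "birth_date", "birthweight_g",
            "gestational_age_wk", "infant_sex", "plurality")
  expect_equal(as.data.frame(reg2)[, cols], as.data.frame(reg)[, cols],
               ignore_attr = TRUE)
  expect_equal(notes2$text, notes$text)
  expect_equal(notes2$age_days, notes$age_days)
  expect_equal(notes2$structured_fields, notes$structured_fields,
               ignore_attr = TRUE)
  # unknown income quintile survives the sentinel
  expect_true(is.na(reg2$income_quintile[1]))
})

test_that("an empty note list writes a valid empty JSON-lines file", {
  cfg <- sim_config(n_infants = 2, seed = 6)
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  notes <- render_visit_corpus(reg, tr, cfg)
  dir <- tempfile()
  paths <- write_corpus(reg, notes[0, ], dir)
  expect_true(file.exists(paths["notes"]))
  empty <- read_notes(paths["notes"])
  expect_equal(nrow(empty), 0)
})
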