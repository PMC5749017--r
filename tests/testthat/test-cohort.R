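test_that("eligibility rules exclude with the documented reason codes", {
  reg <- rbind(
    make_record("ok"),
    make_record("late", ),
    make_record("preterm", gestational_age_wk = 36),
    make_record("twin", plurality = 2)
  )
  obs <- rbind(
    make_obs("ok", c(10, 62), c("EBF", "EBF")),
    make_obs("late", 200, "EBF"),       # first visit at 200 d
    make_obs("preterm", 10, "EBF"),
    make_obs("twin", 10, "EBF")
  )
  cohort <- build_cohort(reg, obs)
  expect_equal(cohort$records$infant_id, "ok")
  excl <- cohort$exclusions
  expect_equal(excl$reason[excl$infant_id == "late"], "no_visit_lt_190d")
  expect_equal(excl$reason[excl$infant_id == "preterm"], "preterm")
  expect_equal(excl$reason[excl$infant_id == "twin"], "multiple_birth")
})

test_that("visits beyond 750 days are dropped but the infant is retained", {
  reg <- make_record("a")
  obs <- make_obs("a", c(10, 800), c("EBF", "FORMULA"))
  cohort <- build_cohort(reg, obs)
  expect_equal(cohort$records$infant_id, "a")
  expect_equal(cohort$observations$age_days, 10L)
})

test_that("observations without a registry record are a data error", {
  expect_error(build_cohort(make_record("a"), make_obs("ghost", 10, "EBF")),
               class = "ebf_data_error")
})

test_that("the index visit is the closest not preceding the target", {
  obs <- make_obs("a", c(58, 63, 130), "EBF")
  expect_equal(select_index_visit(obs, 60)$age_days, 63L)
  expect_null(select_index_visit(make_obs("a", 58, "EBF"), 60))
  obs2 <- make_obs("a", c(60, 185), "EBF")
  expect_equal(select_index_visit(obs2, 60)$age_days, 60L)
})

test_that("status inference handles direct, future and historical evidence", {
  # current EBF at 60 and at 185 -> EBF at 122 (backward from future
  # current EBF) and at 182 (index within window)
  obs <- make_obs("a", c(60, 185), "EBF")
  s122 <- infer_status_at_timepoint(obs, 122)
  expect_equal(s122$status, "EBF")
  expect_equal(s122$evidence, "future_current_ebf")
  s182 <- infer_status_at_timepoint(obs, 182)
  expect_equal(s182$status, "EBF")
  expect_equal(s182$evidence, "index_visit")

  # single MIXED visit at 185: determines 182, not 60
  obs2 <- make_obs("a", 185, "MIXED")
  expect_equal(infer_status_at_timepoint(obs2, 182)$status, "NOT_EBF")
  expect_equal(infer_status_at_timepoint(obs2, 60)$status, "UNDETERMINED")

  # single visit at 200 with a historical statement covering 152 days
  obs3 <- rbind(make_obs("a", 200, "FORMULA"),
                make_obs("a", 200, "EBF", tense = "historical",
                         duration = 152))
  expect_equal(infer_status_at_timepoint(obs3, 60)$status, "EBF")
  expect_equal(infer_status_at_timepoint(obs3, 122)$status, "EBF")
  expect_equal(infer_status_at_timepoint(obs3, 182)$status, "NOT_EBF")

  # no qualifying visit leaves the infant outside the denominator
  s <- infer_status_at_timepoint(make_obs("a", 58, "EBF"), 60)
  expect_false(s$in_denominator)
  expect_equal(s$status, "UNDETERMINED")
  expect_equal(s$evidence, "none")
})

test_that("timepoint table has 3 rows per infant and propagates backwards", {
  cfg <- closure_config(200, seed = 23)
  res <- local({
    reg <- generate_birth_registry(cfg)
    tr <- generate_feeding_trajectories(reg, cfg)
    obs <- extract_all(render_visit_corpus(reg, tr, cfg))
    list(cohort = build_cohort(reg, obs), tr = tr)
  })
  st <- timepoint_table(res$cohort)
  expect_equal(nrow(st), 3 * nrow(res$cohort$records))
  wide <- reshape(st[, c("infant_id", "target_age", "status")],
                  idvar = "infant_id", timevar = "target_age",
                  direction = "wide")
  # EBF later implies EBF earlier
  expect_false(any(wide$status.182 == "EBF" & wide$status.60 != "EBF"))
  expect_false(any(wide$status.182 == "EBF" & wide$status.122 != "EBF"))
  expect_false(any(wide$status.122 == "EBF" & wide$status.60 != "EBF"))
  # closure corpus: nothing undetermined
  expect_equal(sum(st$status == "UNDETERMINED"), 0)
  # denominator counts are non-increasing in target age
  denom <- tapply(st$in_denominator, st$target_age, sum)
  expect_true(all(diff(denom) <= 0))
})

test_that("pipeline rates recover the generator survival targets", {
  # on-schedule visits so the index visit sits at the target age itself
  cfg <- sim_config(
    n_infants = 4000, seed = 37,
    visit_schedule = data.frame(age = c(7, 60, 122, 182),
                                attend_prob = 0.9, jitter_sd = 0))
  reg <- generate_birth_registry(cfg)
  tr <- generate_feeding_trajectories(reg, cfg)
  obs <- extract_all(render_visit_corpus(reg, tr, cfg))
  st <- timepoint_table(build_cohort(reg, obs))
  rates <- ebf_rates(st)
  targets <- c(0.395, 0.324, 0.251)
  for (k in 1:3) {
    se <- sqrt(targets[k] * (1 - targets[k]) / rates$n[k])
    expect_lt(abs(rates$rate[k] / 100 - targets[k]), 3 * se,
              label = sprintf("rate at %d d", rates$target_age[k]))
  }
})

test_that("EBF duration is the age of the latest confirmed EBF visit", {
  obs <- make_obs("a", c(60, 122, 182), c("EBF", "EBF", "MIXED"))
  expect_equal(ebf_duration(obs), 122)
  expect_true(is.na(ebf_duration(make_obs("a", 60, "FORMULA"))))
  expect_equal(ebf_duration(make_obs("a", 5, "EBF")), 5)
  # historical observations do not count as confirmed visits
  h <- make_obs("a", 200, "EBF", tense = "historical", duration = 150)
  expect_true(is.na(ebf_duration(h)))
})

test_that("complete cases require direct documentation at all three targets", {
  reg <- rbind(make_record("full"), make_record("gap"))
  obs <- rbind(
    make_obs("full", c(62, 125, 183), c("EBF", "EBF", "MIXED")),
    make_obs("gap", c(62, 183), c("EBF", "MIXED"))  # no 4-month visit
  )
  cohort <- build_cohort(reg, obs)
  st <- timepoint_table(cohort)
  cc <- complete_case_subset(cohort, st)
  expect_equal(cc$records$infant_id, "full")
  expect_lte(nrow(cc$records), nrow(cohort$records))
})
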