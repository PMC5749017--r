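# Shared fixtures: all corpora are generated in code at test time.

# Closure conditions: every infant fully documented, on-schedule jitterless
# visits — the regime in which the pipeline must recover ground truth
# exactly.
closure_config <- function(n, seed, ...) {
  sim_config(
    n_infants = n, seed = seed,
    undocumented_prob = 0,
    visit_schedule = data.frame(age = c(7, 60, 122, 182),
                                attend_prob = 1, jitter_sd = 0),
    ...
  )
}

# Hand-built observation rows for cohort/timepoint unit tests.
make_obs <- function(infant_id, age_days, status, tense = "current",
                     duration = NA_real_, source = "progress_note") {
  n <- max(length(age_days), length(status))
  out <- data.frame(
    infant_id = rep_len(infant_id, n),
    age_days = as.integer(rep_len(age_days, n)),
    status = rep_len(status, n),
    tense = rep_len(tense, n),
    historical_duration = as.numeric(rep_len(duration, n)),
    source = rep_len(source, n),
    stringsAsFactors = FALSE
  )
  out$matched_terms <- rep(list("term"), n)
  out
}

# One-row registry with overridable fields, valid under the default rules.
make_record <- function(infant_id = "X1", maternal_age = 30, parity = 1,
                        urban = TRUE, immigrant = FALSE, income_quintile = 3,
                        world_region = "Canada",
                        birth_date = as.Date("2010-06-01"),
                        birthweight_g = 3400, gestational_age_wk = 39,
                        infant_sex = "F", plurality = 1) {
  out <- data.frame(
    infant_id = infant_id, maternal_age = maternal_age, parity = parity,
    urban = urban, immigrant = immigrant, income_quintile = income_quintile,
    world_region = world_region, birth_date = birth_date,
    birthweight_g = birthweight_g, gestational_age_wk = gestational_age_wk,
    infant_sex = infant_sex, plurality = plurality,
    stringsAsFactors = FALSE
  )
  out$birth_year_band <- ifelse(
    as.integer(format(out$birth_date, "%Y")) <= 2007,
    "2002-2007", "2008-2013")
  class(out) <- c("ebf_registry", "data.frame")
  out
}

# Ground-truth EBF flag per infant at a target age, aligned to a status
# table's infant order.
truth_ebf_at <- function(trajectories, statuses, target) {
  ids <- unique(statuses$infant_id)
  tr <- trajectories[match(ids, trajectories$infant_id), ]
  stats::setNames(target < tr$ebf_end_age, ids)
}
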