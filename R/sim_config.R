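# Simulation configuration for the synthetic EMR corpus generator.

#' Default registry marginals for the synthetic birth registry
#'
#' Marginal covariate distributions used by [generate_birth_registry()],
#' chosen to emulate a primary-care EMR birth cohort in Ontario: maternal age
#' ~ N(30.2, 5.3) years, 75.6% urban residence, 12.4% immigrant mothers,
#' income quintiles near-uniform with a small unknown fraction, birthweight
#' ~ N(3490, 464) g, gestational age truncated-normal(39.3, 1.1) at >= 37
#' completed weeks (the generator emits term singletons only; preterm and
#' multiple births are excluded from the emulated design), 51.4% male, and
#' 77.2% of births in the 2008-2013 band reflecting growing EMR uptake.
#'
#' @return named list of marginal parameters.
#' @export
default_registry_marginals <- function() {
  list(
    maternal_age_mean = 30.2, maternal_age_sd = 5.3,
    parity_lambda     = 1.2,
    urban_prob        = 0.756,
    region_probs      = c("Canada" = 0.876, "Europe/Western" = 0.041,
                          "Africa/Caribbean" = 0.015,
                          "Middle East/N Africa" = 0.014,
                          "Latin America" = 0.014, "South Asia" = 0.015,
                          "East Asia" = 0.026),
    income_probs      = c("Q1" = 0.175, "Q2" = 0.188, "Q3" = 0.218,
                          "Q4" = 0.216, "Q5" = 0.199, "unknown" = 0.004),
    birthweight_mean  = 3490, birthweight_sd = 464,
    ga_mean           = 39.3, ga_sd = 1.1,
    male_prob         = 0.514,
    late_band_prob    = 0.772
  )
}

#' Default covariate effects on exclusive-breastfeeding discontinuation
#'
#' Log hazard ratios applied multiplicatively to the baseline discontinuation
#' hazard of exclusive breastfeeding. Positive values mean earlier weaning.
#' The defaults qualitatively reproduce the gradients seen in primary-care
#' cohorts (younger, rural, lower-income mothers wean earlier; immigrant
#' status nearly neutral overall); they are deliberately modest so that the
#' population-average survival stays close to the configured calibration
#' targets (the per-infant hazard ratio is normalized to mean 1, see
#' [generate_feeding_trajectory()]).
#'
#' @return named list: one named numeric vector of log hazard ratios per
#'   covariate.
#' @export
default_covariate_effects <- function() {
  list(
    maternal_age_band = c("<20" = 0.24, "20-24" = 0.15, "25-29" = 0.03,
                          "30-34" = -0.06, "35-39" = -0.07, ">=40" = -0.09),
    urban             = c("no" = 0, "yes" = -0.15),
    income_quintile   = c("Q1" = 0.07, "Q2" = 0, "Q3" = -0.01,
                          "Q4" = -0.05, "Q5" = -0.03, "unknown" = 0.18),
    immigrant         = c("no" = 0, "yes" = -0.03),
    birth_year_band   = c("2002-2007" = 0.11, "2008-2013" = -0.02)
  )
}

#' Default well-baby visit schedule
#'
#' Target visit ages follow the infant immunization-schedule anchors: an
#' early newborn check then visits near 2, 4 and 6 months. Each visit is
#' attended with probability 0.9 and jittered by a Gaussian with SD 7 days
#' (ages truncated at 0).
#'
#' @return data.frame with columns `age`, `attend_prob`, `jitter_sd`.
#' @export
default_visit_schedule <- function() {
  data.frame(age = c(7, 60, 122, 182),
             attend_prob = 0.9,
             jitter_sd = 7)
}

#' Build a validated simulation configuration
#'
#' Assembles and validates every knob of the synthetic EMR generator. The
#' central calibration constants are the exclusive-breastfeeding (EBF)
#' survival targets at 60/122/182 days of age — defaults 39.5%/32.4%/25.1% —
#' together with a point mass `p_never_ebf` of infants exclusively
#' formula-fed from birth (default 14.5%). A piecewise-constant
#' discontinuation hazard is solved from these targets so that, at reference
#' covariates, P(EBF end age > t) equals the targets exactly.
#'
#' @param n_infants number of infants to simulate (>= 1).
#' @param seed integer RNG seed; mandatory, all corpus randomness derives
#'   from it.
#' @param rourke_prob probability an infant's chart carries a Rourke Baby
#'   Record form name (default 0.80).
#' @param undocumented_prob probability an infant's notes carry no feeding
#'   terms at all (default 0.118).
#' @param ebf_survival_targets length-3 non-increasing probabilities of
#'   still-exclusive breastfeeding at 60, 122 and 182 days.
#' @param p_never_ebf point mass of never-exclusively-breastfed infants;
#'   must not exceed `1 - ebf_survival_targets[1]`.
#' @param covariate_effects named list of log hazard ratios per covariate
#'   level (see [default_covariate_effects()]); `NULL` disables covariate
#'   dependence (all infants at reference).
#' @param visit_schedule data.frame of target ages, attendance probabilities
#'   and jitter SDs (see [default_visit_schedule()]).
#' @param structured_prob probability a Rourke note records feeding in a
#'   structured field rather than free text.
#' @param historical_prob probability a post-weaning note states the past
#'   exclusive-breastfeeding duration in past tense.
#' @param mixed_mean_extra mean additional days of mixed feeding after
#'   exclusive breastfeeding ends.
#' @param marginals registry marginals, see [default_registry_marginals()].
#' @param study_start,study_end calendar bounds on birth dates.
#' @param max_age_days maximum note age retained by the study design (750).
#' @return an object of class `ebf_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_infants = 100, seed = 42)
sim_config <- function(n_infants,
                       seed,
                       rourke_prob = 0.80,
                       undocumented_prob = 0.118,
                       ebf_survival_targets = c(0.395, 0.324, 0.251),
                       p_never_ebf = 0.145,
                       covariate_effects = default_covariate_effects(),
                       visit_schedule = default_visit_schedule(),
                       structured_prob = 0.5,
                       historical_prob = 0.5,
                       mixed_mean_extra = 60,
                       marginals = default_registry_marginals(),
                       study_start = as.Date("2002-04-01"),
                       study_end = as.Date("2013-03-31"),
                       max_age_days = 750) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    config_error("a seed is mandatory in sim_config()")
  }
  seed <- as.integer(seed)
  if (!is.numeric(n_infants) || length(n_infants) != 1 || is.na(n_infants) ||
      n_infants < 1) {
    config_error("n_infants must be >= 1")
  }
  stopifnot_prob(rourke_prob, "rourke_prob")
  stopifnot_prob(undocumented_prob, "undocumented_prob")
  stopifnot_prob(structured_prob, "structured_prob")
  stopifnot_prob(historical_prob, "historical_prob")
  stopifnot_prob(ebf_survival_targets, "ebf_survival_targets")
  stopifnot_prob(p_never_ebf, "p_never_ebf")
  if (length(ebf_survival_targets) != 3 ||
      any(diff(ebf_survival_targets) > 0)) {
    config_error("ebf_survival_targets must be 3 non-increasing probabilities")
  }
  if (any(ebf_survival_targets <= 0)) {
    config_error("ebf_survival_targets must be positive")
  }
  if (p_never_ebf > 1 - ebf_survival_targets[1] + 1e-12) {
    config_error(
      "p_never_ebf (%.3f) exceeds 1 - ebf_survival_targets[1] (%.3f)",
      p_never_ebf, 1 - ebf_survival_targets[1])
  }
  if (!is.data.frame(visit_schedule) ||
      !all(c("age", "attend_prob", "jitter_sd") %in% names(visit_schedule))) {
    config_error("visit_schedule needs columns age, attend_prob, jitter_sd")
  }
  stopifnot_prob(visit_schedule$attend_prob, "visit_schedule$attend_prob")
  if (any(visit_schedule$jitter_sd < 0)) {
    config_error("visit_schedule$jitter_sd must be >= 0")
  }
  structure(list(
    n_infants = as.integer(n_infants),
    seed = seed,
    rourke_prob = rourke_prob,
    undocumented_prob = undocumented_prob,
    ebf_survival_targets = stats::setNames(ebf_survival_targets,
                                           c("d60", "d122", "d182")),
    p_never_ebf = p_never_ebf,
    covariate_effects = covariate_effects,
    visit_schedule = visit_schedule,
    structured_prob = structured_prob,
    historical_prob = historical_prob,
    mixed_mean_extra = mixed_mean_extra,
    marginals = marginals,
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    max_age_days = max_age_days
  ), class = "ebf_sim_config")
}

#' @export
print.ebf_sim_config <- function(x, ...) {
  cat("<ebf_sim_config>\n")
  cat(sprintf("  n_infants: %d   seed: %d\n", x$n_infants, x$seed))
  cat(sprintf("  EBF survival targets (60/122/182 d): %.3f / %.3f / %.3f\n",
              x$ebf_survival_targets[1], x$ebf_survival_targets[2],
              x$ebf_survival_targets[3]))
  cat(sprintf("  rourke_prob: %.3f   undocumented_prob: %.3f\n",
              x$rourke_prob, x$undocumented_prob))
  cat(sprintf("  visits at ages: %s\n",
              paste(x$visit_schedule$age, collapse = ", ")))
  invisible(x)
}

#' Read/write a simulation configuration as YAML
#'
#' @param config an `ebf_sim_config`.
#' @param path YAML file path.
#' @return `write_sim_config()` returns the path invisibly;
#'   `read_sim_config()` returns a validated `ebf_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "ebf_sim_config"))
  x <- unclass(config)
  x$study_start <- as.character(x$study_start)
  x$study_end <- as.character(x$study_end)
  x$ebf_survival_targets <- as.numeric(x$ebf_survival_targets)
  x$visit_schedule <- as.list(x$visit_schedule)
  # named vectors must become maps to keep their names in YAML
  if (!is.null(x$covariate_effects)) {
    x$covariate_effects <- lapply(x$covariate_effects, as.list)
  }
  x$marginals <- lapply(x$marginals, function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) io_error("config file not found: %s", path)
  x <- yaml::read_yaml(path)
  if (is.null(x$seed)) config_error("config file has no seed: %s", path)
  vs <- if (!is.null(x$visit_schedule)) {
    as.data.frame(lapply(x$visit_schedule, unlist))
  } else {
    default_visit_schedule()
  }
  ce <- if (is.null(x$covariate_effects)) NULL else {
    lapply(x$covariate_effects, function(v) unlist(v))
  }
  sim_config(
    n_infants = x$n_infants, seed = x$seed,
    rourke_prob = x$rourke_prob %||% 0.80,
    undocumented_prob = x$undocumented_prob %||% 0.118,
    ebf_survival_targets = unlist(x$ebf_survival_targets) %||%
      c(0.395, 0.324, 0.251),
    p_never_ebf = x$p_never_ebf %||% 0.145,
    covariate_effects = ce,
    visit_schedule = vs,
    structured_prob = x$structured_prob %||% 0.5,
    historical_prob = x$historical_prob %||% 0.5,
    mixed_mean_extra = x$mixed_mean_extra %||% 60,
    marginals = if (is.null(x$marginals)) default_registry_marginals() else
      utils::modifyList(default_registry_marginals(),
                        lapply(x$marginals, unlist)),
    study_start = x$study_start %||% "2002-04-01",
    study_end = x$study_end %||% "2013-03-31",
    max_age_days = x$max_age_days %||% 750
  )
}
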