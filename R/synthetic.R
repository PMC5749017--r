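# Synthetic EMR generator: birth registry, latent feeding trajectories and
# a rendered well-baby visit-note corpus with known ground truth.

#' Generate a synthetic birth registry
#'
#' Draws `config$n_infants` maternal-infant records with independent
#' covariates at the configured marginal frequencies (see
#' [default_registry_marginals()]). All infants are term singletons; birth
#' dates fall inside the configured study window with the configured split
#' between the 2002-2007 and 2008-2013 birth-year bands. The draw is fully
#' determined by `config$seed`.
#'
#' @param config an [sim_config()] object.
#' @return data.frame of class `ebf_registry`, one row per infant, columns
#'   `infant_id, maternal_age, parity, urban, immigrant, income_quintile,
#'   world_region, birth_date, birthweight_g, gestational_age_wk, infant_sex,
#'   plurality, birth_year_band`. Unknown income quintile is `NA`.
#' @export
#' @examples
#' reg <- generate_birth_registry(sim_config(n_infants = 50, seed = 1))
#' table(reg$income_quintile, useNA = "ifany")
generate_birth_registry <- function(config) {
  stopifnot(inherits(config, "ebf_sim_config"))
  set.seed(config$seed)
  n <- config$n_infants
  m <- config$marginals

  maternal_age <- pmin(55L, pmax(12L, as.integer(round(
    stats::rnorm(n, m$maternal_age_mean, m$maternal_age_sd)))))
  parity <- stats::rpois(n, m$parity_lambda)
  urban <- stats::runif(n) < m$urban_prob
  region_probs <- m$region_probs / sum(m$region_probs)
  world_region <- sample(names(region_probs), n, replace = TRUE,
                         prob = region_probs)
  immigrant <- world_region != "Canada"
  income_probs <- m$income_probs / sum(m$income_probs)
  iq <- sample(names(income_probs), n, replace = TRUE, prob = income_probs)
  income_quintile <- match(iq, paste0("Q", 1:5))  # "unknown" -> NA

  # birth dates: band membership first, then uniform within band
  band_break <- as.Date("2008-01-01")
  late <- stats::runif(n) < m$late_band_prob
  early_days <- as.integer(band_break - 1 - config$study_start)
  late_days <- as.integer(config$study_end - band_break)
  birth_date <- as.Date(ifelse(
    late,
    band_break + floor(stats::runif(n) * (late_days + 1)),
    config$study_start + floor(stats::runif(n) * (early_days + 1))),
    origin = "1970-01-01")

  birthweight_g <- pmin(6000L, pmax(1500L, as.integer(round(
    stats::rnorm(n, m$birthweight_mean, m$birthweight_sd)))))
  # gestational age truncated at term (>= 37 completed weeks)
  p_lo <- stats::pnorm(37, m$ga_mean, m$ga_sd)
  p_hi <- stats::pnorm(44, m$ga_mean, m$ga_sd)
  ga <- as.integer(floor(stats::qnorm(stats::runif(n, p_lo, p_hi),
                                      m$ga_mean, m$ga_sd)))
  infant_sex <- ifelse(stats::runif(n) < m$male_prob, "M", "F")

  out <- data.frame(
    infant_id = sprintf("INF%06d", seq_len(n)),
    maternal_age = maternal_age,
    parity = parity,
    urban = urban,
    immigrant = immigrant,
    income_quintile = income_quintile,
    world_region = world_region,
    birth_date = birth_date,
    birthweight_g = birthweight_g,
    gestational_age_wk = ga,
    infant_sex = infant_sex,
    plurality = 1L,
    stringsAsFactors = FALSE
  )
  out$birth_year_band <- birth_year_band(out$birth_date)
  class(out) <- c("ebf_registry", "data.frame")
  out
}

birth_year_band <- function(birth_date) {
  ifelse(as.integer(format(as.Date(birth_date), "%Y")) <= 2007,
         "2002-2007", "2008-2013")
}

# Covariate level labels used both by the hazard model and by the
# Table-2-style stratification.
covariate_level <- function(registry, covariate) {
  switch(covariate,
    maternal_age_band = cut(registry$maternal_age,
                            breaks = c(-Inf, 19, 24, 29, 34, 39, Inf),
                            labels = c("<20", "20-24", "25-29", "30-34",
                                       "35-39", ">=40")),
    parity_band = factor(ifelse(registry$parity >= 1, "Multiparous",
                                "Primiparous"),
                         levels = c("Multiparous", "Primiparous")),
    urban = factor(ifelse(registry$urban, "yes", "no"),
                   levels = c("no", "yes")),
    immigrant = factor(ifelse(registry$immigrant, "yes", "no"),
                       levels = c("no", "yes")),
    income_quintile = factor(
      ifelse(is.na(registry$income_quintile), "unknown",
             paste0("Q", registry$income_quintile)),
      levels = c("Q1", "Q2", "Q3", "Q4", "Q5", "unknown")),
    income_immigrant = factor(
      ifelse(is.na(registry$income_quintile), "unknown",
        ifelse(registry$income_quintile == 1,
          ifelse(registry$immigrant, "Q1 & immigrant", "Q1 & non-immigrant"),
          ifelse(registry$immigrant, "Q2-Q5 & immigrant",
                 "Q2-Q5 & non-immigrant"))),
      levels = c("Q1 & non-immigrant", "Q1 & immigrant",
                 "Q2-Q5 & non-immigrant", "Q2-Q5 & immigrant", "unknown")),
    birthweight_band = cut(registry$birthweight_g,
                           breaks = c(-Inf, 2499, 2999, 3499, Inf),
                           labels = c("<2500", "2500-<3000", "3000-<3500",
                                      ">=3500")),
    birth_year_band = factor(registry$birth_year_band,
                             levels = c("2002-2007", "2008-2013")),
    config_error("unknown covariate '%s'", covariate)
  )
}

# --- feeding trajectory model ------------------------------------------------

# Piecewise-constant hazard rates on (0,60], (60,122], (122,182], (182,750]
# solved from the three survival targets (rescaled for the never-EBF point
# mass); the tail hazard continues the last solved rate.
hazard_rates <- function(config) {
  s <- as.numeric(config$ebf_survival_targets) / (1 - config$p_never_ebf)
  if (any(s > 1 + 1e-12)) {
    config_error("survival targets incompatible with p_never_ebf")
  }
  s <- pmin(s, 1)
  widths <- c(60, 62, 60)
  lam <- -diff(c(0, log(s))) / widths  # -log(s1)/60, -log(s2/s1)/62, ...
  c(lam, lam[3])
}

#' Draw latent exclusive-breastfeeding end ages
#'
#' Inverse-transform sampling from the piecewise-constant-hazard survival
#' model calibrated to `config$ebf_survival_targets`, combined with the
#' `p_never_ebf` point mass at 0. With `hazard_ratio = 1` (reference
#' covariates), P(end age > t) equals the configured target at t = 60, 122
#' and 182 days exactly. Uses the current RNG state.
#'
#' @param n number of draws.
#' @param config an [sim_config()] object.
#' @param hazard_ratio multiplicative shift of the discontinuation hazard
#'   (vector of length 1 or `n`).
#' @return numeric vector of end ages in days; 0 means never exclusively
#'   breastfed, `Inf` means the hazard never accumulated enough mass (e.g.
#'   all-zero hazards).
#' @export
draw_ebf_end <- function(n, config, hazard_ratio = 1) {
  lam <- hazard_rates(config)
  never <- stats::runif(n) < config$p_never_ebf
  target <- stats::rexp(n) / hazard_ratio  # cumulative hazard to absorb
  breaks <- c(0, 60, 122, 182)
  cumL <- cumsum(c(lam[1] * 60, lam[2] * 62, lam[3] * 60))  # Lambda at breaks
  t_end <- rep(Inf, n)
  lo <- c(0, cumL)
  for (seg in 4:1) {
    in_seg <- if (seg == 4) target >= lo[4] else
      target >= lo[seg] & target < lo[seg + 1]
    if (lam[seg] > 0) {
      t_end[in_seg] <- breaks[seg] + (target[in_seg] - lo[seg]) / lam[seg]
    } else {
      t_end[in_seg] <- Inf
    }
  }
  ifelse(never, 0, t_end)
}

# Population-mean hazard ratio implied by the configured marginals, used to
# normalize per-infant hazard ratios to mean 1 so covariate effects do not
# shift the population survival away from the calibration targets.
mean_hazard_ratio <- function(config) {
  eff <- config$covariate_effects
  if (is.null(eff) || length(eff) == 0) return(1)
  m <- config$marginals
  region_probs <- m$region_probs / sum(m$region_probs)
  income_probs <- m$income_probs / sum(m$income_probs)
  age_cuts <- c(-Inf, 19.5, 24.5, 29.5, 34.5, 39.5, Inf)
  age_p <- diff(stats::pnorm(age_cuts, m$maternal_age_mean,
                             m$maternal_age_sd))
  level_probs <- list(
    maternal_age_band = stats::setNames(age_p, c("<20", "20-24", "25-29",
                                                 "30-34", "35-39", ">=40")),
    urban = c("no" = 1 - m$urban_prob, "yes" = m$urban_prob),
    immigrant = c("no" = unname(region_probs["Canada"]),
                  "yes" = 1 - unname(region_probs["Canada"])),
    income_quintile = income_probs,
    birth_year_band = c("2002-2007" = 1 - m$late_band_prob,
                        "2008-2013" = m$late_band_prob)
  )
  out <- 1
  for (cov in names(eff)) {
    p <- level_probs[[cov]]
    if (is.null(p)) next  # user-supplied covariate with no marginal: skip
    e <- eff[[cov]][names(p)]
    e[is.na(e)] <- 0
    out <- out * sum(p * exp(e))
  }
  out
}

# Per-record multiplicative hazard ratio (normalized to population mean 1).
record_hazard_ratio <- function(record, config) {
  eff <- config$covariate_effects
  if (is.null(eff) || length(eff) == 0) return(rep(1, nrow(record)))
  lp <- numeric(nrow(record))
  for (cov in names(eff)) {
    lev <- as.character(covariate_level(record, cov))
    e <- eff[[cov]][lev]
    e[is.na(e)] <- 0
    lp <- lp + e
  }
  exp(lp) / mean_hazard_ratio(config)
}

#' Generate a latent feeding trajectory for one infant
#'
#' Draws the age at which exclusive breastfeeding (EBF) ends from the
#' calibrated piecewise-constant-hazard model, shifted multiplicatively by
#' the infant's covariate hazard ratio, followed by an exponential tail of
#' mixed feeding. Ground truth at age `a` is EBF iff `a < ebf_end_age`,
#' MIXED on `[ebf_end_age, mixed_end_age)`, FORMULA afterwards; infants with
#' `ebf_end_age = 0` are exclusively formula-fed from birth.
#'
#' Uses the current RNG state; use [generate_feeding_trajectories()] for a
#' whole registry under a deterministic seed.
#'
#' @param record one-row registry data.frame.
#' @param config an [sim_config()] object.
#' @return one-row data.frame with `infant_id, ebf_end_age, mixed_end_age,
#'   ever_formula`.
#' @export
generate_feeding_trajectory <- function(record, config) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  hr <- record_hazard_ratio(record, config)
  ebf_end <- draw_ebf_end(1, config, hazard_ratio = hr)
  mixed_end <- if (ebf_end == 0) 0 else
    ebf_end + stats::rexp(1, 1 / config$mixed_mean_extra)
  data.frame(
    infant_id = record$infant_id,
    ebf_end_age = ebf_end,
    mixed_end_age = mixed_end,
    ever_formula = ebf_end < config$max_age_days,
    stringsAsFactors = FALSE
  )
}

#' Generate feeding trajectories for a whole registry
#'
#' Vectorized, deterministic counterpart of [generate_feeding_trajectory()]:
#' seeds the RNG at `config$seed + 1` and draws one trajectory per registry
#' row.
#'
#' @param registry output of [generate_birth_registry()].
#' @param config an [sim_config()] object.
#' @return data.frame with one row per infant.
#' @export
generate_feeding_trajectories <- function(registry, config) {
  stopifnot(inherits(config, "ebf_sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(registry)
  hr <- record_hazard_ratio(registry, config)
  ebf_end <- draw_ebf_end(n, config, hazard_ratio = hr)
  extra <- stats::rexp(n, 1 / config$mixed_mean_extra)
  mixed_end <- ifelse(ebf_end == 0, 0, ebf_end + extra)
  data.frame(
    infant_id = registry$infant_id,
    ebf_end_age = ebf_end,
    mixed_end_age = mixed_end,
    ever_formula = ebf_end < config$max_age_days,
    stringsAsFactors = FALSE
  )
}

#' Ground-truth feeding status at a given age
#'
#' @param trajectory data.frame of trajectories (any number of rows).
#' @param age age in days.
#' @return character vector: `"EBF"`, `"MIXED"` or `"FORMULA"`.
#' @export
truth_status <- function(trajectory, age) {
  ifelse(age < trajectory$ebf_end_age, "EBF",
         ifelse(age < trajectory$mixed_end_age, "MIXED", "FORMULA"))
}
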