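# Stratified rate-ratio tables, covariate balance tables, and reproduction
# of the published summary tables from their printed cells.

# Fixed referent level per covariate (the published table convention); the
# alternative "lowest" convention takes the level with the lowest rate.
FIXED_REFERENTS <- c(
  maternal_age_band = "<20",
  parity_band = "Multiparous",
  urban = "no",
  immigrant = "no",
  income_quintile = "Q1",
  income_immigrant = "Q1 & non-immigrant",
  birthweight_band = "<2500",
  birth_year_band = "2002-2007"
)

#' Covariates available for stratified rate-ratio tables
#' @return character vector of covariate names.
#' @export
rr_covariates <- function() names(FIXED_REFERENTS)

#' Stratified exclusive-breastfeeding rates and rate ratios
#'
#' Builds one row per covariate level (plus the unknown level where
#' applicable) at one target age: stratum size, exclusive-breastfeeding rate
#' (percent, among determined statuses) and the rate ratio against the
#' referent with its Katz 95% CI. The referent is either the fixed
#' published-convention level (`referent = "fixed"`, default) or the level
#' with the lowest rate (`referent = "lowest"`; ties go to the first level).
#'
#' @param statuses output of [timepoint_table()].
#' @param registry an `ebf_registry` covering the statuses' infants.
#' @param covariate one of [rr_covariates()].
#' @param target_age one of 60, 122, 182.
#' @param referent `"fixed"` or `"lowest"`, or give `referent_level`.
#' @param referent_level explicit referent level label (overrides
#'   `referent`).
#' @return data.frame: `stratum_label, n, n_ebf, rate, rr, ci_low, ci_high,
#'   is_referent`. Empty strata keep `n = 0` with undefined rate.
#' @export
stratified_rr_table <- function(statuses, registry, covariate, target_age,
                                referent = c("fixed", "lowest"),
                                referent_level = NULL) {
  referent <- match.arg(referent)
  st <- statuses[statuses$target_age == target_age &
                   statuses$status != "UNDETERMINED", , drop = FALSE]
  idx <- match(st$infant_id, registry$infant_id)
  if (anyNA(idx)) data_error("statuses contain infants missing from registry")
  lev <- covariate_level(registry[idx, , drop = FALSE], covariate)

  levels_all <- levels(lev)
  n <- as.integer(table(lev))
  n_ebf <- as.integer(tapply(st$status == "EBF", lev, sum, default = 0))
  rate_pct <- ifelse(n > 0, 100 * n_ebf / n, NA_real_)

  ref_level <- referent_level %||% if (referent == "fixed") {
    unname(FIXED_REFERENTS[covariate])
  } else {
    levels_all[which.min(replace(rate_pct, n == 0, Inf))]
  }
  ref_i <- match(ref_level, levels_all)
  if (is.na(ref_i)) config_error("unknown referent level '%s'", ref_level)

  out <- data.frame(stratum_label = levels_all, n = n, n_ebf = n_ebf,
                    rate = rate_pct, rr = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, is_referent = FALSE,
                    stringsAsFactors = FALSE)
  out$is_referent[ref_i] <- TRUE
  # an empty or zero-rate referent leaves every ratio undefined
  p0 <- if (n[ref_i] > 0) n_ebf[ref_i] / n[ref_i] else NA_real_
  if (n[ref_i] > 0) out$rr[ref_i] <- 1
  for (i in seq_along(levels_all)) {
    if (i == ref_i || n[i] == 0) next
    if (is.na(p0) || p0 == 0) next
    f <- rate_ratio(n_ebf[i] / n[i], n[i], p0, n[ref_i])
    out$rr[i] <- f$rr
    out$ci_low[i] <- f$ci_low
    out$ci_high[i] <- f$ci_high
  }
  rownames(out) <- NULL
  out
}

registry_balance_summaries <- function(registry) {
  iq <- registry$income_quintile
  list(
    maternal_age = list(mean = mean(registry$maternal_age),
                        sd = stats::sd(registry$maternal_age)),
    parity = list(mean = mean(registry$parity),
                  sd = stats::sd(registry$parity)),
    rural = list(p = mean(!registry$urban)),
    immigrant = list(p = mean(registry$immigrant)),
    income_q1 = list(p = mean(!is.na(iq) & iq == 1)),
    income_q2 = list(p = mean(!is.na(iq) & iq == 2)),
    income_q3 = list(p = mean(!is.na(iq) & iq == 3)),
    income_q4 = list(p = mean(!is.na(iq) & iq == 4)),
    income_q5 = list(p = mean(!is.na(iq) & iq == 5)),
    income_unknown = list(p = mean(is.na(iq))),
    birthweight = list(mean = mean(registry$birthweight_g),
                       sd = stats::sd(registry$birthweight_g)),
    gestational_age = list(mean = mean(registry$gestational_age_wk),
                           sd = stats::sd(registry$gestational_age_wk)),
    male_sex = list(p = mean(registry$infant_sex == "M"))
  )
}

#' Covariate balance table between two birth registries
#'
#' One row per characteristic with each cohort's summary (proportion, or
#' mean and SD) and the standardized difference (sign: `registry_a` minus
#' `registry_b`).
#'
#' @param registry_a,registry_b two `ebf_registry` data.frames sharing the
#'   registry schema.
#' @return data.frame: `characteristic, kind, a_mean, a_sd, a_p, b_mean,
#'   b_sd, b_p, std_diff`.
#' @export
balance_table <- function(registry_a, registry_b) {
  need <- setdiff(REGISTRY_COLUMNS, "infant_id")
  if (!all(need %in% names(registry_a)) || !all(need %in% names(registry_b))) {
    data_error("balance_table: registries do not share the registry schema")
  }
  sa <- registry_balance_summaries(registry_a)
  sb <- registry_balance_summaries(registry_b)
  rows <- lapply(names(sa), function(ch) {
    a <- sa[[ch]]; b <- sb[[ch]]
    binary <- !is.null(a$p)
    data.frame(
      characteristic = ch,
      kind = if (binary) "binary" else "continuous",
      a_mean = if (binary) NA_real_ else a$mean,
      a_sd = if (binary) NA_real_ else a$sd,
      a_p = if (binary) a$p else NA_real_,
      b_mean = if (binary) NA_real_ else b$mean,
      b_sd = if (binary) NA_real_ else b$sd,
      b_p = if (binary) b$p else NA_real_,
      std_diff = standardized_difference(a, b),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- published-table reproduction -------------------------------------------

#' Published summary tables bundled as plain-text fixtures
#'
#' `printed_table2()` returns the published stratified
#' exclusive-breastfeeding rate table (stratum sizes, rates, rate ratios and
#' CI bounds at the three target ages); `printed_table1()` the published
#' cohort-balance summaries; `printed_flow()` the published cohort flow
#' counts as a named numeric vector.
#'
#' @return data.frame (or named numeric vector for `printed_flow()`).
#' @export
printed_table2 <- function() {
  utils::read.csv(system.file("extdata", "printed_table2.csv",
                              package = "ebfemr"),
                  stringsAsFactors = FALSE)
}

#' @rdname printed_table2
#' @export
printed_table1 <- function() {
  utils::read.csv(system.file("extdata", "printed_table1.csv",
                              package = "ebfemr"),
                  stringsAsFactors = FALSE)
}

#' @rdname printed_table2
#' @export
printed_flow <- function() {
  x <- utils::read.csv(system.file("extdata", "printed_flow.csv",
                                   package = "ebfemr"),
                       stringsAsFactors = FALSE)
  stats::setNames(x$value, x$quantity)
}

#' Recompute published rate ratios from printed rates and denominators
#'
#' For every non-referent row of the published stratified table, recomputes
#' the rate ratio and its Katz 95% CI from the printed stratum rate and
#' denominator against the printed referent row of the same covariate and
#' target age. Numerator counts are recovered as `round(n * rate / 100)`.
#'
#' @param table2 the printed table (default [printed_table2()]).
#' @return the table with added columns `rr_calc, ci_low_calc, ci_high_calc`.
#' @export
#' @examples
#' rep <- reproduce_printed_rr()
#' subset(rep, covariate == "urban" & age_days == 182)
reproduce_printed_rr <- function(table2 = printed_table2()) {
  t2 <- table2[table2$covariate != "overall", , drop = FALSE]
  t2$rr_calc <- NA_real_
  t2$ci_low_calc <- NA_real_
  t2$ci_high_calc <- NA_real_
  for (cov in unique(t2$covariate)) {
    for (age in unique(t2$age_days)) {
      blk <- which(t2$covariate == cov & t2$age_days == age)
      ref <- blk[t2$is_referent[blk]]
      stopifnot(length(ref) == 1)
      n0 <- t2$n[ref]
      p0 <- round(n0 * t2$rate[ref] / 100) / n0
      t2$rr_calc[ref] <- 1
      for (i in setdiff(blk, ref)) {
        n1 <- t2$n[i]
        p1 <- round(n1 * t2$rate[i] / 100) / n1
        f <- rate_ratio(p1, n1, p0, n0)
        t2$rr_calc[i] <- f$rr
        t2$ci_low_calc[i] <- f$ci_low
        t2$ci_high_calc[i] <- f$ci_high
      }
    }
  }
  rownames(t2) <- NULL
  t2
}
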