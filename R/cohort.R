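# Cohort eligibility, index-visit selection and longitudinal inference of
# exclusive-breastfeeding status at the 2/4/6-month target ages.

TARGET_AGES <- c(60L, 122L, 182L)

#' Default index-visit carry-forward windows
#'
#' Number of days after each target age within which an index visit's
#' current status is carried to the target. Defaults are the gap to the next
#' target (62 days after the 2-month target, 60 after the 4-month target)
#' and effectively unbounded (568 days, i.e. to the 750-day record limit)
#' for the 6-month target. Beyond the window, only current exclusive
#' breastfeeding, or a historical statement covering the target, is
#' informative (backward inference).
#'
#' @return named numeric vector over target ages 60/122/182.
#' @export
default_windows <- function() {
  c("60" = 62, "122" = 60, "182" = 568)
}

#' Apply the study eligibility rules
#'
#' Retains singleton (`plurality == 1`), term (`gestational_age_wk >=
#' term_weeks`) infants with at least one visit-backed observation before
#' `min_visit_age` days of age; observations beyond `max_age` days are
#' dropped (record-retention limit). Excluded infants are logged with reason
#' codes `multiple_birth`, `preterm` and `no_visit_lt_190d`.
#'
#' @param registry an `ebf_registry`.
#' @param observations an `ebf_observations` data.frame (per-visit extracted
#'   statuses).
#' @param term_weeks completed weeks of gestation defining a term birth (37).
#' @param min_visit_age eligibility cut-off for the first visit (190 days).
#' @param max_age record-retention limit in days (750).
#' @return list of class `ebf_cohort`: `records`, `observations`,
#'   `exclusions` (data.frame `infant_id, reason`).
#' @export
build_cohort <- function(registry, observations, term_weeks = 37,
                         min_visit_age = 190, max_age = 750) {
  orphan <- setdiff(unique(observations$infant_id), registry$infant_id)
  if (length(orphan) > 0) {
    data_error("observation(s) with no registry record: %s",
               paste(utils::head(orphan, 5), collapse = ", "))
  }
  observations <- observations[observations$age_days <= max_age, ,
                               drop = FALSE]
  first_visit <- tapply(observations$age_days, observations$infant_id, min)
  fv <- first_visit[registry$infant_id]

  reason <- rep(NA_character_, nrow(registry))
  reason[is.na(reason) & registry$plurality > 1] <- "multiple_birth"
  reason[is.na(reason) & registry$gestational_age_wk < term_weeks] <- "preterm"
  reason[is.na(reason) & (is.na(fv) | fv >= min_visit_age)] <-
    "no_visit_lt_190d"

  keep <- is.na(reason)
  exclusions <- data.frame(infant_id = registry$infant_id[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  records <- registry[keep, , drop = FALSE]
  observations <- observations[
    observations$infant_id %in% records$infant_id, , drop = FALSE]
  structure(list(records = records, observations = observations,
                 exclusions = exclusions),
            class = "ebf_cohort")
}

#' @export
print.ebf_cohort <- function(x, ...) {
  cat("<ebf_cohort>\n")
  cat(sprintf("  %d eligible infants, %d observations, %d excluded\n",
              nrow(x$records), nrow(x$observations), nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason)
    cat(sprintf("  exclusions: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' Select the index visit for a target age
#'
#' The visit closest to, but not preceding, the target age: the
#' minimum-age current-status observation with `age_days >= target_age`.
#'
#' @param observations observations for one infant, sorted by age.
#' @param target_age target age in days.
#' @return the one-row observation, or `NULL` if no visit qualifies.
#' @export
select_index_visit <- function(observations, target_age) {
  cur <- observations[observations$tense == "current" &
                        observations$age_days >= target_age, , drop = FALSE]
  if (nrow(cur) == 0) return(NULL)
  cur[which.min(cur$age_days), , drop = FALSE]
}

#' Infer exclusive-breastfeeding status at one target age
#'
#' Decision order for one infant's sorted observations: (1) no visit at or
#' after the target age puts the infant outside the denominator
#' (UNDETERMINED); (2) an informative index visit within `window` days of
#' the target carries its current status (EBF vs NOT_EBF); (3) beyond the
#' window, current exclusive breastfeeding at the index visit is carried
#' backwards to the target, and a past-tense statement of exclusive
#' breastfeeding decides by its stated duration (>= target: EBF; < target:
#' NOT_EBF, the infant had already stopped); (4) otherwise UNDETERMINED.
#' Notes whose current status is NONE_DOCUMENTED count as visits (they
#' anchor the denominator) but carry no status; the next informative visit
#' acts as the index.
#'
#' Backward propagation of EBF from later targets to earlier ones is applied
#' across targets by [timepoint_table()].
#'
#' @param observations observations for one infant, sorted by age.
#' @param target_age one of 60, 122, 182 (days).
#' @param window carry-forward window in days (see [default_windows()]).
#' @return one-row data.frame: `target_age, in_denominator, status,
#'   evidence` with status in EBF/NOT_EBF/UNDETERMINED and evidence in
#'   index_visit/future_current_ebf/future_historical_ebf/none.
#' @export
infer_status_at_timepoint <- function(observations, target_age,
                                      window = default_windows()) {
  w <- if (length(window) > 1) {
    unname(window[as.character(target_age)])
  } else {
    unname(window)
  }
  if (is.na(w)) w <- Inf
  cur <- observations[observations$tense == "current", , drop = FALSE]
  in_denom <- any(cur$age_days >= target_age)
  res <- function(status, evidence) {
    data.frame(target_age = as.integer(target_age),
               in_denominator = in_denom,
               status = status, evidence = evidence,
               stringsAsFactors = FALSE)
  }
  if (!in_denom) return(res("UNDETERMINED", "none"))

  hist_check <- function() {
    hist <- observations[observations$tense == "historical" &
                           observations$status == "EBF" &
                           !is.na(observations$historical_duration) &
                           observations$age_days >= target_age, ,
                         drop = FALSE]
    if (nrow(hist) == 0) return(NULL)
    if (any(hist$historical_duration >= target_age)) {
      res("EBF", "future_historical_ebf")
    } else {
      res("NOT_EBF", "future_historical_ebf")
    }
  }

  inf <- cur[cur$status != "NONE_DOCUMENTED" &
               cur$age_days >= target_age, , drop = FALSE]
  if (nrow(inf) == 0) {
    return(hist_check() %||% res("UNDETERMINED", "none"))
  }
  index <- inf[which.min(inf$age_days), ]
  if (index$age_days <= target_age + w) {
    res(if (index$status == "EBF") "EBF" else "NOT_EBF", "index_visit")
  } else if (index$status == "EBF") {
    res("EBF", "future_current_ebf")
  } else {
    hist_check() %||% res("UNDETERMINED", "none")
  }
}

#' Timepoint status table for a cohort
#'
#' Applies [infer_status_at_timepoint()] for every eligible infant at the
#' three target ages, then enforces backward consistency: exclusive
#' breastfeeding at a later target propagates to all earlier targets.
#'
#' @param cohort an `ebf_cohort`.
#' @param window carry-forward windows (see [default_windows()]).
#' @return data.frame with exactly 3 rows per infant: `infant_id,
#'   target_age, in_denominator, status, evidence`.
#' @export
timepoint_table <- function(cohort, window = default_windows()) {
  stopifnot(inherits(cohort, "ebf_cohort"))
  obs_split <- split(cohort$observations,
                     factor(cohort$observations$infant_id,
                            levels = cohort$records$infant_id))
  rows <- lapply(cohort$records$infant_id, function(id) {
    obs <- obs_split[[id]]
    obs <- obs[order(obs$age_days), , drop = FALSE]
    out <- do.call(rbind, lapply(TARGET_AGES, function(t) {
      infer_status_at_timepoint(obs, t, window)
    }))
    # backward propagation: EBF at a later target implies EBF earlier
    for (k in 2:3) {
      if (out$status[k] == "EBF") {
        earlier <- seq_len(k - 1)
        promote <- out$status[earlier] != "EBF"
        out$status[earlier][promote] <- "EBF"
        out$evidence[earlier][promote] <- "future_current_ebf"
      }
    }
    out$infant_id <- id
    out
  })
  out <- do.call(rbind, rows)
  out <- out[, c("infant_id", "target_age", "in_denominator", "status",
                 "evidence")]
  rownames(out) <- NULL
  out
}

#' Exclusive-breastfeeding duration for one infant
#'
#' Age in days of the latest visit with confirmed current exclusive
#' breastfeeding.
#'
#' @param observations observations for one infant.
#' @return duration in days, or `NA` if exclusive breastfeeding was never
#'   documented.
#' @export
ebf_duration <- function(observations) {
  ebf <- observations[observations$tense == "current" &
                        observations$status == "EBF", , drop = FALSE]
  if (nrow(ebf) == 0) return(NA_real_)
  max(ebf$age_days)
}

#' Complete-case subset of a cohort
#'
#' Sensitivity-analysis subset: infants whose feeding status was determined
#' directly from an index visit (no inference from future visits) at all
#' three target ages.
#'
#' @param cohort an `ebf_cohort`.
#' @param statuses output of [timepoint_table()] for the same cohort.
#' @return an `ebf_cohort` restricted to the complete cases.
#' @export
complete_case_subset <- function(cohort, statuses) {
  stopifnot(inherits(cohort, "ebf_cohort"))
  ok <- statuses$status != "UNDETERMINED" & statuses$evidence == "index_visit"
  n_ok <- tapply(ok, statuses$infant_id, sum)
  keep_ids <- names(n_ok)[n_ok == 3]
  structure(list(
    records = cohort$records[cohort$records$infant_id %in% keep_ids, ,
                             drop = FALSE],
    observations = cohort$observations[
      cohort$observations$infant_id %in% keep_ids, , drop = FALSE],
    exclusions = cohort$exclusions
  ), class = "ebf_cohort")
}

#' Exclusive-breastfeeding rates at the target ages
#'
#' Rates are computed among infants with a qualifying visit and a determined
#' status: UNDETERMINED infants contribute to neither numerator nor
#' denominator.
#'
#' @param statuses output of [timepoint_table()].
#' @return data.frame: `target_age, n, n_ebf, rate` (rate in percent).
#' @export
ebf_rates <- function(statuses) {
  det <- statuses[statuses$status != "UNDETERMINED", , drop = FALSE]
  out <- do.call(rbind, lapply(TARGET_AGES, function(t) {
    d <- det[det$target_age == t, , drop = FALSE]
    data.frame(target_age = t, n = nrow(d),
               n_ebf = sum(d$status == "EBF"),
               rate = if (nrow(d) > 0) 100 * sum(d$status == "EBF") / nrow(d)
                      else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
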