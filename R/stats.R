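# Rates, rate ratios (Katz log-transform CIs), standardized differences and
# Cohen's kappa.

#' Rate as a percentage
#'
#' @param numerator,denominator non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @return `100 * numerator / denominator` (unrounded; use
#'   [round_half_away()] for display).
#' @export
#' @examples
#' rate(1044, 8815)  # 11.84345...
rate <- function(numerator, denominator) {
  if (any(denominator == 0)) {
    data_error("rate undefined: zero denominator")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    data_error("rate needs 0 <= numerator <= denominator")
  }
  100 * numerator / denominator
}

#' Rate ratio with Katz log-transform confidence interval
#'
#' The ratio of two proportions with the standard normal approximation on
#' the log scale: `exp(log(p1/p0) +/- z * sqrt((1-p1)/(n1*p1) +
#' (1-p0)/(n0*p0)))`.
#'
#' @param p1,n1 proportion and denominator in the comparison stratum.
#' @param p0,n0 proportion and denominator in the referent stratum (`p0 >
#'   0`).
#' @param conf_level confidence level (default 0.95).
#' @return list with `rr`, `ci_low`, `ci_high`, `se_log`. A zero numerator
#'   in either arm leaves the CI `NA` (flagged non-computable).
#' @export
#' @examples
#' rate_ratio(0.267, 5464, 0.198, 1719)  # rr 1.35, CI ~ 1.22-1.50
rate_ratio <- function(p1, n1, p0, n0, conf_level = 0.95) {
  if (p0 <= 0) data_error("rate ratio undefined: referent proportion is 0")
  if (p0 > 1 || p1 < 0 || p1 > 1) {
    data_error("proportions must lie in [0, 1]")
  }
  if (n1 <= 0 || n0 <= 0) data_error("denominators must be positive")
  rr <- p1 / p0
  if (p1 <= 0 || p1 >= 1 + 1e-12 || p0 >= 1) {
    return(list(rr = rr, ci_low = NA_real_, ci_high = NA_real_,
                se_log = NA_real_))
  }
  se <- sqrt((1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(rr = rr,
       ci_low = exp(log(rr) - z * se),
       ci_high = exp(log(rr) + z * se),
       se_log = se)
}

#' Standardized difference between two cohort summaries
#'
#' Scale-free between-cohort difference used for covariate balance tables.
#' For binary characteristics (summaries `list(p = ...)`):
#' `(p_a - p_b) / sqrt((p_a (1 - p_a) + p_b (1 - p_b)) / 2)`.
#' For continuous characteristics (summaries `list(mean = ..., sd = ...)`):
#' `(m_a - m_b) / sqrt((s_a^2 + s_b^2) / 2)`.
#'
#' @param summary_a,summary_b summaries of the same kind.
#' @return the standardized difference (sign = a minus b), 0 when the
#'   summaries are identical.
#' @export
#' @examples
#' standardized_difference(list(p = 0.105), list(p = 0.244))  # -0.37
standardized_difference <- function(summary_a, summary_b) {
  is_binary <- !is.null(summary_a$p)
  if (is_binary != !is.null(summary_b$p)) {
    data_error("summaries must be of the same kind (binary or continuous)")
  }
  if (is_binary) {
    pa <- summary_a$p; pb <- summary_b$p
    stopifnot_prob(c(pa, pb), "proportions")
    if (pa == pb) return(0)
    denom <- sqrt((pa * (1 - pa) + pb * (1 - pb)) / 2)
    if (denom == 0) data_error("standardized difference undefined: zero variance")
    (pa - pb) / denom
  } else {
    if (is.null(summary_a$mean) || is.null(summary_a$sd) ||
        is.null(summary_b$mean) || is.null(summary_b$sd)) {
      data_error("continuous summaries need mean and sd")
    }
    if (summary_a$mean == summary_b$mean) return(0)
    denom <- sqrt((summary_a$sd^2 + summary_b$sd^2) / 2)
    if (denom == 0) data_error("standardized difference undefined: zero variance")
    (summary_a$mean - summary_b$mean) / denom
  }
}

#' Cohen's kappa for two categorical label vectors
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement `p_e` computed from the raters' marginal label distributions.
#'
#' @param labels_a,labels_b equal-length categorical vectors.
#' @return kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(c("x", "x", "y"), c("x", "x", "y"))  # 1
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) == 0 || length(labels_b) == 0) {
    data_error("kappa undefined for empty label vectors")
  }
  if (length(labels_a) != length(labels_b)) {
    data_error("label vectors must have equal length")
  }
  levs <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = levs)
  b <- factor(as.character(labels_b), levels = levs)
  n <- length(a)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    data_error("kappa degenerate: expected agreement is 1")
  }
  (p_o - p_e) / (1 - p_e)
}
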