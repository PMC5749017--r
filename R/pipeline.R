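# End-to-end orchestration: simulate -> extract -> analyze, with a run
# manifest recording configuration hash, seed and stage counts.

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_sim_config(config, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, sprintf("manifest_%s.json", manifest$stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a corpus to disk
#'
#' Generates the birth registry, latent trajectories and visit-note corpus
#' for `config`, writes `registry.csv` and `notes.jsonl` to `out_dir`, and
#' records a manifest (`manifest.json`) with the configuration hash, seed
#' and stage counts.
#'
#' @param config an [sim_config()] object (or path to its YAML).
#' @param out_dir output directory.
#' @param lexicon lexicon used for Rourke form-name rendering.
#' @return invisibly, a list with `registry`, `trajectories`, `notes`,
#'   `paths` and `manifest`.
#' @export
pipeline_simulate <- function(config, out_dir, lexicon = load_lexicon()) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "ebf_sim_config"))
  registry <- generate_birth_registry(config)
  trajectories <- generate_feeding_trajectories(registry, config)
  notes <- render_visit_corpus(registry, trajectories, config, lexicon)
  paths <- write_corpus(registry, notes, out_dir)
  manifest <- list(
    stage = "simulate",
    config_hash = config_hash(config),
    seed = config$seed,
    outputs = as.list(paths),
    counts = list(generated = nrow(registry), notes = nrow(notes))
  )
  write_manifest(manifest, out_dir)
  invisible(list(registry = registry, trajectories = trajectories,
                 notes = notes, paths = paths, manifest = manifest))
}

#' Run the feeding search algorithm over a corpus directory
#'
#' Reads `registry.csv`/`notes.jsonl` from `corpus_dir`, runs
#' [extract_all()] and writes `observations.csv` plus an updated manifest
#' with Rourke-detection and classification counts.
#'
#' @param corpus_dir directory holding a written corpus.
#' @param lexicon an [load_lexicon()] object (or path to a lexicon YAML).
#' @param out_dir output directory (defaults to `corpus_dir`).
#' @return invisibly, a list with `observations`, `path` and `manifest`.
#' @export
pipeline_extract <- function(corpus_dir, lexicon = load_lexicon(),
                             out_dir = corpus_dir) {
  if (is.character(lexicon)) lexicon <- load_lexicon(lexicon)
  notes <- read_notes(file.path(corpus_dir, "notes.jsonl"))
  registry <- read_registry(file.path(corpus_dir, "registry.csv"))
  observations <- extract_all(notes, lexicon)

  infants <- unique(registry$infant_id)
  cur <- observations[observations$tense == "current", , drop = FALSE]
  documented <- unique(cur$infant_id[cur$status != "NONE_DOCUMENTED"])
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, "observations.csv")
  write_observations(observations, path)
  manifest <- list(
    stage = "extract",
    inputs = list(corpus_dir = corpus_dir),
    outputs = list(observations = path),
    counts = list(
      infants = length(infants),
      rourke_detected = length(attr(observations, "rourke_detected")),
      classified = length(documented),
      undetermined = length(infants) - length(documented)
    )
  )
  write_manifest(manifest, out_dir)
  invisible(list(observations = observations, path = path,
                 manifest = manifest))
}

#' Analyze an extracted corpus
#'
#' Applies the eligibility rules, infers exclusive-breastfeeding status at
#' the three target ages and writes the per-timepoint rate summary plus
#' Table-2-style stratified rate-ratio CSVs (one file per target age) to
#' `out_dir`. With `complete_case = TRUE`, the analysis is additionally run
#' on the complete-case subset (feeding documented directly at all three
#' targets).
#'
#' @param corpus_dir directory holding `registry.csv` and
#'   `observations.csv`.
#' @param out_dir output directory.
#' @param covariates covariates to stratify on (default all of
#'   [rr_covariates()]).
#' @param referent `"fixed"` or `"lowest"` (see [stratified_rr_table()]).
#' @param complete_case also emit the complete-case sensitivity analysis.
#' @param window carry-forward windows (see [default_windows()]).
#' @return invisibly, a list with `cohort`, `statuses`, `rates`, `tables`
#'   (and `complete_case` when requested) plus `manifest`.
#' @export
pipeline_analyze <- function(corpus_dir, out_dir = corpus_dir,
                             covariates = rr_covariates(),
                             referent = "fixed", complete_case = FALSE,
                             window = default_windows()) {
  registry <- read_registry(file.path(corpus_dir, "registry.csv"))
  obs_path <- file.path(corpus_dir, "observations.csv")
  if (!file.exists(obs_path)) {
    io_error("no observations.csv in %s; run pipeline_extract() first",
             corpus_dir)
  }
  observations <- read_observations(obs_path)
  cohort <- build_cohort(registry, observations)
  statuses <- timepoint_table(cohort, window)
  rates <- ebf_rates(statuses)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(rates, file.path(out_dir, "ebf_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(statuses, file.path(out_dir, "timepoint_statuses.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)

  tables <- list()
  for (t in TARGET_AGES) {
    tab <- do.call(rbind, lapply(covariates, function(cov) {
      cbind(covariate = cov,
            stratified_rr_table(statuses, registry, cov, t,
                                referent = referent))
    }))
    utils::write.csv(tab,
                     file.path(out_dir, sprintf("rr_table_%dd.csv", t)),
                     row.names = FALSE)
    tables[[as.character(t)]] <- tab
  }

  result <- list(cohort = cohort, statuses = statuses, rates = rates,
                 tables = tables)
  if (complete_case) {
    cc <- complete_case_subset(cohort, statuses)
    cc_statuses <- timepoint_table(cc, window)
    cc_rates <- ebf_rates(cc_statuses)
    utils::write.csv(cc_rates,
                     file.path(out_dir, "ebf_rates_complete_case.csv"),
                     row.names = FALSE)
    result$complete_case <- list(cohort = cc, statuses = cc_statuses,
                                 rates = cc_rates)
  }
  manifest <- list(
    stage = "analyze",
    inputs = list(corpus_dir = corpus_dir),
    counts = list(
      registry = nrow(registry),
      eligible = nrow(cohort$records),
      excluded = nrow(cohort$exclusions),
      undetermined = as.list(stats::setNames(
        vapply(TARGET_AGES, function(t) {
          sum(statuses$target_age == t & statuses$status == "UNDETERMINED")
        }, 0L), paste0("d", TARGET_AGES)))
    ),
    referent = referent
  )
  write_manifest(manifest, out_dir)
  result$manifest <- manifest
  invisible(result)
}

#' Run the whole pipeline
#'
#' [pipeline_simulate()], [pipeline_extract()] and [pipeline_analyze()] in
#' sequence on one directory. Fully deterministic given `config$seed`.
#'
#' @inheritParams pipeline_simulate
#' @inheritParams pipeline_analyze
#' @return invisibly, the [pipeline_analyze()] result list, plus
#'   `simulation` (the [pipeline_simulate()] result).
#' @export
#' @examples
#' \donttest{
#' dir <- tempfile()
#' res <- run_pipeline(sim_config(n_infants = 200, seed = 7), dir)
#' res$rates
#' }
run_pipeline <- function(config, out_dir, lexicon = load_lexicon(),
                         covariates = rr_covariates(), referent = "fixed",
                         complete_case = FALSE,
                         window = default_windows()) {
  sim <- pipeline_simulate(config, out_dir, lexicon)
  pipeline_extract(out_dir, lexicon)
  res <- pipeline_analyze(out_dir, out_dir, covariates = covariates,
                          referent = referent,
                          complete_case = complete_case, window = window)
  res$simulation <- sim
  invisible(res)
}
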