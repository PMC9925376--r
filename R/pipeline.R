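#' Run the full analysis chain on one registry
#'
#' Orchestrates simulate (or load) -> phenotype -> episodes -> outcome
#' derivation -> model fitting, and returns all intermediate tables plus a
#' results table covering the analysis grid: per drug group, early
#' non-persistence (GEE logistic, six-level phenotype), discontinuation and
#' switch (cluster-robust Cox, six-level phenotype), and treatment-emergent
#' mania (cluster-robust Cox, three-level collapse plus activity-score
#' trend). Re-running with the same config reproduces identical output; a
#' manifest records the seed, parameters and row counts so attrition is
#' auditable.
#'
#' @param config a `pgx_sim_config` to simulate from, or a directory path
#'   holding the four registry CSVs (see [read_registry()]).
#' @param gap_days,tail_cap_days episode-construction parameters.
#' @param mania_window_days,nonpersistence_window_days outcome windows.
#' @param study_end administrative censoring date.
#' @param out_dir if non-NULL, intermediate tables and results are written
#'   there as CSV.
#' @param fit_models set FALSE to stop after outcome derivation.
#' @return list: tables (registry), phenotypes, episodes, records (one
#'   element per outcome kind), results (data.frame of model terms),
#'   manifest.
#' @export
run_study <- function(config = sim_config(), gap_days = 122,
                      tail_cap_days = 90, mania_window_days = 91,
                      nonpersistence_window_days = 122,
                      study_end = as.Date("2016-12-31"),
                      out_dir = NULL, fit_models = TRUE) {
  if (is.character(config)) {
    tables <- read_registry(config)
    registry_start <- as.Date("2005-07-01")
  } else if (inherits(config, "pgx_sim_config")) {
    tables <- simulate_registry(config)
    registry_start <- config$study_start
  } else stop("config must be a pgx_sim_config or a directory path")

  phenotypes <- classify_genotypes(tables$genotypes)
  episodes <- build_all_episodes(tables$dispenses, gap_days = gap_days,
                                 tail_cap_days = tail_cap_days)
  n_before <- nrow(episodes)
  episodes <- filter_left_truncated(
    episodes, earliest_valid_start = registry_start + gap_days)
  episodes <- episodes[episodes$start_date <= study_end, , drop = FALSE]
  n_truncated <- n_before - nrow(episodes)

  records <- list(
    nonpersistence = add_phenotypes(
      nonpersistence_records(episodes, tables$persons,
                             window_days = nonpersistence_window_days),
      phenotypes),
    discontinuation = add_phenotypes(
      discontinuation_records(episodes, tables$persons,
                              study_end = study_end),
      phenotypes),
    switch = add_phenotypes(
      switch_records(tables$dispenses, tables$persons,
                     followup_end = study_end),
      phenotypes),
    mania = add_phenotypes(
      mania_records(episodes, tables$admissions, tables$persons,
                    window_days = mania_window_days),
      phenotypes))

  results <- NULL
  if (fit_models) results <- fit_analysis_grid(records)

  manifest <- list(
    seed = if (inherits(config, "pgx_sim_config")) config$seed else NA,
    gap_days = gap_days, tail_cap_days = tail_cap_days,
    mania_window_days = mania_window_days,
    n_persons = nrow(tables$persons),
    n_dispenses = nrow(tables$dispenses),
    n_admissions = nrow(tables$admissions),
    n_episodes = nrow(episodes),
    n_left_truncated = n_truncated,
    n_records = vapply(records, nrow, 0L),
    n_events = vapply(records, function(r) sum(r$event), 0L))

  out <- list(tables = tables, phenotypes = phenotypes, episodes = episodes,
              records = records, results = results, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_registry(tables, out_dir)
    write.csv(phenotypes, file.path(out_dir, "phenotypes.csv"),
              row.names = FALSE)
    write.csv(episodes, file.path(out_dir, "episodes.csv"),
              row.names = FALSE)
    for (k in names(records)) {
      write.csv(records[[k]], file.path(out_dir, paste0(k, "_records.csv")),
                row.names = FALSE)
    }
    if (!is.null(results)) {
      write.csv(results, file.path(out_dir, "results.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

# one tidy row per model term
.result_rows <- function(res, outcome, drug_group, coding) {
  cbind(data.frame(outcome = outcome, drug_group = drug_group,
                   coding = coding),
        res$terms,
        data.frame(n = res$n, n_persons = res$n_persons,
                   events = res$n_events))
}

#' Fit the per-drug-group analysis grid on derived outcome records
#'
#' For each drug group with enough events: non-persistence by GEE logistic
#' (six-level phenotype), discontinuation and switch by cluster-robust Cox
#' (six-level phenotype), mania by cluster-robust Cox (three-level collapse
#' and activity-score trend). Cells whose models cannot be fitted (no
#' events, absent reference level) are skipped with a message rather than
#' failing the run.
#'
#' @param records named list of outcome record tables (with phenotypes).
#' @return data.frame of model terms across the grid.
#' @export
fit_analysis_grid <- function(records) {
  rows <- list()
  groups <- unique(records$nonpersistence$drug_group)
  add <- function(expr, outcome, grp, coding) {
    res <- tryCatch(suppressWarnings(expr), error = function(e) {
      message(sprintf("skipping %s/%s/%s: %s", outcome, grp, coding,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      rows[[length(rows) + 1]] <<- .result_rows(res, outcome, grp, coding)
    }
  }
  for (grp in groups) {
    np <- records$nonpersistence[records$nonpersistence$drug_group == grp, ]
    add(fit_gee_logistic(code_exposure(np, "phenotype6")),
        "nonpersistence", grp, "phenotype6")
    dc <- records$discontinuation[
      records$discontinuation$drug_group == grp, ]
    add(fit_cox_clustered(code_exposure(dc, "phenotype6")),
        "discontinuation", grp, "phenotype6")
    sw <- records$switch[records$switch$drug_group == grp, ]
    add(fit_cox_clustered(code_exposure(sw, "phenotype6")),
        "switch", grp, "phenotype6")
    ma <- records$mania[records$mania$drug_group == grp, ]
    add(fit_cox_clustered(code_exposure(ma, "collapse3")),
        "mania", grp, "collapse3")
    add(trend_cox(ma), "mania", grp, "trend")
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Named input fixtures for tests and examples
#'
#' `"tiny"` is a fully hand-constructed registry of 12 persons whose
#' episodes, outcome records and exclusions can be verified by hand;
#' `"null"` is a simulated cohort with no pharmacogenetic effect on mania
#' (per-step log HR 0); `"effect"` simulates the study's sertraline-arm
#' effect size (per-step HR 1.3).
#'
#' @param name fixture name: "tiny", "null" or "effect".
#' @param seed master seed for the simulated fixtures.
#' @return list of the four registry tables.
#' @export
make_fixture <- function(name = c("tiny", "null", "effect"), seed = 1L) {
  name <- match.arg(name)
  if (name == "tiny") return(.tiny_fixture())
  cfg <- sim_config(
    n_subjects = 800,
    true_log_hr_per_step = if (name == "null") 0 else log(1.3),
    seed = seed)
  simulate_registry(cfg)
}

# 12 hand-written persons exercising: gap of exactly 122 (continues), 123
# (splits), tail cap, left truncation, death before refill, mania inside
# and outside the 91-day window, switch washout violation
.tiny_fixture <- function() {
  d <- function(x) as.Date(x)
  persons <- data.frame(
    person_id = sprintf("T%02d", 1:12),
    sex = rep(c("female", "male"), 6),
    birth_year = rep(c(1960, 1975, 1950), 4),
    death_date = as.Date(c(NA, NA, NA, "2010-03-01", NA, NA, NA, NA, NA,
                           NA, NA, NA)),
    wave = rep(1:3, 4), stringsAsFactors = FALSE)
  g <- function(h1, h2) {
    alle <- list("*1" = c("G", "C"), "*2" = c("A", "C"), "*17" = c("G", "T"))
    c(alle[[h1]], alle[[h2]])
  }
  stars <- list(c("*1", "*1"), c("*2", "*2"), c("*17", "*17"),
                c("*1", "*2"), c("*2", "*17"), c("*1", "*17"),
                c("*1", "*1"), c("*1", "*1"), c("*1", "*2"),
                c("*1", "*17"), c("*1", "*1"), c("*2", "*2"))
  gm <- t(vapply(stars, function(s) g(s[1], s[2]), character(4)))
  genotypes <- data.frame(person_id = persons$person_id,
                          h1_rs4244285 = gm[, 1], h1_rs12248560 = gm[, 2],
                          h2_rs4244285 = gm[, 3], h2_rs12248560 = gm[, 4],
                          stringsAsFactors = FALSE)
  disp <- rbind(
    # T01: two dispenses 122 days apart -> one episode (gap not exceeded)
    data.frame(person_id = "T01", date = d("2010-01-01") + c(0, 122),
               atc = "N06AB06", n_ddd = 100),
    # T02: gap 123 -> two episodes; 120-DDD tail capped at 90
    data.frame(person_id = "T02", date = d("2010-01-01") + c(0, 123),
               atc = "N06AB06", n_ddd = 120),
    # T03: left-truncated episode (starts 2005-09-01)
    data.frame(person_id = "T03", date = d("2005-09-01"),
               atc = "N06AB06", n_ddd = 100),
    # T04: single dispense then death within 122 days
    data.frame(person_id = "T04", date = d("2010-01-15"),
               atc = "N06AB06", n_ddd = 100),
    # T05: single dispense, persists (no refill)
    data.frame(person_id = "T05", date = d("2010-06-01"),
               atc = "N06AB10", n_ddd = 30),
    # T06: mania admission on day 45 (see admissions)
    data.frame(person_id = "T06", date = d("2012-01-01"),
               atc = "N06AB06", n_ddd = 100),
    # T07: mania admission on day 120 -> outside the 91-day window
    data.frame(person_id = "T07", date = d("2012-01-01"),
               atc = "N06AB06", n_ddd = 100),
    # T08: index sertraline; mirtazapine on day 200 -> switch event
    data.frame(person_id = "T08", date = d("2012-01-01"),
               atc = "N06AB06", n_ddd = 100),
    data.frame(person_id = "T08", date = d("2012-01-01") + 200,
               atc = "N06AX11", n_ddd = 100),
    # T09: citalopram 100 days before sertraline -> washout violation
    data.frame(person_id = "T09", date = d("2012-01-01") - 100,
               atc = "N06AB04", n_ddd = 100),
    data.frame(person_id = "T09", date = d("2012-01-01"),
               atc = "N06AB06", n_ddd = 100),
    # T10: lithium at -300 and -60 days -> mood stabilizer flag on
    data.frame(person_id = "T10", date = d("2012-01-01") + c(-300, -60),
               atc = "N05AN01", n_ddd = 100),
    data.frame(person_id = "T10", date = d("2012-01-01"),
               atc = "N06AB06", n_ddd = 100),
    # T11: three dispenses, 100-day gaps -> one episode of 3 dispenses
    data.frame(person_id = "T11", date = d("2013-01-01") + c(0, 100, 200),
               atc = "N06AA09", n_ddd = 90),
    # T12: single tricyclic dispense late in the study
    data.frame(person_id = "T12", date = d("2016-10-01"),
               atc = "N06AA04", n_ddd = 100))
  disp$date <- as.Date(disp$date)
  admissions <- data.frame(
    person_id = c("T06", "T07", "T07"),
    admission_date = d(c("2012-02-15", "2012-04-30", "2011-06-01")),
    discharge_date = d(c("2012-03-01", "2012-05-15", "2011-06-20")),
    icd10_codes = c("F301", "F310", "F329;F603"),  # last one: depression
    stringsAsFactors = FALSE)
  list(persons = persons, genotypes = genotypes, dispenses = disp,
       admissions = admissions)
}

#' Trend-HR parameter recovery across replicate cohorts
#'
#' Simulates `n_reps` replicate cohorts with a known per-activity-score-step
#' mania hazard ratio, runs the full pipeline on each (simulate genotypes,
#' dispenses and admissions; rebuild episodes with the gap rule; derive
#' 91-day mania records; fit the cluster-robust activity-score trend Cox
#' model) and returns the estimated per-step HRs for the requested drug
#' group. Cohorts are sized so each replicate yields on the order of
#' `target_episodes` exposed episodes.
#'
#' @param true_hr true per-step hazard ratio used by the simulator.
#' @param n_reps number of replicate cohorts.
#' @param seed base seed; replicate r uses seed `seed * 1000 + r`.
#' @param drug_group drug group analysed (default sertraline).
#' @param target_episodes approximate exposed episodes per replicate.
#' @param target_event_rate expected 91-day mania event proportion.
#' @return numeric vector of estimated per-step HRs (one per replicate;
#'   NA if a replicate's model failed).
#' @export
recover_trend_hr <- function(true_hr, n_reps = 200, seed = 1L,
                             drug_group = "sertraline",
                             target_episodes = 4000,
                             target_event_rate = 0.015) {
  # episodes per subject under the default refill/dropout parameters is
  # close to the expected number of dispense streams per subject
  years <- as.numeric(as.Date("2019-12-31") - as.Date("2005-07-01")) / 365.25
  rate <- 1.35 / years                     # ~1.35 streams per subject
  n_subjects <- ceiling(target_episodes / 1.35)
  vapply(seq_len(n_reps), function(r) {
    rep_seed <- (as.integer(seed) * 1000L + r) %% .Machine$integer.max
    init <- c(escitalopram_citalopram = 0, sertraline = 0,
              amitriptyline_clomipramine = 0)
    init[drug_group] <- rate
    cfg <- sim_config(n_subjects = n_subjects,
                      drug_initiation_rate = init,
                      true_log_hr_per_step = log(true_hr),
                      target_mania_rate = target_event_rate,
                      seed = rep_seed)
    run <- run_study(cfg, fit_models = FALSE)
    ma <- run$records$mania
    ma <- ma[ma$drug_group == drug_group, , drop = FALSE]
    est <- tryCatch(suppressWarnings(trend_cox(ma)),
                    error = function(e) NULL)
    if (is.null(est)) return(NA_real_)
    unname(est$terms$estimate[est$terms$term == "exposure"])
  }, numeric(1))
}
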