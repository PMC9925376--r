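#' ICD-10 codes counted as mania or mixed episode
#'
#' Dot-free codes: F300-F302, F308, F309 (manic episode), F310-F312
#' (bipolar, current episode hypomanic/manic) and F316 (current episode
#' mixed). F313-F315 (depressive episodes) are deliberately absent.
#'
#' @return character vector of four-character code prefixes.
#' @export
mania_icd_codes <- function() {
  c("F300", "F301", "F302", "F308", "F309",
    "F310", "F311", "F312", "F316")
}

#' Does an ICD-10 code denote mania or a mixed episode?
#'
#' Matching is on the first four characters, so subcodes such as "F3010"
#' match via their prefix; three-character codes never match.
#'
#' @param code character vector of dot-free ICD-10 codes.
#' @param codes the accepted four-character prefixes.
#' @return logical vector.
#' @export
#' @examples
#' icd_mania_match(c("F301", "F313", "F316", "F32"))
icd_mania_match <- function(code, codes = mania_icd_codes()) {
  nchar(code) >= 4 & substr(code, 1, 4) %in% codes
}

#' ATC code sets used for covariate flags
#'
#' Substance-to-code mapping for the co-medication definitions: mood
#' stabilizers lithium (N05AN01), valproate (N03AG01), lamotrigine
#' (N03AX09); CYP2C19 enzyme inducers carbamazepine (N03AF01),
#' phenobarbital (N03AA02), phenytoin (N03AB02); inhibitors omeprazole
#' (A02BC01), esomeprazole (A02BC05), lansoprazole (A02BC03), pantoprazole
#' (A02BC02), fluoxetine (N06AB03), fluvoxamine (N06AB08).
#'
#' @return named list with n06a_prefix, mood_stabilizers,
#'   inducers_inhibitors.
#' @export
pgx_atc_sets <- function() {
  list(n06a_prefix = "N06A",
       mood_stabilizers = c("N05AN01", "N03AG01", "N03AX09"),
       inducers_inhibitors = c("N03AF01", "N03AA02", "N03AB02",
                               "A02BC01", "A02BC05", "A02BC03", "A02BC02",
                               "N06AB03", "N06AB08"))
}

# dispenses of each person falling in [start + lo, start + hi] per episode;
# returns data.table(row, atc, date) where row indexes the episode table
.window_hits <- function(ep, disp, lo, hi = 0) {
  if (nrow(disp) == 0 || nrow(ep) == 0) {
    return(data.table(row = integer(), atc = character(),
                      date = as.Date(character())))
  }
  e <- data.table(person_id = ep$person_id,
                  lo = ep$start_date + lo, hi = ep$start_date + hi,
                  row = seq_len(nrow(ep)))
  d <- as.data.table(disp)[, .(person_id, date, atc)]
  d[e, on = .(person_id, date >= lo, date <= hi), nomatch = 0L,
    .(row = i.row, atc = x.atc, date = x.date)]
}

#' Co-medication covariate flags for treatment episodes
#'
#' For each episode start date, computes: `monotherapy_flag` - no dispense
#' of an antidepressant (ATC N06A) outside the episode's own drug group in
#' the 4 months (122 days) up to and including the start;
#' `mood_stabilizer_flag` - at least two mood-stabilizer dispenses in the
#' year (365 days) before start, at least one of them within the last 4
#' months; `inducer_inhibitor_flag` - any dispense of a CYP2C19 enzyme
#' inducer or inhibitor within 6 months (183 days) before start. All
#' windows include the start date itself.
#'
#' @param episodes episode table (person_id, drug_group, start_date, ...).
#' @param dispenses full dispense table, including co-medications.
#' @param groups ATC groups defining "own drug" per episode.
#' @param atc_sets see [pgx_atc_sets()].
#' @param monotherapy_window,ms_long_window,ms_short_window,ii_window
#'   look-back lengths in days.
#' @return `episodes` with the three logical flag columns appended.
#' @export
covariate_flags <- function(episodes, dispenses, groups = atc_groups(),
                            atc_sets = pgx_atc_sets(),
                            monotherapy_window = 122,
                            ms_long_window = 365, ms_short_window = 122,
                            ii_window = 183) {
  ep <- as.data.frame(episodes)
  disp <- as.data.table(dispenses)
  n06a <- disp[startsWith(atc, atc_sets$n06a_prefix)]
  hits <- .window_hits(ep, n06a, -monotherapy_window, 0)
  if (nrow(hits) > 0) {
    own <- mapply(function(a, g) a %in% groups[[g]],
                  hits$atc, ep$drug_group[hits$row])
    other_rows <- unique(hits$row[!own])
  } else other_rows <- integer()
  ep$monotherapy_flag <- !(seq_len(nrow(ep)) %in% other_rows)

  ms <- disp[atc %in% atc_sets$mood_stabilizers]
  long_hits <- .window_hits(ep, ms, -ms_long_window, 0)
  short_hits <- .window_hits(ep, ms, -ms_short_window, 0)
  n_long <- tabulate(long_hits$row, nbins = nrow(ep))
  n_short <- tabulate(short_hits$row, nbins = nrow(ep))
  ep$mood_stabilizer_flag <- n_long >= 2 & n_short >= 1

  ii <- disp[atc %in% atc_sets$inducers_inhibitors]
  ii_hits <- .window_hits(ep, ii, -ii_window, 0)
  ep$inducer_inhibitor_flag <- tabulate(ii_hits$row, nbins = nrow(ep)) > 0
  ep
}

# carry covariate-flag columns from the episode table onto records built
# row-parallel to it
.carry_flags <- function(rec, ep) {
  for (fl in intersect(c("monotherapy_flag", "mood_stabilizer_flag",
                         "inducer_inhibitor_flag"), names(ep))) {
    rec[[fl]] <- ep[[fl]]
  }
  rec
}

# sex, wave, age at episode start merged onto outcome records
.add_person_covariates <- function(records, persons) {
  p <- as.data.frame(persons)[, c("person_id", "sex", "birth_year", "wave")]
  out <- merge(records, p, by = "person_id", all.x = TRUE, sort = FALSE)
  out$age_at_start <-
    as.integer(format(out$start_date, "%Y")) - out$birth_year
  out$birth_year <- NULL
  out
}

#' Early treatment non-persistence records
#'
#' One binary record per episode: the event (1) is failure to collect a
#' second dispense within `window_days` of the episode's first dispense
#' (a refill on exactly day `window_days` counts as persistent). Episodes
#' of persons who died within `window_days` of the first dispense are
#' excluded, since they had no chance to refill.
#'
#' @param episodes episode table carrying `second_gap_days`.
#' @param persons person table (person_id, sex, birth_year, death_date, wave).
#' @param window_days refill window (default 122; sensitivity 183).
#' @return data.frame of outcome records: person_id, drug_group,
#'   episode_id, start_date, outcome, event, sex, wave, age_at_start.
#'   Covariate-flag columns present on the episode table (e.g. from
#'   [covariate_flags()]) are carried through; the same holds for
#'   [discontinuation_records()] and [mania_records()].
#' @export
nonpersistence_records <- function(episodes, persons, window_days = 122) {
  ep <- as.data.frame(episodes)
  p <- as.data.frame(persons)
  death <- p$death_date[match(ep$person_id, p$person_id)]
  died_early <- !is.na(death) & death <= ep$start_date + window_days
  ep <- ep[!died_early, , drop = FALSE]
  rec <- data.frame(person_id = ep$person_id, drug_group = ep$drug_group,
                    episode_id = ep$episode_id, start_date = ep$start_date,
                    outcome = "nonpersistence",
                    event = as.integer(is.na(ep$second_gap_days) |
                                         ep$second_gap_days > window_days))
  .add_person_covariates(.carry_flags(rec, ep), persons)
}

#' Treatment discontinuation records (first year of treatment)
#'
#' Follow-up runs from each episode's first dispense. The event (1) is
#' reaching the episode's reconstructed last treatment day before any
#' censoring cause; censoring (0) occurs at the earliest of study end,
#' death, or `max_days` after start. An episode end that coincides with a
#' censoring date is treated as censored (whether treatment truly ended
#' there cannot be observed).
#'
#' @param episodes left-truncation-filtered episode table.
#' @param persons person table.
#' @param study_end administrative end of follow-up.
#' @param max_days follow-up cap in days (default 365; the early-window
#'   sensitivity analysis uses 60).
#' @param first_episode_only keep only each person's first episode per drug
#'   group.
#' @return outcome records with event and time_days.
#' @export
discontinuation_records <- function(episodes, persons,
                                    study_end = as.Date("2016-12-31"),
                                    max_days = 365,
                                    first_episode_only = FALSE) {
  ep <- as.data.frame(episodes)
  study_end <- as.Date(study_end)
  if (any(ep$start_date > study_end)) {
    stop("episode starting after study end")
  }
  if (first_episode_only && nrow(ep) > 0) {
    dt <- as.data.table(ep)
    setorder(dt, person_id, drug_group, start_date)
    ep <- as.data.frame(dt[, head(.SD, 1), by = .(person_id, drug_group)])
  }
  p <- as.data.frame(persons)
  death <- p$death_date[match(ep$person_id, p$person_id)]
  death_t <- ifelse(is.na(death), Inf, as.numeric(death - ep$start_date))
  cens_t <- pmin(as.numeric(study_end - ep$start_date), death_t, max_days)
  ep_len <- as.numeric(ep$end_date - ep$start_date)
  event <- as.integer(ep_len < cens_t)
  rec <- data.frame(person_id = ep$person_id, drug_group = ep$drug_group,
                    episode_id = ep$episode_id, start_date = ep$start_date,
                    outcome = "discontinuation",
                    event = event,
                    time_days = ifelse(event == 1, ep_len, cens_t))
  .add_person_covariates(.carry_flags(rec, ep), persons)
}

#' Antidepressant switch records under a new-user design
#'
#' Index events are dispenses of a study drug during the follow-up period
#' with no antidepressant (ATC N06A) dispense during the preceding
#' `washout_days` days, so the index marks a genuine treatment start. A
#' same-day dispense of a different N06A substance makes the start
#' ambiguous and excludes the index. The event is the first dispense of a
#' different N06A substance (different 7-character ATC code) within
#' `max_days`; censoring occurs at death, `followup_end`, or `max_days`,
#' whichever comes first.
#'
#' @param dispenses full N06A dispense history (not just study drugs).
#' @param persons person table.
#' @param groups study-drug ATC groups.
#' @param followup_start,followup_end index-accrual window.
#' @param washout_days look-back free of any N06A dispense (default 365).
#' @param max_days switch window after index (default 365).
#' @param n06a_prefix ATC prefix defining "antidepressant".
#' @return outcome records with event and time_days; start_date is the
#'   index dispense date.
#' @export
switch_records <- function(dispenses, persons, groups = atc_groups(),
                           followup_start = as.Date("2006-07-01"),
                           followup_end = as.Date("2016-12-31"),
                           washout_days = 365, max_days = 365,
                           n06a_prefix = "N06A") {
  disp <- as.data.table(dispenses)
  n06a <- unique(disp[startsWith(atc, n06a_prefix),
                      .(person_id, date, atc)])
  map <- data.table(atc = unlist(groups),
                    drug_group = rep(names(groups), lengths(groups)))
  idx <- merge(n06a, map, by = "atc")[
    date >= as.Date(followup_start) & date <= as.Date(followup_end)]
  if (nrow(idx) == 0) {
    return(data.frame(person_id = character(), drug_group = character(),
                      start_date = as.Date(character()),
                      outcome = character(), event = integer(),
                      time_days = numeric(), sex = character(),
                      wave = integer(), age_at_start = integer()))
  }
  setorder(idx, person_id, date)
  idx[, row := .I]
  # washout: any N06A dispense in [index - washout, index - 1]
  w <- data.table(person_id = idx$person_id, lo = idx$date - washout_days,
                  hi = idx$date - 1L, row = idx$row)
  washed <- unique(n06a[w, on = .(person_id, date >= lo, date <= hi),
                        nomatch = 0L, .(row = i.row)]$row)
  # same-day different-substance dispense: ambiguous start
  same_day <- n06a[idx, on = .(person_id, date), allow.cartesian = TRUE,
                   .(row = i.row, other = x.atc != i.atc)]
  ambiguous <- unique(same_day$row[same_day$other])
  idx <- idx[!row %in% c(washed, ambiguous)]
  if (nrow(idx) == 0) {
    return(switch_records(dispenses[0, ], persons, groups))
  }
  # first later dispense of a different N06A substance within max_days
  s <- data.table(person_id = idx$person_id, lo = idx$date + 1L,
                  hi = idx$date + max_days, row = seq_len(nrow(idx)),
                  index_atc = idx$atc)
  cand <- n06a[s, on = .(person_id, date >= lo, date <= hi), nomatch = 0L,
               .(row = i.row, atc = x.atc, date = x.date,
                 index_atc = i.index_atc)][atc != index_atc]
  first_switch <- cand[, .(switch_date = min(date)), by = row]
  switch_t <- rep(NA_real_, nrow(idx))
  switch_t[first_switch$row] <-
    as.numeric(first_switch$switch_date - idx$date[first_switch$row])
  p <- as.data.frame(persons)
  death <- p$death_date[match(idx$person_id, p$person_id)]
  death_t <- ifelse(is.na(death), Inf, as.numeric(death - idx$date))
  cens_t <- pmin(as.numeric(as.Date(followup_end) - idx$date),
                 death_t, max_days)
  event <- as.integer(!is.na(switch_t) & switch_t <= cens_t)
  rec <- data.frame(person_id = idx$person_id, drug_group = idx$drug_group,
                    start_date = idx$date, outcome = "switch",
                    event = event,
                    time_days = ifelse(event == 1, switch_t, cens_t))
  .add_person_covariates(rec, persons)
}

#' Treatment-emergent mania records
#'
#' Follow-up runs from each episode's first dispense until the first
#' inpatient admission carrying a mania/mixed-episode diagnosis, censored
#' at `window_days` (3 months = 91 days) after start or at death, whichever
#' comes first. The event is anchored at the admission date by default
#' (admission marks onset even though the diagnosis is recorded at
#' discharge); set `anchor = "discharge"` to use the discharge date.
#'
#' @param episodes left-truncation-filtered episode table.
#' @param admissions admission table: person_id, admission_date,
#'   discharge_date, icd10_codes (semicolon-joined string or list column).
#' @param persons person table.
#' @param window_days risk window after treatment start (default 91).
#' @param anchor "admission" or "discharge".
#' @param codes accepted ICD-10 prefixes, see [mania_icd_codes()].
#' @return outcome records with event and time_days (capped at
#'   `window_days`).
#' @export
mania_records <- function(episodes, admissions, persons, window_days = 91,
                          anchor = c("admission", "discharge"),
                          codes = mania_icd_codes()) {
  anchor <- match.arg(anchor)
  ep <- as.data.frame(episodes)
  adm <- as.data.frame(admissions)
  code_list <- if (is.list(adm$icd10_codes)) adm$icd10_codes
               else strsplit(as.character(adm$icd10_codes), ";", fixed = TRUE)
  is_mania <- vapply(code_list, function(x) any(icd_mania_match(x, codes)),
                     logical(1))
  adm_dt <- data.table(
    person_id = adm$person_id,
    anchor_date = if (anchor == "admission") as.Date(adm$admission_date)
                  else as.Date(adm$discharge_date))[is_mania]
  p <- as.data.frame(persons)
  death <- p$death_date[match(ep$person_id, p$person_id)]
  death_t <- ifelse(is.na(death), Inf, as.numeric(death - ep$start_date))
  fu <- pmin(window_days, death_t)
  e <- data.table(person_id = ep$person_id, lo = ep$start_date,
                  hi = ep$start_date + fu, row = seq_len(nrow(ep)))
  hit <- adm_dt[e, on = .(person_id, anchor_date >= lo, anchor_date <= hi),
                nomatch = 0L, .(row = i.row, t_adm = x.anchor_date - i.lo)]
  first_hit <- hit[, .(t_adm = min(as.numeric(t_adm))), by = row]
  event <- rep(0L, nrow(ep))
  time_days <- fu
  event[first_hit$row] <- 1L
  time_days[first_hit$row] <- first_hit$t_adm
  rec <- data.frame(person_id = ep$person_id, drug_group = ep$drug_group,
                    episode_id = ep$episode_id, start_date = ep$start_date,
                    outcome = "mania", event = event, time_days = time_days)
  .add_person_covariates(.carry_flags(rec, ep), persons)
}

#' Merge phenotype classifications onto outcome records
#'
#' @param records outcome records carrying person_id.
#' @param phenotypes output of [classify_genotypes()].
#' @return records with phenotype, activity_score and, when present,
#'   cyp2c_rank / cyp2c_collapse3 columns appended.
#' @export
add_phenotypes <- function(records, phenotypes) {
  keep <- intersect(c("person_id", "phenotype", "activity_score",
                      "cyp2c_rank", "cyp2c_collapse3"), names(phenotypes))
  merge(records, as.data.frame(phenotypes)[, keep],
        by = "person_id", all.x = TRUE, sort = FALSE)
}
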