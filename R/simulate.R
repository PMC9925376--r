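#' Configuration for the synthetic registry generator
#'
#' Bundles and validates the free parameters of the simulator. Defaults
#' describe a cohort with the haplotype frequencies of the two core
#' CYP2C19 variants (*2 carrying rs4244285-A at frequency 0.147, *17
#' carrying rs12248560-T at 0.19), a registry window July 2005 - December
#' 2016 with dispense data continuing to December 2019, refill streams
#' around a 100-day interval, and rare inpatient mania events whose hazard
#' during the first 91 days of each treatment episode scales with the
#' inverted activity score.
#'
#' @param n_subjects cohort size.
#' @param haplotype_freqs named probabilities for haplotypes *1, *2, *17
#'   (must sum to 1).
#' @param cyp2c_background_freqs probabilities of the rs2860840/rs11188059
#'   backgrounds CG, TA, TG on a *1 haplotype (the TG background defines
#'   the ultra-rapid CYP2C:TG haplotype).
#' @param study_start,study_end registry follow-up window.
#' @param dispense_end last date with dispense data (extends past study
#'   end, so treatment at study end is observable).
#' @param drug_initiation_rate named per-subject per-year rate of starting
#'   a new dispense stream, one entry per drug group.
#' @param mean_dispense_ddd mean dispensed quantity per purchase, DDD units.
#' @param refill_interval_mean,refill_interval_sd days between refills.
#' @param refill_dropout_prob per-refill probability that the stream stops.
#' @param true_log_hr_per_step log hazard ratio of mania per one-step
#'   increase of the inverted activity score (0 = no pharmacogenetic
#'   effect).
#' @param baseline_mania_hazard events per person-day during exposure for
#'   a person at the reference score (EM, score 3). `NULL` (default) tunes
#'   it with [tune_baseline_hazard()] so the expected 91-day event
#'   proportion equals `target_mania_rate`.
#' @param target_mania_rate expected 91-day mania event proportion used
#'   when tuning (default 0.015).
#' @param background_mania_rate admissions per person-day outside any
#'   treatment context (default on, low, so the specificity of the risk
#'   window is testable).
#' @param death_rate deaths per person-year.
#' @param comedication_probs named probabilities that a subject is a user
#'   of other_n06a / mood_stabilizer / inducer_inhibitor co-medication.
#' @param p_female probability of female sex.
#' @param wave_probs probabilities of the three genotyping waves.
#' @param seed master seed; each output table uses an independent stream
#'   derived from it.
#' @return validated `pgx_sim_config` list.
#' @export
sim_config <- function(n_subjects = 2000,
                       haplotype_freqs = c("*1" = 0.663, "*2" = 0.147,
                                           "*17" = 0.19),
                       cyp2c_background_freqs = c(CG = 0.6, TA = 0.2,
                                                  TG = 0.2),
                       study_start = as.Date("2005-07-01"),
                       study_end = as.Date("2016-12-31"),
                       dispense_end = as.Date("2019-12-31"),
                       drug_initiation_rate = c(
                         escitalopram_citalopram = 0.045,
                         sertraline = 0.028,
                         amitriptyline_clomipramine = 0.015),
                       mean_dispense_ddd = 100,
                       refill_interval_mean = 100,
                       refill_interval_sd = 25,
                       refill_dropout_prob = 0.2,
                       true_log_hr_per_step = log(1.3),
                       baseline_mania_hazard = NULL,
                       target_mania_rate = 0.015,
                       background_mania_rate = 5e-6,
                       death_rate = 0.006,
                       comedication_probs = c(other_n06a = 0.25,
                                              mood_stabilizer = 0.5,
                                              inducer_inhibitor = 0.15),
                       p_female = 0.62,
                       wave_probs = c(1, 1, 1) / 3,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              haplotype_freqs = haplotype_freqs,
              cyp2c_background_freqs = cyp2c_background_freqs,
              study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              dispense_end = as.Date(dispense_end),
              drug_initiation_rate = drug_initiation_rate,
              mean_dispense_ddd = mean_dispense_ddd,
              refill_interval_mean = refill_interval_mean,
              refill_interval_sd = refill_interval_sd,
              refill_dropout_prob = refill_dropout_prob,
              true_log_hr_per_step = true_log_hr_per_step,
              baseline_mania_hazard = baseline_mania_hazard,
              target_mania_rate = target_mania_rate,
              background_mania_rate = background_mania_rate,
              death_rate = death_rate,
              comedication_probs = comedication_probs,
              p_female = p_female,
              wave_probs = wave_probs,
              seed = as.integer(seed))
  class(cfg) <- "pgx_sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `pgx_sim_config` list.
#' @export
validate_sim_config <- function(cfg) {
  probs <- c(cfg$refill_dropout_prob, cfg$p_female, cfg$wave_probs,
             cfg$comedication_probs, cfg$haplotype_freqs,
             cfg$cyp2c_background_freqs)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$haplotype_freqs) - 1) > 1e-8) {
    stop("configuration error: haplotype frequencies must sum to 1")
  }
  if (abs(sum(cfg$cyp2c_background_freqs) - 1) > 1e-8 ||
      abs(sum(cfg$wave_probs) - 1) > 1e-8) {
    stop("configuration error: frequency vectors must sum to 1")
  }
  if (!all(c("*1", "*2", "*17") %in% names(cfg$haplotype_freqs))) {
    stop("configuration error: haplotype_freqs needs *1, *2, *17")
  }
  if (cfg$study_start >= cfg$study_end) {
    stop("configuration error: study_start must precede study_end")
  }
  if (cfg$n_subjects <= 0) stop("configuration error: n_subjects > 0")
  if (any(cfg$drug_initiation_rate < 0) || cfg$death_rate < 0 ||
      cfg$background_mania_rate < 0) {
    stop("configuration error: rates must be non-negative")
  }
  if (is.null(cfg$baseline_mania_hazard)) {
    cfg$baseline_mania_hazard <- tune_baseline_hazard(
      target_rate = cfg$target_mania_rate,
      log_hr_per_step = cfg$true_log_hr_per_step,
      haplotype_freqs = cfg$haplotype_freqs)
  }
  if (cfg$baseline_mania_hazard < 0) {
    stop("configuration error: baseline hazard must be >= 0")
  }
  cfg
}

#' Baseline mania hazard matching a target 91-day event proportion
#'
#' Given the per-step log hazard ratio and the activity-score distribution
#' implied by Hardy-Weinberg sampling of the haplotype frequencies, solves
#' for the baseline (score = 3) exponential hazard h such that the mean of
#' `1 - exp(-w * h * exp(b * (s - 3)))` over the score distribution equals
#' `target_rate`.
#'
#' @param target_rate expected event proportion within the window.
#' @param log_hr_per_step per-step log hazard ratio.
#' @param haplotype_freqs *1/*2/*17 haplotype frequencies.
#' @param window_days risk-window length (default 91).
#' @return hazard in events per person-day.
#' @export
tune_baseline_hazard <- function(target_rate, log_hr_per_step,
                                 haplotype_freqs, window_days = 91) {
  if (target_rate <= 0) return(0)
  probs <- hwe_score_probs(haplotype_freqs)
  f <- function(h) {
    sum(probs * (1 - exp(-window_days * h *
                           exp(log_hr_per_step * (1:6 - 3))))) - target_rate
  }
  uniroot(f, c(1e-10, 1), tol = 1e-12)$root
}

#' Activity-score distribution under Hardy-Weinberg diplotype sampling
#'
#' @param haplotype_freqs named *1/*2/*17 frequencies.
#' @return probabilities of scores 1..6 (UM..PM order reversed: index s is
#'   the probability of activity score s).
#' @export
hwe_score_probs <- function(haplotype_freqs) {
  p1 <- haplotype_freqs[["*1"]]
  p2 <- haplotype_freqs[["*2"]]
  p17 <- haplotype_freqs[["*17"]]
  # score: UM=1 (*17/*17), EM+=2 (*1/*17), EM=3 (*1/*1),
  #        IM+=4 (*2/*17), IM=5 (*1/*2), PM=6 (*2/*2)
  c(p17^2, 2 * p1 * p17, p1^2, 2 * p2 * p17, 2 * p1 * p2, p2^2)
}

# independent, reproducible seed streams per output table
.table_seeds <- function(master) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  names(s) <- c("persons", "genotypes", "dispenses", "comeds",
                "admissions", "background")
  s
}

#' Simulate phased CYP2C19 genotypes
#'
#' Each person receives two independent haplotype draws from the configured
#' *1/*2/*17 frequencies; SNP alleles follow deterministically (A at
#' rs4244285 on *2, T at rs12248560 on *17), so no haplotype can carry both
#' variant alleles. On *1 haplotypes the rs2860840/rs11188059 background is
#' drawn from `cyp2c_background_freqs` (TG defines CYP2C:TG); *2 and *17
#' haplotypes get the CG background.
#'
#' @param n number of subjects.
#' @param freqs named haplotype frequencies (*1, *2, *17; sum to 1).
#' @param seed RNG seed for this table.
#' @param cyp2c_background_freqs CG/TA/TG background probabilities.
#' @param person_id optional ids (default P00001...).
#' @return genotype data.frame in the genotypes.csv schema.
#' @export
simulate_genotypes <- function(n, freqs, seed,
                               cyp2c_background_freqs = c(CG = 0.6,
                                                          TA = 0.2,
                                                          TG = 0.2),
                               person_id = sprintf("P%05d", seq_len(n))) {
  stopifnot(n > 0)
  if (abs(sum(freqs) - 1) > 1e-8 || any(freqs < 0) ||
      !all(c("*1", "*2", "*17") %in% names(freqs))) {
    stop("configuration error: invalid haplotype frequency vector")
  }
  set.seed(seed)
  draw_hap <- function() {
    star <- sample(c("*1", "*2", "*17"), n, replace = TRUE,
                   prob = freqs[c("*1", "*2", "*17")])
    bg <- sample(names(cyp2c_background_freqs), n, replace = TRUE,
                 prob = cyp2c_background_freqs)
    bg[star != "*1"] <- "CG"
    data.frame(rs4244285 = ifelse(star == "*2", "A", "G"),
               rs12248560 = ifelse(star == "*17", "T", "C"),
               rs2860840 = substr(bg, 1, 1),
               rs11188059 = substr(bg, 2, 2),
               stringsAsFactors = FALSE)
  }
  h1 <- draw_hap(); h2 <- draw_hap()
  data.frame(person_id = person_id,
             h1_rs4244285 = h1$rs4244285, h1_rs12248560 = h1$rs12248560,
             h2_rs4244285 = h2$rs4244285, h2_rs12248560 = h2$rs12248560,
             h1_rs2860840 = h1$rs2860840, h1_rs11188059 = h1$rs11188059,
             h2_rs2860840 = h2$rs2860840, h2_rs11188059 = h2$rs11188059,
             stringsAsFactors = FALSE)
}

#' Simulate the demographic table
#'
#' Ages at study start are uniform 18-75, sex Bernoulli(`p_female`), wave
#' from `wave_probs`, and death times exponential at `death_rate` per year
#' from study start (death dates beyond `dispense_end` are recorded as
#' missing).
#'
#' @param config a `pgx_sim_config`.
#' @param seed RNG seed for this table.
#' @return persons data.frame: person_id, sex, birth_year, death_date, wave.
#' @export
simulate_persons <- function(config, seed) {
  set.seed(seed)
  n <- config$n_subjects
  age0 <- sample(18:75, n, replace = TRUE)
  if (config$death_rate > 0) {
    death_days <- rexp(n, rate = config$death_rate / 365.25)
    death_date <- config$study_start + round(death_days)
    death_date[death_date > config$dispense_end] <- NA
  } else {
    death_date <- rep(as.Date(NA), n)
  }
  data.frame(person_id = sprintf("P%05d", seq_len(n)),
             sex = ifelse(runif(n) < config$p_female, "female", "male"),
             birth_year = as.integer(format(config$study_start, "%Y")) - age0,
             death_date = death_date,
             wave = sample(1:3, n, replace = TRUE, prob = config$wave_probs),
             stringsAsFactors = FALSE)
}

# one refill stream: start dates + geometric number of refills, vectorized
.simulate_streams <- function(persons, atc_codes, rate_per_year, config) {
  n <- nrow(persons)
  years <- as.numeric(config$dispense_end - config$study_start) / 365.25
  n_streams <- rpois(n, rate_per_year * years)
  total <- sum(n_streams)
  if (total == 0) return(NULL)
  pid <- rep(persons$person_id, n_streams)
  first <- config$study_start +
    sample.int(as.integer(config$dispense_end - config$study_start),
               total, replace = TRUE)
  n_refills <- stats::rgeom(total, prob = max(config$refill_dropout_prob,
                                              1e-9))
  n_refills <- pmin(n_refills, 80L)  # cap pathological streams
  dt <- data.table(stream_id = rep(seq_len(total), n_refills + 1L),
                   person_id = rep(pid, n_refills + 1L),
                   first_date = rep(first, n_refills + 1L))
  m <- nrow(dt)
  dt[, interval := pmax(7, round(rnorm(m, config$refill_interval_mean,
                                       config$refill_interval_sd)))]
  dt[, date := first_date + cumsum(c(0, interval[-1])) , by = stream_id]
  dt[, atc := sample(atc_codes, m, replace = TRUE)]
  dt[, n_ddd := pmax(10, round(rnorm(m, config$mean_dispense_ddd,
                                     0.15 * config$mean_dispense_ddd)))]
  dt[, .(person_id, date, atc, n_ddd)]
}

#' Simulate pharmacy dispense histories
#'
#' Per person and drug group, a Poisson number of dispense streams starts
#' uniformly over the data window; each stream continues with
#' inter-dispense intervals around `refill_interval_mean` until a
#' per-refill dropout event. Quantities are drawn around
#' `mean_dispense_ddd`. Co-medication users (other antidepressants, mood
#' stabilizers, enzyme inducers/inhibitors, per `comedication_probs`)
#' additionally dispense those drugs at roughly quarterly intervals. No
#' dispense is dated after a person's death.
#'
#' @param persons persons table from [simulate_persons()].
#' @param config a `pgx_sim_config`.
#' @param seed RNG seed for study-drug streams.
#' @param comed_seed RNG seed for co-medication dispenses.
#' @return dispense data.frame: person_id, date, atc, n_ddd.
#' @export
simulate_dispense_histories <- function(persons, config, seed,
                                        comed_seed = seed + 1L) {
  stopifnot(nrow(persons) > 0)
  groups <- atc_groups()
  set.seed(seed)
  parts <- lapply(names(config$drug_initiation_rate), function(g) {
    .simulate_streams(persons, groups[[g]],
                      config$drug_initiation_rate[[g]], config)
  })
  set.seed(comed_seed)
  comed_atc <- list(other_n06a = c("N06AX11", "N06AX16", "N06AB05"),
                    mood_stabilizer = c("N05AN01", "N03AG01", "N03AX09"),
                    inducer_inhibitor = c("A02BC01", "N03AF01", "N06AB03"))
  window_days <- as.integer(config$dispense_end - config$study_start)
  comed_parts <- lapply(names(comed_atc), function(cls) {
    users <- runif(nrow(persons)) < config$comedication_probs[[cls]]
    if (!any(users)) return(NULL)
    pid <- persons$person_id[users]
    k <- rpois(length(pid), window_days / 91)  # ~quarterly dispensing
    total <- sum(k)
    if (total == 0) return(NULL)
    data.table(person_id = rep(pid, k),
               date = config$study_start +
                 sample.int(window_days, total, replace = TRUE),
               atc = sample(comed_atc[[cls]], total, replace = TRUE),
               n_ddd = pmax(10, round(rnorm(total, 100, 15))))
  })
  disp <- rbindlist(c(parts, comed_parts))
  if (is.null(disp) || nrow(disp) == 0) {
    return(data.frame(person_id = character(), date = as.Date(character()),
                      atc = character(), n_ddd = numeric()))
  }
  disp <- disp[date <= config$dispense_end]
  death <- as.data.table(persons)[, .(person_id, death_date)]
  disp <- merge(disp, death, by = "person_id")
  disp <- disp[is.na(death_date) | date <= death_date]
  disp[, death_date := NULL]
  setorder(disp, person_id, date, atc)
  as.data.frame(disp)
}

#' Simulate inpatient mania admissions
#'
#' During the first `window_days` days of each treatment episode, an event
#' time is drawn from an exponential distribution with hazard
#' `baseline_mania_hazard * exp(true_log_hr_per_step * (score - 3))`; the
#' event becomes an admission with a mania/mixed ICD-10 discharge code.
#' Independent background admissions (not tied to treatment) occur at
#' `background_mania_rate` per person-day over the whole study period.
#' Admissions are never dated after death.
#'
#' @param persons persons table.
#' @param episodes treatment-episode table (built from the simulated
#'   dispenses) whose starts anchor the risk windows.
#' @param scores named vector of activity scores by person_id (from
#'   [classify_genotypes()]).
#' @param config a `pgx_sim_config`.
#' @param seed RNG seed for treatment-window events.
#' @param background_seed RNG seed for background admissions.
#' @param window_days risk-window length (default 91).
#' @return admissions data.frame: person_id, admission_date,
#'   discharge_date, icd10_codes (semicolon-joined).
#' @export
simulate_mania_admissions <- function(persons, episodes, scores, config,
                                      seed, background_seed = seed + 1L,
                                      window_days = 91) {
  set.seed(seed)
  ep <- as.data.frame(episodes)
  codes <- mania_icd_codes()
  out <- list()
  if (nrow(ep) > 0 && config$baseline_mania_hazard > 0) {
    s <- scores[as.character(ep$person_id)]
    haz <- config$baseline_mania_hazard *
      exp(config$true_log_hr_per_step * (s - 3))
    t_ev <- rexp(nrow(ep), rate = haz)
    death <- persons$death_date[match(ep$person_id, persons$person_id)]
    death_t <- ifelse(is.na(death), Inf,
                      as.numeric(death - ep$start_date))
    hit <- t_ev <= pmin(window_days, death_t) & t_ev >= 1
    if (any(hit)) {
      adm_date <- ep$start_date[hit] + floor(t_ev[hit])
      out$treatment <- data.table(
        person_id = ep$person_id[hit],
        admission_date = adm_date,
        discharge_date = adm_date + sample(3:21, sum(hit), replace = TRUE),
        icd10_codes = sample(codes, sum(hit), replace = TRUE))
    }
  }
  set.seed(background_seed)
  if (config$background_mania_rate > 0) {
    days <- as.integer(config$study_end - config$study_start)
    k <- rpois(nrow(persons), config$background_mania_rate * days)
    total <- sum(k)
    if (total > 0) {
      pid <- rep(persons$person_id, k)
      adm_date <- config$study_start + sample.int(days, total, replace = TRUE)
      bg <- data.table(person_id = pid, admission_date = adm_date,
                       discharge_date = adm_date +
                         sample(3:21, total, replace = TRUE),
                       icd10_codes = sample(codes, total, replace = TRUE))
      death <- as.data.table(persons)[, .(person_id, death_date)]
      bg <- merge(bg, death, by = "person_id")
      bg <- bg[is.na(death_date) | admission_date <= death_date]
      bg[, death_date := NULL]
      out$background <- bg
    }
  }
  if (length(out) == 0) {
    return(data.frame(person_id = character(),
                      admission_date = as.Date(character()),
                      discharge_date = as.Date(character()),
                      icd10_codes = character()))
  }
  res <- rbindlist(out)
  setorder(res, person_id, admission_date)
  as.data.frame(res)
}

#' Simulate a complete synthetic registry
#'
#' Generates the four input tables (persons, genotypes, dispenses,
#' admissions) with independent RNG streams derived from the master seed,
#' so the whole run is reproducible and adding one table does not perturb
#' the others. Mania admissions are anchored on treatment episodes derived
#' from the simulated dispenses with the default gap/tail rules.
#'
#' @param config a `pgx_sim_config` (see [sim_config()]).
#' @return named list: persons, genotypes, dispenses, admissions.
#' @export
simulate_registry <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  seeds <- .table_seeds(config$seed)
  persons <- simulate_persons(config, seeds[["persons"]])
  genotypes <- simulate_genotypes(config$n_subjects, config$haplotype_freqs,
                                  seeds[["genotypes"]],
                                  config$cyp2c_background_freqs,
                                  person_id = persons$person_id)
  dispenses <- simulate_dispense_histories(persons, config,
                                           seeds[["dispenses"]],
                                           comed_seed = seeds[["comeds"]])
  episodes <- filter_left_truncated(
    build_all_episodes(dispenses),
    earliest_valid_start = config$study_start + 122)
  episodes <- episodes[episodes$start_date <= config$study_end, ,
                       drop = FALSE]
  phen <- classify_genotypes(genotypes)
  scores <- setNames(phen$activity_score, phen$person_id)
  admissions <- simulate_mania_admissions(persons, episodes, scores, config,
                                          seeds[["admissions"]],
                                          seeds[["background"]])
  list(persons = persons, genotypes = genotypes,
       dispenses = dispenses, admissions = admissions)
}

#' Write the four registry tables as CSV
#'
#' @param tables list from [simulate_registry()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_registry <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("persons.csv", "genotypes.csv",
                            "dispenses.csv", "admissions.csv"))
  write.csv(tables$persons, paths[1], row.names = FALSE)
  write.csv(tables$genotypes, paths[2], row.names = FALSE)
  write.csv(tables$dispenses, paths[3], row.names = FALSE)
  write.csv(tables$admissions, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read the four registry tables from CSV
#'
#' @param dir directory containing persons.csv, genotypes.csv,
#'   dispenses.csv, admissions.csv.
#' @return named list of data.frames with date columns parsed.
#' @export
read_registry <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  persons <- rd("persons.csv")
  persons$death_date <- as.Date(persons$death_date)
  dispenses <- rd("dispenses.csv")
  dispenses$date <- as.Date(dispenses$date)
  admissions <- rd("admissions.csv")
  admissions$admission_date <- as.Date(admissions$admission_date)
  admissions$discharge_date <- as.Date(admissions$discharge_date)
  list(persons = persons, genotypes = rd("genotypes.csv"),
       dispenses = dispenses, admissions = admissions)
}
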