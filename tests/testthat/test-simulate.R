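test_that("degenerate haplotype frequencies give a monomorphic cohort", {
  g <- simulate_genotypes(200, c("*1" = 0, "*2" = 1, "*17" = 0), seed = 1)
  ph <- classify_genotypes(g)
  expect_true(all(ph$phenotype == "PM"))
  expect_true(all(ph$activity_score == 6))
})

test_that("sampled allele frequencies converge to the configured values", {
  n <- 50000
  g <- simulate_genotypes(n, c("*1" = 0.663, "*2" = 0.147, "*17" = 0.19),
                          seed = 77)
  f2 <- mean(c(g$h1_rs4244285, g$h2_rs4244285) == "A")
  f17 <- mean(c(g$h1_rs12248560, g$h2_rs12248560) == "T")
  sd2 <- sqrt(0.147 * (1 - 0.147) / (2 * n))
  sd17 <- sqrt(0.19 * (1 - 0.19) / (2 * n))
  expect_lt(abs(f2 - 0.147), 3 * sd2)
  expect_lt(abs(f17 - 0.19), 3 * sd17)
})

test_that("no simulated haplotype carries both defining variant alleles", {
  g <- simulate_genotypes(20000, c("*1" = 0.2, "*2" = 0.4, "*17" = 0.4),
                          seed = 3)
  expect_false(any(g$h1_rs4244285 == "A" & g$h1_rs12248560 == "T"))
  expect_false(any(g$h2_rs4244285 == "A" & g$h2_rs12248560 == "T"))
  # classification therefore never errors
  expect_silent(classify_genotypes(g))
  expect_error(simulate_genotypes(10, c("*1" = 0.5, "*2" = 0.7,
                                        "*17" = -0.2), seed = 1),
               "configuration error")
})

test_that("identical seeds reproduce byte-identical registries", {
  cfg <- sim_config(n_subjects = 300, seed = 42)
  a <- simulate_registry(cfg)
  b <- simulate_registry(cfg)
  expect_identical(a, b)
  c <- simulate_registry(sim_config(n_subjects = 300, seed = 43))
  expect_false(identical(a$dispenses, c$dispenses))
})

test_that("no dispense or admission is dated after death", {
  cfg <- sim_config(n_subjects = 400, death_rate = 0.05, seed = 8)
  tabs <- simulate_registry(cfg)
  d <- merge(tabs$dispenses, tabs$persons[, c("person_id", "death_date")])
  expect_true(all(is.na(d$death_date) | d$date <= d$death_date))
  a <- merge(tabs$admissions, tabs$persons[, c("person_id", "death_date")])
  expect_true(all(is.na(a$death_date) | a$admission_date <= a$death_date))
})

test_that("certain dropout yields single-dispense streams; zero dropout
           yields streams paced by the refill interval", {
  # dropout 1: total study-drug dispenses ~ expected number of streams
  cfg <- sim_config(n_subjects = 1000, refill_dropout_prob = 1,
                    death_rate = 0,
                    drug_initiation_rate = c(escitalopram_citalopram = 0,
                                             sertraline = 0.1,
                                             amitriptyline_clomipramine = 0),
                    comedication_probs = c(other_n06a = 0,
                                           mood_stabilizer = 0,
                                           inducer_inhibitor = 0),
                    seed = 5)
  tabs <- simulate_registry(cfg)
  years <- as.numeric(cfg$dispense_end - cfg$study_start) / 365.25
  expected_streams <- 1000 * 0.1 * years
  expect_lt(abs(nrow(tabs$dispenses) / expected_streams - 1), 0.15)
  # (near-)zero dropout: dispenses per stream = 1 + floor(remaining / X),
  # X ~ refill interval; with a uniform first date the expectation is about
  # 0.5 + W/(2 * interval)
  cfg2 <- sim_config(n_subjects = 400, refill_dropout_prob = 1e-9,
                     death_rate = 0,
                     study_end = as.Date("2006-06-30"),
                     dispense_end = as.Date("2006-06-30"),
                     drug_initiation_rate = c(escitalopram_citalopram = 0,
                                              sertraline = 2,
                                              amitriptyline_clomipramine = 0),
                     comedication_probs = c(other_n06a = 0,
                                            mood_stabilizer = 0,
                                            inducer_inhibitor = 0),
                     seed = 6)
  tabs2 <- simulate_registry(cfg2)
  w <- as.numeric(cfg2$dispense_end - cfg2$study_start)
  n_streams <- 400 * 2 * (w / 365.25)
  per_stream <- nrow(tabs2$dispenses) / n_streams
  expect_lt(abs(per_stream - (0.5 + w / 2 / 100)), 0.35)
})

test_that("treatment-window mania events match the closed-form exponential
           expectation", {
  n <- 4000
  persons <- data.frame(person_id = sprintf("P%05d", 1:n), sex = "female",
                        birth_year = 1970, death_date = as.Date(NA),
                        wave = 1)
  episodes <- data.frame(person_id = persons$person_id,
                         drug_group = "sertraline", episode_id = 1,
                         start_date = as.Date("2010-01-01"),
                         end_date = as.Date("2010-12-31"))
  h <- 0.002
  cfg <- sim_config(n_subjects = n, true_log_hr_per_step = 0,
                    baseline_mania_hazard = h, background_mania_rate = 0,
                    seed = 1)
  scores <- setNames(rep(3, n), persons$person_id)
  adm <- simulate_mania_admissions(persons, episodes, scores, cfg, seed = 13)
  # events require 1 <= T <= 91 under rate h
  p <- exp(-h) - exp(-91 * h)
  expect_lt(abs(nrow(adm) - n * p), 4 * sqrt(n * p * (1 - p)))
  # zero hazard, zero background: no admissions at all
  cfg0 <- sim_config(n_subjects = n, baseline_mania_hazard = 0,
                     background_mania_rate = 0, seed = 1)
  adm0 <- simulate_mania_admissions(persons, episodes, scores, cfg0,
                                    seed = 13)
  expect_equal(nrow(adm0), 0)
})

test_that("with no pharmacogenetic effect the mania event rate is
           independent of phenotype", {
  cfg <- sim_config(n_subjects = 3000, true_log_hr_per_step = 0,
                    target_mania_rate = 0.05, background_mania_rate = 0,
                    drug_initiation_rate = c(escitalopram_citalopram = 0,
                                             sertraline = 0.1,
                                             amitriptyline_clomipramine = 0),
                    seed = 99)
  tabs <- simulate_registry(cfg)
  ep <- filter_left_truncated(build_all_episodes(tabs$dispenses))
  ep <- ep[ep$start_date <= as.Date("2016-12-31"), ]
  ma <- add_phenotypes(mania_records(ep, tabs$admissions, tabs$persons),
                       classify_genotypes(tabs$genotypes))
  grp <- ifelse(ma$activity_score <= 2, "fast",
                ifelse(ma$activity_score == 3, "normal", "slow"))
  tab <- table(grp, ma$event)
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("the tuned baseline hazard hits the target event proportion", {
  freqs <- c("*1" = 0.663, "*2" = 0.147, "*17" = 0.19)
  h <- tune_baseline_hazard(0.015, log(1.3), freqs)
  probs <- hwe_score_probs(freqs)
  got <- sum(probs * (1 - exp(-91 * h * exp(log(1.3) * (1:6 - 3)))))
  expect_equal(got, 0.015, tolerance = 1e-8)
  expect_equal(sum(probs), 1)
  expect_equal(tune_baseline_hazard(0, log(1.3), freqs), 0)
})

test_that("the simulation configuration rejects invalid inputs", {
  expect_error(sim_config(haplotype_freqs = c("*1" = 0.5, "*2" = 0.5,
                                              "*17" = 0.5)),
               "sum to 1")
  expect_error(sim_config(p_female = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(study_start = "2017-01-01",
                          study_end = "2016-01-01"), "precede")
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(death_rate = -1), "non-negative")
})
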