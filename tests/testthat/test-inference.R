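# Frozen oracle: the same data fitted with Python statsmodels GEE
# (Binomial family, exchangeable covariance, robust covariance) gives the
# coefficients, working correlation and robust SEs asserted below.
test_that("exchangeable GEE reproduces an independent reference fit", {
  set.seed(42)
  n_person <- 80
  id <- rep(sprintf("P%03d", 1:n_person), each = 3)
  u <- rep(rnorm(n_person, 0, 0.8), each = 3)
  x <- rnorm(length(id))
  sexv <- rep(sample(c("male", "female"), n_person, TRUE), each = 3)
  eta <- -0.5 + 0.7 * x + 0.3 * (sexv == "female") + u
  y <- rbinom(length(id), 1, plogis(eta))
  df <- data.frame(person_id = id, event = y, exposure = x, sex = sexv,
                   wave = rep(rep(1:3, length.out = n_person), each = 3),
                   age_at_start = round(rep(runif(n_person, 20, 70),
                                            each = 3)))
  fit <- fit_gee_logistic(df)
  expect_true(fit$converged)
  want_coef <- c("(Intercept)" = -0.906663, exposure = 0.413254,
                 sexmale = -0.091294, wave2 = -0.073317,
                 wave3 = -0.139378, age_at_start = 0.016627)
  expect_equal(fit$coef[names(want_coef)], want_coef, tolerance = 1e-4)
  expect_equal(fit$alpha, 0.2003037, tolerance = 1e-4)
  want_se <- c("(Intercept)" = 0.540420, exposure = 0.135878,
               sexmale = 0.320907, wave2 = 0.392071,
               wave3 = 0.375740, age_at_start = 0.009884)
  expect_equal(sqrt(diag(fit$vcov_robust))[names(want_se)], want_se,
               tolerance = 1e-4)
  # odds-ratio scale output brackets the estimate
  expect_true(all(fit$terms$ci_low < fit$terms$estimate &
                    fit$terms$estimate < fit$terms$ci_high))
})

test_that("GEE with singleton clusters equals plain logistic regression", {
  set.seed(7)
  df <- null_binary_records(n_person = 500, per = 1)
  fit <- fit_gee_logistic(df)
  g <- glm(event ~ exposure + sex + wave + age_at_start,
           data = transform(df, wave = factor(wave)), family = binomial)
  expect_equal(fit$coef, coef(g), tolerance = 1e-8)
  expect_equal(fit$alpha, 0)
  skip_if_not_installed("sandwich")
  vc <- sandwich::vcovCL(g, cluster = df$person_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(sqrt(diag(fit$vcov_robust)), sqrt(diag(vc)),
               tolerance = 1e-6)
})

test_that("GEE rejects degenerate inputs", {
  df <- null_binary_records(50)
  df$event <- 0
  expect_error(fit_gee_logistic(df), "at least one event")
  # perfect separation
  df2 <- null_binary_records(200)
  df2$event <- as.integer(df2$exposure > 0)
  expect_error(fit_gee_logistic(df2), "separation|rank deficient")
})

test_that("GEE Wald test holds its nominal size under the null", {
  set.seed(314)
  n_rep <- 1000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    df <- null_binary_records(n_person = 300, per = 2)
    fit <- fit_gee_logistic(df, covariates = c("sex", "age_at_start"))
    rej[i] <- fit$terms$p[fit$terms$term == "exposure"] < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("clustered Cox recovers a known two-group hazard ratio", {
  set.seed(11)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = 0.01 * exp(log(2) * x))
  df <- data.frame(person_id = sprintf("P%05d", 1:n), exposure = x,
                   time_days = pmin(t, 365), event = as.integer(t <= 365),
                   sex = "female", wave = 1, age_at_start = 40)
  fit <- fit_cox_clustered(df, covariates = character())
  hr <- fit$terms$estimate[fit$terms$term == "exposure"]
  expect_gt(hr, 1.85); expect_lt(hr, 2.15)
})

test_that("null Cox confidence intervals reach nominal coverage", {
  set.seed(22)
  n_rep <- 300
  cover <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    n <- 300
    df <- data.frame(person_id = seq_len(n), exposure = rnorm(n),
                     time_days = rexp(n, 0.02), event = 1L)
    fit <- fit_cox_clustered(df, covariates = character())
    r <- fit$terms[fit$terms$term == "exposure", ]
    cover[i] <- r$ci_low < 1 && 1 < r$ci_high
  }
  # binomial(300, 0.95) 3.5 SD band
  expect_lt(abs(mean(cover) - 0.95), 3.5 * sqrt(0.95 * 0.05 / n_rep))
})

test_that("robust SE matches model-based SE for independent observations", {
  set.seed(33)
  n <- 2000
  df <- data.frame(person_id = seq_len(n), exposure = rnorm(n),
                   time_days = rexp(n, 0.02 * exp(0.3 * 0)), event = 1L)
  fit <- fit_cox_clustered(df, covariates = character())
  naive_se <- sqrt(diag(fit$fit$naive.var))
  robust_se <- fit$terms$se_log
  expect_lt(abs(robust_se / naive_se - 1), 0.10)
})

test_that("trend Cox is equivariant under score reversal and errors
           without score variation", {
  set.seed(44)
  rec <- null_trend_records(500)
  f1 <- trend_cox(rec, covariates = c("sex", "age_at_start"))
  rec2 <- rec
  rec2$activity_score <- 7 - rec$activity_score
  f2 <- trend_cox(rec2, covariates = c("sex", "age_at_start"))
  hr1 <- f1$terms$estimate[f1$terms$term == "exposure"]
  hr2 <- f2$terms$estimate[f2$terms$term == "exposure"]
  expect_equal(hr2, 1 / hr1, tolerance = 1e-6)
  rec$activity_score <- 3
  expect_error(trend_cox(rec), "does not vary")
})

test_that("Cox trend test holds its nominal size under the null", {
  set.seed(55)
  n_rep <- 1000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    rec <- null_trend_records(400)
    fit <- trend_cox(rec, covariates = character())
    rej[i] <- fit$terms$p[fit$terms$term == "exposure"] < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("the wave covariate is dropped when a wave has no events", {
  set.seed(66)
  rec <- null_trend_records(300)
  rec$event[rec$wave == 2] <- 0L
  expect_warning(fit <- trend_cox(rec), "wave dropped")
  expect_false(any(grepl("wave", names(fit$coef))))
  expect_match(fit$note, "no events")
})

test_that("nested Wald interaction test is calibrated and degenerates to
           p = 1", {
  set.seed(77)
  rec <- null_trend_records(600)
  rec$monotherapy_flag <- runif(nrow(rec)) < 0.5
  rec <- code_exposure(rec, "score")
  full <- fit_cox_clustered(rec, covariates = c("sex", "age_at_start"),
                            interaction_monotherapy = TRUE)
  red <- fit_cox_clustered(rec, covariates = c("sex", "age_at_start"))
  w <- wald_interaction_test(full, red)
  expect_equal(w$df, 2L)  # monotherapy main effect + interaction
  expect_true(w$p > 0 && w$p <= 1)
  expect_equal(wald_interaction_test(full, full)$p, 1)
  expect_error(wald_interaction_test(red, full), "not nested")
  # size under the null, testing only the interaction block
  n_rep <- 400
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    rec <- null_trend_records(400)
    rec$monotherapy_flag <- runif(nrow(rec)) < 0.5
    rec <- code_exposure(rec, "score")
    full <- fit_cox_clustered(rec, covariates = character(),
                              interaction_monotherapy = TRUE)
    red <- fit_cox_clustered(rec, covariates = character())
    rej[i] <- wald_interaction_test(full, red)$p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("a strong simulated interaction is detected with high power", {
  set.seed(88)
  n_rep <- 60
  hit <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    n <- 800
    score <- sample(1:6, n, replace = TRUE)
    mono <- runif(n) < 0.5
    t <- rexp(n, 0.01 * exp(0.35 * (score - 3) * mono))
    rec <- data.frame(person_id = seq_len(n), activity_score = score,
                      monotherapy_flag = mono,
                      time_days = pmin(t, 365),
                      event = as.integer(t <= 365))
    rec <- code_exposure(rec, "score")
    full <- fit_cox_clustered(rec, covariates = character(),
                              interaction_monotherapy = TRUE)
    red <- fit_cox_clustered(rec, covariates = character())
    hit[i] <- wald_interaction_test(full, red)$p < 0.05
  }
  expect_gt(mean(hit), 0.8)
})

test_that("Kaplan-Meier medians match closed forms and edge cases", {
  set.seed(99)
  lambda <- 0.01
  t <- rexp(20000, lambda)
  expect_equal(km_median(t, rep(1L, length(t))), log(2) / lambda,
               tolerance = 0.03)
  expect_true(is.na(km_median(c(10, 20, 30), c(0, 0, 0))))
  expect_equal(km_median(10, 1), 10)
})

test_that("Cox sample-size formula reproduces its closed-form examples", {
  # small-group comparison at 80% power, alpha 0.05 two-sided
  expect_equal(cox_sample_size(1.2, 0.036, 0.5)$n_total, 13608)
  expect_equal(cox_sample_size(1.5, 0.036, 0.5)$n_total, 2752)
  # hand-evaluated: E = 7.849 / (0.25 * log(2)^2), rate 1
  expect_equal(cox_sample_size(2, 0.5, 1)$n_total, 66)
  expect_error(cox_sample_size(1, 0.5, 0.5), "infinite")
  expect_error(cox_sample_size(1.2, 0, 0.5))
})

test_that("sample-size requirement is monotone and symmetric in the
           exposed proportion", {
  n1 <- cox_sample_size(1.2, 0.3, 0.5)$n_total
  expect_lt(cox_sample_size(1.5, 0.3, 0.5)$n_total, n1)       # |log HR| up
  expect_lt(cox_sample_size(1 / 1.5, 0.3, 0.5)$n_total, n1)   # symmetric HR
  expect_lt(cox_sample_size(1.2, 0.3, 0.8)$n_total, n1)       # rate up
  expect_gt(cox_sample_size(1.2, 0.3, 0.5, power = 0.9)$n_total, n1)
  expect_equal(cox_sample_size(1.2, 0.3, 0.5)$n_events,
               cox_sample_size(1.2, 0.7, 0.5)$n_events)       # p <-> 1-p
})

test_that("exposure codings expose the expected reference levels", {
  rec <- data.frame(person_id = 1:6,
                    phenotype = c("PM", "IM", "IM+", "EM", "EM+", "UM"),
                    activity_score = 6:1,
                    cyp2c_rank = c(10, 9, 7, 6, 2, 1),
                    cyp2c_collapse3 = c("higher-exposure", "higher-exposure",
                                        "higher-exposure", "reference",
                                        "lower-exposure", "lower-exposure"))
  r6 <- code_exposure(rec, "phenotype6")
  expect_equal(levels(r6$exposure)[1], "EM")
  r3 <- code_exposure(rec, "collapse3")
  expect_equal(as.character(r3$exposure),
               c("PM/IM/IM+", "PM/IM/IM+", "PM/IM/IM+", "EM",
                 "EM+/UM", "EM+/UM"))
  expect_equal(code_exposure(rec, "score")$exposure, 6:1)
  expect_equal(code_exposure(rec, "cyp2c_rank")$exposure, rec$cyp2c_rank)
  expect_equal(levels(code_exposure(rec, "cyp2c_collapse3")$exposure)[1],
               "reference")
  expect_error(code_exposure(rec[rec$phenotype != "EM", ], "phenotype6"),
               "reference")
})
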