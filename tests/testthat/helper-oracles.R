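# Independent brute-force oracles, deliberately written with different
# mechanics than the package implementations.

# Episode reconstruction by explicit one-at-a-time scanning.
oracle_episodes <- function(dates, n_ddd, gap_days = 122,
                            tail_cap_days = 90) {
  o <- order(dates)
  dates <- dates[o]; n_ddd <- n_ddd[o]
  eps <- list()
  cur_dates <- dates[1]; cur_ddd <- n_ddd[1]
  close_ep <- function(ds, qs) {
    list(start = ds[1],
         end = ds[length(ds)] + min(round(qs[length(qs)]), tail_cap_days),
         n = length(ds), dates = ds)
  }
  if (length(dates) > 1) {
    for (i in 2:length(dates)) {
      if (as.integer(dates[i] - dates[i - 1]) > gap_days) {
        eps[[length(eps) + 1]] <- close_ep(cur_dates, cur_ddd)
        cur_dates <- dates[i]; cur_ddd <- n_ddd[i]
      } else {
        cur_dates <- c(cur_dates, dates[i])
        cur_ddd <- c(cur_ddd, n_ddd[i])
      }
    }
  }
  eps[[length(eps) + 1]] <- close_ep(cur_dates, cur_ddd)
  eps
}

# Mania event finding by a double loop over episodes x admissions.
oracle_mania_events <- function(episodes, admissions, persons,
                                window_days = 91) {
  out <- data.frame(row = integer(), event = integer(), time = numeric())
  for (i in seq_len(nrow(episodes))) {
    ep <- episodes[i, ]
    death <- persons$death_date[persons$person_id == ep$person_id]
    death_t <- if (length(death) == 0 || is.na(death)) Inf
               else as.numeric(death - ep$start_date)
    fu <- min(window_days, death_t)
    best <- Inf
    for (j in seq_len(nrow(admissions))) {
      ad <- admissions[j, ]
      if (ad$person_id != ep$person_id) next
      codes <- strsplit(ad$icd10_codes, ";")[[1]]
      hit <- any(nchar(codes) >= 4 &
                   substr(codes, 1, 4) %in% mania_icd_codes())
      if (!hit) next
      t <- as.numeric(as.Date(ad$admission_date) - ep$start_date)
      if (t >= 0 && t <= fu && t < best) best <- t
    }
    if (is.finite(best)) {
      out <- rbind(out, data.frame(row = i, event = 1L, time = best))
    } else {
      out <- rbind(out, data.frame(row = i, event = 0L, time = fu))
    }
  }
  out
}

# Random small dispense streams for the oracle-equivalence property.
random_stream <- function() {
  n <- sample(1:8, 1)
  gaps <- sample(1:400, n - 1, replace = TRUE)
  start <- as.Date("2008-01-01") + sample(0:2000, 1)
  dates <- start + cumsum(c(0, gaps))
  list(dates = dates, n_ddd = sample(5:150, n, replace = TRUE))
}

# Small simulated outcome-record tables for inference tests.
null_binary_records <- function(n_person = 300, per = 2) {
  id <- rep(sprintf("P%04d", seq_len(n_person)), each = per)
  u <- rep(rnorm(n_person, 0, 0.6), each = per)
  n <- length(id)
  data.frame(person_id = id,
             exposure = rep(rnorm(n_person), each = per),
             sex = rep(sample(c("male", "female"), n_person, TRUE),
                       each = per),
             wave = rep(sample(1:3, n_person, TRUE), each = per),
             age_at_start = rep(round(runif(n_person, 20, 70)), each = per),
             event = rbinom(n, 1, plogis(-1 + u)))
}

null_trend_records <- function(n = 400) {
  score <- sample(1:6, n, replace = TRUE,
                  prob = hwe_score_probs(c("*1" = 0.663, "*2" = 0.147,
                                           "*17" = 0.19)))
  t <- rexp(n, rate = 0.01)
  data.frame(person_id = sprintf("P%04d", seq_len(n)),
             activity_score = score,
             sex = sample(c("male", "female"), n, TRUE),
             wave = sample(1:3, n, TRUE),
             age_at_start = round(runif(n, 20, 70)),
             time_days = pmin(t, 91), event = as.integer(t <= 91))
}
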