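#' Defined daily doses (mg) for the five study antidepressants
#'
#' WHO DDDs: citalopram 20 mg, escitalopram 10 mg, sertraline 50 mg,
#' clomipramine 100 mg, amitriptyline 75 mg. Dispensed quantity in DDD
#' units approximates days of supply at the assumed maintenance dose.
#'
#' @return named numeric vector, mg per DDD.
#' @export
ddd_table <- function() {
  c(citalopram = 20, escitalopram = 10, sertraline = 50,
    clomipramine = 100, amitriptyline = 75)
}

#' Convert a dispensed amount in mg to DDD units
#'
#' @param drug substance name present in [ddd_table()].
#' @param total_mg dispensed amount in mg (>= 0).
#' @return quantity in DDD units.
#' @export
#' @examples
#' mg_to_ddd("sertraline", 5000)  # 100 DDD
mg_to_ddd <- function(drug, total_mg) {
  tab <- ddd_table()
  if (!all(drug %in% names(tab))) {
    stop("unknown drug(s): ", paste(setdiff(drug, names(tab)), collapse = ", "))
  }
  if (any(total_mg < 0)) stop("total_mg must be non-negative")
  unname(total_mg / tab[drug])
}

#' ATC codes defining the three analysed drug groups
#'
#' Citalopram (N06AB04) and escitalopram (N06AB10) are pooled, sertraline
#' (N06AB06) stands alone, and the tricyclics amitriptyline (N06AA09) and
#' clomipramine (N06AA04) are pooled. Override to regroup or add codes.
#'
#' @return named list of ATC code vectors.
#' @export
atc_groups <- function() {
  list(escitalopram_citalopram = c("N06AB04", "N06AB10"),
       sertraline = "N06AB06",
       amitriptyline_clomipramine = c("N06AA09", "N06AA04"))
}

#' Reconstruct treatment episodes from one dispense stream
#'
#' Dispense dates of one person x drug group are scanned left to right; a
#' new episode starts whenever the gap since the previous dispense exceeds
#' `gap_days` (a gap of exactly `gap_days` continues the episode). Each
#' episode runs from its first dispense date to its last dispense date plus
#' the last dispense's supply, `min(round(n_ddd), tail_cap_days)` days. The
#' tail is applied at the end of every episode, including the final one.
#'
#' @param dates dispense dates (Date), any order.
#' @param n_ddd dispensed quantities in DDD units, parallel to `dates`.
#' @param gap_days maximum refill gap in days (default 122 = 4 months;
#'   183 = 6 months is the usual sensitivity value).
#' @param tail_cap_days cap on the supply tail in days (default 90).
#' @return data.frame of episodes in chronological order: start_date,
#'   end_date, n_dispenses, second_gap_days (days from first to second
#'   dispense, NA for single-dispense episodes), and a `dispense_dates`
#'   list column with the ordered dates of each episode.
#' @export
#' @examples
#' d <- as.Date("2010-01-01") + c(0, 100, 300)
#' build_episodes(d, c(30, 30, 30))  # splits at the 200-day gap
build_episodes <- function(dates, n_ddd, gap_days = 122, tail_cap_days = 90) {
  stopifnot(length(dates) == length(n_ddd), gap_days > 0, tail_cap_days >= 0)
  if (length(dates) == 0) {
    return(data.frame(start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      n_dispenses = integer(), second_gap_days = integer(),
                      dispense_dates = I(list())))
  }
  if (any(n_ddd < 0)) stop("negative dispensed quantity")
  o <- order(dates)
  dates <- dates[o]; n_ddd <- n_ddd[o]
  grp <- cumsum(c(TRUE, diff(as.integer(dates)) > gap_days))
  sp_d <- split(dates, grp)
  sp_q <- split(n_ddd, grp)
  out <- data.frame(
    start_date = as.Date(vapply(sp_d, function(x) as.numeric(x[1]), 0)),
    end_date = as.Date(vapply(seq_along(sp_d), function(i) {
      d <- sp_d[[i]]; q <- sp_q[[i]]
      as.numeric(d[length(d)]) +
        min(round(q[length(q)]), tail_cap_days)
    }, 0)),
    n_dispenses = vapply(sp_d, length, 0L),
    second_gap_days = vapply(sp_d, function(x) {
      if (length(x) > 1) as.integer(x[2] - x[1]) else NA_integer_
    }, 0L))
  out$dispense_dates <- I(unname(sp_d))
  rownames(out) <- NULL
  out
}

#' Reconstruct treatment episodes for a whole dispense table
#'
#' Applies [build_episodes()] per person x drug group over a dispense table.
#' Dispenses whose ATC code is not in any group are ignored.
#'
#' @param dispenses data.frame: person_id, date (Date), atc, n_ddd.
#' @param groups named list of ATC code vectors (default [atc_groups()]).
#' @inheritParams build_episodes
#' @return data.frame: person_id, drug_group, episode_id (1.. within person
#'   x group), start_date, end_date, n_dispenses, second_gap_days.
#' @export
build_all_episodes <- function(dispenses, groups = atc_groups(),
                               gap_days = 122, tail_cap_days = 90) {
  dt <- as.data.table(dispenses)
  stopifnot(all(c("person_id", "date", "atc", "n_ddd") %in% names(dt)))
  if (any(dt$n_ddd < 0)) stop("negative dispensed quantity")
  map <- data.table(atc = unlist(groups),
                    drug_group = rep(names(groups), lengths(groups)))
  dt <- merge(dt, map, by = "atc")
  if (nrow(dt) == 0) {
    return(data.frame(person_id = character(), drug_group = character(),
                      episode_id = integer(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      n_dispenses = integer(), second_gap_days = integer()))
  }
  setorder(dt, person_id, drug_group, date)
  dt[, gap := c(NA_integer_, diff(as.integer(date))),
     by = .(person_id, drug_group)]
  dt[, episode_id := cumsum(is.na(gap) | gap > gap_days),
     by = .(person_id, drug_group)]
  ep <- dt[, .(
    start_date = date[1],
    end_date = date[.N] + min(round(n_ddd[.N]), tail_cap_days),
    n_dispenses = .N,
    second_gap_days = if (.N > 1) as.integer(date[2] - date[1])
                      else NA_integer_
  ), by = .(person_id, drug_group, episode_id)]
  setorder(ep, person_id, drug_group, start_date)
  as.data.frame(ep)
}

#' Drop left-truncated episodes
#'
#' Episodes that start on or before `earliest_valid_start` may be
#' continuations of treatment begun before registry coverage and are
#' removed; with the default 122-day gap and a registry starting 2005-07-01
#' this keeps only episodes starting after 2005-10-31.
#'
#' @param episodes episode table from [build_all_episodes()].
#' @param earliest_valid_start last inadmissible start date
#'   (registry start + gap_days).
#' @return the filtered episode table.
#' @export
filter_left_truncated <- function(episodes,
                                  earliest_valid_start = as.Date("2005-10-31")) {
  episodes[episodes$start_date > as.Date(earliest_valid_start), , drop = FALSE]
}
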