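#' Exposure coding for outcome models
#'
#' Adds an `exposure` column to an outcome-record table under one of the
#' codings used in the analyses: `"phenotype6"` - six-level factor with EM
#' (normal metabolizer) as reference; `"collapse3"` - PM/IM/IM+ vs EM vs
#' EM+/UM with EM as reference (used when events are sparse);
#' `"score"` - the inverted activity score 1..6 as a continuous trend
#' variable; `"cyp2c_rank"` - the ten-level CYP2C diplotype rank as a
#' continuous variable; `"cyp2c_collapse3"` - the three-level CYP2C
#' collapse with the reference diplotype group as reference.
#'
#' @param records outcome records carrying phenotype / activity_score (and
#'   cyp2c columns for the expanded codings).
#' @param coding one of the codings above.
#' @return records with an `exposure` column (factor or numeric).
#' @export
code_exposure <- function(records,
                          coding = c("phenotype6", "collapse3", "score",
                                     "cyp2c_rank", "cyp2c_collapse3")) {
  coding <- match.arg(coding)
  r <- as.data.frame(records)
  r$exposure <- switch(coding,
    phenotype6 = factor(r$phenotype,
                        levels = c("EM", "PM", "IM", "IM+", "EM+", "UM")),
    collapse3 = {
      g <- ifelse(r$phenotype %in% c("PM", "IM", "IM+"), "PM/IM/IM+",
                  ifelse(r$phenotype == "EM", "EM", "EM+/UM"))
      factor(g, levels = c("EM", "PM/IM/IM+", "EM+/UM"))
    },
    score = as.numeric(r$activity_score),
    cyp2c_rank = as.numeric(r$cyp2c_rank),
    cyp2c_collapse3 = factor(r$cyp2c_collapse3,
                             levels = c("reference", "lower-exposure",
                                        "higher-exposure")))
  if (is.factor(r$exposure) && !any(r$exposure == levels(r$exposure)[1],
                                    na.rm = TRUE)) {
    stop("reference exposure level absent from the data")
  }
  r
}

# Drop the study-wave covariate when some wave has no events (its
# coefficient would be unidentified / infinite). Returns possibly shortened
# covariate vector plus a note.
.maybe_drop_wave <- function(records, covariates) {
  note <- NULL
  if ("wave" %in% covariates) {
    ev <- tapply(records$event, factor(records$wave), sum)
    if (any(is.na(ev)) || any(ev == 0)) {
      covariates <- setdiff(covariates, "wave")
      note <- "wave dropped: no events in at least one study wave"
      warning(note, call. = FALSE)
    }
  }
  list(covariates = covariates, note = note)
}

.build_rhs <- function(covariates, interaction_monotherapy = FALSE) {
  rhs <- c("exposure", covariates)
  if (interaction_monotherapy) {
    rhs <- c(rhs, "monotherapy_flag", "exposure:monotherapy_flag")
  }
  paste(rhs, collapse = " + ")
}

.new_model_result <- function(model, coef_log, vcov_robust, records,
                              converged, note = NULL, scale = "HR") {
  se <- sqrt(diag(vcov_robust))
  z <- coef_log / se
  terms_df <- data.frame(term = names(coef_log),
                         estimate = exp(coef_log),
                         se_log = se,
                         ci_low = exp(coef_log - qnorm(0.975) * se),
                         ci_high = exp(coef_log + qnorm(0.975) * se),
                         p = 2 * pnorm(-abs(z)),
                         row.names = NULL)
  structure(list(model = model, scale = scale, terms = terms_df,
                 coef = coef_log, vcov_robust = vcov_robust,
                 n = nrow(records),
                 n_persons = length(unique(records$person_id)),
                 n_events = sum(records$event),
                 converged = converged, note = note),
            class = "pgx_model_result")
}

#' @export
print.pgx_model_result <- function(x, ...) {
  cat(sprintf("%s model (%s scale): %d records, %d persons, %d events%s\n",
              x$model, x$scale, x$n, x$n_persons, x$n_events,
              if (x$converged) "" else " [DID NOT CONVERGE]"))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  df <- x$terms
  df$estimate <- round(df$estimate, 3)
  df$ci_low <- round(df$ci_low, 3)
  df$ci_high <- round(df$ci_high, 3)
  df$p <- signif(df$p, 3)
  print(df[, c("term", "estimate", "ci_low", "ci_high", "p")],
        row.names = FALSE)
  invisible(x)
}

#' GEE logistic regression with exchangeable working correlation
#'
#' Population-averaged logistic regression fitted by iteratively reweighted
#' GEE with an exchangeable working correlation (all pairs of records from
#' the same person share one correlation), and a robust sandwich covariance
#' clustered on person. With singleton clusters the estimates coincide with
#' ordinary logistic regression and the sandwich reduces to the usual
#' heteroscedasticity-robust clustered estimator.
#'
#' @param records binary outcome records (column `event` in 0/1) with an
#'   `exposure` column from [code_exposure()].
#' @param covariates adjustment terms (columns of `records`); defaults to
#'   sex, wave, age at start.
#' @param interaction_monotherapy add monotherapy main effect and
#'   exposure x monotherapy interaction terms.
#' @param id_var cluster identifier column.
#' @param maxit,tol IRLS control.
#' @return a `pgx_model_result`: odds-ratio scale estimates with robust
#'   SEs, CIs and p-values; the estimated working correlation is attached
#'   as `alpha`.
#' @export
fit_gee_logistic <- function(records,
                             covariates = c("sex", "wave", "age_at_start"),
                             interaction_monotherapy = FALSE,
                             id_var = "person_id", maxit = 50, tol = 1e-8) {
  r <- as.data.frame(records)
  stopifnot("exposure" %in% names(r), all(r$event %in% 0:1))
  if (sum(r$event) == 0 || sum(r$event) == nrow(r)) {
    stop("need at least one event and one non-event")
  }
  dw <- .maybe_drop_wave(r, covariates)
  if ("wave" %in% names(r)) r$wave <- factor(r$wave)
  f <- as.formula(paste("event ~",
                        .build_rhs(dw$covariates, interaction_monotherapy)))
  used <- intersect(all.vars(f), names(r))
  ok <- stats::complete.cases(r[, used, drop = FALSE])
  r <- r[ok, , drop = FALSE]
  mf <- model.frame(f, r)
  X <- model.matrix(f, mf)
  y <- model.response(mf)
  id <- r[[id_var]]
  o <- order(id)
  X <- X[o, , drop = FALSE]; y <- y[o]; id <- id[o]
  p <- ncol(X)
  beta <- suppressWarnings(glm.fit(X, y, family = binomial())$coefficients)
  if (anyNA(beta)) stop("design matrix is rank deficient")
  if (max(abs(beta)) > 15) stop("separation: diverging GEE coefficients")
  cl <- split(seq_along(y), id)
  sizes <- lengths(cl)
  npairs <- sum(sizes * (sizes - 1) / 2)
  alpha <- 0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    v <- mu * (1 - mu)
    pe <- (y - mu) / sqrt(v)                    # Pearson residuals
    if (!all(is.finite(pe))) {
      stop("separation: fitted probabilities at 0 or 1")
    }
    phi <- sum(pe^2) / (length(y) - p)
    if (npairs > p) {
      s <- vapply(cl, function(ix) {
        e <- pe[ix]
        (sum(e)^2 - sum(e^2)) / 2
      }, 0)
      alpha <- sum(s) / (phi * (npairs - p))
      max_n <- max(sizes)
      alpha <- min(max(alpha, -0.95 / max(1, max_n - 1)), 0.99)
    }
    M <- matrix(0, p, p)
    U <- numeric(p)
    for (ix in cl) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      vi <- v[ix]
      resi <- y[ix] - mu[ix]
      # D_i' V_i^{-1} with V_i = phi A^{1/2} R A^{1/2}, D_i = A X_i:
      # reduces to X_i' A^{1/2} R^{-1} A^{-1/2} ... worked in half-scaled
      # form: let u = A^{-1/2} res (Pearson), Z = A^{1/2} X
      Zi <- Xi * sqrt(vi)
      ui <- resi / sqrt(vi)
      if (ni == 1 || alpha == 0) {
        Rinv_u <- ui
        Rinv_Z <- Zi
      } else {
        c1 <- 1 / (1 - alpha)
        c2 <- alpha / ((1 - alpha) * (1 - alpha + ni * alpha))
        Rinv_u <- c1 * ui - c2 * sum(ui)
        Rinv_Z <- c1 * Zi - matrix(c2 * colSums(Zi), ni, p, byrow = TRUE)
      }
      M <- M + crossprod(Zi, Rinv_Z)
      U <- U + drop(crossprod(Zi, Rinv_u))
    }
    delta <- solve(M, U)
    beta <- beta + delta
    if (max(abs(beta)) > 15) stop("separation: diverging GEE coefficients")
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  # sandwich covariance at the final beta
  eta <- drop(X %*% beta); mu <- plogis(eta); v <- mu * (1 - mu)
  M <- matrix(0, p, p); B <- matrix(0, p, p)
  for (ix in cl) {
    ni <- length(ix)
    Zi <- X[ix, , drop = FALSE] * sqrt(v[ix])
    ui <- (y[ix] - mu[ix]) / sqrt(v[ix])
    if (ni == 1 || alpha == 0) {
      Rinv_u <- ui; Rinv_Z <- Zi
    } else {
      c1 <- 1 / (1 - alpha)
      c2 <- alpha / ((1 - alpha) * (1 - alpha + ni * alpha))
      Rinv_u <- c1 * ui - c2 * sum(ui)
      Rinv_Z <- c1 * Zi - matrix(c2 * colSums(Zi), ni, p, byrow = TRUE)
    }
    M <- M + crossprod(Zi, Rinv_Z)
    gi <- drop(crossprod(Zi, Rinv_u))
    B <- B + tcrossprod(gi)
  }
  Minv <- solve(M)
  V <- Minv %*% B %*% Minv
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  res <- .new_model_result("gee-logistic", beta, V, r, converged,
                           note = dw$note, scale = "OR")
  res$alpha <- alpha
  res
}

#' Cox regression with cluster-robust standard errors
#'
#' Proportional-hazards regression of `time_days`/`event` on the exposure
#' and adjustment covariates, with a robust sandwich variance clustered on
#' person to account for multiple treatment episodes per individual. Ties
#' are handled by the Efron method so repeated runs are bit-for-bit
#' reproducible at registry day resolution.
#'
#' @inheritParams fit_gee_logistic
#' @param records survival outcome records with `time_days`, `event` and an
#'   `exposure` column.
#' @return a `pgx_model_result` on the hazard-ratio scale; the underlying
#'   `coxph` fit is attached as `fit`.
#' @export
fit_cox_clustered <- function(records,
                              covariates = c("sex", "wave", "age_at_start"),
                              interaction_monotherapy = FALSE,
                              id_var = "person_id") {
  r <- as.data.frame(records)
  stopifnot(all(c("time_days", "event", "exposure") %in% names(r)))
  if (sum(r$event) == 0) stop("no events: Cox model is undefined")
  dw <- .maybe_drop_wave(r, covariates)
  if ("wave" %in% names(r)) r$wave <- factor(r$wave)
  r$.cluster_id <- r[[id_var]]
  f <- as.formula(paste("Surv(time_days, event) ~",
                        .build_rhs(dw$covariates, interaction_monotherapy),
                        "+ cluster(.cluster_id)"))
  fit <- coxph(f, data = r, ties = "efron", robust = TRUE)
  converged <- is.null(fit$info) && !anyNA(coef(fit))
  if (anyNA(coef(fit))) {
    warning("some coefficients not estimable (dropped as NA)", call. = FALSE)
  }
  keep <- !is.na(coef(fit))
  beta <- coef(fit)[keep]
  V <- fit$var[keep, keep, drop = FALSE]
  dimnames(V) <- list(names(beta), names(beta))
  res <- .new_model_result("cox-clustered", beta, V, r, converged,
                           note = dw$note, scale = "HR")
  res$fit <- fit
  res
}

#' Activity-score trend Cox model
#'
#' Convenience wrapper fitting the cluster-robust Cox model with the
#' inverted activity score (UM = 1 ... PM = 6) as a single continuous
#' exposure; the exposure hazard ratio is per one-step slowing of
#' metabolism.
#'
#' @inheritParams fit_cox_clustered
#' @param records outcome records carrying `activity_score`.
#' @return a `pgx_model_result`; the per-step HR is the `exposure` term.
#' @export
trend_cox <- function(records, covariates = c("sex", "wave", "age_at_start"),
                      id_var = "person_id") {
  r <- code_exposure(records, "score")
  if (length(unique(r$exposure)) < 2) {
    stop("activity score does not vary: trend is undefined")
  }
  fit_cox_clustered(r, covariates = covariates, id_var = id_var)
}

#' Joint Wald test for an interaction block
#'
#' Compares two nested fitted models and tests the extra terms of the full
#' model (typically the exposure x monotherapy interaction block) with a
#' joint Wald chi-square using the full model's robust covariance; degrees
#' of freedom equal the number of extra terms.
#'
#' @param full,reduced `pgx_model_result` objects; the reduced model's
#'   terms must be a subset of the full model's.
#' @return list with statistic, df and p (p = 1 with zero extra terms).
#' @export
wald_interaction_test <- function(full, reduced) {
  extra <- setdiff(names(full$coef), names(reduced$coef))
  if (!all(names(reduced$coef) %in% names(full$coef))) {
    stop("models are not nested")
  }
  if (length(extra) == 0) {
    return(list(statistic = 0, df = 0L, p = 1))
  }
  b <- full$coef[extra]
  V <- full$vcov_robust[extra, extra, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  list(statistic = stat, df = length(extra),
       p = pchisq(stat, df = length(extra), lower.tail = FALSE))
}

#' Kaplan-Meier median time to event
#'
#' @param time_days,event follow-up times and 0/1 event indicators.
#' @return the KM median in days, or NA if the survival curve never drops
#'   below 0.5 (e.g. all records censored).
#' @export
km_median <- function(time_days, event) {
  if (sum(event) == 0) return(NA_real_)
  fit <- survfit(Surv(time_days, event) ~ 1)
  unname(quantile(fit, probs = 0.5)$quantile)
}

#' Required sample size for a two-group Cox comparison
#'
#' Schoenfeld-type calculation: the required number of events is
#' \deqn{E = (z_{1-\alpha/2} + z_{power})^2 / (p (1 - p) (\log HR)^2)}
#' where p is the exposed proportion, and the total sample size is
#' E divided by the overall event rate, rounded up.
#'
#' @param hazard_ratio target hazard ratio (> 0, not 1).
#' @param exposed_proportion proportion in the smaller group, in (0, 1).
#' @param event_rate overall event probability, in (0, 1].
#' @param power desired power (default 0.8).
#' @param alpha two-sided significance level (default 0.05).
#' @return list with `n_total` (subjects) and `n_events`.
#' @export
#' @examples
#' cox_sample_size(1.2, 0.036, 0.5)$n_total
cox_sample_size <- function(hazard_ratio, exposed_proportion, event_rate,
                            power = 0.8, alpha = 0.05) {
  stopifnot(hazard_ratio > 0, exposed_proportion > 0, exposed_proportion < 1,
            event_rate > 0, event_rate <= 1, power > 0, power < 1,
            alpha > 0, alpha < 1)
  if (hazard_ratio == 1) stop("hazard ratio of 1 requires infinite n")
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  E <- z^2 / (exposed_proportion * (1 - exposed_proportion) *
                log(hazard_ratio)^2)
  list(n_total = ceiling(E / event_rate), n_events = E)
}
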