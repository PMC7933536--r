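# Prognostic analysis: univariable Cox models with bootstrap percentile CIs,
# median-dichotomized Kaplan-Meier with log-rank tests, cohort summary.

#' Univariable Cox proportional-hazards fit with bootstrap CI
#'
#' Fits a single-covariate Cox model (Efron tie handling) and reports the
#' hazard ratio per covariate unit, a full-sample Wald p-value, and a 95%
#' percentile confidence interval over `n_boot` patient resamples with
#' replacement (default 5000). Cases with an undefined covariate (`NA`, e.g.
#' a ratio with a zero denominator) are excluded and counted. Resamples in
#' which the model cannot be fitted (no covariate variation, fewer than two
#' events, or a diverging coefficient) are dropped and counted; the CI is
#' computed from the remainder.
#'
#' @param covariate Per-case numeric covariate; `NA` marks undefined.
#' @param time,event Follow-up times (months) and event indicators (0/1).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the resampling stream; identical seed and
#'   inputs give a bit-identical fit.
#' @param conf_level Confidence level for the percentile interval.
#' @return Object of class `cox_fit`: `hr`, `ci_low`, `ci_high`, `p`,
#'   `beta`, `se`, `n_used`, `n_excluded_undefined`, `n_events`,
#'   `n_boot_used`, `n_boot_failed`, `converged`.
#' @export
fit_cox_univariable <- function(covariate, time, event, n_boot = 5000L,
                                seed = 1L, conf_level = 0.95) {
  stopifnot(length(covariate) == length(time), length(time) == length(event),
            n_boot >= 0)
  ok <- !is.na(covariate) & !is.na(time) & !is.na(event)
  n_excluded <- sum(!ok)
  z <- covariate[ok]; t <- time[ok]; e <- as.integer(event[ok])
  if (!all(e %in% 0:1)) stop("event indicators must be 0/1")
  n <- length(z)
  if (sum(e) < 2) stop("fewer than 2 events among cases with a defined covariate")

  res <- list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              p = NA_real_, beta = NA_real_, se = NA_real_,
              n_used = n, n_excluded_undefined = n_excluded,
              n_events = sum(e), n_boot_used = 0L, n_boot_failed = 0L,
              converged = FALSE, conf_level = conf_level, seed = seed,
              message = NULL)
  class(res) <- "cox_fit"
  if (stats::var(z) == 0) {
    res$message <- "covariate has zero variance; hazard ratio not identifiable"
    return(res)
  }

  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(t, e) ~ z, ties = "efron"),
    warning = function(w) {
      diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  res$beta <- beta; res$se <- se
  res$hr <- exp(beta)
  res$p <- 2 * stats::pnorm(-abs(beta / se))
  res$converged <- !diverged && is.finite(beta) && is.finite(se)
  if (diverged) res$message <- "main fit did not converge cleanly; estimates reported as-is"

  if (n_boot > 0) {
    ctrl <- survival::coxph.control()
    bhr <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        eb <- e[idx]; zb <- z[idx]
        if (sum(eb) < 2 || stats::var(zb) == 0) return(NA_real_)
        f <- tryCatch(
          suppressWarnings(survival::coxph.fit(
            x = matrix(zb, ncol = 1), y = survival::Surv(t[idx], eb),
            strata = NULL, offset = NULL, init = 0, control = ctrl,
            weights = NULL, method = "efron", rownames = NULL)),
          error = function(err) NULL)
        if (is.null(f) || !is.finite(f$coefficients[1])) return(NA_real_)
        exp(unname(f$coefficients[1]))
      }, numeric(1))
    })
    res$n_boot_failed <- sum(is.na(bhr))
    res$n_boot_used <- sum(!is.na(bhr))
    if (res$n_boot_used >= 2) {
      alpha <- (1 - conf_level) / 2
      qs <- stats::quantile(bhr, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
      res$ci_low <- qs[1]; res$ci_high <- qs[2]
    }
  }
  res
}

#' @export
print.cox_fit <- function(x, ...) {
  if (x$converged || is.finite(x$hr))
    cat(sprintf("<cox_fit> HR %.3f (%.2f-%.2f), p = %.4g, n = %d (%d excluded), %d/%d bootstraps%s\n",
                x$hr, x$ci_low, x$ci_high, x$p, x$n_used, x$n_excluded_undefined,
                x$n_boot_used, x$n_boot_used + x$n_boot_failed,
                if (x$converged) "" else " [not converged]"))
  else cat(sprintf("<cox_fit> not identifiable (%s)\n", x$message))
  invisible(x)
}

#' Dichotomize values at the sample median
#'
#' Splits cases at the median of the covariate: values less than or equal to
#' the median form the "low" group, values above it "high" (ties go low).
#'
#' @param values Numeric vector with at least two distinct values.
#' @return List with `labels` (factor low/high, `NA` kept) and `cutoff`.
#' @export
dichotomize_median <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2)
    stop("cannot dichotomize: fewer than 2 distinct values")
  med <- stats::median(v)
  labels <- factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
  list(labels = labels, cutoff = med)
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit survival curves per group and the two-sample log-rank
#' chi-square (1 df) with its p-value.
#'
#' @param groups Factor with two non-empty levels (`NA` cases dropped).
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param cutoff Optional cutoff value to record (see [km_median()]).
#' @return Object of class `km_fit`: `fit` (a [survival::survfit] object),
#'   `chisq`, `logrank_p`, group sizes `n`, `cutoff`.
#' @export
km_logrank <- function(groups, time, event, cutoff = NA_real_) {
  keep <- !is.na(groups) & !is.na(time) & !is.na(event)
  groups <- droplevels(factor(groups[keep])); time <- time[keep]; event <- event[keep]
  if (nlevels(groups) != 2 || any(table(groups) == 0))
    stop("log-rank comparison requires two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  chisq <- unname(sd$chisq)
  fit <- survival::survfit(survival::Surv(time, event) ~ groups)
  structure(list(fit = fit, chisq = chisq,
                 logrank_p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 n = table(groups), cutoff = cutoff),
            class = "km_fit")
}

#' Median-dichotomized Kaplan-Meier analysis of one TIL measure
#'
#' @param values Per-case covariate (e.g. scaled CD3 ITA density).
#' @param time,event Outcome.
#' @return A `km_fit` including the median cutoff used.
#' @export
km_median <- function(values, time, event) {
  d <- dichotomize_median(values)
  km_logrank(d$labels, time, event, cutoff = d$cutoff)
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> log-rank chi2 = %.3f, p = %.4g; n = %s%s\n",
              x$chisq, x$logrank_p,
              paste(sprintf("%s:%d", names(x$n), x$n), collapse = ", "),
              if (is.na(x$cutoff)) "" else sprintf("; cutoff = %.4g", x$cutoff)))
  invisible(x)
}

#' Cohort characteristics summary
#'
#' Count and percentage of the cohort per category level, percentages to one
#' decimal with half-up rounding (report convention).
#'
#' @param clinical data.frame of categorical per-case fields.
#' @param n Denominator; defaults to `nrow(clinical)`.
#' @return data.frame with columns variable, level, n, pct.
#' @export
cohort_summary <- function(clinical, n = nrow(clinical)) {
  rows <- lapply(names(clinical), function(v) {
    tab <- table(factor(clinical[[v]]), useNA = "no")
    data.frame(variable = v, level = names(tab), n = as.integer(tab),
               pct = round_half_up(100 * as.integer(tab) / n, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Univariable survival table across all TIL measures
#'
#' Runs [fit_cox_univariable()] for every measure column against both
#' outcomes (RFS and OS), mirroring the standard report layout: hazard ratio
#' with bootstrap percentile CI and Wald p per measure, marker and outcome.
#' No multiple-comparison adjustment is applied to the p-values; instead,
#' results significant at `alpha` that would not survive a Bonferroni
#' correction across the family of measures for the same marker and outcome
#' are annotated (`bonferroni_robust = FALSE`).
#'
#' @param measures Measures table from [cohort_measures()] (or the
#'   synthetic-cohort pipeline).
#' @param outcomes data.frame with case_id, rfs_months, rfs_event, os_months,
#'   os_event, aligned by case_id.
#' @param n_boot Bootstraps per model.
#' @param seed Master seed; per-model streams are derived deterministically.
#' @param measure_cols Columns to analyse; defaults to [measure_names()]
#'   (those present).
#' @param alpha Baseline significance level (not adjusted).
#' @return data.frame with one row per measure x outcome.
#' @export
til_survival_table <- function(measures, outcomes, n_boot = 5000L, seed = 1L,
                               measure_cols = NULL, alpha = 0.05) {
  if (is.null(measure_cols))
    measure_cols <- intersect(measure_names(), names(measures))
  m <- merge(measures, outcomes, by = "case_id", sort = TRUE)
  outs <- list(RFS = c("rfs_months", "rfs_event"), OS = c("os_months", "os_event"))
  seeds <- derive_seeds(seed, length(measure_cols) * length(outs))
  k <- 0L
  rows <- list()
  for (col in measure_cols) {
    marker <- sub("_.*$", "", col)
    for (on in names(outs)) {
      k <- k + 1L
      fit <- tryCatch(
        fit_cox_univariable(m[[col]], m[[outs[[on]][1]]], m[[outs[[on]][2]]],
                            n_boot = n_boot, seed = seeds[k]),
        error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[k]] <- data.frame(measure = col, marker = marker, outcome = on,
                                hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                                p = NA_real_, n_used = 0L, n_excluded_undefined = NA_integer_,
                                converged = FALSE, note = conditionMessage(fit),
                                stringsAsFactors = FALSE)
      } else {
        rows[[k]] <- data.frame(measure = col, marker = marker, outcome = on,
                                hr = fit$hr, ci_low = fit$ci_low, ci_high = fit$ci_high,
                                p = fit$p, n_used = fit$n_used,
                                n_excluded_undefined = fit$n_excluded_undefined,
                                converged = fit$converged,
                                note = fit$message %||% "", stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  fam <- stats::ave(seq_len(nrow(tab)), tab$marker, tab$outcome, FUN = length)
  tab$bonferroni_robust <- ifelse(is.na(tab$p), NA,
                                  tab$p < alpha / fam)
  tab
}

#' Median-cutoff Kaplan-Meier table for the intratumoural measures
#'
#' @param measures,outcomes As in [til_survival_table()].
#' @param measure_cols Measures to dichotomize; default: the intratumoural
#'   covariates (ITA, ITT, ITS) per marker.
#' @return data.frame: measure, outcome, cutoff, group sizes, log-rank p.
#' @export
til_km_table <- function(measures, outcomes, measure_cols = NULL) {
  if (is.null(measure_cols))
    measure_cols <- intersect(
      paste0(rep(TIL_MARKERS, each = 3), "_", c("ITA", "ITT", "ITS")),
      names(measures))
  m <- merge(measures, outcomes, by = "case_id", sort = TRUE)
  outs <- list(RFS = c("rfs_months", "rfs_event"), OS = c("os_months", "os_event"))
  rows <- list()
  for (col in measure_cols) {
    for (on in names(outs)) {
      km <- tryCatch(km_median(m[[col]], m[[outs[[on]][1]]], m[[outs[[on]][2]]]),
                     error = function(e) e)
      rows[[length(rows) + 1L]] <-
        if (inherits(km, "error"))
          data.frame(measure = col, outcome = on, cutoff = NA_real_,
                     n_low = NA_integer_, n_high = NA_integer_,
                     logrank_p = NA_real_, note = conditionMessage(km),
                     stringsAsFactors = FALSE)
        else
          data.frame(measure = col, outcome = on, cutoff = km$cutoff,
                     n_low = as.integer(km$n[["low"]]), n_high = as.integer(km$n[["high"]]),
                     logrank_p = km$logrank_p, note = "", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Export Kaplan-Meier curves as a step-function table
#'
#' @param km A `km_fit`.
#' @return data.frame with group, time, n_risk, n_event, surv.
#' @export
km_curve_table <- function(km) {
  s <- summary(km$fit, censored = TRUE)
  data.frame(group = sub("^groups=", "", as.character(s$strata)),
             time = s$time, n_risk = s$n.risk, n_event = s$n.event,
             surv = s$surv, stringsAsFactors = FALSE)
}
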