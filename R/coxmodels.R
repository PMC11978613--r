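# Comparison analyses: baseline Cox models (continuous and tertile),
# the extended Cox model with counting-process time-updated covariates,
# reverse Kaplan-Meier follow-up, and the nested case-control design
# with conditional logistic regression.  Model fitting is delegated to
# the survival package; the Efron partial likelihood is also
# implemented directly for verification against explicit risk-set
# enumeration.

#' Tertile cut points over the entire sample
#'
#' Cut points at the 1/3 and 2/3 sample quantiles (linear-interpolation
#' quantile definition, \code{type = 7}).  Tertiles are determined on
#' the whole analysis sample, never within subgroups.
#'
#' @param values numeric vector (raw-scale areas).
#' @param provenance label recording which sample defined the cuts.
#' @return a \code{"tertile_scheme"} with fields \code{cut1},
#'   \code{cut2}.
#' @export
tertile_cut <- function(values, provenance = "entire sample") {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3L)
    stop("tertiles need at least 3 distinct values", call. = FALSE)
  q <- quantile(values, c(1, 2) / 3, type = 7, names = FALSE)
  if (q[1] >= q[2])
    stop("degenerate tertile cuts (cut1 >= cut2)", call. = FALSE)
  structure(list(cut1 = q[1], cut2 = q[2], provenance = provenance),
            class = "tertile_scheme")
}

#' Assign tertile groups
#'
#' Left-closed assignment: T1 = [min, cut1), T2 = [cut1, cut2),
#' T3 = [cut2, max].
#'
#' @param scheme a \code{\link{tertile_cut}} scheme.
#' @param values numeric vector.
#' @return factor with levels T1, T2, T3.
#' @export
assign_tertiles <- function(scheme, values) {
  stopifnot(inherits(scheme, "tertile_scheme"))
  g <- ifelse(values < scheme$cut1, "T1",
              ifelse(values < scheme$cut2, "T2", "T3"))
  factor(g, levels = c("T1", "T2", "T3"))
}

#' Baseline (first-visit) marker values per subject
#'
#' Augments the subject table with the raw and square-root transformed
#' marker values from each woman's first mammogram.
#'
#' @param cohort list with \code{subjects} and \code{visits}.
#' @return the subject table with columns \code{nd_area}, \code{d_area},
#'   \code{sqrt_nd}, \code{sqrt_d} appended.
#' @export
baseline_table <- function(cohort) {
  visits <- cohort$visits[order(match(cohort$visits$id, cohort$subjects$id),
                                cohort$visits$age), , drop = FALSE]
  first <- visits[!duplicated(visits$id), , drop = FALSE]
  idx <- match(cohort$subjects$id, first$id)
  out <- cohort$subjects
  out$nd_area <- first$nd_area[idx]
  out$d_area <- first$d_area[idx]
  out$sqrt_nd <- sqrt(out$nd_area)
  out$sqrt_d <- sqrt(out$d_area)
  out
}

#' Counting-process expansion of the visit history
#'
#' One row per inter-visit interval: covariates measured at a visit are
#' carried forward unchanged until the next visit (last value carried
#' forward); the final row ends at the exit age and carries the event
#' indicator.  Zero-length intervals (a visit on the exit day) are
#' merged into the preceding interval.
#'
#' @param cohort list with \code{subjects} and \code{visits}.
#' @return data.frame with columns \code{id}, \code{age_start},
#'   \code{age_stop}, \code{event}, \code{sqrt_nd}, \code{sqrt_d} and
#'   the baseline covariates.
#' @export
expand_counting_process <- function(cohort) {
  subjects <- cohort$subjects
  visits <- cohort$visits[order(match(cohort$visits$id, subjects$id),
                                cohort$visits$age), , drop = FALSE]
  idx <- match(visits$id, subjects$id)
  if (anyNA(idx)) stop("visits reference unknown ids", call. = FALSE)
  exit <- subjects$exit_age[idx]
  late <- visits$age > exit + 1e-9
  if (any(late))
    stop("visit after exit_age in visit row(s) ",
         paste(head(which(late)), collapse = ", "), call. = FALSE)
  last_of_subj <- !duplicated(idx, fromLast = TRUE)
  age_stop <- c(visits$age[-1L], NA)
  age_stop[last_of_subj] <- exit[last_of_subj]
  rows <- data.frame(id = visits$id,
                     age_start = visits$age,
                     age_stop = age_stop,
                     event = ifelse(last_of_subj, subjects$event[idx], 0L),
                     sqrt_nd = sqrt(visits$nd_area),
                     sqrt_d = sqrt(visits$d_area),
                     stringsAsFactors = FALSE)
  keep_cols <- c("bmi", "hrt", "fh")
  for (cc in keep_cols) rows[[cc]] <- subjects[[cc]][idx]
  drop_zero <- rows$age_stop - rows$age_start <= 1e-12
  if (any(drop_zero)) {
    # re-attach the event flag to the last surviving row of the subject
    ev_ids <- rows$id[drop_zero & rows$event == 1L]
    rows <- rows[!drop_zero, , drop = FALSE]
    for (sid in ev_ids) {
      jj <- which(rows$id == sid)
      if (length(jj)) rows$event[max(jj)] <- 1L
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Cox partial log-likelihood with delayed entry (Efron ties)
#'
#' Direct evaluation of the partial log-likelihood on counting-process
#' rows \code{(age_start, age_stop]}; baseline-only models are the
#' special case of one interval per subject.  A subject is in the risk
#' set at an event age t when \code{age_start < t <= age_stop}.
#'
#' @param rows data.frame with \code{age_start}, \code{age_stop},
#'   \code{event} and the covariate columns named in \code{beta}.
#' @param beta named coefficient vector.
#' @return scalar partial log-likelihood.
#' @export
cox_partial_loglik <- function(rows, beta) {
  X <- as.matrix(rows[, names(beta), drop = FALSE])
  lp <- drop(X %*% beta)
  elp <- exp(lp)
  etimes <- sort(unique(rows$age_stop[rows$event == 1]))
  ll <- 0
  for (t in etimes) {
    at_risk <- rows$age_start < t & rows$age_stop >= t
    if (!any(at_risk))
      stop("empty risk set at event age ", format(t), call. = FALSE)
    dead <- at_risk & rows$age_stop == t & rows$event == 1
    d <- sum(dead)
    S_R <- sum(elp[at_risk]); S_D <- sum(elp[dead])
    ll <- ll + sum(lp[dead]) -
      sum(log(S_R - (seq_len(d) - 1L) / d * S_D))
  }
  ll
}

cox_covariate_frame <- function(tab) {
  data.frame(bmi = tab$bmi,
             hrt = factor(as.character(tab$hrt), levels = .hrt_levels),
             fh = factor(as.character(tab$fh), levels = .fh_levels))
}

#' Fit the comparison Cox models
#'
#' Three modes on the age scale with delayed entry at the entry age,
#' Efron tie handling throughout:
#' \describe{
#'   \item{baseline_continuous}{first-visit square-root areas entered
#'     linearly, adjusted for baseline BMI, HRT status and family
#'     history (model 1);}
#'   \item{baseline_tertile}{first-visit raw areas categorized by
#'     full-sample tertiles (model 2), with a joint 2-df Wald test for
#'     the nondense tertile terms and, optionally, the 9-cell joint
#'     tertile grid;}
#'   \item{extended}{counting-process expansion with time-updated
#'     square-root areas carried forward between visits (model 3).}
#' }
#'
#' @param cohort list with \code{subjects} and \code{visits}.
#' @param mode one of \code{"baseline_continuous"},
#'   \code{"baseline_tertile"}, \code{"extended"}.
#' @param tertiles optional list with elements \code{nd} and \code{d}
#'   (\code{\link{tertile_cut}} schemes); when NULL they are computed
#'   from the supplied cohort's baseline values.
#' @param joint_grid also fit the 9-cell nondense-by-dense tertile
#'   classification (tertile mode only).
#' @return object of class \code{"cox_fit"}: coefficient estimates,
#'   covariance, hazard-ratio rows, log-likelihood and convergence
#'   flag; tertile fits also carry the cut schemes and the joint Wald
#'   test.
#' @export
fit_cox <- function(cohort, mode = c("baseline_continuous",
                                     "baseline_tertile", "extended"),
                    tertiles = NULL, joint_grid = FALSE) {
  mode <- match.arg(mode)
  base <- baseline_table(cohort)

  if (mode == "extended") {
    rows <- expand_counting_process(cohort)
    df <- cbind(rows[, c("age_start", "age_stop", "event",
                         "sqrt_nd", "sqrt_d")],
                cox_covariate_frame(rows))
    fml <- Surv(age_start, age_stop, event) ~ sqrt_nd + sqrt_d + bmi +
      hrt + fh
  } else {
    df <- cbind(data.frame(age_start = base$entry_age,
                           age_stop = base$exit_age,
                           event = base$event,
                           sqrt_nd = base$sqrt_nd,
                           sqrt_d = base$sqrt_d),
                cox_covariate_frame(base))
    if (mode == "baseline_tertile") {
      if (is.null(tertiles))
        tertiles <- list(nd = tertile_cut(base$nd_area),
                         d = tertile_cut(base$d_area))
      df$nd_t <- assign_tertiles(tertiles$nd, base$nd_area)
      df$d_t <- assign_tertiles(tertiles$d, base$d_area)
      fml <- Surv(age_start, age_stop, event) ~ nd_t + d_t + bmi + hrt + fh
    } else {
      fml <- Surv(age_start, age_stop, event) ~ sqrt_nd + sqrt_d + bmi +
        hrt + fh
    }
  }

  fit <- coxph(fml, data = df, ties = "efron")
  est <- coef(fit)
  vc <- vcov(fit)
  flagged <- any(is.na(est)) || any(!is.finite(diag(vc)))
  se <- sqrt(diag(vc))[names(est)]
  hr_rows <- data.frame(term = names(est), estimate = unname(est),
                        HR = exp(unname(est)),
                        ci_low = exp(unname(est - 1.96 * se)),
                        ci_high = exp(unname(est + 1.96 * se)),
                        p = unname(2 * pnorm(-abs(est / se))),
                        stringsAsFactors = FALSE)
  out <- list(estimates = est, vcov = vc, hr_rows = hr_rows,
              loglik = fit$loglik[length(fit$loglik)],
              converged = !flagged, mode = mode,
              n = nrow(cohort$subjects), n_events = sum(df$event),
              coxph = fit)
  if (mode == "baseline_tertile") {
    out$tertiles <- tertiles
    nd_terms <- grep("^nd_t", names(est), value = TRUE)
    out$wald_nd <- wald_test(list(estimates = est, vcov = vc), nd_terms)
    if (joint_grid) {
      df$cell <- interaction(df$nd_t, df$d_t, sep = ":")
      grid_fit <- coxph(Surv(age_start, age_stop, event) ~ cell + bmi +
                          hrt + fh, data = df, ties = "efron")
      out$joint_grid <- summary(grid_fit)$conf.int
    }
  }
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox model (", x$mode, "), n = ", x$n, ", events = ", x$n_events,
      "\n", sep = "")
  print(x$hr_rows, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Kaplan-Meier estimate of the follow-up distribution with the roles of
#' event and censoring reversed, on the follow-up-duration scale; the
#' median is the first time the curve drops to 0.5 or below, with a
#' log-log Greenwood 95\% confidence interval.
#'
#' @param subjects subject table with \code{entry_age}, \code{exit_age},
#'   \code{event}.
#' @return list with \code{median}, \code{ci_low}, \code{ci_high}
#'   (NA when the median is not reached).
#' @export
reverse_km_median_followup <- function(subjects) {
  time <- subjects$exit_age - subjects$entry_age
  cens <- 1 - subjects$event
  if (!any(cens == 1))
    stop("reverse Kaplan-Meier needs at least one censored subject",
         call. = FALSE)
  sf <- survfit(Surv(time, cens) ~ 1, conf.type = "log-log")
  qq <- quantile(sf, probs = 0.5)
  list(median = unname(qq$quantile), ci_low = unname(qq$lower),
       ci_high = unname(qq$upper))
}

#' Nested case-control sample by incidence-density sampling
#'
#' For each case, controls are drawn without replacement from the
#' subjects at risk at the case's event age (entered before, not yet
#' exited), matched on entry age within a band.  Risk sets smaller than
#' \code{m_controls} are kept with fewer controls and reported via a
#' message.
#'
#' @param cohort list with \code{subjects} and \code{visits}.
#' @param m_controls controls per case; \code{Inf} takes the entire
#'   risk set.
#' @param match_entry_width half-width (years) of the entry-age
#'   matching band; \code{Inf} disables matching.
#' @return data.frame of matched sets: \code{set}, \code{case},
#'   baseline covariates and first-visit marker values.
#' @export
nested_case_control <- function(cohort, m_controls = 2L,
                                match_entry_width = 2.5) {
  base <- baseline_table(cohort)
  cases <- which(base$event == 1)
  if (!length(cases)) stop("no cases in the cohort", call. = FALSE)
  sets <- vector("list", length(cases))
  short_sets <- 0L
  for (s in seq_along(cases)) {
    i <- cases[s]
    t_i <- base$exit_age[i]
    at_risk <- base$entry_age < t_i & base$exit_age >= t_i &
      seq_len(nrow(base)) != i
    if (is.finite(match_entry_width))
      at_risk <- at_risk &
        abs(base$entry_age - base$entry_age[i]) <= match_entry_width
    pool <- which(at_risk)
    m <- if (is.infinite(m_controls)) length(pool)
         else min(m_controls, length(pool))
    if (m < m_controls && is.finite(m_controls)) short_sets <- short_sets + 1L
    ctrl <- if (m > 0) sample(pool, m) else integer(0)
    rows <- base[c(i, ctrl), , drop = FALSE]
    rows$case <- c(1L, rep(0L, length(ctrl)))
    rows$set <- s
    sets[[s]] <- rows
  }
  if (short_sets > 0L)
    message(short_sets, " matched set(s) kept with fewer than ",
            m_controls, " controls")
  out <- do.call(rbind, sets)
  rownames(out) <- NULL
  out
}

#' Conditional logistic regression on matched sets
#'
#' Exact set-conditional likelihood via \code{survival::clogit}.
#'
#' @param ncc output of \code{\link{nested_case_control}}.
#' @param terms covariate columns to include (default: square-root
#'   areas plus baseline adjustment covariates).
#' @return object of class \code{"cox_fit"} (shared result layout).
#' @export
conditional_logistic_fit <- function(ncc,
                                     terms = c("sqrt_nd", "sqrt_d", "bmi",
                                               "hrt", "fh")) {
  df <- cbind(ncc[, c("set", "case", "sqrt_nd", "sqrt_d")],
              cox_covariate_frame(ncc))
  # drop factor covariates without variation inside the sample
  keep <- vapply(terms, function(tt)
    length(unique(df[[tt]])) > 1L, TRUE)
  terms <- terms[keep]
  fml <- stats::as.formula(paste("case ~",
                                 paste(terms, collapse = " + "),
                                 "+ strata(set)"))
  fit <- clogit(fml, data = df)
  est <- coef(fit)
  vc <- vcov(fit)
  se <- sqrt(diag(vc))[names(est)]
  hr_rows <- data.frame(term = names(est), estimate = unname(est),
                        HR = exp(unname(est)),
                        ci_low = exp(unname(est - 1.96 * se)),
                        ci_high = exp(unname(est + 1.96 * se)),
                        p = unname(2 * pnorm(-abs(est / se))),
                        stringsAsFactors = FALSE)
  structure(list(estimates = est, vcov = vc, hr_rows = hr_rows,
                 loglik = fit$loglik[length(fit$loglik)],
                 converged = !any(is.na(est)), mode = "ncc",
                 n = nrow(ncc), n_events = sum(ncc$case),
                 coxph = fit),
            class = "cox_fit")
}
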