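# Synthetic screening-cohort generator.
#
# Emulates the structure of a mammography screening cohort: entry at
# screening ages 40-74, repeated mammograms roughly every two years (at
# most 8), administrative censoring after a fixed follow-up window, and
# two mammographic markers (plus BMI) generated from the joint model
# itself so that every estimator in the package can be validated by
# parameter recovery.

#' Configuration of the synthetic cohort generator
#'
#' All defaults form the package's fixed calibration: screening entry
#' between ages 40 and 74 with median entry age about 54, log-normal
#' inter-visit gaps with median 1.97 years, at most 8 visits, 7.9 years
#' of administrative follow-up, covariate frequencies matching a large
#' Swedish screening cohort (about 56\% postmenopausal, 12.6\% with a
#' family history, explicit "missing" categories), and marker
#' trajectories generated from \code{\link{default_true_params}}.
#'
#' @param n_subjects number of women to generate.
#' @param seed integer seed; generation is deterministic given the
#'   configuration and seed.
#' @param entry_age_dist mixture-of-truncated-normals specification
#'   (fields \code{w}, \code{mean}, \code{sd}, \code{range}).
#' @param gap_dist log-normal gap specification (fields \code{meanlog},
#'   \code{sdlog}).
#' @param max_visits maximum number of mammograms per woman.
#' @param admin_censor_years administrative censoring: maximum follow-up
#'   duration in years after entry.
#' @param covariate_rules marginal frequencies and dependencies for the
#'   categorical covariates; see \code{default_covariate_rules}.
#' @param bmi_visit_prob probability that BMI is recorded at a
#'   post-baseline visit (baseline BMI is always recorded); emulates the
#'   limited BMI follow-up of the emulated cohort.
#' @param true_params generating \code{\link{joint_params}}.
#' @return object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_subjects = 20000L,
                             seed = 1L,
                             entry_age_dist = list(w = c(0.43, 0.57),
                                                   mean = c(44.5, 61),
                                                   sd = c(3, 6),
                                                   range = c(40, 74)),
                             gap_dist = list(meanlog = log(1.997),
                                             sdlog = 0.2005),
                             max_visits = 8L,
                             admin_censor_years = 7.9,
                             covariate_rules = default_covariate_rules(),
                             bmi_visit_prob = 0.3,
                             true_params = default_true_params("joint2")) {
  if (n_subjects < 1L) stop("`n_subjects` must be at least 1", call. = FALSE)
  if (max_visits < 1L) stop("`max_visits` must be at least 1", call. = FALSE)
  if (admin_censor_years < 0) stop("`admin_censor_years` must be >= 0",
                                   call. = FALSE)
  check_dist <- function(d, fields, name) {
    if (!is.list(d) || !all(fields %in% names(d)))
      stop("invalid distribution spec for `", name, "`: needs fields ",
           paste(fields, collapse = ", "), call. = FALSE)
    if (!all(vapply(d[fields], function(z) all(is.finite(z)), TRUE)))
      stop("invalid distribution spec for `", name,
           "`: non-finite values", call. = FALSE)
  }
  check_dist(entry_age_dist, c("w", "mean", "sd", "range"), "entry_age_dist")
  if (abs(sum(entry_age_dist$w) - 1) > 1e-8 || any(entry_age_dist$w < 0))
    stop("invalid distribution spec for `entry_age_dist`: weights must be ",
         "a probability vector", call. = FALSE)
  if (entry_age_dist$range[1] < 40 - 1e-9 || entry_age_dist$range[2] > 74 + 1e-9)
    stop("invalid distribution spec for `entry_age_dist`: support must lie ",
         "within [40, 74]", call. = FALSE)
  check_dist(gap_dist, c("meanlog", "sdlog"), "gap_dist")
  if (gap_dist$sdlog < 0)
    stop("invalid distribution spec for `gap_dist`: sdlog < 0", call. = FALSE)
  validate_covariate_rules(covariate_rules)
  if (!inherits(true_params, "joint_params"))
    stop("`true_params` must be a joint_params object", call. = FALSE)
  if (bmi_visit_prob < 0 || bmi_visit_prob > 1)
    stop("`bmi_visit_prob` must be a probability", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 entry_age_dist = entry_age_dist, gap_dist = gap_dist,
                 max_visits = as.integer(max_visits),
                 admin_censor_years = admin_censor_years,
                 covariate_rules = covariate_rules,
                 bmi_visit_prob = bmi_visit_prob,
                 true_params = true_params),
            class = "synthetic_config")
}

#' Default covariate frequency rules
#'
#' Marginal frequencies for family history, parity and (conditional on
#' menopausal status) HRT use, with "missing" as an explicit category;
#' menopausal status is derived by comparing the entry age with a
#' normally distributed age at menopause.
#'
#' @return a named list of frequency tables and rule constants.
#' @export
default_covariate_rules <- function() {
  list(
    fh = c(no = 0.840, yes = 0.126, missing = 0.034),
    hrt_post = c(never = 0.612, previous = 0.232, current = 0.054,
                 missing = 0.102),
    hrt_pre = c(never = 0.940, previous = 0.019, current = 0.007,
                missing = 0.034),
    parity = c("0" = 0.124, "1" = 0.144, "2" = 0.473, "3plus" = 0.245,
               missing = 0.014),
    menopause_age = c(mean = 51, sd = 3),
    peri_window = 1.3
  )
}

validate_covariate_rules <- function(rules) {
  for (f in c("fh", "hrt_post", "hrt_pre", "parity")) {
    p <- rules[[f]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("invalid distribution spec for covariate rule `", f, "`",
           call. = FALSE)
  }
  if (is.null(rules$menopause_age) || rules$menopause_age[["sd"]] < 0)
    stop("invalid distribution spec for covariate rule `menopause_age`",
         call. = FALSE)
  invisible(TRUE)
}

# truncated-normal sampler via the inverse-cdf map (exact, vectorized)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

sample_entry_ages <- function(n, dist) {
  comp <- sample.int(length(dist$w), n, replace = TRUE, prob = dist$w)
  rtruncnorm(n, dist$mean[comp], dist$sd[comp],
             dist$range[1], dist$range[2])
}

sample_categorical <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

#' Sample baseline covariates and entry ages
#'
#' Draws entry ages from the configured mixture, derives menopausal
#' status from a latent age at menopause, draws HRT conditionally on
#' menopausal status, family history and parity from their marginal
#' frequencies, and generates baseline BMI from the BMI marker submodel
#' evaluated at the entry age (its random intercept is retained so that
#' the longitudinal BMI trajectory stays consistent with the baseline
#' value).  Uses R's global random number generator.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param n number of subjects (defaults to \code{config$n_subjects}).
#' @return data.frame with one row per subject: \code{id},
#'   \code{entry_age}, \code{bmi}, \code{hrt}, \code{fh},
#'   \code{menopause}, \code{parity}, plus internal columns
#'   \code{.b_bmi} and \code{.bmi_eps1} used by the marker sampler.
#' @export
sample_covariates <- function(config, n = config$n_subjects) {
  rules <- config$covariate_rules
  entry <- sample_entry_ages(n, config$entry_age_dist)
  m_age <- rnorm(n, rules$menopause_age[["mean"]], rules$menopause_age[["sd"]])
  status <- ifelse(entry >= m_age, "post",
                   ifelse(entry > m_age - rules$peri_window, "peri", "pre"))
  status <- factor(status, levels = .menopause_levels)

  hrt <- character(n)
  is_post <- status == "post"
  hrt[is_post] <- as.character(sample_categorical(sum(is_post),
                                                  rules$hrt_post))
  hrt[!is_post] <- as.character(sample_categorical(sum(!is_post),
                                                   rules$hrt_pre))
  hrt <- factor(hrt, levels = .hrt_levels)
  fh <- sample_categorical(n, rules$fh)
  fh <- factor(as.character(fh), levels = .fh_levels)
  parity <- sample_categorical(n, rules$parity)
  parity <- factor(as.character(parity), levels = .parity_levels)

  # baseline BMI = the BMI marker at the entry-age visit
  tp <- config$true_params
  sd_b <- sqrt(tp$Sigma_b["bmi", "bmi"])
  sd_e <- sqrt(tp$Sigma_eps["bmi", "bmi"])
  b_bmi <- rnorm(n, 0, sd_b)
  eps1 <- rnorm(n, 0, sd_e)
  Xb <- cbind(1, eval_basis(tp$marker_basis, entry))
  mu_b <- drop(Xb %*% tp$beta$bmi[seq_len(tp$marker_basis$df + 1L)])
  bmi <- pmin(pmax(mu_b + b_bmi + eps1, 12.05), 69.95)

  data.frame(id = sprintf("S%06d", seq_len(n)),
             entry_age = entry, bmi = bmi, hrt = hrt, fh = fh,
             menopause = status, parity = parity,
             .b_bmi = b_bmi, .bmi_eps1 = eps1,
             stringsAsFactors = FALSE)
}

#' Sample a visit (mammogram) schedule
#'
#' The first visit is at the entry age; successive gaps are drawn from
#' the configured log-normal until the next visit would fall beyond the
#' administrative window, beyond screening age 74, or the visit cap is
#' reached.
#'
#' @param entry_age numeric vector of entry ages.
#' @param config a \code{\link{synthetic_config}}.
#' @return a list of numeric vectors of visit ages, one per entry age.
#' @export
sample_visit_schedule <- function(entry_age, config) {
  sched <- visit_schedule_long(entry_age, config)
  split(sched$age, sched$subject)[as.character(seq_along(entry_age))]
}

# long-format schedule: one row per visit with the subject index
visit_schedule_long <- function(entry_age, config) {
  n <- length(entry_age)
  mv <- config$max_visits
  if (mv == 1L || config$admin_censor_years <= 0) {
    return(data.frame(subject = seq_len(n), age = entry_age))
  }
  gaps <- matrix(rlnorm(n * (mv - 1L), config$gap_dist$meanlog,
                        config$gap_dist$sdlog), n, mv - 1L)
  cum_gaps <- gaps
  if (ncol(gaps) > 1L)
    for (j in 2L:ncol(gaps)) cum_gaps[, j] <- cum_gaps[, j - 1L] + gaps[, j]
  ages <- cbind(entry_age, entry_age + cum_gaps)
  limit <- pmin(entry_age + config$admin_censor_years, 74)
  keep <- ages <= limit  # first column always kept: entry <= limit cap
  keep[, 1L] <- TRUE
  # a visit is kept only if all earlier visits are kept (monotone ages)
  keep <- t(apply(keep, 1L, cumall))
  data.frame(subject = rep(seq_len(n), times = rowSums(keep)),
             age = t(ages)[t(keep)])
}

cumall <- function(x) cumprod(as.logical(x)) > 0

#' Sample marker trajectories at the scheduled visits
#'
#' Draws the random intercepts (conditionally on the BMI intercept fixed
#' at covariate-sampling time) and generates noisy marker observations:
#' on the square-root scale for the areas (stored raw areas are the
#' squares, floored at zero) and on the raw scale for BMI.  Residuals
#' are correlated within a visit and independent across visits.
#'
#' @param subjects output of \code{\link{sample_covariates}}.
#' @param schedule long-format schedule from the internal scheduler
#'   (columns \code{subject}, \code{age}).
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{visits} (data.frame \code{id}, \code{age},
#'   \code{nd_area}, \code{d_area}, \code{bmi}) and \code{b} (n x 3
#'   matrix of random intercepts).
#' @export
sample_marker_paths <- function(subjects, schedule, config) {
  tp <- config$true_params
  if (!is_pd(tp$Sigma_b) || !is_pd(tp$Sigma_eps))
    stop("Sigma_b and Sigma_eps must be positive definite", call. = FALSE)
  n <- nrow(subjects)
  markers <- names(tp$beta)

  # (b_nd, b_d) | b_bmi from the joint normal
  S <- tp$Sigma_b
  i12 <- c("nd", "d")
  cond_gain <- S[i12, "bmi"] / S["bmi", "bmi"]
  cond_cov <- S[i12, i12] - tcrossprod(S[i12, "bmi"]) / S["bmi", "bmi"]
  Lc <- t(chol(cond_cov))
  z <- matrix(rnorm(2 * n), 2L, n)
  b12 <- t(outer(cond_gain, subjects$.b_bmi) + Lc %*% z)
  b <- cbind(nd = b12[, 1L], d = b12[, 2L], bmi = subjects$.b_bmi)

  idx <- schedule$subject
  m <- nrow(schedule)
  Xage <- cbind(1, eval_basis(tp$marker_basis, schedule$age))
  p_age <- tp$marker_basis$df + 1L
  Le <- t(chol(tp$Sigma_eps))
  eps <- t(Le %*% matrix(rnorm(3L * m), 3L, m))
  colnames(eps) <- markers

  ylat <- matrix(NA_real_, m, 3L, dimnames = list(NULL, markers))
  for (k in markers) {
    bk <- tp$beta[[k]]
    mu <- drop(Xage %*% bk[seq_len(p_age)])
    if (length(bk) > p_age) {
      Z <- covariate_design(subjects[idx, , drop = FALSE],
                            tp$specs[[k]]$covariates)
      mu <- mu + drop(Z %*% bk[(p_age + 1L):length(bk)])
    }
    ylat[, k] <- mu + b[idx, k] + eps[, k]
  }

  first <- !duplicated(idx)
  # the recorded baseline BMI is the first-visit BMI observation
  ylat[first, "bmi"] <- subjects$bmi[idx[first]]

  bmi_obs <- ylat[, "bmi"]
  later <- !first
  hide <- later & (runif(m) > config$bmi_visit_prob)
  bmi_obs[hide] <- NA_real_
  bmi_obs <- ifelse(is.na(bmi_obs), NA_real_,
                    pmin(pmax(bmi_obs, 12.05), 69.95))

  visits <- data.frame(id = subjects$id[idx], age = schedule$age,
                       nd_area = pmax(ylat[, "nd"], 0)^2,
                       d_area = pmax(ylat[, "d"], 0)^2,
                       bmi = bmi_obs, stringsAsFactors = FALSE)
  list(visits = visits, b = b)
}

# Constant (per-subject) and age-profile parts of the log hazard under
# the generating truth:
#   log lambda_i(u) = h(u) + c_i + alpha' b_i
# with h(u) the baseline spline plus the association-weighted marker age
# profiles and c_i the covariate contributions.
hazard_profile_parts <- function(subjects, config) {
  tp <- config$true_params
  p_age <- tp$marker_basis$df + 1L
  comb_age <- rep(0, p_age)
  c_i <- rep(0, nrow(subjects))
  for (k in names(tp$beta)) {
    a_k <- tp$alpha[[k]]
    if (a_k == 0) next
    bk <- tp$beta[[k]]
    comb_age <- comb_age + a_k * bk[seq_len(p_age)]
    if (length(bk) > p_age) {
      Z <- covariate_design(subjects, tp$specs[[k]]$covariates)
      c_i <- c_i + a_k * drop(Z %*% bk[(p_age + 1L):length(bk)])
    }
  }
  W <- covariate_design(subjects, c(if ("bmi_baseline" %in% names(tp$gamma))
                                      "bmi_baseline", "hrt", "fh"))
  W <- W[, names(tp$gamma), drop = FALSE]
  c_i <- c_i + drop(W %*% tp$gamma)
  list(comb_age = comb_age, c_i = c_i)
}

eval_log_hazard_profile <- function(ages, config, comb_age) {
  tp <- config$true_params
  s0 <- cbind(1, eval_basis(tp$hazard_basis, ages))
  m <- cbind(1, eval_basis(tp$marker_basis, ages))
  drop(s0 %*% tp$omega) + drop(m %*% comb_age)
}

#' Sample event times from the generating hazard
#'
#' Event ages solve \eqn{\Lambda_i(entry \to T) = -\log U} with
#' \eqn{U \sim Uniform(0,1)}, where the cumulative hazard integrates the
#' generating joint-model hazard by Gauss-Legendre quadrature; inversion
#' is by bisection.  Follow-up is administratively censored
#' \code{admin_censor_years} after entry.
#'
#' @param subjects covariate table (with \code{entry_age}).
#' @param b matrix of random intercepts (columns nd, d, bmi).
#' @param config a \code{\link{synthetic_config}}.
#' @param gl_nodes Gauss-Legendre node count per cumulative-hazard
#'   evaluation.
#' @param bisect_tol bisection tolerance on the event age.
#' @return data.frame with \code{exit_age} and \code{event}.
#' @export
sample_event_time <- function(subjects, b, config, gl_nodes = 30L,
                              bisect_tol = 1e-10) {
  n <- nrow(subjects)
  parts <- hazard_profile_parts(subjects, config)
  loglin <- parts$c_i + drop(b %*% config$true_params$alpha)
  if (any(!is.finite(loglin)))
    stop("non-finite hazard linear predictor", call. = FALSE)
  entry <- subjects$entry_age
  target <- -log(runif(n))

  gl <- gl_rule01(gl_nodes)
  horizon <- min(config$admin_censor_years, 200)
  cum_profile <- function(a0, a1) {
    # integral of exp(h(u)) over [a0, a1], vectorized over subjects
    len <- a1 - a0
    u <- outer(len, gl$x) + a0
    hv <- eval_log_hazard_profile(as.vector(u), config, parts$comb_age)
    if (any(!is.finite(hv)))
      stop("non-finite hazard on the integration grid", call. = FALSE)
    H <- matrix(exp(hv), nrow = length(a0))
    len * drop(H %*% gl$w)
  }

  cum_full <- exp(loglin) * cum_profile(entry, entry + horizon)
  is_event <- cum_full >= target
  exit <- entry + config$admin_censor_years

  if (any(is_event)) {
    ii <- which(is_event)
    lo <- entry[ii]; hi <- entry[ii] + horizon
    e_i <- entry[ii]; t_i <- target[ii] / exp(loglin[ii])
    for (it in seq_len(80L)) {
      mid <- (lo + hi) / 2
      val <- cum_profile(e_i, mid)
      high <- val >= t_i
      hi[high] <- mid[high]
      lo[!high] <- mid[!high]
      if (max(hi - lo) < bisect_tol) break
    }
    exit[ii] <- (lo + hi) / 2
  }
  data.frame(exit_age = exit, event = as.integer(is_event))
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative pipeline (covariates, visit schedules,
#' marker trajectories, event times; visits after exit are dropped) and
#' returns the two analysis tables together with a truth record for
#' parameter-recovery experiments.  Deterministic given the
#' configuration and its seed.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return object of class \code{"mdjm_cohort"}: list with
#'   \code{subjects}, \code{visits} and \code{truth} (the generating
#'   parameters, per-subject random intercepts and the seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  subjects <- sample_covariates(config)
  schedule <- visit_schedule_long(subjects$entry_age, config)
  paths <- sample_marker_paths(subjects, schedule, config)
  surv <- sample_event_time(subjects, paths$b, config)

  subjects$exit_age <- surv$exit_age
  subjects$event <- surv$event
  keep_visit <- paths$visits$age <= surv$exit_age[schedule$subject]
  visits <- paths$visits[keep_visit, , drop = FALSE]
  rownames(visits) <- NULL

  out_subjects <- subjects[, c("id", "entry_age", "exit_age", "event",
                               "bmi", "hrt", "fh", "menopause", "parity")]
  truth <- list(true_params = config$true_params,
                b = paths$b, seed = config$seed)
  structure(list(subjects = out_subjects, visits = visits, truth = truth),
            class = "mdjm_cohort")
}

#' @export
print.mdjm_cohort <- function(x, ...) {
  cat("Synthetic screening cohort:", nrow(x$subjects), "women,",
      nrow(x$visits), "mammograms,", sum(x$subjects$event), "events\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes \code{subjects.csv}, \code{visits.csv} and (when a truth
#' record is present) \code{truth.json} into \code{dir}.
#'
#' @param cohort an \code{"mdjm_cohort"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             visits = file.path(dir, "visits.csv"))
  ok <- try({
    write.csv(cohort$subjects, paths[["subjects"]], row.names = FALSE)
    write.csv(cohort$visits, paths[["visits"]], row.names = FALSE)
  }, silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write cohort tables under `", dir, "`: ",
         attr(ok, "condition")$message, call. = FALSE)
  if (!is.null(cohort$truth)) {
    tp <- cohort$truth$true_params
    truth <- list(seed = cohort$truth$seed,
                  alpha = as.list(tp$alpha),
                  gamma = as.list(tp$gamma),
                  omega = tp$omega,
                  beta = tp$beta,
                  Sigma_b = tp$Sigma_b,
                  Sigma_eps = tp$Sigma_eps,
                  b = cohort$truth$b)
    paths[["truth"]] <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, paths[["truth"]], digits = NA,
                         auto_unbox = TRUE, matrix = "rowmajor")
  }
  invisible(paths)
}

#' Generate a cohort and write it to disk
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param dir output directory.
#' @return the cohort, invisibly.
#' @export
generate_dataset <- function(config, dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, dir)
  invisible(cohort)
}
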