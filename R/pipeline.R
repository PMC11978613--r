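# Orchestration: cohort I/O and validation, subgroup construction, the
# five-model analysis run, and the parameter-recovery harness.

#' Read and validate a cohort from CSV tables
#'
#' Joins the subject and visit tables on \code{id} and enforces the
#' cohort invariants: entry between 40 and 74, entry <= exit, strictly
#' increasing visit ages within [entry, exit] starting at the entry
#' age, non-negative areas and plausible BMI.  Violations are reported
#' with row numbers.  Per-column missingness proportions are attached
#' as the \code{"missingness"} attribute.
#'
#' @param subjects_path path to \code{subjects.csv}.
#' @param visits_path path to \code{visits.csv}.
#' @return an \code{"mdjm_cohort"} (without a truth record).
#' @export
read_cohort <- function(subjects_path, visits_path) {
  for (p in c(subjects_path, visits_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  subjects <- read.csv(subjects_path, stringsAsFactors = FALSE)
  visits <- read.csv(visits_path, stringsAsFactors = FALSE)
  need_s <- c("id", "entry_age", "exit_age", "event", "bmi", "hrt", "fh",
              "menopause", "parity")
  need_v <- c("id", "age", "nd_area", "d_area")
  if (!all(need_s %in% names(subjects)))
    stop("subjects table lacks column(s): ",
         paste(setdiff(need_s, names(subjects)), collapse = ", "),
         call. = FALSE)
  if (!all(need_v %in% names(visits)))
    stop("visits table lacks column(s): ",
         paste(setdiff(need_v, names(visits)), collapse = ", "),
         call. = FALSE)
  if (!"bmi" %in% names(visits)) visits$bmi <- NA_real_
  if (anyDuplicated(subjects$id))
    stop("duplicated subject ids", call. = FALSE)

  idx <- match(visits$id, subjects$id)
  if (anyNA(idx))
    stop("orphan visit row(s) ", paste(head(which(is.na(idx))),
                                       collapse = ", "),
         ": id not in subject table", call. = FALSE)
  bad_entry <- which(subjects$entry_age < 40 - 1e-9 |
                     subjects$entry_age > 74 + 1e-9)
  if (length(bad_entry))
    stop("entry age outside [40, 74] in subject row(s) ",
         paste(head(bad_entry), collapse = ", "), call. = FALSE)
  bad_exit <- which(subjects$exit_age < subjects$entry_age)
  if (length(bad_exit))
    stop("exit before entry in subject row(s) ",
         paste(head(bad_exit), collapse = ", "), call. = FALSE)
  if (!all(subjects$event %in% 0:1))
    stop("event must be 0/1", call. = FALSE)
  bad_area <- which(visits$nd_area < 0 | visits$d_area < 0)
  if (length(bad_area))
    stop("negative area in visit row(s) ",
         paste(head(bad_area), collapse = ", "), call. = FALSE)
  late <- which(visits$age > subjects$exit_age[idx] + 1e-9)
  if (length(late))
    stop("visit after exit_age in visit row(s) ",
         paste(head(late), collapse = ", "), call. = FALSE)
  early <- which(visits$age < subjects$entry_age[idx] - 1e-9)
  if (length(early))
    stop("visit before entry_age in visit row(s) ",
         paste(head(early), collapse = ", "), call. = FALSE)
  ord <- order(idx, visits$age)
  vo <- visits[ord, , drop = FALSE]
  io <- idx[ord]
  same <- io[-1L] == io[-length(io)]
  nonmono <- which(same & diff(vo$age) <= 0)
  if (length(nonmono))
    stop("non-increasing visit ages for subject(s) ",
         paste(head(unique(vo$id[nonmono])), collapse = ", "),
         call. = FALSE)
  has_entry <- tapply(abs(visits$age - subjects$entry_age[idx]) < 1e-6,
                      factor(visits$id, levels = subjects$id), any)
  if (!all(has_entry))
    stop("subject(s) without a visit at the entry age: ",
         paste(head(subjects$id[!has_entry]), collapse = ", "),
         call. = FALSE)
  bad_bmi <- which(!is.na(visits$bmi) &
                   (visits$bmi <= 12 | visits$bmi >= 70))
  if (length(bad_bmi))
    stop("implausible BMI in visit row(s) ",
         paste(head(bad_bmi), collapse = ", "), call. = FALSE)

  miss <- c(vapply(subjects, function(col)
    mean(is.na(col) | col == "missing"), 0),
    visits_bmi = mean(is.na(visits$bmi)))
  cohort <- structure(list(subjects = subjects, visits = visits,
                           truth = NULL),
                      class = "mdjm_cohort")
  attr(cohort, "missingness") <- miss
  cohort
}

#' Construct the analysis subgroups
#'
#' \code{postmenopausal}: women postmenopausal at the start of
#' follow-up; \code{premenopausal_under50}: premenopausal and strictly
#' under age 50 at entry; \code{full}: everyone.  Perimenopausal women
#' appear only in the full cohort.  Subgroup membership is evaluated at
#' baseline only.
#'
#' @param cohort an \code{"mdjm_cohort"}.
#' @param which subset of \code{c("full", "postmenopausal",
#'   "premenopausal_under50")}.
#' @return named list of cohorts.
#' @export
make_subgroups <- function(cohort,
                           which = c("full", "postmenopausal",
                                     "premenopausal_under50")) {
  which <- match.arg(which, several.ok = TRUE)
  pick <- function(keep) {
    ids <- cohort$subjects$id[keep]
    structure(list(subjects = cohort$subjects[keep, , drop = FALSE],
                   visits = cohort$visits[cohort$visits$id %in% ids, ,
                                          drop = FALSE],
                   truth = NULL),
              class = "mdjm_cohort")
  }
  out <- list()
  for (w in which) {
    out[[w]] <- switch(w,
      full = pick(rep(TRUE, nrow(cohort$subjects))),
      postmenopausal = pick(cohort$subjects$menopause == "post"),
      premenopausal_under50 = pick(cohort$subjects$menopause == "pre" &
                                   cohort$subjects$entry_age < 50))
  }
  out
}

#' Analysis run configuration
#'
#' @param models subset of \code{c("m1","m2","m3","m4","m5")} in the
#'   canonical order (baseline Cox, tertile Cox, extended Cox,
#'   bivariate joint, trivariate joint).
#' @param subgroups subset of \code{c("full", "postmenopausal",
#'   "premenopausal_under50")}.
#' @param joint_options options forwarded to
#'   \code{\link{fit_joint_model}}.
#' @param out_dir optional output directory for the results CSV/JSON.
#' @param seed integer seed (recorded; fitting itself is
#'   deterministic).
#' @return a list of class \code{"analysis_config"}.
#' @export
analysis_config <- function(models = c("m1", "m2", "m3", "m4", "m5"),
                            subgroups = "full",
                            joint_options = list(),
                            out_dir = NULL, seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(models = models, subgroups = subgroups,
                 joint_options = joint_options, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

model_fitters <- function(config, tertiles) {
  jo <- config$joint_options
  list(
    m1 = function(co) fit_cox(co, "baseline_continuous"),
    m2 = function(co) fit_cox(co, "baseline_tertile", tertiles = tertiles),
    m3 = function(co) fit_cox(co, "extended"),
    m4 = function(co) fit_joint_model(co, "joint2", options = jo),
    m5 = function(co) fit_joint_model(co, "joint3", options = jo)
  )
}

#' Run the five-model comparison analysis
#'
#' Executes the requested models on the requested subgroups (tertile
#' cuts always come from the full sample), assembling one table of
#' hazard-ratio rows per model, subgroup and term.  A failing model is
#' recorded as a failure row for that cell and the run continues.
#'
#' @param cohort an \code{"mdjm_cohort"}.
#' @param config an \code{\link{analysis_config}}.
#' @return object of class \code{"mdjm_results"}: \code{table}
#'   (data.frame model, subgroup, term, HR, ci_low, ci_high, p),
#'   \code{fits}, \code{metadata}.
#' @export
run_analysis <- function(cohort, config = analysis_config()) {
  set.seed(config$seed)
  groups <- make_subgroups(cohort, config$subgroups)
  base_full <- baseline_table(cohort)
  tertiles <- list(nd = tertile_cut(base_full$nd_area, "full sample"),
                   d = tertile_cut(base_full$d_area, "full sample"))
  fitters <- model_fitters(config, tertiles)

  rows <- list(); fits <- list(); meta <- list()
  for (g in names(groups)) {
    co <- groups[[g]]
    meta[[g]] <- list(n_subjects = nrow(co$subjects),
                      n_events = sum(co$subjects$event),
                      n_mammograms = nrow(co$visits),
                      median_followup =
                        tryCatch(reverse_km_median_followup(co$subjects)$median,
                                 error = function(e) NA_real_))
    message(sprintf("[%s] n=%d events=%d mammograms=%d", g,
                    meta[[g]]$n_subjects, meta[[g]]$n_events,
                    meta[[g]]$n_mammograms))
    for (m in config$models) {
      fit <- tryCatch(fitters[[m]](co), error = function(e) e)
      key <- paste(m, g, sep = ".")
      if (inherits(fit, "error")) {
        rows[[key]] <- data.frame(model = m, subgroup = g,
                                  term = "(failed)", estimate = NA_real_,
                                  HR = NA_real_, ci_low = NA_real_,
                                  ci_high = NA_real_, p = NA_real_,
                                  note = conditionMessage(fit),
                                  stringsAsFactors = FALSE)
        next
      }
      fits[[key]] <- fit
      hr <- fit$hr_rows
      hr$note <- if (isTRUE(fit$converged)) "" else "not converged"
      rows[[key]] <- cbind(data.frame(model = m, subgroup = g,
                                      stringsAsFactors = FALSE), hr)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  res <- structure(list(table = table, fits = fits,
                        metadata = list(groups = meta,
                                        models = config$models,
                                        tertiles = tertiles,
                                        seed = config$seed)),
                   class = "mdjm_results")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(table, file.path(config$out_dir, "results.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(table = table, metadata = res$metadata$groups,
                              seed = config$seed),
                         file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}

#' @export
print.mdjm_results <- function(x, ...) {
  cat("Five-model comparison analysis\n")
  tab <- x$table
  tab$p <- format_pvalue(tab$p)
  print(tab, digits = 4, row.names = FALSE)
  invisible(x)
}

# p-value rendering used in printed tables (".060", "<.001")
format_pvalue <- function(p) {
  out <- ifelse(is.na(p), "NA",
                ifelse(p < 0.001, "<.001",
                       sub("^0", "", sprintf("%.3f", p))))
  out
}

#' Parameter-recovery experiment
#'
#' Simulates replicate cohorts from a known truth, fits the requested
#' joint model to each, and summarizes recovery of the association
#' coefficients and the random-intercept and residual correlations:
#' per-parameter mean estimate, bias, empirical standard error, mean
#' model standard error and 95\% confidence-interval coverage.
#' Replicate-level fit failures are reported, not fatal.
#'
#' @param model \code{"joint2"} or \code{"joint3"}.
#' @param n_subjects cohort size per replicate.
#' @param n_replicates number of replicates.
#' @param seed integer seed; per-replicate seeds are derived from it.
#' @param true_params generating truth (default
#'   \code{default_true_params(model)}).
#' @param config_args further arguments to
#'   \code{\link{synthetic_config}}.
#' @param options fitting options (see \code{\link{fit_joint_model}});
#'   set \code{se = FALSE} to skip Hessian computation when only point
#'   estimates are needed.
#' @return object of class \code{"mdjm_recovery"}: \code{summary}
#'   data.frame and the per-replicate estimate matrix.
#' @export
recovery_experiment <- function(model = c("joint2", "joint3"),
                                n_subjects = 1000L, n_replicates = 10L,
                                seed = 1L, true_params = NULL,
                                config_args = list(), options = list()) {
  model <- match.arg(model)
  if (is.null(true_params)) true_params <- default_true_params(model)
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_replicates)

  track <- c("alpha.nd", "alpha.d",
             if (model == "joint3") "alpha.bmi",
             "corr_b.nd.d", "corr_eps.nd.d")
  truth <- c(alpha.nd = unname(true_params$alpha["nd"]),
             alpha.d = unname(true_params$alpha["d"]),
             alpha.bmi = unname(true_params$alpha["bmi"]),
             corr_b.nd.d = cov2corr_ij(true_params$Sigma_b, 1, 2),
             corr_eps.nd.d = cov2corr_ij(true_params$Sigma_eps, 1, 2))

  est <- matrix(NA_real_, n_replicates, length(track),
                dimnames = list(NULL, track))
  se <- est; cover <- est
  failures <- character(0)
  for (r in seq_len(n_replicates)) {
    cfg <- do.call(synthetic_config,
                   c(list(n_subjects = n_subjects, seed = rep_seeds[r],
                          true_params = true_params), config_args))
    cohort <- generate_cohort(cfg)
    fit <- tryCatch(fit_joint_model(cohort, model, options = options),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(fit)))
      next
    }
    if (!fit$converged)
      failures <- c(failures, sprintf("replicate %d: not converged", r))
    for (p in intersect(track, names(fit$estimates))) {
      est[r, p] <- fit$estimates[p]
      if (!is.null(fit$vcov)) {
        se[r, p] <- sqrt(fit$vcov[p, p])
        cover[r, p] <- abs(est[r, p] - truth[p]) <= 1.96 * se[r, p]
      }
    }
    est[r, "corr_b.nd.d"] <- cov2corr_ij(fit$par$Sigma_b, 1, 2)
    est[r, "corr_eps.nd.d"] <- cov2corr_ij(fit$par$Sigma_eps, 1, 2)
  }

  summary <- data.frame(
    param = track,
    truth = unname(truth[track]),
    mean_est = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - unname(truth[track]),
    emp_se = apply(est, 2L, sd, na.rm = TRUE),
    mean_model_se = colMeans(se, na.rm = TRUE),
    coverage = colMeans(cover, na.rm = TRUE),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(summary = summary, estimates = est, model_se = se,
                 failures = failures, model = model,
                 n_subjects = n_subjects, n_replicates = n_replicates,
                 seed = seed),
            class = "mdjm_recovery")
}

#' @export
print.mdjm_recovery <- function(x, ...) {
  cat("Parameter recovery (", x$model, "): ", x$n_replicates,
      " replicates of n = ", x$n_subjects, "\n", sep = "")
  print(x$summary, digits = 4, row.names = FALSE)
  if (length(x$failures))
    cat("failures:\n ", paste(x$failures, collapse = "\n  "), "\n")
  invisible(x)
}
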