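test_that("configuration validation names the offending field", {
  expect_error(synthetic_config(n_subjects = 0), "n_subjects")
  expect_error(synthetic_config(gap_dist = list(meanlog = 1)), "gap_dist")
  expect_error(synthetic_config(entry_age_dist = list(
    w = c(0.7, 0.7), mean = c(45, 60), sd = c(3, 5), range = c(40, 74))),
    "entry_age_dist")
  rules <- default_covariate_rules()
  rules$fh <- c(no = 0.5, yes = 0.2, missing = 0.1)  # does not sum to 1
  expect_error(synthetic_config(covariate_rules = rules), "fh")
})

test_that("covariate sampling matches the configured frequencies", {
  cfg <- synthetic_config(n_subjects = 20000, seed = 3)
  set.seed(cfg$seed)
  s <- sample_covariates(cfg)
  expect_true(all(s$entry_age >= 40 & s$entry_age <= 74))
  # postmenopausal fraction near the emulated cohort's 56.1%
  expect_lt(abs(mean(s$menopause == "post") - 0.561), 0.02)
  expect_lt(abs(mean(s$fh == "yes") - 0.126), 0.01)
  expect_lt(abs(mean(s$parity == "2") - 0.473), 0.015)
  # degenerate family-history rule
  rules <- default_covariate_rules()
  rules$fh <- c(no = 1, yes = 0, missing = 0)
  cfg2 <- synthetic_config(n_subjects = 500, seed = 4,
                           covariate_rules = rules)
  set.seed(4)
  expect_true(all(sample_covariates(cfg2)$fh == "no"))
})

test_that("baseline BMI matches a direct Monte-Carlo draw of its marginal", {
  cfg <- synthetic_config(n_subjects = 50000, seed = 8)
  set.seed(8)
  s <- sample_covariates(cfg)
  # direct draw: BMI marker mean at a fresh entry age + N(0, sd_b^2+sd_e^2)
  set.seed(881)
  n <- 2e5
  entry <- mdjm:::sample_entry_ages(n, cfg$entry_age_dist)
  tp <- cfg$true_params
  mu <- drop(cbind(1, eval_basis(tp$marker_basis, entry)) %*%
               tp$beta$bmi[1:6])
  direct <- mu + rnorm(n, 0, sqrt(tp$Sigma_b["bmi", "bmi"] +
                                  tp$Sigma_eps["bmi", "bmi"]))
  expect_lt(abs(median(s$bmi) - median(direct)), 0.3)
})

test_that("visit schedules respect caps and degenerate settings", {
  cfg1 <- synthetic_config(n_subjects = 5, seed = 1, max_visits = 1)
  set.seed(1)
  sch <- sample_visit_schedule(c(45, 60, 73.5), cfg1)
  expect_equal(sch, list(`1` = 45, `2` = 60, `3` = 73.5),
               ignore_attr = TRUE)
  cfg0 <- synthetic_config(n_subjects = 5, seed = 1,
                           admin_censor_years = 0)
  set.seed(1)
  expect_equal(sample_visit_schedule(50, cfg0)[[1]], 50)
  cfg <- synthetic_config(n_subjects = 5, seed = 2)
  set.seed(2)
  sch <- sample_visit_schedule(rep(50, 400), cfg)
  lens <- lengths(sch)
  expect_true(all(lens <= cfg$max_visits))
  ages <- unlist(sch)
  expect_true(all(ages <= 50 + cfg$admin_censor_years + 1e-9))
  expect_true(all(vapply(sch, function(a) !is.unsorted(a, strictly = TRUE),
                         TRUE)))
})

test_that("marker covariance at a fixed design point equals Sigma_b + Sigma_eps", {
  cfg <- synthetic_config(n_subjects = 2, seed = 1)
  n <- 2e5
  subjects <- data.frame(id = sprintf("S%06d", 1:n), entry_age = 55,
                         bmi = 24.5, hrt = "never", fh = "no",
                         menopause = "post", parity = "2",
                         .b_bmi = 0, .bmi_eps1 = 0,
                         stringsAsFactors = FALSE)
  schedule <- data.frame(subject = 1:n, age = rep(55, n))
  set.seed(99)
  paths <- sample_marker_paths(subjects, schedule, cfg)
  y <- cbind(sqrt(paths$visits$nd_area), sqrt(paths$visits$d_area))
  tp <- cfg$true_params
  target <- tp$Sigma_b[1:2, 1:2] + tp$Sigma_eps[1:2, 1:2]
  emp <- cov(y)
  expect_lt(max(abs(emp - target)), 0.08)
})

test_that("degenerate noise reproduces the fixed-effect mean exactly", {
  cfg <- synthetic_config(n_subjects = 50, seed = 5)
  tp <- cfg$true_params
  sdnames <- c("nd", "d", "bmi")
  tpz <- tp
  tpz$Sigma_b <- diag(1e-8, 3, 3); dimnames(tpz$Sigma_b) <- list(sdnames, sdnames)
  tpz$Sigma_eps <- diag(1e-8, 3, 3); dimnames(tpz$Sigma_eps) <- list(sdnames, sdnames)
  cfgz <- synthetic_config(n_subjects = 50, seed = 5, true_params = tpz)
  set.seed(5)
  s <- sample_covariates(cfgz)
  sch <- mdjm:::visit_schedule_long(s$entry_age, cfgz)
  paths <- sample_marker_paths(s, sch, cfgz)
  idx <- sch$subject
  Z <- mdjm:::covariate_design(s[idx, ], tp$specs$nd$covariates)
  mu_nd <- drop(cbind(1, eval_basis(tp$marker_basis, sch$age)) %*%
                  tpz$beta$nd[1:6]) +
    drop(Z %*% tpz$beta$nd[-(1:6)])
  expect_equal(sqrt(paths$visits$nd_area), mu_nd, tolerance = 1e-3)
})

test_that("event times reduce to the exponential in the constant-hazard limit", {
  cfg <- synthetic_config(n_subjects = 2e4, seed = 21,
                          admin_censor_years = 150)
  tp <- cfg$true_params
  lam0 <- 0.08
  tp$omega <- mdjm:::project_curve(tp$hazard_basis, function(a)
    rep(log(lam0), length(a)))
  tp$alpha[] <- 0
  tp$gamma[] <- 0
  cfgc <- synthetic_config(n_subjects = 2e4, seed = 21,
                           admin_censor_years = 150, true_params = tp)
  set.seed(21)
  s <- sample_covariates(cfgc)
  b <- matrix(0, nrow(s), 3, dimnames = list(NULL, c("nd", "d", "bmi")))
  surv <- sample_event_time(s, b, cfgc)
  expect_gt(mean(surv$event), 0.999)
  gap <- surv$exit_age - s$entry_age
  ks <- suppressWarnings(ks.test(gap, "pexp", rate = lam0))
  expect_gt(ks$p.value, 0.01)
})

test_that("hazard scale and random effects act monotonically on events", {
  cfg <- synthetic_config(n_subjects = 5000, seed = 13)
  set.seed(13)
  s <- sample_covariates(cfg)
  sch <- mdjm:::visit_schedule_long(s$entry_age, cfg)
  set.seed(14)
  paths <- sample_marker_paths(s, sch, cfg)
  set.seed(15)
  e1 <- sample_event_time(s, paths$b, cfg)
  # doubling the baseline hazard (omega intercept + log 2) on a common seed
  tp2 <- cfg$true_params
  tp2$omega[1] <- tp2$omega[1] + log(2)
  cfg2 <- synthetic_config(n_subjects = 5000, seed = 13, true_params = tp2)
  set.seed(15)
  e2 <- sample_event_time(s, paths$b, cfg2)
  expect_gt(sum(e2$event), sum(e1$event))
  # higher dense-area intercept raises the hazard pointwise (alpha_d > 0)
  p2 <- bivariate_params()
  subj <- data.frame(id = "A", entry_age = 50, exit_age = 57, event = 1L,
                     bmi = 25, hrt = "never", fh = "no",
                     menopause = "post", parity = "1")
  ages <- c(51, 54, 57)
  h_lo <- jm_hazard(ages, subj, p2, c(nd = 0, d = 0))
  h_hi <- jm_hazard(ages, subj, p2, c(nd = 0, d = 1))
  expect_true(all(h_hi > h_lo))
})

test_that("generation is deterministic and respects truncation invariants", {
  cfg <- synthetic_config(n_subjects = 400, seed = 31)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$visits, co2$visits)
  s <- co1$subjects; v <- co1$visits
  expect_true(all(s$exit_age >= s$entry_age))
  idx <- match(v$id, s$id)
  expect_true(all(v$age <= s$exit_age[idx] + 1e-9))
  first <- tapply(v$age, factor(v$id, levels = s$id), min)
  expect_equal(as.vector(first), s$entry_age, tolerance = 1e-9)
  # byte-identical CSV output
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(co1, d1); write_cohort(co2, d2)
  expect_identical(readBin(file.path(d1, "subjects.csv"), "raw", 1e6),
                   readBin(file.path(d2, "subjects.csv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "visits.csv"), "raw", 1e6),
                   readBin(file.path(d2, "visits.csv"), "raw", 1e6))
})

test_that("a 3-subject toy cohort has hand-countable tables", {
  cfg <- synthetic_config(n_subjects = 3, seed = 7, max_visits = 3,
                          admin_censor_years = 5)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$subjects), 3L)
  counts <- table(factor(co$visits$id, levels = co$subjects$id))
  expect_true(all(counts >= 1 & counts <= 3))
  expect_equal(nrow(co$visits), sum(counts))
  expect_equal(colnames(co$visits), c("id", "age", "nd_area", "d_area", "bmi"))
})
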