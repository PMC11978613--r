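p2 <- bivariate_params()
toy_subject <- data.frame(id = "A", entry_age = 50, exit_age = 57,
                          event = 1L, bmi = 25, hrt = "never", fh = "no",
                          menopause = "post", parity = "1",
                          stringsAsFactors = FALSE)

test_that("hazard assembles the linear predictor as defined", {
  # baseline only: alpha = gamma = 0
  p0 <- p2
  p0$alpha[] <- 0; p0$gamma[] <- 0
  ages <- c(51, 54, 56.5)
  s0 <- cbind(1, eval_basis(p0$hazard_basis, ages))
  expect_equal(jm_hazard(ages, toy_subject, p0),
               exp(drop(s0 %*% p0$omega)))
  # log-hazard is affine in each alpha_k with slope mu_ik(age)
  b <- c(nd = 0.4, d = -0.2)
  for (k in c("nd", "d")) {
    pa <- p2; pb <- p2
    pa$alpha[k] <- 0.1; pb$alpha[k] <- 0.35
    mu_k <- marker_mean(ages, toy_subject, p2$specs[[k]], p2$beta[[k]],
                        b[[k]], p2$marker_basis)
    slope <- (log(jm_hazard(ages, toy_subject, pb, b)) -
              log(jm_hazard(ages, toy_subject, pa, b))) / 0.25
    expect_equal(slope, mu_k, tolerance = 1e-10)
  }
  # hand-assembled toy value on a 3-point grid
  W <- mdjm:::covariate_design(toy_subject, c("bmi_baseline", "hrt", "fh"))
  lp <- drop(s0 %*% p2$omega) +
    drop(W[, names(p2$gamma)] %*% p2$gamma) +
    p2$alpha[["nd"]] * marker_mean(ages, toy_subject, p2$specs$nd,
                                   p2$beta$nd, b[["nd"]], p2$marker_basis) +
    p2$alpha[["d"]] * marker_mean(ages, toy_subject, p2$specs$d,
                                  p2$beta$d, b[["d"]], p2$marker_basis)
  expect_equal(jm_hazard(ages, toy_subject, p2, b), exp(lp))
})

test_that("cumulative hazard: exactness, additivity, convergence", {
  pc <- p2
  pc$alpha[] <- 0; pc$gamma[] <- 0
  pc$omega <- mdjm:::project_curve(pc$hazard_basis,
                                   function(a) rep(log(0.37), length(a)))
  for (nn in c(1L, 5L, 30L))
    expect_equal(jm_cumulative_hazard(48, 56, toy_subject, pc,
                                      n_nodes = nn),
                 0.37 * 8, tolerance = 1e-12)
  b <- c(nd = 0.3, d = 0.1)
  l1 <- jm_cumulative_hazard(50, 53, toy_subject, p2, b)
  l2 <- jm_cumulative_hazard(53, 57, toy_subject, p2, b)
  l12 <- jm_cumulative_hazard(50, 57, toy_subject, p2, b)
  expect_equal(l1 + l2, l12, tolerance = 1e-10)
  expect_equal(jm_cumulative_hazard(50, 50, toy_subject, p2, b), 0)
  # doubling the node count changes a smooth integral negligibly
  d30 <- jm_cumulative_hazard(50, 57, toy_subject, p2, b, n_nodes = 30)
  d60 <- jm_cumulative_hazard(50, 57, toy_subject, p2, b, n_nodes = 60)
  expect_lt(abs(d30 - d60), 1e-8)
  expect_error(jm_cumulative_hazard(57, 50, toy_subject, p2), "a0")
})

test_that("single-marker degenerate random effect has a closed form", {
  spec1 <- list(nd = marker_spec("nd"))
  p1 <- joint_params(list(nd = p2$beta$nd), matrix(1e-8, 1, 1),
                     matrix(0.8^2, 1, 1), p2$omega, p2$gamma,
                     c(nd = p2$alpha[["nd"]]), spec1,
                     p2$marker_basis, p2$hazard_basis)
  subj <- toy_subject; subj$event <- 0L
  visits <- data.frame(id = "A", age = 50, nd_area = 120, d_area = 20,
                       bmi = 25)
  ll <- subject_loglik(subj, visits, p1, gl_nodes = 40)
  des <- build_marker_design(visits, subj, spec1$nd, p2$marker_basis)
  expected <- dnorm(sqrt(120), drop(des$X %*% p2$beta$nd), 0.8, log = TRUE) -
    jm_cumulative_hazard(50, 57, subj, p1, c(nd = 0), n_nodes = 40)
  expect_equal(ll, unname(expected), tolerance = 1e-6)
})

test_that("marginal likelihood agrees with brute-force grid integration", {
  co <- toy_cohort(60, seed = 202)
  co$subjects$event[c(2, 9)] <- 1L   # ensure event subjects are covered
  ids <- co$subjects$id[1:12]
  for (id in ids) {
    s1 <- co$subjects[co$subjects$id == id, , drop = FALSE]
    v1 <- co$visits[co$visits$id == id, , drop = FALSE]
    ll <- subject_loglik(s1, v1, p2, gl_nodes = 40)
    llg <- grid_loglik_oracle(s1, v1, p2)
    expect_equal(ll, llg, tolerance = 1e-6)
  }
})

test_that("increasing quadrature nodes leaves the log-likelihood stable", {
  co <- toy_cohort(200, seed = 17)
  tp <- default_true_params("joint2")
  prep <- mdjm:::jm_prepare(co$subjects, co$visits,
                            default_marker_specs("joint2"),
                            tp$marker_basis, tp$hazard_basis,
                            c("bmi_baseline", "hrt", "fh"), 15L)
  args <- list(tp$beta[c("nd", "d")], tp$Sigma_b[1:2, 1:2],
               tp$Sigma_eps[1:2, 1:2], tp$omega, tp$gamma,
               tp$alpha[c("nd", "d")], prep)
  ll7 <- do.call(mdjm:::jm_loglik_vec, c(args, gh_nodes = 7L))
  ll15 <- do.call(mdjm:::jm_loglik_vec, c(args, gh_nodes = 15L))
  expect_lt(max(abs(ll7 - ll15)), 1e-4)        # per subject
  expect_lt(abs(sum(ll7) - sum(ll15)), 1e-3)   # cohort total
})

test_that("left truncation is not a no-op", {
  co <- toy_cohort(40, seed = 55)
  s1 <- co$subjects[co$subjects$event == 0, , drop = FALSE][5, , drop = FALSE]
  v1 <- co$visits[co$visits$id == s1$id, , drop = FALSE]
  ll <- subject_loglik(s1, v1, p2)
  s2 <- s1; s2$entry_age <- s1$entry_age - 3
  ll_shift <- subject_loglik(s2, v1, p2)
  expect_false(isTRUE(all.equal(ll, ll_shift)))
  expect_lt(ll_shift, ll)  # longer exposure, no event: more survival mass
})

test_that("joint model fit recovers structure on a small cohort", {
  co <- toy_cohort(500, seed = 404)
  fit <- fit_joint_model(co, "joint2",
                         options = list(se = TRUE, gh_nodes = 5))
  expect_s3_class(fit, "jm_fit")
  expect_true(fit$converged)
  # the optimum cannot be worse than the generating truth
  tp <- default_true_params("joint2")
  prep <- mdjm:::jm_prepare(co$subjects, co$visits,
                            default_marker_specs("joint2"),
                            fit$knots$marker, fit$knots$hazard,
                            c("bmi_baseline", "hrt", "fh"),
                            fit$options$gl_nodes)
  ll_truth <- sum(mdjm:::jm_loglik_vec(
    tp$beta[c("nd", "d")], tp$Sigma_b[1:2, 1:2], tp$Sigma_eps[1:2, 1:2],
    tp$omega, tp$gamma, tp$alpha[c("nd", "d")], prep, gh_nodes = 5L))
  expect_gte(fit$loglik, ll_truth)
  # estimated correlations land near the truth
  expect_lt(abs(mdjm:::cov2corr_ij(fit$par$Sigma_b, 1, 2) - (-0.63)), 0.12)
  expect_lt(abs(mdjm:::cov2corr_ij(fit$par$Sigma_eps, 1, 2) - (-0.43)), 0.1)
  expect_true(all(c("alpha.nd", "alpha.d") %in% fit$hr_rows$term))
  expect_true(all(fit$hr_rows$ci_low <= fit$hr_rows$HR &
                  fit$hr_rows$HR <= fit$hr_rows$ci_high))
})

test_that("trivariate fit with frozen BMI block nests the bivariate fit", {
  tp3 <- default_true_params("joint2")  # zero cross-correlation truth
  co <- generate_cohort(synthetic_config(n_subjects = 500, seed = 661,
                                         bmi_visit_prob = 1,
                                         true_params = tp3))
  opts <- list(se = FALSE, gh_nodes = 5,
               survival_covariates = c("hrt", "fh"))
  fit2 <- fit_joint_model(co, "joint2", options = opts)
  fixed <- c(Sigma_b.L3.1 = 0, Sigma_b.L3.2 = 0,
             Sigma_eps.L3.1 = 0, Sigma_eps.L3.2 = 0, alpha.bmi = 0)
  fit3 <- fit_joint_model(co, "joint3", options = list(se = FALSE,
                                                       gh_nodes = 5),
                          fixed = fixed)
  expect_equal(fit3$estimates[["alpha.nd"]], fit2$estimates[["alpha.nd"]],
               tolerance = 2e-3)
  expect_equal(fit3$estimates[["alpha.d"]], fit2$estimates[["alpha.d"]],
               tolerance = 2e-3)
})

test_that("Wald inference: identities and hand-computed joint test", {
  fake <- list(estimates = c(alpha.nd = 0, alpha.d = 0.3),
               vcov = matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2,
                             dimnames = list(c("alpha.nd", "alpha.d"),
                                             c("alpha.nd", "alpha.d"))))
  rows <- wald_inference(fake)
  expect_equal(rows$HR[rows$term == "alpha.nd"], 1)
  expect_equal(rows$p[rows$term == "alpha.nd"], 1)
  # single term: chi-square equals the squared z statistic
  w1 <- wald_test(fake, "alpha.d")
  expect_equal(w1$chisq, (0.3 / 0.3)^2)
  # 2x2 joint test against explicit matrix arithmetic
  w2 <- wald_test(fake, c("alpha.nd", "alpha.d"))
  th <- fake$estimates
  expect_equal(w2$chisq, drop(t(th) %*% solve(fake$vcov) %*% th))
  expect_equal(w2$df, 2L)
  expect_error(wald_test(fake, "nope"), "unknown")
})
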