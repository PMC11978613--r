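# Joint-model parameter container and the default generating calibration.

#' Joint-model parameter set
#'
#' Bundles every parameter of the K-marker joint model: per-marker
#' fixed-effect vectors, the random-intercept and within-visit residual
#' covariance matrices, the natural-spline log baseline-hazard
#' coefficients (intercept + basis), the survival covariate effects and
#' the association coefficients (one per marker, on the transformed
#' marker scale).  The spline bases are carried with the parameters so
#' that a parameter set fully determines the model.
#'
#' @param beta named list of fixed-effect vectors, one per marker, in
#'   the order of \code{specs}.
#' @param Sigma_b K x K random-intercept covariance (positive definite).
#' @param Sigma_eps K x K within-visit residual covariance (positive
#'   definite); residuals are independent across visits.
#' @param omega log baseline-hazard coefficients: intercept followed by
#'   the hazard-basis coefficients.
#' @param gamma named vector of survival covariate coefficients.
#' @param alpha association coefficients, length K, named by marker.
#' @param specs list of \code{\link{marker_spec}}s (defines K and order).
#' @param marker_basis \code{\link{spline_basis}} for the marker age
#'   effects.
#' @param hazard_basis \code{\link{spline_basis}} for the log baseline
#'   hazard.
#' @param validate check positive definiteness of the covariance
#'   matrices (disabled internally for fitted values at the numerical
#'   boundary).
#' @return object of class \code{"joint_params"}.
#' @export
joint_params <- function(beta, Sigma_b, Sigma_eps, omega, gamma, alpha,
                         specs, marker_basis, hazard_basis,
                         validate = TRUE) {
  K <- length(specs)
  if (!K %in% 1:3)
    stop("the joint model supports at most 3 markers", call. = FALSE)
  if (length(beta) != K || length(alpha) != K)
    stop("`beta` and `alpha` must have one entry per marker", call. = FALSE)
  Sigma_b <- as.matrix(Sigma_b); Sigma_eps <- as.matrix(Sigma_eps)
  if (!all(dim(Sigma_b) == K) || !all(dim(Sigma_eps) == K))
    stop("covariance matrices must be K x K", call. = FALSE)
  if (validate && !is_pd(Sigma_b))
    stop("`Sigma_b` is not positive definite", call. = FALSE)
  if (validate && !is_pd(Sigma_eps))
    stop("`Sigma_eps` is not positive definite", call. = FALSE)
  if (length(omega) != hazard_basis$df + 1L)
    stop("`omega` must have length hazard df + 1 (explicit intercept)",
         call. = FALSE)
  nm <- vapply(specs, function(s) s$name, "")
  names(beta) <- nm
  alpha <- setNames(as.numeric(alpha), nm)
  if ("bmi" %in% nm && alpha[["bmi"]] != 0 &&
      "bmi_baseline" %in% names(gamma))
    stop("when the BMI trajectory enters the hazard, baseline BMI must be ",
         "excluded from the survival submodel", call. = FALSE)
  structure(list(beta = beta, Sigma_b = Sigma_b, Sigma_eps = Sigma_eps,
                 omega = as.numeric(omega), gamma = gamma, alpha = alpha,
                 specs = specs, marker_basis = marker_basis,
                 hazard_basis = hazard_basis),
            class = "joint_params")
}

# Least-squares projection of a smooth age curve onto [1, basis(age)];
# the projected spline *is* the generating truth.
project_curve <- function(basis, f, from = NULL, to = NULL) {
  from <- from %||% basis$boundary_knots[1]
  to <- to %||% basis$boundary_knots[2]
  g <- seq(from, to, length.out = 400)
  X <- cbind(1, eval_basis(basis, g))
  qr.coef(qr(X), f(g))
}

# Calibration constants for the default synthetic truth.  Level/slope/
# curvature describe each marker's mean curve at the reference covariate
# values (age 55, BMI 24.6, never-user, no family history); variance
# components and correlations are on the transformed scales.
default_calibration <- function() {
  list(
    ref_age = 55, ref_bmi = 24.6,
    nd  = list(level = 11.90, bmi = 0.565, slope = 0.045, quad = -8e-4,
               hrt = c(previous = 0, current = -0.10, missing = 0),
               fh = c(yes = 0, missing = 0)),
    d   = list(level = 4.50, bmi = -0.075, slope = -0.060, quad = 4e-4,
               hrt = c(previous = 0.10, current = 0.30, missing = 0),
               fh = c(yes = 0.10, missing = 0)),
    bmi = list(level = 24.50, bmi = 0, slope = 0.020, quad = 0,
               hrt = c(previous = 0, current = 0, missing = 0),
               fh = c(yes = 0, missing = 0)),
    sd_b = c(nd = 1.84, d = 1.30, bmi = 3.60),
    corr_b = c(nd_d = -0.63, nd_bmi = 0, d_bmi = 0),
    sd_e = c(nd = 1.00, d = 0.80, bmi = 1.00),
    corr_e = c(nd_d = -0.43, nd_bmi = 0, d_bmi = 0),
    hazard = list(level = -7.73, slope = 0.045),
    gamma = c(bmi_baseline = 0.015, hrtprevious = 0.05, hrtcurrent = 0.30,
              hrtmissing = 0, fhyes = 0.45, fhmissing = 0)
  )
}

cal_cov_matrix <- function(sd, corr, markers) {
  K <- length(markers)
  S <- diag(sd[markers]^2, K)
  dimnames(S) <- list(markers, markers)
  pairs <- utils::combn(markers, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    key <- paste(a, b, sep = "_")
    r <- if (key %in% names(corr)) corr[[key]] else corr[[paste(b, a, sep = "_")]]
    S[a, b] <- S[b, a] <- r * sd[a] * sd[b]
  }
  S
}

#' Default generating parameters
#'
#' The true parameter values used by the synthetic-cohort generator.
#' Association log hazard ratios and the random-intercept and residual
#' correlations of the mammographic markers are pinned to the published
#' full-cohort estimates (bivariate model: HR 1.059 for nondense area
#' and 1.158 for dense area per unit of the square-root scale as fitted;
#' correlations -0.63 and -0.43; trivariate model: HR 1.030 and 1.149).
#' The remaining constants (mean curves, variance components, covariate
#' prevalence effects, baseline log hazard) are fixed calibration
#' choices reproducing the cohort's printed summary statistics; see the
#' package vignette.
#'
#' @param model \code{"joint2"} generates from the bivariate-association
#'   mechanism (BMI affects the hazard only through its baseline value);
#'   \code{"joint3"} generates from the trivariate mechanism (the BMI
#'   trajectory itself enters the hazard).
#' @param calibration list of calibration constants, by default
#'   \code{default_calibration()}.
#' @return a \code{\link{joint_params}} with K = 3 markers (the third,
#'   BMI, has association zero under \code{model = "joint2"}).
#' @export
default_true_params <- function(model = c("joint2", "joint3"),
                                calibration = default_calibration()) {
  model <- match.arg(model)
  cal <- calibration
  markers <- c("nd", "d", "bmi")
  specs <- list(nd = marker_spec("nd"), d = marker_spec("d"),
                bmi = marker_spec("bmi"))
  marker_basis <- spline_basis(c(40, 74), c(47, 52, 57, 63))
  hazard_basis <- spline_basis(c(42, 78), c(52, 58, 64, 70))

  beta <- lapply(markers, function(mk) {
    cc <- cal[[mk]]
    curve <- function(a)
      cc$level + cc$slope * (a - cal$ref_age) + cc$quad * (a - cal$ref_age)^2
    co <- project_curve(marker_basis, curve)
    # move the BMI adjustment out of the level: intercept refers to bmi = 0
    co[1] <- co[1] - cc$bmi * cal$ref_bmi
    b <- c(co, if (mk != "bmi") c(bmi_baseline = unname(cc$bmi),
                                  hrtprevious = unname(cc$hrt["previous"]),
                                  hrtcurrent = unname(cc$hrt["current"]),
                                  hrtmissing = unname(cc$hrt["missing"]),
                                  fhyes = unname(cc$fh["yes"]),
                                  fhmissing = unname(cc$fh["missing"])))
    names(b)[seq_len(marker_basis$df + 1L)] <-
      c("(Intercept)", paste0("age_ns", seq_len(marker_basis$df)))
    b
  })
  names(beta) <- markers

  Sigma_b <- cal_cov_matrix(cal$sd_b, cal$corr_b, markers)
  Sigma_eps <- cal_cov_matrix(cal$sd_e, cal$corr_e, markers)

  omega <- project_curve(hazard_basis, function(a)
    cal$hazard$level + cal$hazard$slope * (a - cal$ref_age))

  if (model == "joint2") {
    alpha <- c(nd = log(1.059), d = log(1.158), bmi = 0)
    gamma <- cal$gamma
  } else {
    alpha <- c(nd = log(1.030), d = log(1.149), bmi = 0.04)
    gamma <- cal$gamma[setdiff(names(cal$gamma), "bmi_baseline")]
  }

  joint_params(beta = beta, Sigma_b = Sigma_b, Sigma_eps = Sigma_eps,
               omega = omega, gamma = gamma, alpha = alpha,
               specs = specs, marker_basis = marker_basis,
               hazard_basis = hazard_basis)
}

#' @export
print.joint_params <- function(x, ...) {
  K <- length(x$specs)
  cat("Joint-model parameters:", K, "markers (",
      paste(names(x$beta), collapse = ", "), ")\n")
  cat("  alpha:", paste(sprintf("%s=%.4f", names(x$alpha), x$alpha),
                        collapse = ", "), "\n")
  cat("  corr(b):", sprintf("%.3f", cov2corr_ij(x$Sigma_b, 1, 2)),
      " corr(eps):", sprintf("%.3f", cov2corr_ij(x$Sigma_eps, 1, 2)), "\n")
  invisible(x)
}
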