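# Marker submodel specification and design construction.

.hrt_levels <- c("never", "previous", "current", "missing")
.fh_levels <- c("no", "yes", "missing")
.menopause_levels <- c("pre", "peri", "post")
.parity_levels <- c("0", "1", "2", "3plus", "missing")

marker_columns <- c(nd = "nd_area", d = "d_area", bmi = "bmi")

#' Longitudinal marker submodel specification
#'
#' Describes one longitudinal submodel: which measurement it models,
#' on which scale, the dimension of its natural-spline age effect, and
#' which baseline covariates it adjusts for.  The mammographic markers
#' (\code{"nd"}, nondense area; \code{"d"}, dense area) are modeled on
#' the square-root cm scale; BMI on its raw scale.  Random effects are
#' restricted to a subject-level random intercept.
#'
#' @param name one of \code{"nd"}, \code{"d"}, \code{"bmi"}.
#' @param transform \code{"sqrt"} or \code{"identity"}; defaults to
#'   \code{"sqrt"} for the area markers and \code{"identity"} for BMI.
#' @param spline_df dimension of the natural-spline age effect.
#' @param covariates subset of \code{c("bmi_baseline", "hrt", "fh")};
#'   missing-indicator levels are retained as explicit dummy columns.
#' @return a \code{"marker_spec"} object.
#' @export
marker_spec <- function(name = c("nd", "d", "bmi"),
                        transform = NULL,
                        spline_df = 5L,
                        covariates = NULL) {
  name <- match.arg(name)
  if (is.null(transform))
    transform <- if (name == "bmi") "identity" else "sqrt"
  transform <- match.arg(transform, c("sqrt", "identity"))
  if (name %in% c("nd", "d") && transform != "sqrt")
    stop("mammographic area markers are modeled on the sqrt scale",
         call. = FALSE)
  if (is.null(covariates))
    covariates <- if (name == "bmi") character(0)
                  else c("bmi_baseline", "hrt", "fh")
  bad <- setdiff(covariates, c("bmi_baseline", "hrt", "fh"))
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = name, transform = transform,
                 spline_df = as.integer(spline_df),
                 covariates = covariates,
                 random_effects = "intercept_only"),
            class = "marker_spec")
}

#' Default marker specifications per model
#'
#' \code{joint2} gives the bivariate (nondense, dense) configuration;
#' \code{joint3} adds the BMI submodel.
#'
#' @param model "joint2" or "joint3".
#' @return list of \code{marker_spec}s.
#' @export
default_marker_specs <- function(model = c("joint2", "joint3")) {
  model <- match.arg(model)
  specs <- list(nd = marker_spec("nd"), d = marker_spec("d"))
  if (model == "joint3") specs$bmi <- marker_spec("bmi")
  specs
}

transform_value <- function(x, transform) {
  switch(transform, sqrt = sqrt(x), identity = x)
}

inverse_transform_value <- function(x, transform) {
  switch(transform, sqrt = x^2, identity = x)
}

# Fixed-effect design columns contributed by baseline covariates of one
# subject row (data.frame with columns bmi, hrt, fh).  Reference levels:
# hrt never, fh no.
covariate_design <- function(subjects, covariates) {
  cols <- list()
  if ("bmi_baseline" %in% covariates)
    cols$bmi_baseline <- as.numeric(subjects$bmi)
  if ("hrt" %in% covariates) {
    h <- factor(as.character(subjects$hrt), levels = .hrt_levels)
    if (anyNA(h)) stop("invalid hrt level", call. = FALSE)
    cols$hrtprevious <- as.numeric(h == "previous")
    cols$hrtcurrent <- as.numeric(h == "current")
    cols$hrtmissing <- as.numeric(h == "missing")
  }
  if ("fh" %in% covariates) {
    f <- factor(as.character(subjects$fh), levels = .fh_levels)
    if (anyNA(f)) stop("invalid fh level", call. = FALSE)
    cols$fhyes <- as.numeric(f == "yes")
    cols$fhmissing <- as.numeric(f == "missing")
  }
  if (!length(cols)) return(matrix(0, nrow(subjects), 0))
  do.call(cbind, cols)
}

#' Build the mixed-model design for one marker
#'
#' Assembles, over all visit rows, the transformed response, the
#' fixed-effects design matrix (intercept, natural-spline age effect,
#' baseline covariate dummies with missingness kept as explicit levels)
#' and the subject index that acts as the random-intercept indicator.
#'
#' @param visits visit table (columns \code{id}, \code{age} and the
#'   marker measurement).
#' @param subjects subject table (one row per id, carrying \code{bmi},
#'   \code{hrt}, \code{fh}).
#' @param spec a \code{\link{marker_spec}}.
#' @param basis a \code{\link{spline_basis}} for the age effect.
#' @return list with \code{y} (response on the transformed scale),
#'   \code{X} (fixed-effects matrix), \code{id} (subject id per row) and
#'   \code{observed} (logical; FALSE where the measurement is absent).
#' @export
build_marker_design <- function(visits, subjects, spec, basis) {
  stopifnot(inherits(spec, "marker_spec"), inherits(basis, "spline_basis"))
  col <- marker_columns[[spec$name]]
  if (!col %in% names(visits))
    stop("visit table lacks column `", col, "`", call. = FALSE)
  raw <- as.numeric(visits[[col]])
  observed <- !is.na(raw)
  if (spec$transform == "sqrt" && any(raw[observed] < 0))
    stop("negative raw area in row(s) ",
         paste(head(which(observed & raw < 0)), collapse = ", "),
         " for marker `", spec$name, "`", call. = FALSE)
  y <- rep(NA_real_, length(raw))
  y[observed] <- transform_value(raw[observed], spec$transform)

  sub_idx <- match(visits$id, subjects$id)
  if (anyNA(sub_idx))
    stop("visit rows with ids absent from the subject table: ",
         paste(head(which(is.na(sub_idx))), collapse = ", "), call. = FALSE)
  S <- eval_basis(basis, as.numeric(visits$age))
  colnames(S) <- paste0("age_ns", seq_len(ncol(S)))
  Z <- covariate_design(subjects[sub_idx, , drop = FALSE], spec$covariates)
  X <- cbind(`(Intercept)` = 1, S, Z)
  list(y = y, X = X, id = visits$id, observed = observed)
}

#' Expected transformed marker value for one subject
#'
#' Evaluates mu_ik(age) = x_ik(age)' beta_k + b_ik, the subject-specific
#' model-implied mean of marker k on its transformed scale; this is the
#' quantity entering the hazard through the expected-value association.
#'
#' @param age numeric vector of ages.
#' @param subject one-row subject data.frame (for covariate values).
#' @param spec a \code{\link{marker_spec}}.
#' @param beta_k fixed-effect vector for the marker.
#' @param b_ik subject's random intercept.
#' @param basis the marker's \code{\link{spline_basis}}.
#' @return numeric vector of expected values at \code{age}.
#' @export
marker_mean <- function(age, subject, spec, beta_k, b_ik, basis) {
  S <- eval_basis(basis, as.numeric(age))
  Z <- covariate_design(subject, spec$covariates)
  X <- cbind(1, S, Z[rep(1L, length(age)), , drop = FALSE])
  if (ncol(X) != length(beta_k))
    stop("beta_k has length ", length(beta_k), " but the design has ",
         ncol(X), " columns", call. = FALSE)
  drop(X %*% beta_k) + b_ik
}
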