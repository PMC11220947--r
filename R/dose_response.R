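# Logistic dose-response modelling per reporting convention.
#
# The central identity: rescaling the dose covariate by the conversion
# factor c divides the fitted slope by c, so the per-unit odds ratio under
# a salt convention is OR_base^(1/c). The fits here make that identity
# observable (and testable) rather than assuming it.

#' Stack the cohort into one row per patient x formulation
#'
#' Each patient's base-molecule dose is re-expressed under every
#' formulation in the registry: `d_f = c_f * d_base`. The stacked design is
#' what the interaction model is fitted on; per-formulation fits subset it.
#'
#' @param cohort Tibble with `patient_id`, `death_28d` and the chosen dose
#'   column (`diagnosis_dose` or `peak_dose_24h`).
#' @param dose Which dose to model: `"diagnosis"` or `"peak"`.
#' @param registry Formulation registry, see [ne_formulations()].
#' @return Tibble with columns `patient_id`, `formulation` (factor, base
#'   first), `factor`, `dose_reported`, `death`. Patients with a missing
#'   dose are dropped with a message.
#' @export
stack_formulations <- function(cohort, dose = c("peak", "diagnosis"),
                               registry = ne_formulations()) {
  dose <- match.arg(dose)
  col <- if (dose == "peak") "peak_dose_24h" else "diagnosis_dose"
  if (!all(c(col, "death_28d", "patient_id") %in% names(cohort))) {
    stop("cohort must have columns patient_id, death_28d, ", col,
         call. = FALSE)
  }
  miss <- is.na(cohort[[col]])
  if (any(miss)) {
    message(sum(miss), " patient(s) omitted: missing ", col)
    cohort <- cohort[!miss, , drop = FALSE]
  }
  if (nrow(cohort) == 0) {
    return(tibble::tibble(patient_id = character(),
                          formulation = factor(character(),
                                               levels = registry$formulation),
                          factor = numeric(), dose_reported = numeric(),
                          death = integer()))
  }
  out <- tidyr::crossing(
    tibble::tibble(patient_id = cohort$patient_id,
                   d_base = cohort[[col]],
                   death = as.integer(cohort$death_28d)),
    tibble::tibble(formulation = registry$formulation,
                   factor = registry$factor))
  out$dose_reported <- out$d_base * out$factor
  out$formulation <- factor(out$formulation, levels = registry$formulation)
  out[, c("patient_id", "formulation", "factor", "dose_reported", "death")]
}

#' Fit the mortality dose-response under each reporting convention
#'
#' Three algebraically equivalent parameterizations are offered:
#' `"per_formulation"` (default) fits an independent logistic regression of
#' death on reported dose within each formulation's rows;
#' `"interaction"` fits one fixed-effects model
#' `death ~ 0 + formulation + formulation:dose_reported` on the stacked
#' design, yielding the same per-formulation intercepts and slopes;
#' `"interaction_random_intercept"` adds a patient-level random intercept
#' (lme4). Because the stacked rows are deterministic rescalings of one
#' observation per patient, the random intercept is weakly identified: its
#' variance is reported in the fit metadata but should not be interpreted.
#'
#' @param design A stacked design from [stack_formulations()].
#' @param variant Model parameterization, see Details.
#' @return Object of class `dose_response_fit`: `estimates` (tibble with
#'   `formulation`, `factor`, `alpha`, `beta`, `or`), `vcov` (named list of
#'   2x2 covariance matrices of `(alpha, beta)` per formulation),
#'   `variant`, `converged`, `n_patients`, and `re_variance` (random-
#'   intercept variance, `NA` unless that variant is used).
#' @export
fit_dose_response <- function(design,
                              variant = c("per_formulation", "interaction",
                                          "interaction_random_intercept")) {
  variant <- match.arg(variant)
  stopifnot(all(c("formulation", "dose_reported", "death") %in% names(design)))
  if (length(unique(design$death)) < 2) {
    stop("fit failure: outcome has a single class", call. = FALSE)
  }
  forms <- levels(design$formulation)
  facs <- vapply(forms, function(f) design$factor[design$formulation == f][1],
                 numeric(1))
  re_var <- NA_real_
  if (variant == "per_formulation") {
    est <- vector("list", length(forms)); vc <- list()
    for (f in forms) {
      sub <- design[design$formulation == f, ]
      m <- stats::glm(death ~ dose_reported, family = stats::binomial(),
                      data = sub,
                      control = stats::glm.control(epsilon = 1e-12,
                                                   maxit = 100))
      check_glm_fit(m, f)
      cf <- stats::coef(m)
      est[[f]] <- tibble::tibble(formulation = f, factor = facs[[f]],
                                 alpha = unname(cf[1]), beta = unname(cf[2]))
      vc[[f]] <- unname(stats::vcov(m))
    }
    estimates <- dplyr::bind_rows(est)
  } else {
    if (variant == "interaction") {
      m <- stats::glm(death ~ 0 + formulation + formulation:dose_reported,
                      family = stats::binomial(), data = design,
                      control = stats::glm.control(epsilon = 1e-12,
                                                   maxit = 100))
      check_glm_fit(m, "interaction")
      cf <- stats::coef(m); V <- stats::vcov(m)
    } else {
      m <- lme4::glmer(
        death ~ 0 + formulation + formulation:dose_reported + (1 | patient_id),
        family = stats::binomial(), data = design)
      cf <- lme4::fixef(m); V <- as.matrix(stats::vcov(m))
      re_var <- unname(lme4::VarCorr(m)$patient_id[1, 1])
    }
    estimates <- dplyr::bind_rows(lapply(forms, function(f) {
      tibble::tibble(formulation = f, factor = facs[[f]],
                     alpha = unname(cf[paste0("formulation", f)]),
                     beta = unname(cf[paste0("formulation", f,
                                             ":dose_reported")]))
    }))
    vc <- lapply(forms, function(f) {
      nm <- c(paste0("formulation", f),
              paste0("formulation", f, ":dose_reported"))
      unname(V[nm, nm])
    })
    names(vc) <- forms
  }
  estimates$or <- exp(estimates$beta)
  structure(list(estimates = estimates, vcov = vc, variant = variant,
                 converged = TRUE,
                 n_patients = length(unique(design$patient_id)),
                 re_variance = re_var),
            class = "dose_response_fit")
}

check_glm_fit <- function(m, label) {
  if (!m$converged || any(abs(stats::coef(m)) > 25)) {
    stop("fit failure (", label, "): ",
         if (!m$converged) "IRLS did not converge" else
           "coefficients diverged (quasi-separation)",
         "; deviance = ", format(m$deviance), call. = FALSE)
  }
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Logistic dose-response fit (", x$variant, "), ",
      x$n_patients, " patients\n", sep = "")
  df <- x$estimates
  df$or <- signif(df$or, 4)
  print(as.data.frame(df), row.names = FALSE)
  if (!is.na(x$re_variance)) {
    cat("Patient random-intercept variance (weakly identified):",
        signif(x$re_variance, 4), "\n")
  }
  invisible(x)
}

#' Analytic slope under a reporting convention
#'
#' Rescaling a covariate by `c` divides its regression coefficient by `c`;
#' the slope under formulation `f` is therefore `beta_base / c_f`. This is
#' the closed-form oracle the fitted models are checked against.
#'
#' @param beta_base Slope on the base-molecule scale (log-odds per
#'   ug/kg/min).
#' @param formulation Formulation name.
#' @param registry Formulation registry.
#' @return Slope on the reported-salt scale.
#' @examples
#' exp(expected_slope(log(9.4), "tartrate")) # OR 9.4^(1/2) = 3.066
#' @export
expected_slope <- function(beta_base, formulation,
                           registry = ne_formulations()) {
  beta_base / formulation_factor(formulation, registry)
}

#' Percent reduction of a salt-scale odds ratio relative to base
#'
#' @param or_f,or_base Per-unit odds ratios (> 0).
#' @return `100 * (1 - or_f / or_base)`.
#' @examples
#' percent_or_reduction(9.4^(1 / 2), 9.4) # ~67.4% for tartrate
#' @export
percent_or_reduction <- function(or_f, or_base) {
  if (any(or_f <= 0) || any(or_base <= 0)) {
    stop("odds ratios must be > 0", call. = FALSE)
  }
  100 * (1 - or_f / or_base)
}

#' Predicted 28-day mortality at a reported dose
#'
#' Evaluates the fitted logistic curve for a formulation at reported
#' dose(s). The 95% CI comes from the delta method on the logit scale (the
#' linear predictor's variance from the coefficient covariance), then
#' transformed, so the interval is always inside \[0, 1\].
#'
#' @param fit A [fit_dose_response()] object.
#' @param dose Reported dose(s), ug/kg/min (>= 0).
#' @param formulation Formulation name.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `formulation`, `dose`, `p`, `lower`, `upper`.
#' @export
predict_mortality <- function(fit, dose, formulation, level = 0.95) {
  stopifnot(inherits(fit, "dose_response_fit"))
  check_dose(dose, "dose")
  row <- fit$estimates[fit$estimates$formulation == formulation, ]
  if (nrow(row) != 1) {
    stop("no fit for formulation '", formulation, "'", call. = FALSE)
  }
  V <- fit$vcov[[formulation]]
  eta <- row$alpha + row$beta * dose
  se <- sqrt(V[1, 1] + 2 * dose * V[1, 2] + dose^2 * V[2, 2])
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(formulation = formulation, dose = dose,
                 p = stats::plogis(eta),
                 lower = stats::plogis(eta - z * se),
                 upper = stats::plogis(eta + z * se))
}

#' Predicted mortality at common severity thresholds
#'
#' Tabulates predicted 28-day mortality with 95% CIs at the commonly used
#' reported-dose thresholds (0.1, 0.25 and 1 ug/kg/min by default) for
#' every fitted formulation, with integer-percent rendering (half-up
#' rounding) alongside the raw probabilities.
#'
#' @param fit A [fit_dose_response()] object.
#' @param thresholds Reported-dose thresholds, ug/kg/min.
#' @return Tibble: `threshold`, `formulation`, `p`, `lower`, `upper`,
#'   `percent`, `percent_lower`, `percent_upper`.
#' @export
threshold_table <- function(fit, thresholds = c(0.1, 0.25, 1)) {
  stopifnot(inherits(fit, "dose_response_fit"))
  out <- list()
  for (th in thresholds) {
    for (f in fit$estimates$formulation) {
      out[[length(out) + 1]] <- cbind(threshold = th,
                                      predict_mortality(fit, th, f))
    }
  }
  tab <- tibble::as_tibble(dplyr::bind_rows(out))
  tab$percent <- round_half_up(100 * tab$p)
  tab$percent_lower <- round_half_up(100 * tab$lower)
  tab$percent_upper <- round_half_up(100 * tab$upper)
  tab[, c("threshold", "formulation", "p", "lower", "upper",
          "percent", "percent_lower", "percent_upper")]
}

#' Threshold table straight from published mortality anchors
#'
#' Solves the two-parameter logistic through base-molecule anchors
#' (dose, mortality) and evaluates it at each reported-dose threshold under
#' each formulation via prediction equivariance: the risk at reported dose
#' `d` under formulation `f` equals the base-curve risk at `d / c_f`. No
#' simulation or fitting is involved; this is the analytic reconstruction
#' of a published cut-off table from its base-formulation column.
#'
#' @param anchors Base-molecule anchors, see
#'   [calibrate_logistic_from_anchors()].
#' @param thresholds Reported-dose thresholds, ug/kg/min.
#' @param registry Formulation registry.
#' @return Tibble: `threshold`, `formulation`, `p`, `percent`.
#' @export
anchor_threshold_table <- function(anchors, thresholds = c(0.1, 0.25, 1),
                                   registry = ne_formulations()) {
  ab <- calibrate_logistic_from_anchors(anchors)
  grid <- tidyr::crossing(threshold = thresholds,
                          tibble::tibble(formulation = registry$formulation,
                                         factor = registry$factor))
  grid$p <- stats::plogis(ab["alpha"] + ab["beta"] * grid$threshold /
                            grid$factor)
  grid$percent <- round_half_up(100 * grid$p)
  grid[, c("threshold", "formulation", "p", "percent")]
}

#' Plot fitted dose-response curves per reporting convention
#'
#' Sigmoid mortality curves on the reported-dose axis with guide lines at
#' the common thresholds: 0.1 (highest SOFA cardiovascular band), 0.25
#' (typical trigger for vasopressin/hydrocortisone) and 1 ug/kg/min
#' ("high-dose" vasopressor).
#'
#' @param fit A [fit_dose_response()] object.
#' @param max_dose Upper end of the dose axis (default 1.2).
#' @param thresholds Guide-line doses.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(fit, max_dose = 1.2,
                               thresholds = c(0.1, 0.25, 1)) {
  stopifnot(inherits(fit, "dose_response_fit"))
  doses <- seq(0, max_dose, length.out = 200)
  curves <- dplyr::bind_rows(lapply(fit$estimates$formulation, function(f) {
    predict_mortality(fit, doses, f)
  }))
  guide_cols <- c("#2e7d32", "#ef6c00", "#c62828")[seq_along(thresholds)]
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$dose, y = .data$p,
                               colour = .data$formulation)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$formulation),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = thresholds, linetype = "dashed",
                        colour = guide_cols) +
    ggplot2::labs(x = "Reported NE dose (ug/kg/min)",
                  y = "Predicted 28-day mortality",
                  colour = "Formulation", fill = "Formulation") +
    ggplot2::theme_minimal()
}
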