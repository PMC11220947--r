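#' Solve a logistic dose-response through anchor points
#'
#' With exactly two anchors `(dose, p)` this solves the 2x2 linear system
#' `qlogis(p_i) = alpha + beta * dose_i` exactly; with more anchors it
#' minimizes squared error on the logit scale (ordinary least squares).
#' Used to calibrate the synthetic cohort's mortality model to published
#' mortality proportions at reference doses.
#'
#' @param anchors A data frame (or tibble) with numeric columns `dose`
#'   (ug/kg/min) and `p` (mortality proportion, strictly inside (0, 1)).
#' @return Named numeric vector `c(alpha = , beta = )` on the log-odds scale;
#'   `beta` is log-odds per ug/kg/min.
#' @examples
#' # anchors: 36% mortality at 0.1 ug/kg/min, 81% at 1.0
#' calibrate_logistic_from_anchors(data.frame(dose = c(0.1, 1), p = c(0.36, 0.81)))
#' @export
calibrate_logistic_from_anchors <- function(anchors) {
  anchors <- as.data.frame(anchors)
  if (!all(c("dose", "p") %in% names(anchors)) || nrow(anchors) < 2) {
    stop("anchors must have columns 'dose' and 'p' and at least 2 rows",
         call. = FALSE)
  }
  if (anyDuplicated(anchors$dose)) {
    stop("invalid anchors: duplicate doses", call. = FALSE)
  }
  if (any(anchors$p <= 0 | anchors$p >= 1)) {
    stop("invalid anchors: proportions must be strictly inside (0, 1)",
         call. = FALSE)
  }
  y <- stats::qlogis(anchors$p)
  if (nrow(anchors) == 2) {
    beta <- (y[2] - y[1]) / (anchors$dose[2] - anchors$dose[1])
    alpha <- y[1] - beta * anchors$dose[1]
  } else {
    cf <- stats::coef(stats::lm(y ~ dose, data = anchors))
    alpha <- unname(cf[1]); beta <- unname(cf[2])
  }
  c(alpha = alpha, beta = beta)
}

#' Log-normal parameters from quartiles
#'
#' Returns `(meanlog, sdlog)` such that the log-normal has the given median
#' and interquartile ratio: `meanlog = log(median)` and
#' `sdlog = log(q3/q1) / (2 * qnorm(0.75))`.
#'
#' @param median,q1,q3 Target median and quartiles (all > 0, q1 < q3).
#' @return Named vector `c(meanlog = , sdlog = )`.
#' @export
lognormal_from_quartiles <- function(median, q1, q3) {
  stopifnot(median > 0, q1 > 0, q3 > q1)
  c(meanlog = log(median), sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

#' Configuration for the synthetic septic-shock cohort
#'
#' Bundles every tunable of [generate_cohort()]. Defaults emulate the
#' published cohort structure: base-molecule peak NE doses log-normal with
#' median 0.24 and quartiles ~0.12/0.42 ug/kg/min, diagnosis doses a
#' Beta-distributed fraction of the peak calibrated to a median near 0.1,
#' 28-day mortality Bernoulli on a logistic function of the base peak dose
#' (default intercept/slope solved through published mortality anchors of
#' 27% at 0.1 and 83% at 1.0 ug/kg/min), a second vasopressor in 57% of
#' patients, and infusion streams with titration steps, occasional transient
#' (< 5 min) spikes and rare registry-error outliers.
#'
#' @param n_patients Number of patients (>= 1).
#' @param alpha,beta Logistic intercept (log-odds) and slope (log-odds per
#'   ug/kg/min base peak dose) of the mortality model.
#' @param dose_median,dose_q1,dose_q3 Target median and quartiles of the
#'   base peak-dose log-normal (ug/kg/min).
#' @param diag_frac_shape Length-2 shape parameters of the Beta distribution
#'   of diagnosis-dose / peak-dose fractions.
#' @param spike_rate Expected number of transient (< 5 min) spikes per
#'   patient (Poisson).
#' @param outlier_rate Probability a patient's stream contains one
#'   registry-error outlier record (rate far above any plausible dose).
#' @param second_pressor_prob Probability of a second vasopressor.
#' @param screen_pass_rate Fraction of patients constructed to pass the
#'   Sepsis-3 screen; the remainder each violate one randomly chosen
#'   criterion.
#' @param rate_unit Unit NE rates are recorded in: `"ug/kg/min"` (native) or
#'   `"ug/min"` (absolute, exercising weight normalization downstream).
#' @param max_plausible_dose Ceiling (ug/kg/min base) applied to latent peak
#'   doses; doses above it are clinically implausible registry errors, which
#'   the generator injects separately via `outlier_rate`.
#' @param seed Master integer seed; every table draws from an independently
#'   derived substream, so generation is fully reproducible.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 4086,
                          alpha = NULL,
                          beta = NULL,
                          dose_median = 0.24,
                          dose_q1 = 0.12,
                          dose_q3 = 0.42,
                          diag_frac_shape = c(2, 2.28),
                          spike_rate = 0.5,
                          outlier_rate = 0.05,
                          second_pressor_prob = 0.57,
                          screen_pass_rate = 1,
                          rate_unit = c("ug/kg/min", "ug/min"),
                          max_plausible_dose = 4.9,
                          seed = 1L) {
  rate_unit <- match.arg(rate_unit)
  if (is.null(alpha) || is.null(beta)) {
    ab <- calibrate_logistic_from_anchors(
      data.frame(dose = c(0.1, 1), p = c(0.27, 0.83)))
    alpha <- alpha %||% unname(ab["alpha"])
    beta <- beta %||% unname(ab["beta"])
  }
  cfg <- list(n_patients = as.integer(n_patients), alpha = alpha, beta = beta,
              dose_median = dose_median, dose_q1 = dose_q1, dose_q3 = dose_q3,
              diag_frac_shape = diag_frac_shape, spike_rate = spike_rate,
              outlier_rate = outlier_rate,
              second_pressor_prob = second_pressor_prob,
              screen_pass_rate = screen_pass_rate, rate_unit = rate_unit,
              max_plausible_dose = max_plausible_dose, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1,
            is.finite(cfg$alpha), is.finite(cfg$beta),
            cfg$dose_median > 0, cfg$dose_q1 > 0, cfg$dose_q3 > cfg$dose_q1,
            length(cfg$diag_frac_shape) == 2, all(cfg$diag_frac_shape > 0),
            cfg$spike_rate >= 0,
            cfg$outlier_rate >= 0, cfg$outlier_rate <= 1,
            cfg$second_pressor_prob >= 0, cfg$second_pressor_prob <= 1,
            cfg$screen_pass_rate >= 0, cfg$screen_pass_rate <= 1,
            cfg$max_plausible_dose > 0)
  invisible(cfg)
}

#' Simulate (dose, mortality) pairs from a calibrated logistic model
#'
#' Draws `n` doses from a log-normal parameterized by its median and
#' quartiles and a Bernoulli death indicator with probability
#' `plogis(alpha + beta * dose)`. This is the bare generative core used for
#' parameter-recovery studies; [generate_cohort()] builds full event tables
#' around the same model.
#'
#' @param n Number of patients.
#' @inheritParams cohort_config
#' @param seed Integer seed.
#' @return Tibble with columns `patient_id`, `dose`, `p_death`, `death`.
#' @export
simulate_dose_mortality <- function(n, alpha, beta,
                                    dose_median = 0.1, dose_q1 = 0.05,
                                    dose_q3 = 0.2, seed = 1L) {
  ln <- lognormal_from_quartiles(dose_median, dose_q1, dose_q3)
  with_seed(seed, {
    dose <- stats::rlnorm(n, ln["meanlog"], ln["sdlog"])
    p <- stats::plogis(alpha + beta * dose)
    tibble::tibble(patient_id = sprintf("P%06d", seq_len(n)),
                   dose = dose, p_death = p,
                   death = stats::rbinom(n, 1, p))
  })
}

# Stage names used both for injected screen failures and the exclusion
# ledger; order is the fixed screening order.
screen_stages <- function() {
  c("age", "infection", "sofa", "ne_use", "lactate", "window",
    "demographics", "dose")
}

#' Generate a synthetic MIMIC-like septic-shock cohort
#'
#' Produces the five event tables the analysis pipeline consumes —
#' `patients`, `infusion_events`, `labs`, `infection_events`, `sofa` — plus
#' a `truth` table retaining each patient's latent base peak dose, diagnosis
#' dose, death probability and (if any) the screening criterion the patient
#' was constructed to violate. Each patient's NE stream starts at the
#' diagnosis dose, titrates up to a sustained plateau at exactly the latent
#' peak (>= 20 min, so the stability filter always accepts it), then tapers;
#' transient spikes (< 5 min, 1.3-1.8x the peak) and registry-error outlier
#' records are appended after short pump-off gaps so they never merge with a
#' stable interval.
#'
#' @param cfg A [cohort_config()].
#' @return List of class `synthetic_tables` with elements `tables` (the five
#'   tibbles), `truth`, and `config`.
#' @examples
#' sim <- generate_cohort(cohort_config(n_patients = 50, seed = 7))
#' sim$tables$patients
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  validate_cohort_config(cfg)
  n <- cfg$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  origin <- as.POSIXct("2150-01-01 00:00:00", tz = "UTC")

  # -- latent structure (substream 1)
  ln <- lognormal_from_quartiles(cfg$dose_median, cfg$dose_q1, cfg$dose_q3)
  latent <- with_seed(derive_seed(cfg$seed, 1), {
    peak <- pmin(stats::rlnorm(n, ln["meanlog"], ln["sdlog"]),
                 cfg$max_plausible_dose)
    frac <- stats::rbeta(n, cfg$diag_frac_shape[1], cfg$diag_frac_shape[2])
    p <- stats::plogis(cfg$alpha + cfg$beta * peak)
    list(peak = peak, diag = peak * frac, p = p,
         death = stats::rbinom(n, 1, p))
  })

  # -- screening-failure assignment (substream 2)
  fail <- with_seed(derive_seed(cfg$seed, 2), {
    reason <- rep(NA_character_, n)
    n_fail <- round((1 - cfg$screen_pass_rate) * n)
    if (n_fail > 0) {
      who <- sample.int(n, n_fail)
      reason[who] <- sample(screen_stages(), n_fail, replace = TRUE)
    }
    reason
  })

  # -- demographics and timeline (substream 3)
  demo <- with_seed(derive_seed(cfg$seed, 3), {
    age <- pmin(pmax(round(stats::rnorm(n, 67, 14)), 18), 99)
    wln <- lognormal_from_quartiles(79, 67, 94)
    weight <- round(stats::rlnorm(n, wln["meanlog"], wln["sdlog"]), 1)
    admit <- origin + round(stats::runif(n, 0, 365 * 24 * 3600))
    t_sepsis <- admit + round(stats::runif(n, 6, 48) * 3600)
    t_ne <- t_sepsis + round(stats::runif(n, 0.5, 6) * 3600)
    list(age = age, weight = weight, admit = admit,
         t_sepsis = t_sepsis, t_ne = t_ne)
  })

  # apply injected failures that touch demographics / timeline
  demo$age[which(fail == "age")] <-
    with_seed(derive_seed(cfg$seed, 4),
              sample(14:17, sum(fail == "age", na.rm = TRUE), replace = TRUE))
  demo$weight[which(fail == "demographics")] <- NA_real_
  iw <- which(fail == "window")
  demo$t_ne[iw] <- demo$t_sepsis[iw] -
    with_seed(derive_seed(cfg$seed, 5),
              round(stats::runif(length(iw), 13, 24) * 3600))

  # -- infusion event streams (substream 6); vectors accumulated per patient
  # and assembled once, so generation stays fast at large n.
  infusion <- with_seed(derive_seed(cfg$seed, 6), {
    offL <- vector("list", n); durL <- offL; rateL <- offL
    for (i in seq_len(n)) {
      reason_i <- fail[i]
      if (identical(reason_i, "ne_use")) next
      peak_i <- latent$peak[i]
      if (identical(reason_i, "dose")) {
        # every record beyond the outlier ceiling -> excluded downstream
        off <- 0; dur <- 120; rate <- stats::runif(1, 6, 9)
      } else {
        plateau <- stats::runif(1, 20, 120)
        rate <- c(latent$diag[i], (latent$diag[i] + peak_i) / 2, peak_i,
                  peak_i * 0.6, peak_i * 0.3)
        dur <- c(stats::runif(1, 20, 40), stats::runif(1, 15, 30), plateau,
                 stats::runif(1, 40, 80), stats::runif(1, 120, 240))
        off <- cumsum(c(0, dur[-length(dur)]))
        cursor <- sum(dur) + 5
        n_spk <- stats::rpois(1, cfg$spike_rate)
        for (k in seq_len(n_spk)) {
          sd_ <- stats::runif(1, 1, 4)
          off <- c(off, cursor); dur <- c(dur, sd_)
          rate <- c(rate, peak_i * stats::runif(1, 1.3, 1.8))
          cursor <- cursor + sd_ + 5
        }
        if (stats::runif(1) < cfg$outlier_rate) {
          off <- c(off, cursor); dur <- c(dur, 1)
          rate <- c(rate, stats::runif(1, 6, 12))
        }
      }
      offL[[i]] <- off; durL[[i]] <- dur; rateL[[i]] <- pmax(rate, 0.01)
    }
    n_seg <- lengths(offL)
    pid_idx <- rep(seq_len(n), n_seg)
    off <- unlist(offL); dur <- unlist(durL); rate <- unlist(rateL)
    absolute <- cfg$rate_unit == "ug/min" & !is.na(demo$weight[pid_idx])
    tibble::tibble(
      patient_id = ids[pid_idx], drug = "norepinephrine",
      start_time = demo$t_ne[pid_idx] + round(off * 60),
      end_time = demo$t_ne[pid_idx] + round((off + dur) * 60),
      rate = ifelse(absolute, rate * demo$weight[pid_idx], rate),
      rate_unit = ifelse(absolute, "ug/min", "ug/kg/min"))
  })

  # -- second vasopressors (substream 7)
  second <- with_seed(derive_seed(cfg$seed, 7), {
    has2 <- stats::runif(n) < cfg$second_pressor_prob & !fail %in% "ne_use"
    if (!any(has2)) return(NULL)
    idx <- which(has2)
    drug <- sample(c("vasopressin", "phenylephrine", "epinephrine"),
                   length(idx), replace = TRUE,
                   prob = c(0.55, 0.25, 0.20))
    rate <- ifelse(drug == "vasopressin", stats::runif(length(idx), 0.01, 0.04),
            ifelse(drug == "phenylephrine", stats::runif(length(idx), 0.5, 2),
                   stats::runif(length(idx), 0.02, 0.3)))
    st <- demo$t_ne[idx] + round(stats::runif(length(idx), 0, 4) * 3600)
    data.frame(patient_id = ids[idx], drug = drug, start_time = st,
               end_time = st + round(stats::runif(length(idx), 2, 12) * 3600),
               rate = rate,
               rate_unit = ifelse(drug == "vasopressin", "U/min", "ug/kg/min"),
               stringsAsFactors = FALSE)
  })
  infusion <- dplyr::arrange(
    tibble::as_tibble(dplyr::bind_rows(infusion, second)),
    .data$patient_id, .data$drug, .data$start_time)

  # -- labs (substream 8): lactate nearest NE start; covariate only loosely
  # calibrated (median ~3.2), independent of dose by construction.
  labs <- with_seed(derive_seed(cfg$seed, 8), {
    val <- 2 + stats::rlnorm(n, log(1.2), 0.9)
    val[which(fail == "lactate")] <-
      stats::runif(sum(fail == "lactate", na.rm = TRUE), 0.8, 1.9)
    tibble::tibble(patient_id = rep(ids, 2),
                   time = c(demo$t_ne, demo$t_ne + 6 * 3600),
                   lab = "lactate",
                   value = round(c(val, val * stats::runif(n, 0.8, 1.3)), 1))
  })

  # -- infection events (substream 9)
  infection <- with_seed(derive_seed(cfg$seed, 9), {
    abx_delay <- round(stats::runif(n, 1, 24) * 3600)
    tb <- tibble::tibble(
      patient_id = rep(ids, 2),
      event = rep(c("culture", "antibiotic"), each = n),
      time = c(demo$t_sepsis, demo$t_sepsis + abx_delay))
    tb[!(tb$patient_id %in% ids[which(fail == "infection")] &
           tb$event == "culture"), ]
  })

  # -- SOFA (substream 10)
  sofa <- with_seed(derive_seed(cfg$seed, 10), {
    sc <- pmin(2 + stats::rpois(n, 5), 24)
    sc2 <- pmax(sc + sample(c(-1L, 0L, 1L), n, replace = TRUE), 1L)
    sc[which(fail == "sofa")] <- 1
    sc2[which(fail == "sofa")] <- 1
    tibble::tibble(patient_id = rep(ids, 2),
                   time = c(demo$t_sepsis, demo$t_sepsis + 24 * 3600),
                   score = c(sc, sc2))
  })

  patients <- tibble::tibble(patient_id = ids, age = demo$age,
                             weight_kg = demo$weight, admit_time = demo$admit,
                             death_28d = latent$death)
  truth <- tibble::tibble(patient_id = ids,
                          base_peak_dose = latent$peak,
                          base_diagnosis_dose = latent$diag,
                          p_death = latent$p,
                          t_sepsis = demo$t_sepsis, t_shock = demo$t_ne,
                          fail_reason = fail)
  structure(list(tables = list(patients = patients,
                               infusion_events = infusion,
                               labs = labs,
                               infection_events = infection,
                               sofa = sofa),
                 truth = truth, config = cfg),
            class = "synthetic_tables")
}

#' @export
print.synthetic_tables <- function(x, ...) {
  cat("Synthetic septic-shock cohort:", x$config$n_patients, "patients\n")
  cat("  infusion events:", nrow(x$tables$infusion_events), "\n")
  cat("  mortality model: logit(p) =", signif(x$config$alpha, 5), "+",
      signif(x$config$beta, 5), "x base peak dose\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write synthetic tables to CSV with a run manifest
#'
#' Writes the five tables as RFC 4180 CSV with ISO-8601 UTC timestamps plus
#' `manifest.json` recording the generating configuration and seed.
#'
#' @param x A `synthetic_tables` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_tables <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(x$tables)) {
    tb <- x$tables[[nm]]
    for (col in names(tb)) {
      if (inherits(tb[[col]], "POSIXt")) {
        tb[[col]] <- format(tb[[col]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      }
    }
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tb, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  cfg <- unclass(x$config)
  manifest <- list(config = cfg,
                   config_hash = fnv1a_hash(jsonlite::toJSON(cfg, digits = NA)),
                   package_version = as.character(utils::packageVersion("nedose")))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read the five pipeline tables back from CSV
#'
#' @param dir Directory containing `patients.csv`, `infusion_events.csv`,
#'   `labs.csv`, `infection_events.csv`, `sofa.csv` as written by
#'   [write_tables()].
#' @return Named list of tibbles with timestamps parsed to POSIXct (UTC).
#' @export
read_tables <- function(dir) {
  nms <- c("patients", "infusion_events", "labs", "infection_events", "sofa")
  out <- list()
  for (nm in nms) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) stop("missing input table: ", p, call. = FALSE)
    tb <- tibble::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
    for (col in intersect(names(tb),
                          c("admit_time", "start_time", "end_time", "time"))) {
      tb[[col]] <- as.POSIXct(tb[[col]], format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
    }
    out[[nm]] <- tb
  }
  out
}
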