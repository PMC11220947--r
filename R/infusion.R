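# Infusion event-stream processing: weight normalization, registry-error
# exclusion, stability-filtered peak dose and diagnosis dose.

#' Normalize an absolute infusion rate by body weight
#'
#' @param rate Rate(s) in ug/min; finite, non-negative.
#' @param weight Body weight in kg; must be present and > 0.
#' @return Rate(s) in ug/kg/min.
#' @examples
#' weight_normalize(16, 80) # 0.2
#' @export
weight_normalize <- function(rate, weight) {
  check_dose(rate, "rate")
  if (any(is.na(weight)) || any(weight <= 0)) {
    stop("missing or non-positive body weight; cannot normalize rate",
         call. = FALSE)
  }
  rate / weight
}

# Validate one patient's event stream: columns, positive durations, sorted,
# non-overlapping. Returns the stream sorted by start.
validate_events <- function(events) {
  req <- c("start", "end", "rate")
  if (!all(req %in% names(events))) {
    stop("event stream needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events) == 0) return(events)
  if (any(as_minutes(events$end, events$start) <= 0)) {
    stop("data-integrity error: event with end <= start", call. = FALSE)
  }
  check_dose(events$rate, "rate")
  o <- order(as.numeric(events$start))
  events <- events[o, ]
  if (nrow(events) > 1) {
    gap <- as_minutes(events$start[-1], events$end[-nrow(events)])
    if (any(gap < -1e-9)) {
      stop("data-integrity error: overlapping infusion segments", call. = FALSE)
    }
  }
  events
}

#' Remove registry-error outlier rates
#'
#' Drops records whose weight-normalized rate exceeds a plausibility ceiling.
#' Patients left with no records are flagged for exclusion downstream
#' (absence of dose values after excluding outliers).
#'
#' @param events Event stream with columns `start`, `end`, `rate`
#'   (ug/kg/min).
#' @param max_rate Ceiling in ug/kg/min base molecule (default 5).
#' @return List with `events` (filtered stream) and `excluded` (count
#'   removed).
#' @export
exclude_outlier_rates <- function(events, max_rate = 5) {
  stopifnot(max_rate > 0)
  keep <- events$rate <= max_rate
  list(events = events[keep, , drop = FALSE], excluded = sum(!keep))
}

#' Stability-filtered peak dose in the first 24 h
#'
#' Finds the highest NE rate that can be trusted as a true peak: among the
#' distinct observed rates in the window, in descending order, the first
#' rate `r` such that the piecewise-constant rate function stays within
#' `[r(1 - stability), r(1 + stability)]` over a contiguous interval of at
#' least `min_duration_min` minutes that contains at least one record at
#' exactly `r`. Transient pump manipulations and registry spikes shorter
#' than the minimum duration therefore never qualify, and the next-highest
#' rate is tried instead. Gaps between segments count as rate 0 (infusion
#' off) and break stability intervals. Returns `NA` when no rate qualifies
#' (no stable peak; such patients hit the dose-availability exclusion).
#'
#' @param events One patient's NE stream: columns `start`, `end`
#'   (POSIXct or numeric minutes) and `rate` (ug/kg/min base).
#' @param t0 Septic shock diagnosis time (same type as `start`).
#' @param window_hours Search window after `t0` (default 24).
#' @param stability Half-width of the multiplicative stability band
#'   (default 0.10, i.e. within 10% of the candidate).
#' @param min_duration_min Minimum stable duration in minutes (default 5).
#' @return Peak dose in ug/kg/min, or `NA_real_` if no rate is stable.
#' @export
stable_peak_dose <- function(events, t0, window_hours = 24,
                             stability = 0.10, min_duration_min = 5) {
  events <- validate_events(events)
  if (nrow(events) == 0) return(NA_real_)
  s <- as_minutes(events$start, t0)
  e <- as_minutes(events$end, t0)
  W <- window_hours * 60
  keep <- e > 1e-9 & s < W - 1e-9
  s <- pmax(s[keep], 0); e <- pmin(e[keep], W); r <- events$rate[keep]
  pos <- (e - s) > 1e-9
  s <- s[pos]; e <- e[pos]; r <- r[pos]
  if (length(r) == 0 || all(r <= 0)) return(NA_real_)
  for (cand in sort(unique(r[r > 0]), decreasing = TRUE)) {
    lo <- cand * (1 - stability) - 1e-12
    hi <- cand * (1 + stability) + 1e-12
    run_len <- 0; has_exact <- FALSE; prev_end <- NA_real_
    for (i in seq_along(r)) {
      inband <- r[i] >= lo && r[i] <= hi
      if (!inband) { run_len <- 0; has_exact <- FALSE; prev_end <- NA_real_; next }
      if (!is.na(prev_end) && abs(s[i] - prev_end) < 1e-6) {
        run_len <- run_len + (e[i] - s[i])
      } else {
        run_len <- e[i] - s[i]
        has_exact <- FALSE
      }
      if (abs(r[i] - cand) < 1e-12) has_exact <- TRUE
      prev_end <- e[i]
      if (has_exact && run_len >= min_duration_min - 1e-9) return(cand)
    }
  }
  NA_real_
}

#' Diagnosis dose: the rate started or titrated closest to shock onset
#'
#' @inheritParams stable_peak_dose
#' @return Rate (ug/kg/min) of the event whose start time is nearest `t0`;
#'   ties are broken toward the earlier event. `NA` for an empty stream.
#' @export
diagnosis_dose <- function(events, t0) {
  events <- validate_events(events)
  if (nrow(events) == 0) return(NA_real_)
  d <- abs(as_minutes(events$start, t0))
  # ties toward the earlier event: events are sorted by start, and
  # which.min returns the first minimum, which is the earlier one.
  events$rate[which.min(d)]
}

#' Peak norepinephrine-equivalent rate over a window
#'
#' Sums concurrent weighted vasopressor rates as a step function and returns
#' its maximum over `[t0, t0 + window_hours]`. No stability filter is
#' applied (it is specific to the NE peak definition).
#'
#' @param events Multi-drug stream: columns `drug`, `start`, `end`, `rate`,
#'   `unit` (each drug's native unit; vasopressin in U/min).
#' @inheritParams stable_peak_dose
#' @param weights NEE weight table, see [nee_weights()].
#' @return Maximum NE-equivalent rate (ug/kg/min) in the window.
#' @export
peak_ne_equivalent <- function(events, t0, window_hours = 24,
                               weights = nee_weights()) {
  if (nrow(events) == 0) return(NA_real_)
  idx <- match(events$drug, weights$drug)
  if (anyNA(idx)) {
    stop("unknown drug(s): ",
         paste(unique(events$drug[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  if ("unit" %in% names(events)) {
    bad <- events$unit != weights$unit[idx]
    if (any(bad)) {
      stop("rate unit mismatch for ",
           paste(unique(events$drug[bad]), collapse = ", "), call. = FALSE)
    }
  }
  w <- weights$weight[idx] * events$rate
  s <- pmax(as_minutes(events$start, t0), 0)
  e <- pmin(as_minutes(events$end, t0), window_hours * 60)
  keep <- e > s
  if (!any(keep)) return(NA_real_)
  s <- s[keep]; e <- e[keep]; w <- w[keep]
  bp <- sort(unique(c(s, e)))
  mid <- (bp[-1] + bp[-length(bp)]) / 2
  tot <- vapply(mid, function(m) sum(w[s <= m & e > m]), numeric(1))
  max(tot)
}

#' Per-patient dose summaries
#'
#' Applies the full dose-extraction chain to each patient: weight
#' normalization of absolute NE rates, registry-error exclusion, the
#' stability-filtered 24-h peak, the diagnosis dose, and the peak
#' NE-equivalent rate including secondary vasopressors.
#'
#' @param infusion_events Tibble with columns `patient_id`, `drug`,
#'   `start_time`, `end_time`, `rate`, `rate_unit`.
#' @param patients Tibble with `patient_id` and `weight_kg` (needed only
#'   when NE rates are recorded in ug/min).
#' @param shock_times Tibble with `patient_id` and `t_shock`.
#' @param max_rate Outlier ceiling in ug/kg/min base, see
#'   [exclude_outlier_rates()].
#' @inheritParams stable_peak_dose
#' @param weights NEE weight table.
#' @return Tibble: `patient_id`, `peak_dose_24h`, `diagnosis_dose`,
#'   `peak_ne_equivalent_24h`, `no_stable_peak`, `outliers_excluded`.
#' @export
dose_summaries <- function(infusion_events, patients, shock_times,
                           max_rate = 5, window_hours = 24, stability = 0.10,
                           min_duration_min = 5, weights = nee_weights()) {
  out <- vector("list", nrow(shock_times))
  wtab <- stats::setNames(patients$weight_kg, patients$patient_id)
  for (i in seq_len(nrow(shock_times))) {
    pid <- shock_times$patient_id[i]
    t0 <- shock_times$t_shock[i]
    ev <- infusion_events[infusion_events$patient_id == pid, , drop = FALSE]
    ne <- ev[ev$drug == "norepinephrine", , drop = FALSE]
    rate <- ne$rate
    if (nrow(ne) > 0 && any(ne$rate_unit == "ug/min")) {
      j <- ne$rate_unit == "ug/min"
      rate[j] <- weight_normalize(ne$rate[j], wtab[[pid]])
    }
    if (nrow(ne) > 0 && any(!ne$rate_unit %in% c("ug/min", "ug/kg/min"))) {
      stop("unsupported NE rate unit for patient ", pid, call. = FALSE)
    }
    stream <- data.frame(start = ne$start_time, end = ne$end_time,
                         rate = rate)
    filt <- exclude_outlier_rates(stream, max_rate)
    peak <- stable_peak_dose(filt$events, t0, window_hours, stability,
                             min_duration_min)
    diag <- diagnosis_dose(filt$events, t0)
    other <- ev$drug != "norepinephrine"
    all_ev <- data.frame(
      drug = c(rep("norepinephrine", nrow(filt$events)), ev$drug[other]),
      start = c(filt$events$start, ev$start_time[other]),
      end = c(filt$events$end, ev$end_time[other]),
      rate = c(filt$events$rate, ev$rate[other]),
      unit = c(rep("ug/kg/min", nrow(filt$events)), ev$rate_unit[other]))
    nee <- if (nrow(all_ev) > 0) {
      peak_ne_equivalent(all_ev, t0, window_hours, weights)
    } else NA_real_
    out[[i]] <- data.frame(
      patient_id = pid, peak_dose_24h = peak, diagnosis_dose = diag,
      peak_ne_equivalent_24h = nee,
      no_stable_peak = is.na(peak), outliers_excluded = filt$excluded)
  }
  tibble::as_tibble(dplyr::bind_rows(out))
}
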