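# Fixtures and independent oracles used across test files.

# Build an event stream from offsets in minutes (numeric times, t0 = 0).
make_events <- function(start, dur, rate) {
  data.frame(start = start, end = start + dur, rate = rate)
}

# Independent brute-force peak scanner: enumerates every candidate interval
# [start_i, end_j] of the step function and checks the stability definition
# directly. O(n^2) per candidate rate; only for small streams.
brute_force_peak <- function(events, t0 = 0, window_hours = 24,
                             stability = 0.10, min_dur = 5) {
  s <- pmax(as.numeric(events$start) - t0, 0)
  e <- pmin(as.numeric(events$end) - t0, window_hours * 60)
  keep <- e > s
  s <- s[keep]; e <- e[keep]; r <- events$rate[keep]
  o <- order(s); s <- s[o]; e <- e[o]; r <- r[o]
  if (!length(r)) return(NA_real_)
  qualifies <- function(cand) {
    lo <- cand * (1 - stability) - 1e-12
    hi <- cand * (1 + stability) + 1e-12
    n <- length(r)
    for (i in seq_len(n)) {
      for (j in i:n) {
        segs <- i:j
        if (j > i &&
            any(abs(s[segs][-1] - e[segs][-length(segs)]) > 1e-6)) next
        if (any(r[segs] < lo | r[segs] > hi)) next
        if (!any(abs(r[segs] - cand) < 1e-12)) next
        if (e[j] - s[i] >= min_dur - 1e-9) return(TRUE)
      }
    }
    FALSE
  }
  for (cand in sort(unique(r[r > 0]), decreasing = TRUE)) {
    if (qualifies(cand)) return(cand)
  }
  NA_real_
}

# Random small stream: <= 10 segments, rates clustered so near-misses of the
# 10% band actually occur, occasional gaps between segments.
random_stream <- function(seed) {
  set.seed(seed)
  n <- sample(3:10, 1)
  rates <- sample(c(0.1, 0.2, 0.21, 0.22, 0.3, 0.32, 0.5, 0.53, 1.0, 1.06),
                  n, replace = TRUE)
  dur <- round(runif(n, 1, 12), 2)
  gap <- ifelse(runif(n) < 0.35, round(runif(n, 0.5, 10), 2), 0)
  start <- cumsum(c(0, (dur + gap)[-n]))
  make_events(start, dur, rates)
}

# Hand-built six-patient screening fixture: A, B, C pass; D fails the NE
# start window, E is missing weight (demographics), F has only an outlier
# dose record (dose availability).
six_patient_tables <- function() {
  t0 <- as.POSIXct("2150-06-01 00:00:00", tz = "UTC")
  ids <- c("A", "B", "C", "D", "E", "F")
  h <- 3600
  t_sepsis <- t0 + (seq_along(ids) - 1) * 240 * h
  t_ne <- t_sepsis + 2 * h
  t_ne[4] <- t_sepsis[4] - 13 * h # window violation
  weight <- c(80, 80, 80, 80, NA, 80)
  rate <- c(0.3, 0.2, 0.4, 0.3, 0.3, 7) # F: outlier only
  patients <- tibble::tibble(
    patient_id = ids, age = 60, weight_kg = weight,
    admit_time = t_sepsis - 12 * h,
    death_28d = c(0L, 1L, 0L, 0L, 1L, 0L))
  infusion_events <- tibble::tibble(
    patient_id = ids, drug = "norepinephrine",
    start_time = t_ne, end_time = t_ne + h,
    rate = rate, rate_unit = "ug/kg/min")
  labs <- tibble::tibble(patient_id = ids, time = t_ne,
                         lab = "lactate", value = 3)
  infection_events <- tibble::tibble(
    patient_id = rep(ids, 2),
    event = rep(c("culture", "antibiotic"), each = length(ids)),
    time = c(t_sepsis, t_sepsis + 2 * h))
  sofa <- tibble::tibble(patient_id = ids, time = t_sepsis, score = 7)
  list(patients = patients, infusion_events = infusion_events, labs = labs,
       infection_events = infection_events, sofa = sofa)
}

# Construct a minimal dose_response_fit object with known coefficients and
# zero coefficient uncertainty, for closed-form prediction checks.
fixed_fit <- function(alpha, beta, registry = ne_formulations()) {
  est <- tibble::tibble(formulation = registry$formulation,
                        factor = registry$factor,
                        alpha = alpha, beta = beta / registry$factor,
                        or = exp(beta / registry$factor))
  vc <- lapply(seq_len(nrow(registry)), function(i) matrix(0, 2, 2))
  names(vc) <- registry$formulation
  structure(list(estimates = est, vcov = vc, variant = "per_formulation",
                 converged = TRUE, n_patients = NA_integer_,
                 re_variance = NA_real_),
            class = "dose_response_fit")
}

# Cohort tibble from the bare dose/mortality simulator, shaped for
# stack_formulations().
sim_cohort <- function(n, alpha, beta, dose_median = 0.1, dose_q1 = 0.05,
                       dose_q3 = 0.2, seed = 1) {
  sim <- simulate_dose_mortality(n, alpha, beta, dose_median, dose_q1,
                                 dose_q3, seed)
  tibble::tibble(patient_id = sim$patient_id,
                 diagnosis_dose = sim$dose, peak_dose_24h = sim$dose,
                 death_28d = sim$death)
}

diagnosis_anchors <- function() data.frame(dose = c(0.1, 1), p = c(0.36, 0.81))
peak_anchors <- function() data.frame(dose = c(0.1, 1), p = c(0.27, 0.83))
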