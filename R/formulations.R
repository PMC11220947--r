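#' Norepinephrine formulation registry
#'
#' Norepinephrine is marketed both as its active base molecule and as several
#' salts (hydrochloride, bitartrate, tartrate) that contain proportionally
#' less base per milligram. A dose reported on the salt scale equals the base
#' dose multiplied by the formulation's conversion factor: 1.22 for
#' hydrochloride, 1.89 for bitartrate and 2 for tartrate. The registry ships
#' as a plain-text config file and can be replaced or extended by pointing
#' `file` at a CSV with columns `formulation` and `factor`.
#'
#' @param file Optional path to a CSV registry; defaults to the file shipped
#'   with the package.
#' @return A tibble with columns `formulation` (character) and `factor`
#'   (numeric multiplier from base to reported salt dose).
#' @examples
#' ne_formulations()
#' @export
ne_formulations <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "formulations.csv", package = "nedose")
  }
  reg <- tibble::as_tibble(utils::read.csv(file, stringsAsFactors = FALSE))
  if (!all(c("formulation", "factor") %in% names(reg))) {
    stop("formulation registry must have columns 'formulation' and 'factor'",
         call. = FALSE)
  }
  if (anyDuplicated(reg$formulation)) {
    stop("duplicate formulation names in registry", call. = FALSE)
  }
  if (!"base" %in% reg$formulation || reg$factor[reg$formulation == "base"] != 1) {
    stop("registry must contain 'base' with factor exactly 1", call. = FALSE)
  }
  if (any(!is.finite(reg$factor)) || any(reg$factor < 1)) {
    stop("conversion factors must be finite and >= 1", call. = FALSE)
  }
  reg[, c("formulation", "factor")]
}

# Resolve formulation names to conversion factors, with a helpful error.
formulation_factor <- function(formulation, registry = ne_formulations()) {
  idx <- match(formulation, registry$formulation)
  if (anyNA(idx)) {
    bad <- unique(formulation[is.na(idx)])
    stop("unknown formulation(s): ", paste(bad, collapse = ", "),
         "; registry has: ", paste(registry$formulation, collapse = ", "),
         call. = FALSE)
  }
  registry$factor[idx]
}

check_dose <- function(dose, what = "dose") {
  if (!is.numeric(dose)) stop(what, " must be numeric", call. = FALSE)
  bad <- !is.finite(dose) | dose < 0
  if (any(bad)) {
    stop("invalid ", what, ": ",
         paste(format(dose[bad]), collapse = ", "),
         " (must be finite and >= 0)", call. = FALSE)
  }
  invisible(dose)
}

#' Convert a base-molecule dose to a salt-reported dose
#'
#' @param dose_base Base-molecule dose(s) in ug/kg/min; finite, non-negative.
#' @param formulation Formulation name(s) from the registry
#'   (`"base"`, `"hydrochloride"`, `"bitartrate"`, `"tartrate"` by default).
#' @param registry Formulation registry, see [ne_formulations()].
#' @return Dose(s) on the reported-salt scale, ug/kg/min.
#' @examples
#' to_salt(0.24, "tartrate") # 0.48
#' @seealso [to_base()]
#' @export
to_salt <- function(dose_base, formulation, registry = ne_formulations()) {
  check_dose(dose_base, "dose_base")
  dose_base * formulation_factor(formulation, registry)
}

#' Convert a salt-reported dose back to the base molecule
#'
#' Inverse of [to_salt()]: divides by the formulation's conversion factor, so
#' `to_base(to_salt(d, f), f)` recovers `d` up to floating-point rounding.
#'
#' @param dose_reported Reported dose(s) in ug/kg/min on the salt scale.
#' @inheritParams to_salt
#' @return Base-molecule dose(s), ug/kg/min.
#' @examples
#' to_base(2, "tartrate") # 1
#' @export
to_base <- function(dose_reported, formulation, registry = ne_formulations()) {
  check_dose(dose_reported, "dose_reported")
  dose_reported / formulation_factor(formulation, registry)
}

#' Norepinephrine-equivalent weight table
#'
#' Weights for expressing a multi-vasopressor regimen as a single
#' norepinephrine-equivalent rate (ug/kg/min). Defaults are transcribed from
#' the updated equivalence formulas of Kotani et al. (2023, Critical Care);
#' each drug's weight applies to its native rate unit (vasopressin in U/min,
#' everything else in ug/kg/min). Override by supplying your own CSV with
#' columns `drug`, `weight`, `unit`.
#'
#' @param file Optional path to a replacement weight table.
#' @return Tibble with columns `drug`, `weight`, `unit`.
#' @examples
#' nee_weights()
#' @export
nee_weights <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "nee_weights.csv", package = "nedose")
  }
  w <- tibble::as_tibble(utils::read.csv(file, stringsAsFactors = FALSE))
  if (!all(c("drug", "weight", "unit") %in% names(w))) {
    stop("weight table must have columns 'drug', 'weight', 'unit'", call. = FALSE)
  }
  if (any(!is.finite(w$weight)) || any(w$weight <= 0)) {
    stop("all NEE weights must be finite and > 0", call. = FALSE)
  }
  ne <- w$weight[w$drug == "norepinephrine"]
  if (length(ne) != 1 || ne != 1) {
    stop("weight table must give norepinephrine weight exactly 1", call. = FALSE)
  }
  w[, c("drug", "weight", "unit")]
}

#' Norepinephrine-equivalent score of a vasopressor regimen
#'
#' Weighted sum of concurrent vasopressor rates, expressing the regimen as a
#' single NE-equivalent rate. Equals the norepinephrine rate when NE is the
#' only drug running.
#'
#' @param rates Named numeric vector of rates, names are drug names; each
#'   rate in the drug's native unit.
#' @param units Optional named character vector declaring the unit of each
#'   rate; any mismatch with the weight table's native unit is an error
#'   (units are never silently converted).
#' @param weights Weight table, see [nee_weights()].
#' @return NE-equivalent rate in ug/kg/min.
#' @examples
#' ne_equivalent(c(norepinephrine = 0.2, phenylephrine = 1, vasopressin = 0.04))
#' @export
ne_equivalent <- function(rates, units = NULL, weights = nee_weights()) {
  if (length(rates) == 0) return(0)
  if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
    stop("rates must be a named vector (names are drug names)", call. = FALSE)
  }
  check_dose(rates, "rate")
  idx <- match(names(rates), weights$drug)
  if (anyNA(idx)) {
    stop("unknown drug(s): ", paste(names(rates)[is.na(idx)], collapse = ", "),
         "; weight table has: ", paste(weights$drug, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(units)) {
    declared <- units[names(rates)]
    native <- weights$unit[idx]
    bad <- !is.na(declared) & declared != native
    if (any(bad)) {
      stop("rate unit mismatch for ", paste(names(rates)[bad], collapse = ", "),
           ": declared ", paste(declared[bad], collapse = ", "),
           ", native ", paste(native[bad], collapse = ", "), call. = FALSE)
    }
  }
  sum(weights$weight[idx] * rates)
}
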