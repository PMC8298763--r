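# Per-day medication exposure reconstruction and levodopa-equivalent-dose
# (LED) conversion. Dispensing events are spread into daily mg at each
# claim's own rate (quantity x strength / days supply) over a half-open
# interval of days-supply days; the LED channel sums all anti-PD drugs via
# per-drug conversion factors, with catechol-O-methyltransferase (COMT)
# adjuncts contributing a multiple of the concurrent daily levodopa dose.

DRUG_CLASSES <- c("LEVODOPA_IR", "LEVODOPA_CR", "COMT_ADJUNCT",
                  "DOPAMINE_AGONIST", "MAOB", "OTHER_PD")

#' Read a drug reference (LED conversion) table
#'
#' YAML mapping drug id to drug class, LED conversion factor (a flat
#' multiplier on daily mg, or for COMT adjuncts a multiplier applied to the
#' concurrent daily levodopa dose) and whether the drug's mg count toward
#' the plain-levodopa channel. The shipped default
#' (`system.file("extdata", "drug_reference.yaml", package = "apdclaims")`)
#' transcribes the standard per-drug factors from the systematic-review
#' conversion algorithm used throughout the PD literature (levodopa
#' immediate-release x1.0, controlled-release x0.75, entacapone 0.33 x
#' concurrent levodopa, pramipexole x100, ropinirole x20, ...). Strengths
#' for carbidopa/levodopa combination products are interpreted as mg of the
#' levodopa moiety per unit. The table is user-editable.
#'
#' @param path YAML file; defaults to the shipped table.
#' @return data.frame with columns `drug_id`, `drug_class`, `led_factor`
#'   (`NA` for COMT adjuncts), `comt_multiplier` (`NA` otherwise) and
#'   `counts_as_levodopa`.
#' @export
read_drug_reference <- function(path = default_drug_reference()) {
  if (!file.exists(path)) stopf("drug reference file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stopf("drug reference %s is empty", path)
  rows <- lapply(names(raw), function(id) {
    b <- raw[[id]]
    cls <- toupper(b$class %||% stop("drug '", id, "' missing class"))
    if (!cls %in% DRUG_CLASSES) {
      stopf("drug '%s': unknown class '%s'", id, cls)
    }
    is_comt <- cls == "COMT_ADJUNCT"
    fac <- if (is_comt) NA_real_ else as.numeric(b$led_factor %||% NA_real_)
    mult <- if (is_comt) as.numeric(b$comt_multiplier %||% NA_real_)
            else NA_real_
    if (!is_comt && (is.na(fac) || fac < 0)) {
      stopf("drug '%s': led_factor must be a nonnegative number", id)
    }
    if (is_comt && (is.na(mult) || mult < 0)) {
      stopf("drug '%s': COMT adjuncts need a nonnegative comt_multiplier", id)
    }
    data.frame(drug_id = id, drug_class = cls, led_factor = fac,
               comt_multiplier = mult,
               counts_as_levodopa = isTRUE(b$counts_as_levodopa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname read_drug_reference
#' @export
default_drug_reference <- function() {
  system.file("extdata", "drug_reference.yaml", package = "apdclaims")
}

#' Reconstruct per-drug per-day dosing from dispensing events
#'
#' Each claim dispenses `quantity * strength_mg` total mg intended to last
#' `days_supply` days, i.e. a daily rate of
#' `quantity * strength_mg / days_supply`, spread over a half-open interval
#' of `days_supply` days starting at the fill date (a 30-day supply filled
#' on day d covers days d..d+29). Coverage is truncated to the study
#' period. Different drugs always sum on shared days; overlapping fills of
#' the *same* drug are resolved by `overlap_policy`:
#'
#' * `"push_forward"` (default): an early refill starts the day after the
#'   earlier supply is exhausted, so stockpiling extends coverage rather
#'   than doubling the daily dose;
#' * `"sum_overlap"`: overlapping supplies add.
#'
#' @param claims pharmacy claims for a single patient (as returned by
#'   [read_pharmacy_claims()]).
#' @param ref drug reference table from [read_drug_reference()].
#' @param period a [study_period()].
#' @param overlap_policy `"push_forward"` or `"sum_overlap"`.
#' @param lookback if `TRUE`, claims filled before the period start
#'   contribute their in-period coverage days; if `FALSE` (default,
#'   matching a single-calendar-year study) such claims are skipped.
#' @return numeric matrix, one row per drug dispensed (rownames = drug
#'   ids), one column per period day; mg supplied on that day.
#' @export
build_daily_dose <- function(claims, ref, period,
                             overlap_policy = c("push_forward",
                                                "sum_overlap"),
                             lookback = FALSE) {
  overlap_policy <- match.arg(overlap_policy)
  claims <- as.data.frame(claims)
  n_days <- period$n_days
  if (nrow(claims) == 0) {
    return(matrix(0, nrow = 0, ncol = n_days,
                  dimnames = list(character(), NULL)))
  }
  if (length(unique(claims$patient_id)) > 1L) {
    stopf("build_daily_dose expects claims for a single patient")
  }
  unknown <- setdiff(unique(claims$drug_id), ref$drug_id)
  if (length(unknown) > 0) {
    stopf("drug id(s) not in the drug reference: %s",
          paste(unknown, collapse = ", "))
  }

  day0 <- as.integer(claims$fill_date - period$start_date) + 1L
  drop <- day0 > n_days | (day0 + claims$days_supply - 1L) < 1L |
    (!lookback & day0 < 1L)
  if (any(drop)) {
    message(sprintf("skipping %d claim(s) outside the study period",
                    sum(drop)))
    claims <- claims[!drop, , drop = FALSE]
    day0 <- day0[!drop]
  }

  drugs <- sort(unique(claims$drug_id))
  dose <- matrix(0, nrow = length(drugs), ncol = n_days,
                 dimnames = list(drugs, NULL))
  for (d in drugs) {
    idx <- which(claims$drug_id == d)
    idx <- idx[order(day0[idx])]
    prev_end <- -.Machine$integer.max
    for (i in idx) {
      ds <- claims$days_supply[i]
      rate <- claims$quantity[i] * claims$strength_mg[i] / ds
      start <- if (overlap_policy == "push_forward") {
        max(day0[i], prev_end + 1L)
      } else {
        day0[i]
      }
      end <- start + ds - 1L
      lo <- max(start, 1L)
      hi <- min(end, n_days)
      if (lo <= hi) dose[d, lo:hi] <- dose[d, lo:hi] + rate
      if (overlap_policy == "push_forward") prev_end <- max(prev_end, end)
    }
  }
  dose
}

#' Construct a per-patient daily dose series
#'
#' Container for the two daily channels the classifier consumes: plain
#' levodopa mg (the levodopa moiety only) and the levodopa-equivalent dose.
#'
#' @param patient_id patient identifier.
#' @param period a [study_period()].
#' @param levodopa_mg,led_mg nonnegative numeric vectors, one entry per
#'   period day.
#' @return a `dose_series` object.
#' @export
dose_series <- function(patient_id, period, levodopa_mg, led_mg) {
  if (length(levodopa_mg) != period$n_days ||
      length(led_mg) != period$n_days) {
    stopf("dose series length must equal the %d period days", period$n_days)
  }
  if (any(levodopa_mg < 0) || any(led_mg < 0)) {
    stopf("daily doses must be nonnegative")
  }
  structure(list(patient_id = patient_id, period = period,
                 levodopa_mg = as.numeric(levodopa_mg),
                 led_mg = as.numeric(led_mg)),
            class = "dose_series")
}

#' @export
print.dose_series <- function(x, ...) {
  cat(sprintf(paste0("<dose_series> patient %s, %d days; ",
                     "mean levodopa %.1f mg/day, mean LED %.1f mg/day\n"),
              x$patient_id, x$period$n_days, mean(x$levodopa_mg),
              mean(x$led_mg)))
  invisible(x)
}

#' Convert per-drug daily dosing to levodopa and LED channels
#'
#' The levodopa channel sums daily mg over drugs flagged
#' `counts_as_levodopa`. The LED channel sums `led_factor * mg` over
#' flat-factor drugs, plus, for each COMT adjunct, `comt_multiplier *`
#' concurrent daily levodopa mg on the days the adjunct is supplied (an
#' adjunct on a day with no levodopa contributes nothing).
#'
#' @param daily_dose per-drug per-day mg matrix from [build_daily_dose()].
#' @param ref drug reference table.
#' @param patient_id identifier stored in the result.
#' @param period the [study_period()] the matrix spans.
#' @return a [dose_series()].
#' @export
compute_led_series <- function(daily_dose, ref, patient_id, period) {
  if (ncol(daily_dose) != period$n_days) {
    stopf("daily_dose has %d columns; period has %d days",
          ncol(daily_dose), period$n_days)
  }
  drugs <- rownames(daily_dose)
  unknown <- setdiff(drugs, ref$drug_id)
  if (length(unknown) > 0) {
    stopf("drug id(s) not in the drug reference: %s",
          paste(unknown, collapse = ", "))
  }
  r <- ref[match(drugs, ref$drug_id), , drop = FALSE]
  if (any(!is.na(r$led_factor) & r$led_factor < 0)) {
    stopf("negative led_factor in drug reference")
  }

  levodopa <- rep(0, period$n_days)
  led <- rep(0, period$n_days)
  for (i in seq_along(drugs)) {
    mg <- daily_dose[i, ]
    if (r$counts_as_levodopa[i]) levodopa <- levodopa + mg
    if (r$drug_class[i] != "COMT_ADJUNCT") {
      led <- led + r$led_factor[i] * mg
    }
  }
  # COMT adjuncts second: they need the completed levodopa channel
  for (i in seq_along(drugs)) {
    if (r$drug_class[i] == "COMT_ADJUNCT") {
      led <- led + r$comt_multiplier[i] * levodopa * (daily_dose[i, ] > 0)
    }
  }
  dose_series(patient_id, period, levodopa, led)
}

#' Rolling window average of a daily series
#'
#' Means over every run of `window_days` consecutive days fully inside the
#' series ("any 30-day period": windows slide by one day, no calendar
#' alignment; zero-dose days count in the mean). Uses a sliding-sum
#' implementation.
#'
#' @param series numeric daily series.
#' @param window_days window length in days (default 30).
#' @return numeric vector of length `length(series) - window_days + 1`;
#'   entry i is the mean of days i..i+window_days-1.
#' @export
rolling_window_average <- function(series, window_days = 30L) {
  n <- length(series)
  window_days <- as.integer(window_days)
  if (window_days < 1L) stopf("window_days must be positive")
  if (n < window_days) {
    stopf("series has %d days; at least %d required for a %d-day window",
          n, window_days, window_days)
  }
  out <- data.table::frollmean(series, window_days, align = "left")
  out[seq_len(n - window_days + 1L)]
}
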