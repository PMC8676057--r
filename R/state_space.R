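#' Convert ETDRS letters to logMAR
#'
#' Standard chart geometry: 5 ETDRS letters per 0.1 logMAR line, with 85
#' letters anchored at logMAR 0.0, i.e. \code{logMAR = (85 - letters) / 50}.
#' This conversion reproduces the published DME/PM utility ladder exactly at
#' the band anchors 75, 60, 45, 30 and 15 letters.
#'
#' @param letters numeric vector of ETDRS letter scores, each in [0, 100].
#' @return numeric vector of logMAR values.
#' @examples
#' letters_to_logmar(85) # 0
#' letters_to_logmar(75) # 0.2
#' @export
letters_to_logmar <- function(letters) {
  stopifnot(is.numeric(letters))
  if (any(!is.finite(letters)) || any(letters < 0) || any(letters > 100)) {
    stop("`letters` must be finite and within [0, 100]", call. = FALSE)
  }
  (85 - letters) / 50
}

#' Map logMAR visual acuity to a health utility
#'
#' Linear time-trade-off valuation \code{utility = 0.828 - 0.359 * logMAR},
#' clamped to [0, 1]. The clamp is a guard for extreme inputs; it is never
#' active over the clinically relevant range logMAR 0.2-1.4.
#'
#' @param logmar numeric vector of logMAR values, each >= 0.
#' @return numeric vector of utilities in [0, 1].
#' @examples
#' utility_from_logmar(0.2) # 0.7562
#' utility_from_logmar(1.4) # 0.3254
#' @export
utility_from_logmar <- function(logmar) {
  stopifnot(is.numeric(logmar))
  if (any(!is.finite(logmar)) || any(logmar < 0)) {
    stop("`logmar` must be finite and non-negative", call. = FALSE)
  }
  pmin(1, pmax(0, 0.828 - 0.359 * logmar))
}

#' Construct a single BCVA-band health state
#'
#' @param name state label.
#' @param letters_low exclusive lower letter bound (`-Inf` for an open
#'   blindness band).
#' @param letters_high inclusive upper letter bound (`Inf` for the open
#'   best-vision band).
#' @param utility health utility in [0, 1].
#' @param baseline_share baseline cohort share in [0, 1].
#' @return an object of class `health_state`.
#' @export
health_state <- function(name, letters_low, letters_high, utility,
                         baseline_share) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(utility) || utility < 0 || utility > 1) {
    stop("utility must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(baseline_share) || baseline_share < 0 || baseline_share > 1) {
    stop("baseline_share must lie in [0, 1]", call. = FALSE)
  }
  if (is.finite(letters_low) && is.finite(letters_high) &&
      letters_low >= letters_high) {
    stop("letters_low must be below letters_high", call. = FALSE)
  }
  structure(
    list(name = name, letters_low = letters_low, letters_high = letters_high,
         utility = utility, baseline_share = baseline_share),
    class = "health_state"
  )
}

#' Assemble and validate a BCVA state space
#'
#' States are ordered from best vision to worst. Baseline shares are
#' renormalized to sum exactly to 1; a raw sum differing from 1 by more than
#' 1e-6 (e.g. the AMD baseline table summing to 0.9999) triggers a warning
#' recording the raw sum. Sums outside [1 - 5e-4, 1 + 5e-4] are rejected as
#' inconsistent rather than rounded.
#'
#' @param disease one of `"AMD"`, `"DME"`, `"PM"`.
#' @param states list of [health_state()] objects, best vision first.
#' @return an object of class `state_space` with elements `disease`,
#'   `states`, and convenience vectors `utilities`, `baseline_shares`,
#'   `state_names`.
#' @export
state_space <- function(disease, states) {
  disease <- match.arg(disease, c("AMD", "DME", "PM"))
  stopifnot(is.list(states), length(states) >= 2L)
  if (!all(vapply(states, inherits, logical(1), "health_state"))) {
    stop("all elements of `states` must be health_state objects", call. = FALSE)
  }
  util <- vapply(states, `[[`, numeric(1), "utility")
  if (any(diff(util) > 0)) {
    stop("utilities must be non-increasing from best to worst state",
         call. = FALSE)
  }
  hi <- vapply(states, `[[`, numeric(1), "letters_high")
  if (any(diff(hi[is.finite(hi)]) >= 0)) {
    stop("letter bands must strictly decrease from best to worst state",
         call. = FALSE)
  }
  share <- vapply(states, `[[`, numeric(1), "baseline_share")
  raw_sum <- sum(share)
  if (abs(raw_sum - 1) > 5e-4) {
    stop(sprintf("baseline shares sum to %.6f; expected 1 within 5e-4",
                 raw_sum), call. = FALSE)
  }
  if (abs(raw_sum - 1) > 1e-6) {
    warning(sprintf(
      "baseline shares for %s sum to %.4f; renormalizing to 1", disease,
      raw_sum), call. = FALSE)
  }
  share <- share / raw_sum
  for (i in seq_along(states)) states[[i]]$baseline_share <- share[i]
  structure(
    list(disease = disease, states = states,
         state_names = vapply(states, `[[`, character(1), "name"),
         utilities = util, baseline_shares = share),
    class = "state_space"
  )
}

# Band definitions: name, exclusive lower bound, inclusive upper bound,
# baseline share ("/" rows carry share 0 but remain reachable states).
.band_table <- function(disease) {
  switch(disease,
    AMD = list(
      names = c("No visual impairment", "Slight visual impairment",
                "Mild visual impairment", "Moderate visual impairment",
                "Severe visual impairment", "Blindness"),
      low  = c(78, 68, 53, 33, 18, -Inf),
      high = c(Inf, 78, 68, 53, 33, 18),
      share = c(0, 0.1111, 0.3827, 0.3210, 0.1728, 0.0123)
    ),
    DME = list(
      names = c("No visual impairment", "Mild visual impairment",
                "Moderate visual impairment", "Severe visual impairment",
                "Blindness"),
      low  = c(75, 60, 45, 30, -Inf),
      high = c(Inf, 75, 60, 45, 30),
      share = c(0, 0.436, 0.419, 0.117, 0.028)
    ),
    PM = list(
      names = c("No visual impairment", "Mild visual impairment",
                "Moderate visual impairment", "Severe visual impairment",
                "Blindness"),
      low  = c(75, 60, 45, 30, -Inf),
      high = c(Inf, 75, 60, 45, 30),
      share = c(0, 0.2938, 0.4463, 0.2034, 0.0565)
    ),
    stop(sprintf("unknown disease '%s'", disease), call. = FALSE)
  )
}

# Published AMD utilities (literature lookup, not the linear formula).
.amd_utilities <- c(0.9, 0.85, 0.81, 0.57, 0.52, 0.4)

# DME/PM utility anchors: each band valued at its inclusive upper letter
# bound; the open blindness band continues the 15-letter spacing (15 letters,
# logMAR 1.4), which matches the published 0.3254.
.formula_anchor_letters <- c(75, 60, 45, 30, 15)

#' Build the health state space for a disease
#'
#' AMD has six states with literature utilities (0.9, 0.85, 0.81, 0.57, 0.52,
#' 0.4); DME and PM have five states valued by the linear logMAR formula at
#' band anchors 75, 60, 45, 30, 15 letters (logMAR 0.2 to 1.4 in steps of
#' 0.3). Baseline shares come from the built-in baseline visual acuity
#' distributions; the best-vision state starts empty but can be reached by
#' improvement.
#'
#' @param disease one of `"AMD"`, `"DME"`, `"PM"`.
#' @param utility_source `"lookup"` (AMD literature values) or `"formula"`
#'   (linear logMAR valuation); the default `"auto"` picks lookup for AMD and
#'   the formula for DME/PM.
#' @return a [state_space()] object.
#' @examples
#' build_state_space("DME")$utilities
#' @export
build_state_space <- function(disease,
                              utility_source = c("auto", "formula", "lookup")) {
  disease <- match.arg(disease, c("AMD", "DME", "PM"))
  utility_source <- match.arg(utility_source)
  if (utility_source == "auto") {
    utility_source <- if (disease == "AMD") "lookup" else "formula"
  }
  bt <- .band_table(disease)
  k <- length(bt$names)
  util <- if (utility_source == "lookup") {
    if (disease != "AMD") {
      stop("lookup utilities are only published for AMD", call. = FALSE)
    }
    .amd_utilities
  } else {
    if (disease == "AMD") {
      stop("AMD utilities come from the literature lookup, not the formula",
           call. = FALSE)
    }
    utility_from_logmar(letters_to_logmar(.formula_anchor_letters))
  }
  states <- lapply(seq_len(k), function(i) {
    health_state(bt$names[i], bt$low[i], bt$high[i], util[i], bt$share[i])
  })
  state_space(disease, states)
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> %s, %d BCVA-band states\n", x$disease,
              length(x$states)))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.state_space <- function(x, ...) {
  data.frame(
    state = x$state_names,
    letters_low = vapply(x$states, `[[`, numeric(1), "letters_low"),
    letters_high = vapply(x$states, `[[`, numeric(1), "letters_high"),
    utility = x$utilities,
    baseline_share = x$baseline_shares,
    stringsAsFactors = FALSE
  )
}
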