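#' Annual BCVA letter-change outcome distribution
#'
#' Probabilities of the annual treatment outcome categories for one drug and
#' disease. AMD and DME use three categories (gain 15 letters, unchanged,
#' lose 15); PM uses five (adding gain/loss of 30 letters).
#'
#' @param drug drug label, e.g. `"conbercept"`.
#' @param disease one of `"AMD"`, `"DME"`, `"PM"`.
#' @param probs named numeric vector with names among `"+30"`, `"+15"`,
#'   `"0"`, `"-15"`, `"-30"`; AMD/DME restricted to the middle three.
#' @return an object of class `outcome_distribution`.
#' @export
outcome_distribution <- function(drug, disease, probs) {
  disease <- match.arg(disease, c("AMD", "DME", "PM"))
  allowed <- if (disease == "PM") c("+30", "+15", "0", "-15", "-30")
             else c("+15", "0", "-15")
  if (is.null(names(probs)) || !all(names(probs) %in% allowed)) {
    stop(sprintf("outcome categories for %s must be among {%s}", disease,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop("outcome probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(drug = drug, disease = disease, probs = probs),
            class = "outcome_distribution")
}

#' Renormalize an outcome distribution to sum exactly to 1
#'
#' Rounded published probabilities can miss 1 by a rounding residue (the PM
#' ranibizumab column sums to 0.9998). Sums within [0.99, 1.01] are divided
#' through; larger deviations signal a typo-level inconsistency and error.
#' Deviations beyond 1e-6 log a warning with the raw sum.
#'
#' @param raw an [outcome_distribution()].
#' @return the renormalized `outcome_distribution`.
#' @export
normalize_outcomes <- function(raw) {
  stopifnot(inherits(raw, "outcome_distribution"))
  s <- sum(raw$probs)
  if (s < 0.99 || s > 1.01) {
    stop(sprintf(
      "outcome probabilities for %s/%s sum to %.4f; outside [0.99, 1.01]",
      raw$drug, raw$disease, s), call. = FALSE)
  }
  if (abs(s - 1) > 1e-6) {
    warning(sprintf("outcome probabilities for %s/%s sum to %.4f; renormalizing",
                    raw$drug, raw$disease, s), call. = FALSE)
  }
  raw$probs <- raw$probs / s
  raw
}

#' Build an annual state-to-state transition matrix
#'
#' Letter-change categories map to band shifts on the severity ladder
#' (states ordered best to worst): +15 letters is a one-band improvement,
#' -15 a one-band worsening, and the PM-only +/-30 categories are two-band
#' shifts, applied uniformly even where AMD bands are 10 or 20 letters wide.
#' A shift that would leave the ladder is folded into the nearest feasible
#' destination, so improvement from the best state and worsening from
#' blindness add to the stay probability and no mass is lost at the
#' boundaries. With `blindness_absorbing = TRUE` the worst state instead
#' keeps all its mass (an alternative reading of the model diagrams).
#'
#' @param outcomes an [outcome_distribution()]; renormalized internally.
#' @param space the matching [state_space()].
#' @param blindness_absorbing logical; default `FALSE` (blindness can
#'   improve like any other state).
#' @return an object of class `transition_matrix`: list with `disease` and
#'   the row-stochastic `matrix` (rows = origin, columns = destination).
#' @examples
#' sp <- build_state_space("DME")
#' od <- outcome_distribution("conbercept", "DME",
#'                            c("+15" = 0.25, "0" = 0.7232, "-15" = 0.0268))
#' build_transition_matrix(od, sp)$matrix
#' @export
build_transition_matrix <- function(outcomes, space,
                                    blindness_absorbing = FALSE) {
  stopifnot(inherits(outcomes, "outcome_distribution"),
            inherits(space, "state_space"))
  if (outcomes$disease != space$disease) {
    stop(sprintf("outcome distribution is for %s but state space is for %s",
                 outcomes$disease, space$disease), call. = FALSE)
  }
  outcomes <- normalize_outcomes(outcomes)
  k <- length(space$states)
  shifts <- c("+30" = -2L, "+15" = -1L, "0" = 0L, "-15" = 1L, "-30" = 2L)
  m <- matrix(0, k, k, dimnames = list(space$state_names, space$state_names))
  for (i in seq_len(k)) {
    for (cat in names(outcomes$probs)) {
      j <- min(max(i + shifts[[cat]], 1L), k) # fold into nearest feasible
      m[i, j] <- m[i, j] + outcomes$probs[[cat]]
    }
  }
  if (blindness_absorbing) {
    m[k, ] <- 0
    m[k, k] <- 1
  }
  structure(list(disease = space$disease, drug = outcomes$drug, matrix = m),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %s / %s (%dx%d, row-stochastic)\n",
              x$disease, x$drug, nrow(x$matrix), ncol(x$matrix)))
  print(round(x$matrix, 4))
  invisible(x)
}

#' @export
as.matrix.transition_matrix <- function(x, ...) x$matrix

#' Export a transition matrix as CSV
#'
#' One row per origin state; the header carries the destination state names.
#'
#' @param x a `transition_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(x, path) {
  stopifnot(inherits(x, "transition_matrix"))
  df <- data.frame(state = rownames(x$matrix), x$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
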