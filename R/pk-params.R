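# Parameter and regimen containers shared by every simulation routine.

#' One-compartment pharmacokinetic parameters
#'
#' Bundles the apparent volume of distribution and the first-order absorption
#' and elimination rate constants that describe a single drug in a single
#' matrix (plasma or epithelial lining fluid). Doses are expressed per kg of
#' body weight, so `volume` is in L/kg and body weight cancels out of every
#' concentration formula.
#'
#' Flip-flop kinetics are permitted: `ka` may be smaller than `kel` (the
#' terminal slope then reflects absorption, as seen for meropenem in murine
#' plasma). The concentration model is symmetric under exchanging the two
#' rate constants (with a compensating volume rescaling), so no ordering is
#' imposed.
#'
#' @param volume Apparent volume of distribution, L/kg. Must be positive.
#' @param ka First-order absorption rate constant, 1/h. Must be positive.
#' @param kel First-order elimination rate constant, 1/h. Must be positive.
#' @param matrix Matrix label, `"plasma"` or `"ELF"`.
#'
#' @return An object of class `pk_params`: a list with elements `volume`,
#'   `ka`, `kel` and `matrix`.
#' @examples
#' pk_params(volume = 0.37, ka = 23.68, kel = 0.31, matrix = "plasma")
#' @export
pk_params <- function(volume, ka, kel, matrix = c("plasma", "ELF")) {
  matrix <- match.arg(matrix)
  for (nm in c("volume", "ka", "kel")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("`", nm, "` must be a single positive finite number.", call. = FALSE)
    }
  }
  structure(
    list(volume = volume, ka = ka, kel = kel, matrix = matrix),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "<pk_params> matrix=%s  V=%g L/kg  Ka=%g 1/h  Kel=%g 1/h%s\n",
    x$matrix, x$volume, x$ka, x$kel,
    if (x$ka < x$kel) "  (flip-flop: ka < kel)" else ""
  ))
  invisible(x)
}

#' Dosing regimen
#'
#' An ordered set of dose events, optionally repeated every `repeat_interval`
#' hours up to `horizon`. Subcutaneous boluses are the default route;
#' zero-order intravenous infusions (used for human comparator profiles) take
#' an `infusion_duration`.
#'
#' @param times Event times, h, all `>= 0`. Recycled against `amounts`.
#' @param amounts Dose amounts, mg/kg, all strictly positive.
#' @param route `"subcutaneous_bolus"` or `"iv_infusion"` (scalar or one per
#'   event).
#' @param infusion_duration Infusion durations, h; required (positive) for
#'   `iv_infusion` events, ignored otherwise.
#' @param repeat_interval Dosing interval, h, if the whole event block is
#'   repeated indefinitely; `NULL` for a single course. All event times must
#'   fall strictly below the interval.
#' @param horizon Simulation horizon, h; must not precede the last event.
#'
#' @return An object of class `regimen`: a list with a tibble of events
#'   (`time_h`, `amount_mg_kg`, `route`, `infusion_duration_h`), the repeat
#'   interval and the horizon.
#' @examples
#' # tobramycin plasma HSR: tapered boluses over 9 h, single course
#' regimen(c(0, 3, 6, 9), c(9, 4, 2, 0.5))
#' # meropenem plasma HSR: four boluses repeated every 8 h
#' regimen(c(0, 1.25, 3.5, 6), c(65, 65, 45, 45), repeat_interval = 8)
#' @export
regimen <- function(times, amounts, route = "subcutaneous_bolus",
                    infusion_duration = NA_real_,
                    repeat_interval = NULL, horizon = 24) {
  n <- max(length(times), length(amounts))
  events <- tibble::tibble(
    time_h = rep_len(as.numeric(times), n),
    amount_mg_kg = rep_len(as.numeric(amounts), n),
    route = rep_len(route, n),
    infusion_duration_h = rep_len(as.numeric(infusion_duration), n)
  )
  if (nrow(events) > 0) {
    if (any(!is.finite(events$time_h)) || any(events$time_h < 0)) {
      stop("Event times must be finite and >= 0.", call. = FALSE)
    }
    if (any(!is.finite(events$amount_mg_kg)) || any(events$amount_mg_kg <= 0)) {
      stop("Dose amounts must be strictly positive.", call. = FALSE)
    }
    if (!all(events$route %in% c("subcutaneous_bolus", "iv_infusion"))) {
      stop("`route` must be \"subcutaneous_bolus\" or \"iv_infusion\".",
           call. = FALSE)
    }
    iv <- events$route == "iv_infusion"
    if (any(iv & (!is.finite(events$infusion_duration_h) |
                    events$infusion_duration_h <= 0))) {
      stop("Infusion events need a positive `infusion_duration`.", call. = FALSE)
    }
    events <- dplyr::arrange(events, .data$time_h)
  }
  if (!is.null(repeat_interval)) {
    if (!is.numeric(repeat_interval) || repeat_interval <= 0) {
      stop("`repeat_interval` must be a positive number of hours.", call. = FALSE)
    }
    if (nrow(events) > 0 && any(events$time_h >= repeat_interval)) {
      stop("All event times must lie strictly below `repeat_interval`.",
           call. = FALSE)
    }
  }
  last_t <- if (nrow(events) > 0) max(events$time_h) else 0
  if (!is.numeric(horizon) || horizon < last_t) {
    stop("`horizon` must be >= the last event time.", call. = FALSE)
  }
  structure(
    list(events = events, repeat_interval = repeat_interval, horizon = horizon),
    class = "regimen"
  )
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf(
    "<regimen> %d event(s)%s, horizon %g h\n", nrow(x$events),
    if (is.null(x$repeat_interval)) ""
    else sprintf(", repeated every %g h", x$repeat_interval),
    x$horizon
  ))
  if (nrow(x$events) > 0) print(x$events, n = 10)
  invisible(x)
}

#' Total dose delivered per repeat interval (or per course)
#'
#' @param x A [regimen()].
#' @return Total mg/kg summed over the event block (one interval when the
#'   regimen repeats, the whole course otherwise).
#' @export
total_dose <- function(x) {
  stopifnot(inherits(x, "regimen"))
  sum(x$events$amount_mg_kg)
}

# Materialize repeated event blocks into explicit events up to the horizon.
expand_events <- function(x, horizon = x$horizon) {
  ev <- x$events
  if (is.null(x$repeat_interval) || nrow(ev) == 0) {
    return(ev[ev$time_h <= horizon, , drop = FALSE])
  }
  tau <- x$repeat_interval
  n_rep <- floor(horizon / tau) + 1L
  out <- purrr::map_dfr(seq_len(n_rep) - 1L, function(k) {
    shifted <- ev
    shifted$time_h <- shifted$time_h + k * tau
    shifted
  })
  out[out$time_h <= horizon, , drop = FALSE]
}
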