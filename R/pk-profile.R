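# Concentration-time profiles as explicit sums of closed-form terms.
#
# A profile is a list of terms, each active from its onset time s:
#   exp    coef * exp(-rate * (t - s))
#   texp   coef * (t - s) * exp(-rate * (t - s))   (degenerate ka == kel)
#   const  coef
#   lin    coef * (t - s)
# Every simulation routine builds profiles from these four primitives, so
# evaluation, maxima, level crossings and the AUC are all exact.

new_pk_profile <- function(terms, window, matrix, binding, unbound_fraction,
                           interval = NULL) {
  stopifnot(
    is.data.frame(terms),
    all(c("onset", "type", "coef", "rate") %in% names(terms)),
    length(window) == 2, window[1] <= window[2],
    binding %in% c("total", "unbound"),
    unbound_fraction > 0, unbound_fraction <= 1
  )
  structure(
    list(
      terms = tibble::as_tibble(terms),
      window = as.numeric(window),
      matrix = matrix,
      binding = binding,
      unbound_fraction = unbound_fraction,
      interval = interval
    ),
    class = "pk_profile"
  )
}

#' Evaluate a concentration-time profile
#'
#' Evaluates the closed-form term list of a [pk_profile][simulate_regimen] at
#' arbitrary times. Times before the first dose evaluate to zero; tiny
#' negative values arising from floating-point cancellation are clamped to
#' zero.
#'
#' @param profile A `pk_profile`.
#' @param t Numeric vector of times, h.
#' @return Numeric vector of concentrations, mg/L.
#' @export
profile_conc <- function(profile, t) {
  stopifnot(inherits(profile, "pk_profile"))
  out <- numeric(length(t))
  tm <- profile$terms
  for (i in seq_len(nrow(tm))) {
    u <- t - tm$onset[i]
    active <- u >= 0
    if (!any(active)) next
    v <- numeric(length(t))
    ua <- u[active]
    v[active] <- switch(
      tm$type[i],
      exp   = tm$coef[i] * exp(-tm$rate[i] * ua),
      texp  = tm$coef[i] * ua * exp(-tm$rate[i] * ua),
      const = tm$coef[i],
      lin   = tm$coef[i] * ua,
      stop("unknown term type: ", tm$type[i])
    )
    out <- out + v
  }
  pmax(out, 0)
}

#' Dense tabular view of a profile
#'
#' @param x A `pk_profile`.
#' @param step Grid step, h (default 0.001 h; the closed form remains the
#'   source of truth, the grid is only a view).
#' @param ... Unused.
#' @return A tibble with `time_h`, `concentration_mg_L`, `matrix`,
#'   `binding_state`.
#' @export
#' @method as_tibble pk_profile
as_tibble.pk_profile <- function(x, step = 0.001, ...) {
  t <- seq(x$window[1], x$window[2], by = step)
  if (t[length(t)] < x$window[2]) t <- c(t, x$window[2])
  tibble::tibble(
    time_h = t,
    concentration_mg_L = profile_conc(x, t),
    matrix = x$matrix,
    binding_state = x$binding
  )
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf(
    "<pk_profile> %s (%s), %d term(s), window [%g, %g] h%s\n",
    x$matrix, x$binding, nrow(x$terms), x$window[1], x$window[2],
    if (is.null(x$interval)) ""
    else sprintf(", steady-state interval %g h", x$interval)
  ))
  invisible(x)
}

#' Plot a concentration-time profile
#'
#' @param object A `pk_profile`.
#' @param step Grid step for the plotted curve, h.
#' @param log_y Plot concentration on a log10 axis (zeros dropped).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot pk_profile
autoplot.pk_profile <- function(object, step = 0.01, log_y = FALSE, ...) {
  df <- as_tibble.pk_profile(object, step = step)
  if (log_y) df <- dplyr::filter(df, .data$concentration_mg_L > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$concentration_mg_L)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (h)",
      y = sprintf("%s concentration, %s (mg/L)", object$matrix, object$binding)
    )
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
plot.pk_profile <- function(x, ...) print(autoplot.pk_profile(x, ...))

# Scale all term coefficients (used for unbound correction and dose scaling).
scale_profile <- function(profile, factor) {
  profile$terms$coef <- profile$terms$coef * factor
  profile
}

# Pointwise sum of two profiles sharing matrix/binding metadata.
add_profiles <- function(a, b) {
  stopifnot(inherits(a, "pk_profile"), inherits(b, "pk_profile"))
  new_pk_profile(
    dplyr::bind_rows(a$terms, b$terms),
    window = c(min(a$window[1], b$window[1]), max(a$window[2], b$window[2])),
    matrix = a$matrix, binding = a$binding,
    unbound_fraction = a$unbound_fraction, interval = a$interval
  )
}

#' Export a profile as CSV
#'
#' Writes the dense-grid view (`time_h`, `concentration_mg_L`, `matrix`,
#' `binding_state`) to a CSV file.
#'
#' @param profile A `pk_profile`.
#' @param path Output path.
#' @param step Grid step, h.
#' @return `path`, invisibly.
#' @export
export_profile_csv <- function(profile, path, step = 0.01) {
  utils::write.csv(as_tibble.pk_profile(profile, step = step), path,
                   row.names = FALSE)
  invisible(path)
}
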