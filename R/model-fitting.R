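# Naive-pooled nonlinear least-squares estimation from sparse destructive
# sampling, with IQR outlier filtering and AIC-based model selection.

#' Interquartile-range outlier filter
#'
#' Single-pass Tukey fence filter: values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are excluded, with quartiles computed by
#' linear interpolation between order statistics (`quantile(type = 7)`).
#' Groups with fewer than 4 values pass through unfiltered — quartiles of
#' very small destructive-sampling groups are too unstable to police.
#'
#' @param values Numeric vector (concentrations at one timepoint for one
#'   analyte in one matrix).
#' @param k Fence multiplier (default 1.5).
#' @return List with `kept`, `excluded`, and the `lower`/`upper` fences.
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100))$excluded
#' @export
iqr_filter <- function(values, k = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 4) {
    return(list(kept = values, excluded = numeric(0),
                lower = -Inf, upper = Inf))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  out <- values < lower | values > upper
  list(kept = values[!out], excluded = values[out],
       lower = lower, upper = upper)
}

#' Apply the IQR filter across a study dataset
#'
#' Runs [iqr_filter()] within each timepoint x analyte x matrix group and
#' reports exclusion tallies per matrix in the conventional `x/n (p%)` form.
#'
#' @param data Data frame with a `conc_mg_L` column plus any of `time_h`,
#'   `analyte`, `matrix` used for grouping.
#' @param group_vars Grouping columns (defaults to whichever of `time_h`,
#'   `analyte`, `matrix` are present).
#' @param k Fence multiplier.
#' @return List with `data` (kept rows), `excluded` (dropped rows) and
#'   `tally`, a tibble of per-matrix exclusion counts with a formatted label.
#' @export
filter_outliers <- function(data, group_vars = NULL, k = 1.5) {
  stopifnot(is.data.frame(data), "conc_mg_L" %in% names(data))
  if (is.null(group_vars)) {
    group_vars <- intersect(c("time_h", "analyte", "matrix"), names(data))
  }
  data <- tibble::as_tibble(data)
  flagged <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::mutate(.excluded = {
      n_grp <- dplyr::n()
      if (n_grp < 4) rep(FALSE, n_grp) else {
        f <- iqr_filter(.data$conc_mg_L, k = k)
        .data$conc_mg_L < f$lower | .data$conc_mg_L > f$upper
      }
    }) |>
    dplyr::ungroup()
  tally_by <- intersect("matrix", names(data))
  tally <- flagged |>
    dplyr::group_by(dplyr::across(dplyr::all_of(tally_by))) |>
    dplyr::summarise(n_excluded = sum(.data$.excluded), n_total = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(label = sprintf("%d/%d (%.1f%%)", .data$n_excluded,
                                  .data$n_total,
                                  100 * .data$n_excluded / .data$n_total))
  list(
    data = dplyr::select(flagged[!flagged$.excluded, ], -".excluded"),
    excluded = dplyr::select(flagged[flagged$.excluded, ], -".excluded"),
    tally = tally
  )
}

#' Least-squares Akaike information criterion
#'
#' `n * log(rss / n) + 2 * k`, the AIC up to an additive constant for
#' Gaussian errors with the variance profiled out — the standard form for
#' comparing nested least-squares PK models on the same data.
#'
#' @param n_obs Number of observations.
#' @param rss Residual sum of squares.
#' @param k_params Number of structural parameters.
#' @return The criterion value; `-Inf` (with a warning) when `rss == 0`.
#' @export
pk_aic <- function(n_obs, rss, k_params) {
  stopifnot(n_obs > 0, rss >= 0)
  if (rss == 0) {
    warning("rss = 0: AIC is -Inf (perfect fit).")
    return(-Inf)
  }
  n_obs * log(rss / n_obs) + 2 * k_params
}

# --- model prediction functions --------------------------------------------

# One-compartment first-order absorption, superposed over dose events.
predict_one_cpt <- function(theta, events, t) {
  V <- theta[["volume"]]; ka <- theta[["ka"]]; kel <- theta[["kel"]]
  out <- numeric(length(t))
  for (i in seq_len(nrow(events))) {
    u <- t - events$time_h[i]
    act <- u >= 0
    if (!any(act)) next
    d <- events$amount_mg_kg[i]
    if (abs(ka - kel) / ka < 1e-9) {
      out[act] <- out[act] + (d / V) * ka * u[act] * exp(-ka * u[act])
    } else {
      out[act] <- out[act] +
        (d / V) * (ka / (ka - kel)) * (exp(-kel * u[act]) - exp(-ka * u[act]))
    }
  }
  pmax(out, 0)
}

# Two-compartment disposition with first-order absorption (tri-exponential
# closed form), superposed over dose events. theta: volume (central), ka,
# k10, k12, k21.
predict_two_cpt <- function(theta, events, t) {
  V <- theta[["volume"]]; ka <- theta[["ka"]]
  k10 <- theta[["k10"]]; k12 <- theta[["k12"]]; k21 <- theta[["k21"]]
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  if (disc < 0) return(rep(NA_real_, length(t)))
  alpha <- (s + sqrt(disc)) / 2
  beta <- (s - sqrt(disc)) / 2
  den <- c((ka - alpha) * (beta - alpha),
           (ka - beta) * (alpha - beta),
           (alpha - ka) * (beta - ka))
  if (any(abs(den) < 1e-12)) return(rep(NA_real_, length(t)))
  co <- c(k21 - alpha, k21 - beta, k21 - ka) / den
  rates <- c(alpha, beta, ka)
  out <- numeric(length(t))
  for (i in seq_len(nrow(events))) {
    u <- t - events$time_h[i]
    act <- u >= 0
    if (!any(act)) next
    d <- events$amount_mg_kg[i]
    for (j in 1:3) {
      out[act] <- out[act] + (d * ka / V) * co[j] * exp(-rates[j] * u[act])
    }
  }
  pmax(out, 0)
}

# --- fitting ----------------------------------------------------------------

#' Fit PK parameters by naive-pooled nonlinear least squares
#'
#' Minimizes the (optionally weighted) residual sum of squares of observed
#' concentrations against the closed-form multi-dose model, pooling all
#' animals' observations as a single curve (destructive sparse sampling
#' leaves no within-animal profile to model). Optimization runs on the log
#' scale from a multi-start grid: the elimination constant is seeded from the
#' terminal log-linear slope, the volume from back-extrapolation, and the
#' absorption constant from a log-spaced ladder, so the procedure is
#' deterministic for given data.
#'
#' @param data Data frame with `time_h` and `conc_mg_L` (other columns are
#'   ignored by the fit).
#' @param regimen The [regimen()] actually administered during the study.
#' @param model `"one_compartment"` (3 parameters: volume, ka, kel) or
#'   `"two_compartment"` (5: volume, ka, k10, k12, k21), both with
#'   first-order absorption.
#' @param weighting Residual weighting: `"none"`, `"1/y"` or `"1/y2"`
#'   (weights from the observed concentrations).
#' @param lloq Lower limit of quantification, mg/L; observations strictly
#'   below it are dropped before fitting (no imputation).
#' @return A `pk_fit`: estimates, `parameters` (a [pk_params()] for the
#'   one-compartment model), `rss`, `n_obs`, `k_params`, `aic`, residual
#'   table and a convergence flag.
#' @examples
#' tob <- pk_params(0.37, 23.68, 0.31)
#' reg <- regimen(c(0, 3, 6, 9), c(9, 4, 2, 0.5))
#' obs <- generate_pk_study(tob, reg, sampling_design(c(0.5, 1, 2, 4, 6, 8, 10)),
#'                          noise_model(cv = 0), seed = 1)
#' fit_pk(obs$observations, reg)
#' @export
fit_pk <- function(data, regimen,
                   model = c("one_compartment", "two_compartment"),
                   weighting = c("none", "1/y", "1/y2"), lloq = NULL) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(data),
            all(c("time_h", "conc_mg_L") %in% names(data)),
            inherits(regimen, "regimen"))
  obs <- tibble::as_tibble(data)[, c("time_h", "conc_mg_L")]
  obs <- obs[is.finite(obs$time_h) & is.finite(obs$conc_mg_L) &
               obs$conc_mg_L > 0, ]
  n_blq <- 0L
  if (!is.null(lloq)) {
    n_blq <- sum(obs$conc_mg_L < lloq)
    obs <- obs[obs$conc_mg_L >= lloq, ]
  }
  k_params <- if (model == "one_compartment") 3L else 5L
  if (length(unique(obs$time_h)) < k_params + 1) {
    stop("Need at least k + 1 distinct timepoints after filtering (",
         k_params + 1, ").", call. = FALSE)
  }
  events <- expand_events(regimen)
  w <- switch(weighting, none = rep(1, nrow(obs)),
              `1/y` = 1 / obs$conc_mg_L, `1/y2` = 1 / obs$conc_mg_L^2)
  predict_fn <- if (model == "one_compartment") predict_one_cpt else
    predict_two_cpt

  objective <- function(log_theta, names_theta) {
    theta <- stats::setNames(exp(log_theta), names_theta)
    pred <- predict_fn(theta, events, obs$time_h)
    if (any(!is.finite(pred))) return(1e12)
    sum(w * (obs$conc_mg_L - pred)^2)
  }

  starts <- fit_starts(obs, events, model)
  names_theta <- colnames(starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch({
      nm <- stats::optim(log(starts[i, ]), objective,
                         names_theta = names_theta,
                         method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
      stats::optim(nm$par, objective, names_theta = names_theta,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
    }, error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("All optimization starts failed.", call. = FALSE)
  }
  theta <- stats::setNames(exp(best$par), names_theta)
  pred <- predict_fn(theta, events, obs$time_h)
  rss <- sum(w * (obs$conc_mg_L - pred)^2)
  converged <- best$convergence == 0 && all(is.finite(theta))
  parameters <- if (model == "one_compartment") {
    pk_params(theta[["volume"]], theta[["ka"]], theta[["kel"]])
  } else NULL
  structure(
    list(
      model = model,
      estimates = theta,
      parameters = parameters,
      rss = rss,
      n_obs = nrow(obs),
      k_params = k_params,
      aic = if (rss > 0) pk_aic(nrow(obs), rss, k_params) else
        suppressWarnings(pk_aic(nrow(obs), rss, k_params)),
      residuals = tibble::tibble(time_h = obs$time_h,
                                 observed = obs$conc_mg_L,
                                 predicted = pred,
                                 residual = obs$conc_mg_L - pred),
      converged = converged,
      weighting = weighting,
      n_starts = nrow(starts),
      n_blq_dropped = n_blq
    ),
    class = "pk_fit"
  )
}

# Multi-start grid: kel from the terminal log-linear slope, V from
# back-extrapolation, ka from a log-spaced ladder around kel.
fit_starts <- function(obs, events, model) {
  means <- stats::aggregate(conc_mg_L ~ time_h, data = obs, FUN = mean)
  means <- means[means$conc_mg_L > 0, ]
  means <- means[order(means$time_h), ]
  n_tail <- min(max(3, ceiling(nrow(means) / 3)), nrow(means))
  tail_pts <- utils::tail(means, n_tail)
  sl <- tryCatch(
    stats::coef(stats::lm(log(conc_mg_L) ~ time_h, data = tail_pts)),
    error = function(e) c(`(Intercept)` = log(max(means$conc_mg_L)),
                          time_h = -0.5))
  kel0 <- max(-unname(sl["time_h"]), 0.02)
  dose1 <- sum(events$amount_mg_kg[events$time_h == min(events$time_h)])
  v0 <- max(dose1 / exp(unname(sl["(Intercept)"])), 1e-3)
  ka_ladder <- kel0 * c(0.05, 0.3, 3, 20, 100)
  if (model == "one_compartment") {
    grid <- rbind(
      cbind(volume = v0, ka = ka_ladder, kel = kel0),
      cbind(volume = v0 * 5, ka = ka_ladder[c(2, 4)], kel = kel0)
    )
    return(grid)
  }
  # two-compartment: branch from the one-compartment geometry
  grid <- NULL
  for (ka in kel0 * c(0.3, 3, 20)) {
    for (ratio in c(0.3, 1)) {
      grid <- rbind(grid, cbind(volume = v0, ka = ka, k10 = kel0,
                                k12 = kel0 * ratio, k21 = kel0 * ratio))
    }
  }
  grid
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> %s, %d obs, rss = %.4g, AIC = %.2f%s\n",
              x$model, x$n_obs, x$rss, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$estimates, 4))
  invisible(x)
}

#' @export
#' @method tidy pk_fit
tidy.pk_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates))
}

#' @export
#' @method glance pk_fit
glance.pk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_obs = x$n_obs, k_params = x$k_params,
                 rss = x$rss, aic = x$aic, converged = x$converged,
                 weighting = x$weighting, n_blq_dropped = x$n_blq_dropped)
}

#' @export
#' @method augment pk_fit
augment.pk_fit <- function(x, ...) x$residuals

#' Select the best compartment model by AIC
#'
#' Returns the converged fit with the lowest AIC; exact ties go to the model
#' with fewer parameters (parsimony).
#'
#' @param fits A list of `pk_fit` objects for the same data.
#' @return The selected `pk_fit`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "pk_fit")))
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(ok)) stop("No converged fits to select from.", call. = FALSE)
  fits <- fits[ok]
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ks <- vapply(fits, function(f) f$k_params, numeric(1))
  fits[[order(aics, ks)[1]]]
}

#' Align a fitted parameter set across the flip-flop ambiguity
#'
#' A one-compartment absorption curve is exactly invariant under exchanging
#' `ka` and `kel` with a compensating volume rescaling
#' (`V -> V * kel / ka`), so a fit can legitimately land on either
#' orientation. For parameter-recovery assessments this helper returns the
#' orientation of `estimates` closer (in summed absolute log ratio) to
#' `truth`.
#'
#' @param estimates,truth [pk_params()] objects (or lists with `volume`,
#'   `ka`, `kel`).
#' @return A list with `volume`, `ka`, `kel` in the aligned orientation.
#' @export
align_flipflop <- function(estimates, truth) {
  d <- function(e) {
    abs(log(e$volume / truth$volume)) + abs(log(e$ka / truth$ka)) +
      abs(log(e$kel / truth$kel))
  }
  swapped <- list(volume = estimates$volume * estimates$kel / estimates$ka,
                  ka = estimates$kel, kel = estimates$ka)
  direct <- list(volume = estimates$volume, ka = estimates$ka,
                 kel = estimates$kel)
  if (d(swapped) < d(direct)) swapped else direct
}
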