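# Matrix corrections: ultrafiltration free fraction, BAL urea-dilution
# estimation of ELF concentrations, and the plasma-to-ELF penetration line.

#' Plasma free fraction from ultrafiltration pairs
#'
#' Each replicate's free fraction is `ultrafiltrate / total`; replicates are
#' averaged within dose group and dose-group means are pooled by an
#' unweighted mean (binding is treated as exposure-independent across the
#' studied dose range). Records with non-positive totals are dropped with a
#' warning; fractions above 1 (ultrafiltrate exceeding total, an assay-noise
#' artefact) are capped at 1 with a warning.
#'
#' @param records Data frame with columns `dose_mg_kg`, `replicate`,
#'   `total_mg_L`, `uf_mg_L`.
#' @return A `free_fraction_fit`: list with `per_replicate` and `per_dose`
#'   tibbles, the `pooled` unbound fraction and the pooled percent bound.
#' @examples
#' rec <- tibble::tibble(
#'   dose_mg_kg = c(2.5, 5, 10), replicate = 1,
#'   total_mg_L = 10, uf_mg_L = c(7.29, 7.95, 8.02)
#' )
#' free_fraction(rec)$pooled
#' @export
free_fraction <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("dose_mg_kg", "total_mg_L", "uf_mg_L") %in% names(records)))
  if (!"replicate" %in% names(records)) {
    records$replicate <- seq_len(nrow(records))
  }
  bad <- !is.finite(records$total_mg_L) | records$total_mg_L <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive total concentration dropped.")
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("No usable binding records.", call. = FALSE)
  per_rep <- records |>
    dplyr::mutate(fraction_raw = .data$uf_mg_L / .data$total_mg_L,
                  capped = .data$fraction_raw > 1,
                  fraction = pmin(.data$fraction_raw, 1)) |>
    tibble::as_tibble()
  if (any(per_rep$capped)) {
    warning(sum(per_rep$capped),
            " fraction(s) above 1 (ultrafiltrate > total) capped at 1.")
  }
  per_dose <- per_rep |>
    dplyr::group_by(.data$dose_mg_kg) |>
    dplyr::summarise(n = dplyr::n(), fraction = mean(.data$fraction),
                     .groups = "drop")
  pooled <- mean(per_dose$fraction)
  structure(
    list(per_replicate = per_rep, per_dose = per_dose, pooled = pooled,
         percent_bound = 100 * (1 - pooled)),
    class = "free_fraction_fit"
  )
}

#' @export
print.free_fraction_fit <- function(x, ...) {
  cat(sprintf(
    "<free_fraction_fit> pooled unbound fraction %.3f (%.1f%% bound) from %d dose group(s)\n",
    x$pooled, x$percent_bound, nrow(x$per_dose)))
  invisible(x)
}

#' @export
#' @method tidy free_fraction_fit
tidy.free_fraction_fit <- function(x, ...) x$per_dose

#' @export
#' @method glance free_fraction_fit
glance.free_fraction_fit <- function(x, ...) {
  tibble::tibble(pooled_fraction = x$pooled,
                 percent_bound = x$percent_bound,
                 n_dose_groups = nrow(x$per_dose),
                 n_replicates = nrow(x$per_replicate))
}

#' ELF concentration from BAL fluid via urea dilution
#'
#' Lavage dilutes the epithelial lining fluid with saline; urea equilibrates
#' freely between plasma and ELF, so the plasma/BAL urea ratio recovers the
#' dilution factor:
#' `ELF = BAL_concentration * urea_plasma / urea_bal`.
#' ELF lacks albumin, so the estimate is treated as an unbound concentration.
#' Urea may be supplied in any unit as only the ratio enters.
#'
#' @param records Data frame with columns `bal_mg_L`, `urea_plasma`,
#'   `urea_bal` (one row per mouse); extra columns pass through.
#' @return The input tibble with an added `elf_mg_L` column.
#' @examples
#' elf_from_bal(tibble::tibble(bal_mg_L = 0.5, urea_plasma = 40, urea_bal = 2))
#' @export
elf_from_bal <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("bal_mg_L", "urea_plasma", "urea_bal") %in% names(records)))
  if (any(!is.finite(records$urea_bal) | records$urea_bal <= 0)) {
    stop("`urea_bal` must be positive (no dilution factor can be recovered).",
         call. = FALSE)
  }
  if (any(!is.finite(records$urea_plasma) | records$urea_plasma <= 0)) {
    stop("`urea_plasma` must be positive.", call. = FALSE)
  }
  if (any(records$urea_bal > records$urea_plasma)) {
    warning("Some BAL urea values exceed plasma urea; ",
            "lavage should dilute, check these records.")
  }
  dplyr::mutate(tibble::as_tibble(records),
                elf_mg_L = .data$bal_mg_L * .data$urea_plasma / .data$urea_bal)
}

#' Fit a linear plasma-to-ELF penetration model
#'
#' Ordinary least squares of single-timepoint penetration ratios
#' (`C_ELF / C_plasma`) on time, giving `ratio(t) = slope * t + intercept`.
#' Used when human ELF data exist only as point-to-point penetration
#' estimates and a full ELF concentration-time profile must be
#' reconstructed from the plasma profile.
#'
#' @param times Times of the observed ratios, h (at least two distinct).
#' @param ratios Observed `C_ELF / C_plasma` ratios, dimensionless.
#' @return A `penetration_model`: slope (1/h), intercept, `r_squared`, the
#'   fitted-time range and the underlying `lm` object.
#' @export
fit_penetration_model <- function(times, ratios) {
  stopifnot(is.numeric(times), is.numeric(ratios),
            length(times) == length(ratios))
  if (length(unique(times)) < 2) {
    stop("Need at least two distinct times to fit a penetration line.",
         call. = FALSE)
  }
  fit <- stats::lm(ratios ~ times)
  # summary() warns on numerically perfect fits; the R^2 of 1 is still right
  r2 <- if (stats::var(ratios) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  penetration_model(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    time_range = range(times),
    fit = fit
  )
}

#' Construct a penetration model from known coefficients
#'
#' @param slope Slope of the penetration line, 1/h.
#' @param intercept Intercept, dimensionless.
#' @param r_squared Coefficient of determination of the source fit, if known.
#' @param time_range Time range over which the line was fitted, h.
#' @param fit Optional underlying `lm` object.
#' @return A `penetration_model` object.
#' @export
penetration_model <- function(slope, intercept, r_squared = NA_real_,
                              time_range = c(0.5, 8), fit = NULL) {
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         time_range = as.numeric(time_range), fit = fit),
    class = "penetration_model"
  )
}

#' @export
print.penetration_model <- function(x, ...) {
  cat(sprintf(
    "<penetration_model> ratio(t) = %.4f * t + %.4f  (R^2 = %s, fitted on [%g, %g] h)\n",
    x$slope, x$intercept,
    ifelse(is.na(x$r_squared), "?", format(x$r_squared, digits = 3)),
    x$time_range[1], x$time_range[2]))
  invisible(x)
}

#' @export
#' @method tidy penetration_model
tidy.penetration_model <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
#' @method glance penetration_model
glance.penetration_model <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared,
                 time_min_h = x$time_range[1], time_max_h = x$time_range[2])
}

#' @export
predict.penetration_model <- function(object, times, ...) {
  object$slope * times + object$intercept
}

#' Project a plasma profile into ELF through a penetration line
#'
#' Multiplies the plasma closed form by the time-varying penetration ratio
#' `slope * t + intercept`. The product of an exponential term and a linear
#' factor stays inside the closed-form term basis, so the resulting ELF
#' profile (and hence its AUC) remains exact. Also reports the
#' `AUC_ELF / AUC_plasma` penetration ratio over the window.
#'
#' By default the model is applied only within its fitted time range;
#' set `extrapolate = TRUE` to cover a full dosing window (e.g. 0-24 h).
#'
#' @param profile_plasma Plasma `pk_profile`.
#' @param model A `penetration_model`.
#' @param window Evaluation window, h; defaults to the profile window.
#' @param extrapolate Allow use outside the model's fitted time range.
#' @return A list with `profile` (the ELF `pk_profile`) and `auc_ratio`.
#' @export
apply_penetration <- function(profile_plasma, model, window = NULL,
                              extrapolate = FALSE) {
  stopifnot(inherits(profile_plasma, "pk_profile"),
            inherits(model, "penetration_model"))
  window <- check_window(profile_plasma, window)
  if (!extrapolate &&
      (window[1] < model$time_range[1] - 1e-9 ||
         window[2] > model$time_range[2] + 1e-9)) {
    stop("Window [", window[1], ", ", window[2],
         "] h extends beyond the fitted range [", model$time_range[1], ", ",
         model$time_range[2], "] h; set `extrapolate = TRUE` to allow this.",
         call. = FALSE)
  }
  # ratio is linear: negativity can only occur at a window endpoint
  ratio_ends <- predict(model, window)
  if (any(ratio_ends < 0)) {
    bad_end <- window[which(ratio_ends < 0)]
    stop("Penetration ratio is negative near t = ",
         paste(signif(bad_end, 4), collapse = ", "),
         " h within the window; refusing to build a negative ELF profile.",
         call. = FALSE)
  }
  a <- model$slope; b <- model$intercept
  tm <- profile_plasma$terms
  pieces <- purrr::map_dfr(seq_len(nrow(tm)), function(i) {
    s <- tm$onset[i]; cf <- tm$coef[i]; r <- tm$rate[i]
    lin_at_onset <- a * s + b
    switch(
      tm$type[i],
      # c e^{-r u} (a t + b) = c (a s + b) e^{-r u} + c a u e^{-r u},  u = t - s
      exp = tibble::tibble(
        onset = c(s, s), type = c("exp", "texp"),
        coef = c(cf * lin_at_onset, cf * a), rate = c(r, r)
      ),
      const = tibble::tibble(
        onset = c(s, s), type = c("const", "lin"),
        coef = c(cf * lin_at_onset, cf * a), rate = c(0, 0)
      ),
      stop("Penetration projection is not defined for `", tm$type[i],
           "` terms (degenerate ka == kel profiles).")
    )
  })
  elf <- new_pk_profile(pieces, window = window, matrix = "ELF",
                        binding = "unbound", unbound_fraction = 1,
                        interval = profile_plasma$interval)
  auc_plasma <- auc(profile_plasma, window)
  list(profile = elf,
       auc_ratio = if (auc_plasma > 0) auc(elf, window) / auc_plasma
       else NA_real_)
}
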