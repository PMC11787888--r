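# Seeded generators of realistic sparse murine PK study data: destructive
# sampling (groups of mice per timepoint), proportional assay noise, BAL
# lavage dilution with paired urea, ultrafiltration pairs and outliers.
# Every generator records the generating truth so recovery can be tested.

#' Assay/biological noise model
#'
#' Observations are generated as `true * (1 + eps)` with
#' `eps ~ Normal(0, cv)` truncated at -0.99 (concentrations stay positive),
#' plus optional additive noise. Outliers are injected separately (see
#' [inject_outliers()]) or here via `outlier_prob`.
#'
#' @param cv Proportional coefficient of variation (default 0.20, inside the
#'   <30% variability typical of antibiotic PK parameters).
#' @param additive_sd Additive noise SD, mg/L (default 0).
#' @param outlier_prob Probability an observation is multiplied by an
#'   outlier factor (default 0).
#' @param outlier_multipliers Pool of multipliers drawn uniformly for
#'   outliers (default `c(5, 10)`).
#' @return A `noise_model` list.
#' @export
noise_model <- function(cv = 0.20, additive_sd = 0, outlier_prob = 0,
                        outlier_multipliers = c(5, 10)) {
  stopifnot(cv >= 0, additive_sd >= 0,
            outlier_prob >= 0, outlier_prob <= 1,
            all(outlier_multipliers > 0))
  structure(list(cv = cv, additive_sd = additive_sd,
                 outlier_prob = outlier_prob,
                 outlier_multipliers = outlier_multipliers),
            class = "noise_model")
}

#' Destructive sampling design
#'
#' Mirrors the murine study layout: groups of mice per timepoint, each mouse
#' contributing at most three samples (two survival bleeds plus one terminal
#' sample), so no mouse spans more than `samples_per_mouse` timepoints.
#'
#' @param timepoints Sampling times, h.
#' @param mice_per_timepoint Mice sampled at each timepoint (default 6).
#' @param samples_per_mouse Maximum samples per mouse (1-3, default 3).
#' @return A `sampling_design` list.
#' @export
sampling_design <- function(timepoints, mice_per_timepoint = 6,
                            samples_per_mouse = 3) {
  stopifnot(length(timepoints) >= 1, all(timepoints >= 0),
            mice_per_timepoint >= 1,
            samples_per_mouse >= 1, samples_per_mouse <= 3)
  structure(list(timepoints = sort(unique(as.numeric(timepoints))),
                 mice_per_timepoint = mice_per_timepoint,
                 samples_per_mouse = samples_per_mouse),
            class = "sampling_design")
}

apply_noise <- function(true_values, noise) {
  eps <- pmax(stats::rnorm(length(true_values), 0, noise$cv), -0.99)
  obs <- true_values * (1 + eps)
  if (noise$additive_sd > 0) {
    obs <- pmax(obs + stats::rnorm(length(obs), 0, noise$additive_sd), 0)
  }
  if (noise$outlier_prob > 0) {
    hit <- stats::runif(length(obs)) < noise$outlier_prob
    mult <- draw_multipliers(noise$outlier_multipliers, length(obs))
    obs[hit] <- obs[hit] * mult[hit]
    attr(obs, "outlier_flag") <- hit
  }
  obs
}

# sample() treats a length-1 pool as 1:n; draw by index instead
draw_multipliers <- function(pool, n) {
  pool[sample.int(length(pool), n, replace = TRUE)]
}

# Assign mouse ids so each mouse covers at most `samples_per_mouse`
# consecutive timepoints (two survival bleeds + one terminal sample).
assign_mice <- function(design) {
  tp <- design$timepoints
  n_tp <- length(tp)
  span <- design$samples_per_mouse
  cohorts <- split(seq_len(n_tp), ceiling(seq_len(n_tp) / span))
  rows <- purrr::map_dfr(seq_along(cohorts), function(ci) {
    idx <- cohorts[[ci]]
    purrr::map_dfr(seq_len(design$mice_per_timepoint), function(m) {
      tibble::tibble(
        subject_id = sprintf("cohort%02d_mouse%02d", ci, m),
        time_h = tp[idx],
        terminal = tp[idx] == max(tp[idx])
      )
    })
  })
  rows
}

#' Generate a sparse murine PK study dataset
#'
#' Simulates the closed-form concentration at each design timepoint for each
#' mouse and applies the noise model. The generating truth and per-row
#' outlier flags are stored so downstream filtering and fitting can be
#' scored. Byte-identical output is guaranteed for a given seed.
#'
#' @param truth A [pk_params()] — the generating parameters.
#' @param regimen The administered [regimen()].
#' @param design A [sampling_design()].
#' @param noise A [noise_model()].
#' @param seed Integer seed controlling all randomness.
#' @param unbound_fraction Scale applied to simulated totals before noise
#'   (default 1: observations are total concentrations, as assayed).
#' @param analyte Analyte label carried through the observation table.
#' @return A `pk_study` list: `observations` tibble (`subject_id`, `time_h`,
#'   `matrix`, `analyte`, `conc_mg_L`, `true_mg_L`, `is_outlier`), plus
#'   `truth`, `regimen`, `design`, `noise` and `seed`.
#' @export
generate_pk_study <- function(truth, regimen, design, noise = noise_model(),
                              seed = 1, unbound_fraction = 1,
                              analyte = "drug") {
  stopifnot(inherits(truth, "pk_params"), inherits(regimen, "regimen"),
            inherits(design, "sampling_design"),
            inherits(noise, "noise_model"))
  if (max(design$timepoints) > regimen$horizon) {
    stop("Sampling timepoints extend beyond the regimen horizon.",
         call. = FALSE)
  }
  profile <- simulate_regimen(truth, regimen,
                              unbound_fraction = unbound_fraction,
                              binding = "total")
  layout <- assign_mice(design)
  obs <- withr::with_seed(seed, {
    true_vals <- profile_conc(profile, layout$time_h)
    noisy <- apply_noise(true_vals, noise)
    flags <- attr(noisy, "outlier_flag") %||% rep(FALSE, length(noisy))
    tibble::tibble(
      subject_id = layout$subject_id,
      time_h = layout$time_h,
      matrix = truth$matrix,
      analyte = analyte,
      conc_mg_L = as.numeric(noisy),
      true_mg_L = true_vals,
      is_outlier = flags
    )
  })
  structure(list(observations = obs, truth = truth, regimen = regimen,
                 design = design, noise = noise, seed = seed),
            class = "pk_study")
}

#' @export
print.pk_study <- function(x, ...) {
  cat(sprintf("<pk_study> %d observations, %d timepoint(s), seed %d\n",
              nrow(x$observations), length(x$design$timepoints), x$seed))
  invisible(x)
}

#' Generate a BAL study with urea-paired lavage dilution
#'
#' Each sampled mouse receives a random lavage dilution factor `d`; the
#' measured BAL drug concentration is `ELF_true * d` and the measured BAL
#' urea is `urea_plasma * d`, each perturbed by its own proportional noise
#' channel. [elf_from_bal()] inverts the dilution exactly when both noise
#' channels are silent.
#'
#' @param truth_elf_profile A `pk_profile` of the true ELF concentrations.
#' @param timepoints Sampling times, h.
#' @param n_per_timepoint Mice lavaged per timepoint (default 6).
#' @param urea_plasma Plasma urea level, mg/dL (default 40, constant across
#'   mice).
#' @param dilution_range Support of the per-mouse Uniform lavage dilution
#'   factor (default `c(0.01, 0.10)`).
#' @param cv Proportional CV applied independently to the drug and urea
#'   channels (default 0.10).
#' @param seed Integer seed.
#' @return A tibble of BAL records: `mouse_id`, `time_h`, `bal_mg_L`,
#'   `urea_plasma`, `urea_bal`, plus the generating `dilution` and
#'   `elf_true_mg_L`.
#' @export
generate_bal_study <- function(truth_elf_profile, timepoints,
                               n_per_timepoint = 6, urea_plasma = 40,
                               dilution_range = c(0.01, 0.10), cv = 0.10,
                               seed = 1) {
  stopifnot(inherits(truth_elf_profile, "pk_profile"),
            length(dilution_range) == 2,
            dilution_range[1] > 0, dilution_range[2] < 1,
            dilution_range[1] <= dilution_range[2],
            cv >= 0, urea_plasma > 0)
  grid <- tidyr::expand_grid(time_h = sort(unique(as.numeric(timepoints))),
                             mouse = seq_len(n_per_timepoint))
  withr::with_seed(seed, {
    n <- nrow(grid)
    d <- stats::runif(n, dilution_range[1], dilution_range[2])
    elf_true <- profile_conc(truth_elf_profile, grid$time_h)
    e1 <- pmax(stats::rnorm(n, 0, cv), -0.99)
    e2 <- pmax(stats::rnorm(n, 0, cv), -0.99)
    tibble::tibble(
      mouse_id = sprintf("bal_t%05.2f_m%02d", grid$time_h, grid$mouse),
      time_h = grid$time_h,
      bal_mg_L = elf_true * d * (1 + e1),
      urea_plasma = urea_plasma,
      urea_bal = urea_plasma * d * (1 + e2),
      dilution = d,
      elf_true_mg_L = elf_true
    )
  })
}

#' Generate an ultrafiltration protein-binding study
#'
#' Escalating single doses, several pooled replicates per dose; the
#' ultrafiltrate concentration is `total * true_fraction * (1 + eps)`.
#' [free_fraction()] recovers `true_fraction` exactly at zero noise.
#'
#' @param true_fraction Generating unbound fraction, in (0, 1].
#' @param dose_groups Dose levels, mg/kg (default the escalating 2.5/5/10
#'   single-dose design).
#' @param replicates Pooled replicates per dose group (default 3).
#' @param cv Proportional CV on the ultrafiltrate channel (default 0.05).
#' @param seed Integer seed.
#' @param truth Optional [pk_params()]; when supplied, the total plasma
#'   concentration per dose is the model value at `sample_time_h`, otherwise
#'   totals are proportional to dose (10 mg/L at the highest dose).
#' @param sample_time_h Sampling time when `truth` is used (default 1 h).
#' @return A tibble of binding records (`dose_mg_kg`, `replicate`,
#'   `total_mg_L`, `uf_mg_L`, `true_fraction`).
#' @export
generate_binding_study <- function(true_fraction,
                                   dose_groups = c(2.5, 5, 10),
                                   replicates = 3, cv = 0.05, seed = 1,
                                   truth = NULL, sample_time_h = 1) {
  stopifnot(true_fraction > 0, true_fraction <= 1, replicates >= 1, cv >= 0)
  grid <- tidyr::expand_grid(dose_mg_kg = dose_groups,
                             replicate = seq_len(replicates))
  totals <- if (!is.null(truth)) {
    vapply(grid$dose_mg_kg,
           function(d) single_dose_concentration(truth, d, sample_time_h),
           numeric(1))
  } else {
    10 * grid$dose_mg_kg / max(dose_groups)
  }
  withr::with_seed(seed, {
    eps <- pmax(stats::rnorm(nrow(grid), 0, cv), -0.99)
    tibble::tibble(
      dose_mg_kg = grid$dose_mg_kg,
      replicate = grid$replicate,
      total_mg_L = totals,
      uf_mg_L = totals * true_fraction * (1 + eps),
      true_fraction = true_fraction
    )
  })
}

#' Inject multiplicative outliers into a study dataset
#'
#' Flags a Bernoulli subset of observations and multiplies them by a factor
#' drawn from `multipliers`, recording which rows were hit so filter
#' operating characteristics (hit rate, false-exclusion rate) can be scored.
#'
#' @param study A `pk_study` (or a plain observations tibble with a
#'   `conc_mg_L` column).
#' @param probability Per-observation contamination probability.
#' @param multipliers Pool of multiplicative factors (default `c(5, 10)`).
#' @param seed Integer seed.
#' @return The same type as `study`, with contaminated `conc_mg_L` and an
#'   updated `is_outlier` flag.
#' @export
inject_outliers <- function(study, probability, multipliers = c(5, 10),
                            seed = 1) {
  stopifnot(probability >= 0, probability <= 1, all(multipliers > 0))
  obs <- if (inherits(study, "pk_study")) study$observations else
    tibble::as_tibble(study)
  stopifnot("conc_mg_L" %in% names(obs))
  obs <- withr::with_seed(seed, {
    hit <- stats::runif(nrow(obs)) < probability
    mult <- draw_multipliers(multipliers, nrow(obs))
    obs$conc_mg_L[hit] <- obs$conc_mg_L[hit] * mult[hit]
    prev <- obs$is_outlier %||% rep(FALSE, nrow(obs))
    obs$is_outlier <- prev | hit
    obs
  })
  if (inherits(study, "pk_study")) {
    study$observations <- obs
    study
  } else {
    obs
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
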