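# Independent oracles used to validate the closed-form machinery.
# These deliberately avoid the package's own term-list code paths.

# Plain-R superposition of the textbook single-dose closed form.
oracle_superpose <- function(t, doses, times, V, ka, kel, fu = 1) {
  out <- numeric(length(t))
  for (i in seq_along(doses)) {
    u <- t - times[i]
    act <- u >= 0
    out[act] <- out[act] +
      (doses[i] / V) * (ka / (ka - kel)) * (exp(-kel * u[act]) - exp(-ka * u[act]))
  }
  fu * out
}

# Numerical integration of the two-state absorption ODE with bolus dosing
# events into the depot compartment.
oracle_ode <- function(times, doses, dose_times, V, ka, kel, fu = 1) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  rhs <- function(t, y, p) {
    list(c(-ka * y[1], ka * y[1] / V - kel * y[2]))
  }
  ev <- data.frame(var = "A", time = dose_times, value = doses,
                   method = "add")
  all_t <- sort(unique(c(0, times, dose_times)))
  out <- deSolve::ode(y = c(A = 0, C = 0), times = all_t, func = rhs,
                      parms = NULL,
                      events = list(data = ev),
                      rtol = 1e-12, atol = 1e-12, method = "lsoda")
  unname(fu * out[match(times, out[, "time"]), "C"])
}

# Expand a repeated dose block (independent re-implementation).
oracle_expand <- function(times, doses, tau, horizon) {
  if (is.null(tau)) return(list(times = times, doses = doses))
  k <- 0:floor(horizon / tau)
  all_times <- as.vector(outer(times, k * tau, `+`))
  keep <- all_times <= horizon
  list(times = all_times[keep],
       doses = rep(doses, times = length(k))[keep])
}

# Fixture parameter/regimen sets (murine, one row per drug x matrix).
fixture_table <- function() {
  tibble::tibble(
    drug = rep(c("meropenem", "cefiderocol", "tobramycin"), each = 2),
    matrix = rep(c("plasma", "ELF"), 3),
    V = c(0.04, 1.60, 0.19, 0.33, 0.37, 0.79),
    ka = c(1.34, 7.00, 21.71, 1.94, 23.68, 1.74),
    kel = c(27.13, 2.50, 0.74, 0.72, 0.31, 0.35),
    fu = c(0.92, 1, 0.684, 1, 0.776, 1),
    times = list(c(0, 1.25, 3.5, 6), c(0, 1.25, 3.5, 4.75, 6),
                 c(0, 1, 2, 4, 6), c(0, 1, 2, 4, 6),
                 c(0, 3, 6, 9), c(0, 1.5, 3, 4.5, 6.5, 9, 12.5, 16)),
    doses = list(c(65, 65, 45, 45), c(20, 50, 30, 20, 15),
                 c(5, 7.5, 10, 3.5, 1), c(3.75, 5, 6.25, 1.75, 1),
                 c(9, 4, 2, 0.5), c(4.8, 3.6, 2.4, 2.4, 2.7, 2.4, 1.2, 1.2)),
    tau = c(8, 8, 8, 8, NA, NA)
  )
}

fixture_params <- function(row) {
  pk_params(row$V, row$ka, row$kel, matrix = row$matrix)
}

fixture_regimen <- function(row) {
  regimen(row$times[[1]], row$doses[[1]],
          repeat_interval = if (is.na(row$tau)) NULL else row$tau,
          horizon = 24)
}
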