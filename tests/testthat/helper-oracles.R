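# Independent oracles used to freeze expected values.

# Numerical ODE integration of dP/dt = k exp(-D t) (1 - P), P(0) = 0 --
# an independent route to the closed-form extension curve.
ode_pe <- function(times, k, D) {
  out <- deSolve::ode(
    y = c(P = 0), times = sort(unique(c(0, times))),
    func = function(t, y, parms) list(parms["k"] * exp(-parms["D"] * t) * (1 - y)),
    parms = c(k = k, D = D), method = "ode45",
    atol = 1e-12, rtol = 1e-12
  )
  out[match(times, out[, "time"]), "P"]
}

# Brute-force lattice search for the least-squares (k, D) on a time course.
grid_fit <- function(times, pe, k_range, D_range, n = 81) {
  ks <- seq(k_range[1], k_range[2], length.out = n)
  Ds <- seq(D_range[1], D_range[2], length.out = n)
  best <- c(NA, NA); best_sse <- Inf
  for (k in ks) for (D in Ds) {
    sse <- sum((pe - pe_model(times, k, D))^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(k, D) }
  }
  c(k = best[1], D = best[2])
}

# Standard 9-point sampling grid used across the fitting tests (minutes).
tc_grid <- c(0, 15, 30, 60, 90, 120, 180, 240, 300)
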