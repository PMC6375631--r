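#' Stochastic three-state conformational-switch ensemble simulation
#'
#' Simulates an ensemble of pol V Mut molecules switching between three
#' conformational states: State 1 (assembled but catalytically inactive,
#' cannot bind p/t DNA), State 2 (ATP-activated, binds and synthesizes DNA),
#' and State 3 (deactivated). Each molecule starts in State 1 and activates at
#' rate `k_act` (instantaneous by default, treating ATP binding as fast);
#' active molecules deactivate at rate `d_dyn` during synthesis (or `d_stat`
#' when synthesis is disabled). Deactivated molecules return to State 2 only
#' at explicit RecA* dosing times, each with probability `reactivation_eff`.
#' Transition times are sampled exactly (exponential waiting times, no
#' fixed-step discretization); the output grid is for reporting only.
#'
#' Predicted primer extension accrues only from time spent in State 2: at the
#' ensemble level `pe(t) = 1 - exp(-k_syn * A(t))` where `A(t)` is the mean
#' per-molecule time spent in State 2 up to `t`. With instantaneous activation
#' and no reactivation this converges to the closed form [pe_model()] as the
#' ensemble grows.
#'
#' @param n_molecules Ensemble size.
#' @param k_syn Per-active-enzyme synthesis rate, min^-1.
#' @param d_dyn Dynamic deactivation rate in the synthesizing state, min^-1.
#' @param d_stat Static deactivation rate when synthesis is disabled, min^-1.
#' @param k_act Activation rate out of State 1, min^-1; `Inf` (default) means
#'   molecules start activated.
#' @param synthesis Logical; when `FALSE` the enzyme idles in State 2 (no
#'   synthesis) and deactivates at `d_stat` instead of `d_dyn`.
#' @param reactivation_times Minutes at which RecA* is added (may be empty).
#' @param reactivation_eff Fraction of deactivated molecules restored at each
#'   dosing time, in `[0, 1]`.
#' @param t_grid Reporting grid, minutes, increasing, nonempty.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `"ensemble_trace"`: data frame with columns
#'   `time_min`, `frac_s1`, `frac_s2`, `frac_s3`, `pe`, with the parameters
#'   stored in `attr(, "params")`. Occupancies sum to 1 at every time.
#' @examples
#' tr <- sim_state_ensemble(2000, k_syn = 0.008, d_dyn = 0.028,
#'                          t_grid = seq(0, 300, 30), seed = 1)
#' head(tr)
#' @export
sim_state_ensemble <- function(n_molecules, k_syn, d_dyn, d_stat = d_dyn,
                               k_act = Inf, synthesis = TRUE,
                               reactivation_times = numeric(0),
                               reactivation_eff = 1,
                               t_grid, seed = NULL) {
  if (missing(t_grid) || !length(t_grid)) stop("'t_grid' must be a nonempty increasing grid")
  if (any(diff(t_grid) <= 0)) stop("'t_grid' must be strictly increasing")
  if (any(c(k_syn, d_dyn, d_stat) < 0) || (is.finite(k_act) && k_act < 0)) {
    stop("rates must be nonnegative")
  }
  if (reactivation_eff < 0 || reactivation_eff > 1) stop("'reactivation_eff' must lie in [0, 1]")
  d_eff <- if (synthesis) d_dyn else d_stat
  r_times <- sort(reactivation_times)
  horizon <- max(t_grid)
  .with_seed(seed, {
    # per-molecule State-2 intervals [a, b) and activation times
    a_all <- numeric(0); b_all <- numeric(0)
    t_on <- if (is.finite(k_act)) stats::rexp(n_molecules, k_act) else rep(0, n_molecules)
    for (i in seq_len(n_molecules)) {
      t_cur <- t_on[i]
      while (t_cur <= horizon) {
        t_off <- t_cur + if (d_eff > 0) stats::rexp(1, d_eff) else Inf
        a_all <- c(a_all, t_cur); b_all <- c(b_all, min(t_off, Inf))
        if (t_off > horizon) break
        # deactivated at t_off: wait for a successful reactivation dose
        # (eff = 0 draws nothing, so the trace matches a no-dose run seed-for-seed)
        t_cur <- Inf
        if (reactivation_eff > 0) {
          for (tr in r_times[r_times >= t_off]) {
            if (stats::runif(1) < reactivation_eff) { t_cur <- tr; break }
          }
        }
        if (!is.finite(t_cur)) break
      }
    }
    frac_s1 <- vapply(t_grid, function(t) mean(t_on > t), numeric(1))
    frac_s2 <- vapply(t_grid, function(t) sum(a_all <= t & t < b_all), numeric(1)) / n_molecules
    frac_s3 <- pmax(0, 1 - frac_s1 - frac_s2)
    # mean time in State 2 up to each grid time
    a_t <- vapply(t_grid, function(t) sum(pmax(0, pmin(b_all, t) - pmin(a_all, t))), numeric(1)) / n_molecules
    pe <- if (synthesis) -expm1(-k_syn * a_t) else rep(0, length(t_grid))
    out <- data.frame(time_min = t_grid, frac_s1 = frac_s1, frac_s2 = frac_s2,
                      frac_s3 = frac_s3, pe = pe)
    attr(out, "params") <- list(n_molecules = n_molecules, k_syn = k_syn,
                                d_dyn = d_dyn, d_stat = d_stat, k_act = k_act,
                                synthesis = synthesis,
                                reactivation_times = r_times,
                                reactivation_eff = reactivation_eff)
    class(out) <- c("ensemble_trace", "data.frame")
    out
  })
}

#' Ensemble response to a single RecA* reactivation dose
#'
#' Convenience wrapper around [sim_state_ensemble()] with one reactivation
#' event at `t_r`. Extension resumes after the dose; with full efficiency and
#' instantaneous activation the post-dose kinetics re-run the plateau formula
#' on the remaining unextended fraction.
#'
#' @param t_r Dosing time, minutes; must lie inside the reporting grid.
#' @inheritParams sim_state_ensemble
#' @export
reactivation_response <- function(n_molecules, k_syn, d_dyn, t_r,
                                  reactivation_eff = 1, t_grid, seed = NULL, ...) {
  if (t_r < min(t_grid) || t_r > max(t_grid)) {
    stop("'t_r' must lie inside the reporting grid")
  }
  sim_state_ensemble(n_molecules, k_syn, d_dyn,
                     reactivation_times = t_r,
                     reactivation_eff = reactivation_eff,
                     t_grid = t_grid, seed = seed, ...)
}

#' @export
plot.ensemble_trace <- function(x, ...) {
  graphics::matplot(x$time_min, cbind(x$frac_s1, x$frac_s2, x$frac_s3, x$pe),
                    type = "l", lty = c(3, 1, 2, 1), lwd = c(1, 2, 1, 2),
                    col = c("grey40", "forestgreen", "firebrick", "navy"),
                    xlab = "Time (min)", ylab = "Fraction", ...)
  graphics::legend("right", c("State 1 (inactive)", "State 2 (active)",
                              "State 3 (deactivated)", "Fraction extended"),
                   lty = c(3, 1, 2, 1), lwd = c(1, 2, 1, 2),
                   col = c("grey40", "forestgreen", "firebrick", "navy"), bty = "n")
  invisible(x)
}
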