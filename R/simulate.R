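#' Simulate a primer-extension time course with dynamic deactivation
#'
#' Draws noisy extension time courses from the closed-form deactivation model
#' [pe_model()]: the noiseless fraction extended is `P(t)` for the given
#' `(k, D)`, additive Gaussian noise with standard deviation `noise_sd` is
#' applied on the fraction scale, and values are clipped to `[0, 1]`.
#' Replicates are independent; the same seed reproduces the output exactly.
#'
#' @param k Synthesis rate constant, min^-1 (`>= 0`).
#' @param D Dynamic deactivation rate, min^-1 (`>= 0`).
#' @param times Sample times in minutes, nonnegative and strictly increasing.
#' @param noise_sd Additive Gaussian SD on the fraction scale (`>= 0`).
#' @param n_replicates Number of independent replicates.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A data frame with columns `time_min`, `pe_fraction`,
#'   `replicate_id`, and attribute `truth = c(k, D)`.
#' @examples
#' sim_extension(0.008, 0.028, times = c(0, 30, 60, 120), seed = 1)
#' @export
sim_extension <- function(k, D, times, noise_sd = 0, n_replicates = 1, seed = NULL) {
  if (k < 0 || D < 0) stop("rates must be nonnegative")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (any(times < 0)) stop("times must be nonnegative")
  d <- diff(times)
  if (any(d <= 0)) stop("times must be strictly increasing; offending index ", which(d <= 0)[1L] + 1L)
  .with_seed(seed, {
    mu <- pe_model(times, k, D)
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      p <- mu
      if (noise_sd > 0) p <- pmin(1, pmax(0, p + stats::rnorm(length(p), 0, noise_sd)))
      data.frame(time_min = times, pe_fraction = p, replicate_id = r)
    }))
    attr(out, "truth") <- c(k = k, D = D)
    out
  })
}

#' Simulate a static-deactivation activity series
#'
#' Relative polymerase activity `A(t) = exp(-rate * t)` plus additive Gaussian
#' noise, clipped to `[0, 1.05]`. Noiseless activity at `t = 0` is exactly 1.
#'
#' @param rate Static deactivation rate, min^-1 (`>= 0`).
#' @param times Incubation times in minutes, starting at 0.
#' @param noise_sd Additive Gaussian SD on the relative-activity scale.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A data frame with columns `time_min`, `rel_activity` and attribute
#'   `truth = rate`.
#' @examples
#' sim_activity(0.015, times = c(0, 30, 60, 120, 240))
#' @export
sim_activity <- function(rate, times, noise_sd = 0, seed = NULL) {
  if (rate < 0) stop("'rate' must be nonnegative")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (times[1L] != 0) stop("'times' must start at 0 (activity is relative to t = 0)")
  .with_seed(seed, {
    a <- exp(-rate * times)
    if (noise_sd > 0) a <- pmin(1.05, pmax(0, a + stats::rnorm(length(a), 0, noise_sd)))
    out <- data.frame(time_min = times, rel_activity = a)
    attr(out, "truth") <- c(rate = rate)
    out
  })
}

#' Simulate two-state smFRET binding trajectories
#'
#' Generates donor/acceptor intensity trajectories from an alternating-renewal
#' two-state process: the enzyme starts unbound, dwell times are exponential
#' with means `tau_unbound` and `tau_bound`, and frames are assigned the state
#' occupying the frame midpoint. In bound frames the acceptor emits
#' `I_total * E_bound` and the donor `I_total * (1 - E_bound)`; in unbound
#' frames the donor emits `unbound_donor` and the acceptor `unbound_acceptor`
#' (the acceptor-labeled enzyme is out of FRET range). Per-channel additive
#' Gaussian noise of SD `noise_sd` is applied to every frame. Optional
#' photobleaching truncates each trajectory at an exponential time with mean
#' `bleach_tau`. The ground-truth event list (continuous-time bound and
#' unbound intervals, including dwells shorter than one frame) is returned so
#' detection bias can be measured against it.
#'
#' @param n_traj Number of trajectories.
#' @param tau_bound,tau_unbound Mean bound / unbound dwell times, seconds.
#' @param E_bound Bound-state FRET efficiency, strictly inside `(0, 1)`.
#' @param frame_dt Frame interval, seconds.
#' @param duration Trajectory length, seconds.
#' @param I_total Total emission intensity in the bound state (arbitrary units).
#' @param noise_sd Per-channel additive Gaussian SD, same units as `I_total`.
#' @param unbound_donor,unbound_acceptor Channel levels while unbound.
#' @param bleach_tau Mean photobleach time in seconds, or `NULL` to disable.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list with `trajectories` (data frame `traj_id, frame, time_s,
#'   intensity_donor, intensity_acceptor`) and `truth` (data frame `traj_id,
#'   start_s, end_s, state` with `state` in `c("bound", "unbound")`), plus
#'   `frame_dt` and `duration`.
#' @examples
#' sim <- sim_fret(2, tau_bound = 6.1, tau_unbound = 17, seed = 1)
#' head(sim$trajectories)
#' subset(sim$truth, state == "bound")
#' @export
sim_fret <- function(n_traj, tau_bound, tau_unbound, E_bound = 0.7,
                     frame_dt = 0.3, duration = 180, I_total = 500,
                     noise_sd = 0, unbound_donor = I_total,
                     unbound_acceptor = 0, bleach_tau = NULL, seed = NULL) {
  if (tau_bound <= 0 || !is.finite(tau_bound)) stop("'tau_bound' must be positive and finite")
  if (tau_unbound <= 0) stop("'tau_unbound' must be positive")
  if (E_bound <= 0 || E_bound >= 1) stop("'E_bound' must lie strictly inside (0, 1)")
  if (frame_dt <= 0 || duration <= 0) stop("'frame_dt' and 'duration' must be positive")
  if (duration < frame_dt) stop("'duration' must cover at least one frame")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (!is.null(bleach_tau) && bleach_tau <= 0) stop("'bleach_tau' must be positive")
  .with_seed(seed, {
    traj_list <- vector("list", n_traj)
    truth_list <- vector("list", n_traj)
    for (i in seq_len(n_traj)) {
      t_end <- duration
      if (!is.null(bleach_tau)) {
        t_end <- min(duration, stats::rexp(1, 1 / bleach_tau))
        t_end <- max(t_end, frame_dt) # keep at least one frame
      }
      # alternating renewal starting unbound
      starts <- numeric(0); ends <- numeric(0); states <- character(0)
      t_cur <- 0; bound <- FALSE
      while (t_cur < t_end) {
        dwell <- stats::rexp(1, 1 / if (bound) tau_bound else tau_unbound)
        t_next <- min(t_cur + dwell, t_end)
        starts <- c(starts, t_cur); ends <- c(ends, t_next)
        states <- c(states, if (bound) "bound" else "unbound")
        t_cur <- t_cur + dwell
        bound <- !bound
      }
      n_frames <- floor(t_end / frame_dt + 1e-9)
      mid <- (seq_len(n_frames) - 0.5) * frame_dt
      seg <- findInterval(mid, starts)
      frame_bound <- states[seg] == "bound"
      i_d <- ifelse(frame_bound, I_total * (1 - E_bound), unbound_donor)
      i_a <- ifelse(frame_bound, I_total * E_bound, unbound_acceptor)
      if (noise_sd > 0) {
        i_d <- i_d + stats::rnorm(n_frames, 0, noise_sd)
        i_a <- i_a + stats::rnorm(n_frames, 0, noise_sd)
      }
      traj_list[[i]] <- data.frame(
        traj_id = i, frame = seq_len(n_frames),
        time_s = (seq_len(n_frames) - 1) * frame_dt,
        intensity_donor = i_d, intensity_acceptor = i_a
      )
      truth_list[[i]] <- data.frame(traj_id = i, start_s = starts,
                                    end_s = ends, state = states)
    }
    list(trajectories = do.call(rbind, traj_list),
         truth = do.call(rbind, truth_list),
         frame_dt = frame_dt, duration = duration)
  })
}

# evaluate `expr` under `seed` without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L) stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible child seeds from a single master seed
#'
#' Fans one master seed out into `n` independent child seeds so that pipeline
#' stages can be re-run in isolation while remaining reproducible end to end.
#' Child seeds are below 2^31.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max, n))
}
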