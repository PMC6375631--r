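#' Per-frame FRET efficiency from donor/acceptor intensities
#'
#' `E = I_A / (I_D + I_A)`, clipped to `[0, 1]`. Frames with a nonpositive
#' total intensity carry no usable signal and are returned as `NA` so event
#' logic can exclude them.
#'
#' @param i_donor,i_acceptor Donor and acceptor intensities (vectors).
#' @return Efficiency vector in `[0, 1]`, `NA` where `i_donor + i_acceptor <= 0`.
#' @examples
#' fret_efficiency(500, 500)        # 0.5
#' fret_efficiency(300 * 0.3, 300 * 0.7)  # 0.7
#' @export
fret_efficiency <- function(i_donor, i_acceptor) {
  if (length(i_donor) != length(i_acceptor)) stop("channel lengths differ")
  total <- i_donor + i_acceptor
  e <- ifelse(total > 0, pmin(1, pmax(0, i_acceptor / total)), NA_real_)
  e
}

#' Detect binding events in smFRET trajectories by threshold runs
#'
#' Idealizes each donor/acceptor trajectory into binding events: maximal runs
#' of at least `min_frames` consecutive frames whose FRET efficiency is at or
#' above `threshold`. A run touching the first or last frame of a trajectory
#' is flagged as left- or right-censored (its true extent is unknown). Event
#' duration counts qualifying frames times the frame interval. Optional
#' hysteresis bridges single-frame sub-threshold gaps inside an event.
#'
#' Background handling: with `background = "median"` the per-trajectory median
#' acceptor intensity over provisionally unbound frames is subtracted from the
#' acceptor channel (floored at zero) before efficiencies are finalized.
#'
#' @param trajectories Data frame with columns `traj_id`, `time_s`,
#'   `intensity_donor`, `intensity_acceptor` (one or more trajectories), e.g.
#'   the `trajectories` element of [sim_fret()].
#' @param threshold Efficiency threshold for the bound state.
#' @param min_frames Minimum run length, frames (`>= 1`).
#' @param background `"median"` (default) or `"none"`.
#' @param hysteresis Logical; bridge single-frame dropouts inside events.
#' @return An object of class `"event_set"`: list with `events` (data frame
#'   `traj_id, start_s, end_s, dwell_s, mean_E, left_censored,
#'   right_censored`), `frames` (per-frame `traj_id, time_s, E, in_event`),
#'   `frame_dt`, and per-trajectory `meta` (`traj_id, duration, n_frames`).
#' @examples
#' sim <- sim_fret(5, tau_bound = 6.1, tau_unbound = 17, seed = 2)
#' es <- detect_events(sim$trajectories)
#' es$events
#' @export
detect_events <- function(trajectories, threshold = 0.2, min_frames = 2,
                          background = c("median", "none"), hysteresis = FALSE) {
  background <- match.arg(background)
  req <- c("traj_id", "time_s", "intensity_donor", "intensity_acceptor")
  if (!all(req %in% names(trajectories))) {
    stop("'trajectories' must have columns ", paste(req, collapse = ", "))
  }
  if (min_frames < 1) stop("'min_frames' must be at least 1")
  by_traj <- split(trajectories, trajectories$traj_id)
  ev_list <- list(); fr_list <- list(); meta_list <- list()
  frame_dt <- NA_real_
  for (tr in by_traj) {
    tr <- tr[order(tr$time_s), ]
    n <- nrow(tr)
    dt <- if (n > 1L) stats::median(diff(tr$time_s)) else NA_real_
    if (n > 2L) {
      rel <- abs(diff(tr$time_s) - dt) / dt
      if (any(rel > 0.01)) stop("frame spacing varies by more than 1% in trajectory ", tr$traj_id[1L])
    }
    if (is.na(frame_dt)) frame_dt <- dt
    e_raw <- fret_efficiency(tr$intensity_donor, tr$intensity_acceptor)
    bound0 <- !is.na(e_raw) & e_raw >= threshold
    i_a <- tr$intensity_acceptor
    if (background == "median" && any(!bound0)) {
      bg <- stats::median(i_a[!bound0])
      if (is.finite(bg) && bg > 0) i_a <- pmax(i_a - bg, 0)
    }
    e <- fret_efficiency(tr$intensity_donor, i_a)
    bound <- !is.na(e) & e >= threshold
    if (hysteresis && n > 2L) {
      # bridge isolated single-frame dropouts flanked by bound frames
      drop1 <- which(!bound[2:(n - 1)]) + 1L
      drop1 <- drop1[bound[drop1 - 1L] & bound[drop1 + 1L]]
      bound[drop1] <- TRUE
    }
    r <- rle(bound)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- r$values & r$lengths >= min_frames
    in_event <- rep(FALSE, n)
    if (any(keep)) {
      s_idx <- run_start[keep]; e_idx <- run_end[keep]
      for (j in seq_along(s_idx)) in_event[s_idx[j]:e_idx[j]] <- TRUE
      nf <- e_idx - s_idx + 1L
      ev_list[[length(ev_list) + 1L]] <- data.frame(
        traj_id = tr$traj_id[1L],
        start_s = tr$time_s[s_idx],
        end_s = tr$time_s[s_idx] + nf * dt,
        dwell_s = nf * dt,
        mean_E = vapply(seq_along(s_idx), function(j) mean(e[s_idx[j]:e_idx[j]]), numeric(1)),
        left_censored = s_idx == 1L,
        right_censored = e_idx == n
      )
    }
    fr_list[[length(fr_list) + 1L]] <- data.frame(
      traj_id = tr$traj_id[1L], time_s = tr$time_s, E = e, in_event = in_event
    )
    meta_list[[length(meta_list) + 1L]] <- data.frame(
      traj_id = tr$traj_id[1L], duration = n * dt, n_frames = n
    )
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(traj_id = integer(0), start_s = numeric(0), end_s = numeric(0),
               dwell_s = numeric(0), mean_E = numeric(0),
               left_censored = logical(0), right_censored = logical(0))
  structure(list(events = events,
                 frames = do.call(rbind, fr_list),
                 meta = do.call(rbind, meta_list),
                 frame_dt = frame_dt,
                 threshold = threshold, min_frames = min_frames),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("smFRET event set: %d event(s) in %d trajectory(ies), frame %.3g s\n",
              nrow(x$events), nrow(x$meta), x$frame_dt))
  cat(sprintf("  threshold E >= %.3g, min %d frames; %d censored event(s)\n",
              x$threshold, x$min_frames,
              sum(x$events$left_censored | x$events$right_censored)))
  invisible(x)
}

#' Bound dwell times from an event set
#'
#' Dwell durations of detected binding events. Events truncated by the start
#' or end of acquisition (censored) are excluded by default because their true
#' dwell is unknown.
#'
#' @param es An `"event_set"` from [detect_events()].
#' @param include_censored Include censored events.
#' @return Numeric vector of dwell times, seconds.
#' @export
dwell_times <- function(es, include_censored = FALSE) {
  stopifnot(inherits(es, "event_set"))
  ev <- es$events
  if (!include_censored) ev <- ev[!ev$left_censored & !ev$right_censored, ]
  ev$dwell_s
}

#' Rebinding times (gaps between consecutive events)
#'
#' Intervals from the end of one binding event to the start of the next event
#' in the same trajectory. Intervals touching the trajectory edges (before the
#' first or after the last event) are excluded by construction.
#'
#' @param es An `"event_set"` from [detect_events()].
#' @return Numeric vector of gap times, seconds.
#' @export
rebind_times <- function(es) {
  stopifnot(inherits(es, "event_set"))
  unlist(lapply(split(es$events, es$events$traj_id), function(ev) {
    if (nrow(ev) < 2L) return(numeric(0))
    ev <- ev[order(ev$start_s), ]
    ev$start_s[-1L] - ev$end_s[-nrow(ev)]
  }), use.names = FALSE)
}

#' Histogram of per-frame FRET efficiencies within binding events
#'
#' Bins the per-frame efficiencies of all frames inside detected events into
#' bins of width `bin_width` centered on multiples of `bin_width` (so 0.70 is
#' a bin center when `bin_width = 0.05`), and reports the modal bin.
#'
#' @param es An `"event_set"` from [detect_events()].
#' @param bin_width Bin width on the efficiency scale.
#' @return A list of class `"eff_hist"`: `mids`, `counts`, `breaks`,
#'   `mode` (center of the most occupied bin), `n` frames binned.
#' @export
efficiency_histogram <- function(es, bin_width = 0.05) {
  stopifnot(inherits(es, "event_set"))
  e <- es$frames$E[es$frames$in_event & !is.na(es$frames$E)]
  if (!length(e)) stop("no bound frames; cannot build an efficiency histogram")
  breaks <- seq(-bin_width / 2, 1 + bin_width, by = bin_width)
  h <- graphics::hist(e, breaks = breaks, plot = FALSE, right = FALSE)
  mode_mid <- h$mids[which.max(h$counts)]
  structure(list(mids = h$mids, counts = h$counts, breaks = h$breaks,
                 mode = mode_mid, n = length(e)), class = "eff_hist")
}

#' @export
print.eff_hist <- function(x, ...) {
  cat(sprintf("FRET efficiency histogram: %d bound frames, mode bin at %.3g\n",
              x$n, x$mode))
  invisible(x)
}

#' @export
plot.eff_hist <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = sprintf("%.2f", x$mids),
                    xlab = "FRET efficiency", ylab = "Frames", ...)
  invisible(x)
}
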