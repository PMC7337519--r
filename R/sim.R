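# Synthetic TPM data: continuous-time three-state kinetics and trajectory
# rendering. Time conventions: rates and dwell times in minutes, frame
# timestamps in seconds (see min_to_s / s_to_min).

#' Convert minutes to seconds
#' @param x numeric, minutes.
#' @return numeric, seconds.
#' @export
min_to_s <- function(x) x * 60

#' Convert seconds to minutes
#' @param x numeric, seconds.
#' @return numeric, minutes.
#' @export
s_to_min <- function(x) x / 60

#' Simulation configuration for a tethered-bead experiment
#'
#' Parameters of the three-state kinetic model (unlooped, looped paired
#' complex, cleaved) and of the rendered RMSD observable. Rates are per
#' minute; RMSD levels and noise are in nm; the frame interval is in
#' seconds; phase durations are in minutes.
#'
#' The default RMSD levels (unlooped 250 nm, looped 160 nm) are
#' illustrative values chosen to be well separated relative to the default
#' per-frame noise, not calibrated tether-length measurements.
#'
#' @param k_loop looping rate per minute (unlooped -> looped).
#' @param k_unloop unlooping rate per minute (looped -> unlooped).
#' @param k_cut cleavage rate per minute (looped -> cleaved, absorbing).
#' @param rmsd_unlooped RMSD level of the unlooped tether, nm.
#' @param rmsd_looped RMSD level of the looped tether, nm; must be below
#'   `rmsd_unlooped`.
#' @param noise_sd per-frame Gaussian observation noise on RMSD, nm.
#' @param frame_interval acquisition frame interval, seconds.
#' @param baseline_duration protein-free baseline phase, minutes; looping
#'   is forbidden during the baseline.
#' @param observation_duration post-baseline observation window, minutes.
#' @param deadend_fraction probability that an entry into the looped state
#'   is a permanently bound "dead-end" complex that never leaves within the
#'   observation window.
#' @param release_duration seconds of trace retained after a cleavage
#'   event before the released bead is lost.
#' @param seed integer master seed; every bead derives an independent
#'   substream from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(k_loop, k_unloop, k_cut,
                       rmsd_unlooped = 250, rmsd_looped = 160,
                       noise_sd = 15, frame_interval = 1,
                       baseline_duration = 10, observation_duration = 60,
                       deadend_fraction = 0, release_duration = 5,
                       seed = 1L) {
  cfg <- list(
    k_loop = k_loop, k_unloop = k_unloop, k_cut = k_cut,
    rmsd_unlooped = rmsd_unlooped, rmsd_looped = rmsd_looped,
    noise_sd = noise_sd, frame_interval = frame_interval,
    baseline_duration = baseline_duration,
    observation_duration = observation_duration,
    deadend_fraction = deadend_fraction,
    release_duration = release_duration,
    seed = as.integer(seed)
  )
  for (r in c("k_loop", "k_unloop", "k_cut")) {
    v <- cfg[[r]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("`%s` must be a single non-negative rate (per min)", r))
    }
  }
  if (cfg$rmsd_looped >= cfg$rmsd_unlooped) {
    stop("`rmsd_looped` must be strictly below `rmsd_unlooped`")
  }
  if (cfg$frame_interval <= 0) stop("`frame_interval` must be positive (s)")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be non-negative (nm)")
  if (cfg$baseline_duration < 0) stop("`baseline_duration` must be >= 0 (min)")
  if (cfg$observation_duration <= 0) {
    stop("`observation_duration` must be positive (min)")
  }
  if (cfg$deadend_fraction < 0 || cfg$deadend_fraction > 1) {
    stop("`deadend_fraction` must lie in [0, 1]")
  }
  if (cfg$release_duration < 0) stop("`release_duration` must be >= 0 (s)")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("TPM simulation config\n")
  cat(sprintf("  rates (per min): k_loop=%.3g  k_unloop=%.3g  k_cut=%.3g\n",
              x$k_loop, x$k_unloop, x$k_cut))
  cat(sprintf("  RMSD levels (nm): unlooped=%.0f  looped=%.0f  noise sd=%.1f\n",
              x$rmsd_unlooped, x$rmsd_looped, x$noise_sd))
  cat(sprintf("  frames: %.3g s interval; baseline %.3g min + observation %.3g min\n",
              x$frame_interval, x$baseline_duration, x$observation_duration))
  cat(sprintf("  deadend fraction %.3g; seed %d\n",
              x$deadend_fraction, x$seed))
  invisible(x)
}

# Derive a reproducible 31-bit substream seed for bead `bead`, stream
# `stream`, from the master seed. Bead i is reproducible independent of how
# many beads are simulated.
bead_seed <- function(seed, bead, stream = 0L) {
  m <- 2147483587
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + as.numeric(bead) * 33614 + as.numeric(stream) * 9973) %% m
  as.integer(s)
}

#' Simulate a ground-truth state path for one bead
#'
#' Draws a realisation of the continuous-time Markov chain: the tether
#' starts unlooped, may not loop during the baseline phase, then alternates
#' unlooped (holding time Exponential(`k_loop`)) and looped states. From
#' the looped state the two fates compete as independent exponentials with
#' total rate `k_unloop + k_cut`; the fate is cleavage with probability
#' `k_cut / (k_unloop + k_cut)`. Cleavage is absorbing. With probability
#' `deadend_fraction` an entry into the looped state is a dead-end complex
#' that persists to the end of the window.
#'
#' @param config a [sim_config()].
#' @param bead bead index used to derive the RNG substream.
#' @return a `data.frame` with columns `state` (`"UNLOOPED"`, `"LOOPED"`,
#'   `"CLEAVED"`), `t_start_min`, `t_end_min`; contiguous, non-overlapping
#'   segments covering `[0, baseline + observation]` minutes. Attribute
#'   `cleaved` records whether the path ends in cleavage.
#' @export
simulate_state_path <- function(config, bead = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(bead_seed(config$seed, bead, 1L))
  t_end <- config$baseline_duration + config$observation_duration
  k_leave <- config$k_unloop + config$k_cut
  states <- character(0)
  starts <- numeric(0)
  ends <- numeric(0)
  push <- function(s, a, b) {
    states <<- c(states, s); starts <<- c(starts, a); ends <<- c(ends, b)
  }
  t_now <- config$baseline_duration  # loops forbidden before this
  seg_start <- 0
  cleaved <- FALSE
  repeat {
    if (config$k_loop == 0) {
      push("UNLOOPED", seg_start, t_end)
      break
    }
    t_loop <- t_now + stats::rexp(1L, config$k_loop)
    if (t_loop >= t_end) {
      push("UNLOOPED", seg_start, t_end)
      break
    }
    push("UNLOOPED", seg_start, t_loop)
    dead <- config$deadend_fraction > 0 &&
      stats::runif(1L) < config$deadend_fraction
    if (dead || k_leave == 0) {
      push("LOOPED", t_loop, t_end)
      break
    }
    dwell <- stats::rexp(1L, k_leave)
    cut <- stats::runif(1L) < config$k_cut / k_leave
    if (t_loop + dwell >= t_end) {
      push("LOOPED", t_loop, t_end)
      break
    }
    push("LOOPED", t_loop, t_loop + dwell)
    if (cut) {
      push("CLEAVED", t_loop + dwell, t_end)
      cleaved <- TRUE
      break
    }
    seg_start <- t_loop + dwell
    t_now <- t_loop + dwell
  }
  structure(
    data.frame(state = states, t_start_min = starts, t_end_min = ends,
               stringsAsFactors = FALSE),
    cleaved = cleaved
  )
}

#' Render a noisy RMSD trajectory from a state path
#'
#' Produces one RMSD sample per frame: the state's RMSD level plus
#' independent Gaussian observation noise. After a cleavage event the
#' released bead is lost and the trace terminates `release_duration`
#' seconds after the cut.
#'
#' @param path a state path from [simulate_state_path()].
#' @param config the [sim_config()] the path was simulated under.
#' @param bead bead index (RNG substream for the noise).
#' @param bead_id label written in the `bead_id` column; defaults to
#'   `sprintf("bead_%04d", bead)`.
#' @return a `data.frame` with columns `bead_id`, `time_s`, `rmsd_nm`, and
#'   attributes `frame_interval_s`, `baseline_s`, `expected_end_s` (the
#'   nominal end of observation, used downstream to detect bead loss).
#' @export
render_trajectory <- function(path, config, bead = 1L,
                              bead_id = sprintf("bead_%04d", bead)) {
  stopifnot(inherits(config, "sim_config"),
            is.data.frame(path),
            all(c("state", "t_start_min", "t_end_min") %in% names(path)))
  total_s <- min_to_s(config$baseline_duration + config$observation_duration)
  dt <- config$frame_interval
  n_frames <- floor(total_s / dt)
  time_s <- (seq_len(n_frames) - 1) * dt
  # state at each frame: index of segment containing the frame time
  seg_idx <- findInterval(s_to_min(time_s), path$t_start_min,
                          rightmost.closed = FALSE)
  seg_idx[seg_idx < 1L] <- 1L
  state <- path$state[seg_idx]
  cleave_row <- match("CLEAVED", path$state)
  if (!is.na(cleave_row)) {
    cut_s <- min_to_s(path$t_start_min[cleave_row])
    keep <- time_s < cut_s + config$release_duration
    time_s <- time_s[keep]
    state <- state[keep]
    # frames during the brief release window still show the looped level
    state[state == "CLEAVED"] <- "LOOPED"
  }
  level <- ifelse(state == "LOOPED", config$rmsd_looped, config$rmsd_unlooped)
  set.seed(bead_seed(config$seed, bead, 2L))
  rmsd <- level + stats::rnorm(length(level), 0, config$noise_sd)
  rmsd <- pmax(rmsd, 0)
  structure(
    data.frame(bead_id = bead_id, time_s = time_s, rmsd_nm = rmsd,
               stringsAsFactors = FALSE),
    frame_interval_s = dt,
    baseline_s = min_to_s(config$baseline_duration),
    expected_end_s = total_s
  )
}

#' Draw dwell times directly from the competing-exponential model
#'
#' Samples paired-complex lifetimes from Exponential(`k_unloop + k_cut`)
#' and assigns each a fate (`"CUT"` with probability
#' `k_cut / (k_unloop + k_cut)`, else `"UNLOOP"`), bypassing trajectory
#' rendering. An optional contamination component emulates heavy-tailed
#' empirical distributions: either a second exponential (hyperexponential
#' mixture) or dead-end lifetimes pinned at an observation limit.
#'
#' @param n number of dwell records.
#' @param k_unloop unlooping rate, per minute.
#' @param k_cut cleavage rate, per minute. `k_unloop + k_cut` must be
#'   positive.
#' @param contamination `NULL`, or a list with `fraction` (mixture weight
#'   in \[0, 1\]) and either `rate` (second exponential component, per
#'   minute) or `deadend_at` (fixed censored lifetime in minutes).
#' @param seed integer RNG seed.
#' @return a `data.frame` with columns `bead_id` (NA; no bead structure),
#'   `duration_min`, `fate` (`"UNLOOP"`, `"CUT"`, or `"CENSORED"` for
#'   dead-end contamination).
#' @export
simulate_dwell_sample <- function(n, k_unloop, k_cut, contamination = NULL,
                                  seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  if (k_unloop < 0 || k_cut < 0) stop("rates must be non-negative")
  k_leave <- k_unloop + k_cut
  if (k_leave == 0) stop("`k_unloop + k_cut` must be positive")
  set.seed(as.integer(seed))
  dur <- stats::rexp(n, k_leave)
  fate <- ifelse(stats::runif(n) < k_cut / k_leave, "CUT", "UNLOOP")
  if (!is.null(contamination)) {
    if (is.null(contamination$fraction) ||
        contamination$fraction < 0 || contamination$fraction > 1) {
      stop("contamination$fraction must lie in [0, 1]")
    }
    mix <- stats::runif(n) < contamination$fraction
    if (!is.null(contamination$rate)) {
      dur[mix] <- stats::rexp(sum(mix), contamination$rate)
    } else if (!is.null(contamination$deadend_at)) {
      dur[mix] <- contamination$deadend_at
      fate[mix] <- "CENSORED"
    } else {
      stop("contamination must supply `rate` or `deadend_at`")
    }
  }
  data.frame(bead_id = NA_character_, duration_min = dur, fate = fate,
             stringsAsFactors = FALSE)
}

#' Simulate a whole TPM experiment
#'
#' Simulates `n_beads` independent beads under one configuration: a
#' ground-truth state path and a rendered noisy trajectory per bead. A
#' fraction of beads can be rendered as corrupted tethers (stuck or
#' multiply tethered: the whole trace, baseline included, sits at the
#' looped level) to exercise bead filtering.
#'
#' @param config a [sim_config()].
#' @param n_beads number of beads.
#' @param corrupt_fraction probability a bead is rendered corrupted.
#' @return a list with `trajectories` (one stacked `data.frame`;
#'   per-bead attributes retained in `meta`), `paths` (stacked ground-truth
#'   segments with a `bead_id` column), `corrupt` (named logical), and
#'   `meta` (frame interval, baseline and nominal end, seconds).
#' @export
simulate_experiment <- function(config, n_beads, corrupt_fraction = 0) {
  stopifnot(inherits(config, "sim_config"), n_beads >= 1)
  set.seed(bead_seed(config$seed, 0L, 3L))
  corrupt <- stats::runif(n_beads) < corrupt_fraction
  ids <- sprintf("bead_%04d", seq_len(n_beads))
  names(corrupt) <- ids
  trajs <- vector("list", n_beads)
  paths <- vector("list", n_beads)
  total_s <- min_to_s(config$baseline_duration + config$observation_duration)
  for (i in seq_len(n_beads)) {
    if (corrupt[i]) {
      n_frames <- floor(total_s / config$frame_interval)
      time_s <- (seq_len(n_frames) - 1) * config$frame_interval
      set.seed(bead_seed(config$seed, i, 2L))
      rmsd <- pmax(config$rmsd_looped +
                     stats::rnorm(n_frames, 0, config$noise_sd), 0)
      trajs[[i]] <- data.frame(bead_id = ids[i], time_s = time_s,
                               rmsd_nm = rmsd, stringsAsFactors = FALSE)
      paths[[i]] <- data.frame(bead_id = ids[i], state = "CORRUPT",
                               t_start_min = 0,
                               t_end_min = s_to_min(total_s),
                               stringsAsFactors = FALSE)
    } else {
      p <- simulate_state_path(config, bead = i)
      trajs[[i]] <- render_trajectory(p, config, bead = i, bead_id = ids[i])
      paths[[i]] <- cbind(bead_id = ids[i], p, stringsAsFactors = FALSE)
    }
  }
  list(
    trajectories = do.call(rbind, trajs),
    paths = do.call(rbind, paths),
    corrupt = corrupt,
    meta = list(frame_interval_s = config$frame_interval,
                baseline_s = min_to_s(config$baseline_duration),
                expected_end_s = total_s)
  )
}
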