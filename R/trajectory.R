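# Turning raw bead traces into called state segments and dwell records.

# Convolve with an arbitrary kernel, renormalising the truncated window at
# the edges so output length equals input length.
renorm_filter <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1L) %/% 2L
  num <- stats::convolve(x, kernel, type = "open")
  den <- stats::convolve(rep(1, n), kernel, type = "open")
  (num / den)[(half + 1L):(half + n)]
}

#' Gaussian-filter a series
#'
#' Smooths with a Gaussian kernel of the given standard deviation (in
#' frames), truncated at 4 sd; edge frames use renormalised truncated
#' windows so the output has the input's length.
#'
#' @param x numeric series.
#' @param sd_frames kernel standard deviation in frames; `<= 0` returns
#'   `x` unchanged.
#' @return smoothed numeric series, same length as `x`.
#' @export
gaussian_smooth <- function(x, sd_frames) {
  if (sd_frames <= 0 || length(x) < 2L) return(x)
  half <- max(1L, ceiling(4 * sd_frames))
  kernel <- stats::dnorm(seq(-half, half), sd = sd_frames)
  renorm_filter(x, kernel)
}

# Centered running mean over a window of `w_frames` frames (edges
# renormalised); used for drift correction.
running_mean <- function(x, w_frames) {
  w <- max(1L, round(w_frames))
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= 2L * length(x)) return(rep(mean(x), length(x)))
  renorm_filter(x, rep(1, w))
}

#' Compute a smoothed RMSD series from bead positions
#'
#' Drift-corrects x/y positions by subtracting a long-window running mean,
#' then computes the root of the Gaussian-weighted mean-squared
#' displacement, RMSD_t = sqrt(< (x - xbar)^2 + (y - ybar)^2 >_w), with a
#' Gaussian weighting window of standard deviation `filter_sd` seconds
#' (default 8 s). Edge frames use renormalised truncated windows.
#'
#' @param x,y numeric position series, nm.
#' @param frame_interval frame interval, seconds; sampling must be uniform.
#' @param filter_sd Gaussian weighting window standard deviation, seconds.
#' @param drift_window running-mean window for drift correction, seconds;
#'   should be much longer than `filter_sd`.
#' @return numeric RMSD series, nm, same length as the input.
#' @export
compute_rmsd <- function(x, y, frame_interval, filter_sd = 8,
                         drift_window = 80) {
  stopifnot(length(x) == length(y), frame_interval > 0, filter_sd > 0)
  dx <- x - running_mean(x, drift_window / frame_interval)
  dy <- y - running_mean(y, drift_window / frame_interval)
  ms <- gaussian_smooth(dx^2 + dy^2, filter_sd / frame_interval)
  sqrt(pmax(ms, 0))
}

#' State-calling configuration
#'
#' Thresholds and filters used to segment an RMSD trace into unlooped,
#' looped and cleaved states. The state boundary defaults to the midpoint
#' of the two expected levels and is set a priori, independent of the data.
#'
#' @param unlooped_level expected unlooped RMSD level, nm.
#' @param looped_level expected looped RMSD level, nm; below
#'   `unlooped_level`.
#' @param threshold explicit state boundary, nm; default midpoint of the
#'   two levels.
#' @param min_dwell shortest accepted excursion, seconds; shorter
#'   excursions are merged into the flanking state. Default 30 s, about
#'   four times the default filter width.
#' @param filter_sd Gaussian smoothing standard deviation applied to the
#'   RMSD trace before thresholding, seconds.
#' @param cleavage_gap minimum missing-trace duration at the end of a
#'   trajectory, seconds, before bead loss is called; defaults to
#'   `min_dwell` so tracking glitches are not misread as cleavage.
#' @return an object of class `state_call_config`.
#' @export
state_call_config <- function(unlooped_level, looped_level,
                              threshold = NULL, min_dwell = 30,
                              filter_sd = 8, cleavage_gap = NULL) {
  if (looped_level >= unlooped_level) {
    stop("`looped_level` must be strictly below `unlooped_level`")
  }
  if (min_dwell < 0) stop("`min_dwell` must be >= 0 (s)")
  if (filter_sd <= 0) stop("`filter_sd` must be positive (s)")
  if (is.null(threshold)) threshold <- (unlooped_level + looped_level) / 2
  if (threshold <= looped_level || threshold >= unlooped_level) {
    stop("`threshold` must lie between the two levels")
  }
  if (is.null(cleavage_gap)) cleavage_gap <- min_dwell
  structure(list(unlooped_level = unlooped_level,
                 looped_level = looped_level,
                 threshold = threshold,
                 min_dwell = min_dwell,
                 filter_sd = filter_sd,
                 cleavage_gap = cleavage_gap),
            class = "state_call_config")
}

# Flip runs shorter than min_frames into the flanking state, shortest
# first; terminates because each pass reduces the number of runs.
merge_short_runs <- function(states, min_frames) {
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_frames)
    if (length(short) == 0L) break
    i <- short[which.min(r$lengths[short])]
    neighbour <- if (i == 1L) 2L else i - 1L
    r$values[i] <- r$values[neighbour]
    states <- inverse.rle(r)
  }
  states
}

# Check frame spacing is uniform within tolerance; returns the interval.
frame_interval_of <- function(time_s, tol = 0.01) {
  d <- diff(time_s)
  if (any(d <= 0)) stop("timestamps must be strictly increasing")
  dt <- stats::median(d)
  if (any(abs(d - dt) > tol * dt)) {
    stop("non-uniform frame sampling beyond tolerance")
  }
  dt
}

#' Segment one trajectory into called states
#'
#' Smooths the RMSD trace with a Gaussian filter, assigns each frame to
#' the unlooped or looped band by a fixed a-priori threshold, merges
#' excursions shorter than `min_dwell` into the flanking state, and calls
#' cleavage when the trace terminates at least `cleavage_gap` seconds
#' before the nominal end of observation while the bead is in the looped
#' state. Early termination while unlooped is flagged as an anomaly
#' (sticking or detachment) so the bead can be excluded.
#'
#' @param traj a single-bead trajectory `data.frame` with columns
#'   `bead_id`, `time_s`, `rmsd_nm`. The attribute `expected_end_s` (set by
#'   [render_trajectory()]) or the argument of the same name supplies the
#'   nominal observation end used for cleavage detection.
#' @param cfg a [state_call_config()].
#' @param expected_end_s nominal end of the observation, seconds;
#'   overrides the trajectory attribute. `NULL` disables cleavage calls.
#' @return a `data.frame` of segments: `bead_id`, `state`, `t_start_min`,
#'   `t_end_min`, `censored` (`TRUE` for the final segment when it is
#'   truncated by the observation end rather than terminated by cleavage).
#'   Attribute `anomaly` is `TRUE` when a loss-of-tether signature occurred
#'   while unlooped.
#' @export
call_states <- function(traj, cfg, expected_end_s = NULL) {
  stopifnot(inherits(cfg, "state_call_config"),
            all(c("bead_id", "time_s", "rmsd_nm") %in% names(traj)))
  if (length(unique(traj$bead_id)) != 1L) {
    stop("`call_states()` takes one bead at a time")
  }
  if (is.null(expected_end_s)) expected_end_s <- attr(traj, "expected_end_s")
  dt <- frame_interval_of(traj$time_s)
  smoothed <- gaussian_smooth(traj$rmsd_nm, cfg$filter_sd / dt)
  sep <- cfg$unlooped_level - cfg$looped_level
  m <- mean(smoothed)
  if (min(abs(m - cfg$unlooped_level), abs(m - cfg$looped_level)) > 3 * sep) {
    warning("trajectory lies far outside both state bands; no states called")
    out <- data.frame(bead_id = character(0), state = character(0),
                      t_start_min = numeric(0), t_end_min = numeric(0),
                      censored = logical(0), stringsAsFactors = FALSE)
    return(structure(out, anomaly = FALSE))
  }
  states <- ifelse(smoothed < cfg$threshold, "LOOPED", "UNLOOPED")
  min_frames <- max(1, cfg$min_dwell / dt)
  states <- merge_short_runs(states, min_frames)
  r <- rle(states)
  ends_i <- cumsum(r$lengths)
  starts_i <- c(1L, utils::head(ends_i, -1L) + 1L)
  seg <- data.frame(
    bead_id = traj$bead_id[1L],
    state = r$values,
    t_start_min = s_to_min(traj$time_s[starts_i]),
    t_end_min = s_to_min(traj$time_s[ends_i] + dt),
    censored = FALSE,
    stringsAsFactors = FALSE
  )
  anomaly <- FALSE
  last_time <- traj$time_s[nrow(traj)] + dt
  terminated <- !is.null(expected_end_s) &&
    (expected_end_s - last_time) >= cfg$cleavage_gap
  k <- nrow(seg)
  if (terminated && seg$state[k] == "LOOPED") {
    seg <- rbind(seg, data.frame(
      bead_id = seg$bead_id[1L], state = "CLEAVED",
      t_start_min = seg$t_end_min[k],
      t_end_min = s_to_min(expected_end_s),
      censored = FALSE, stringsAsFactors = FALSE
    ))
  } else if (terminated) {
    # tether lost while called unlooped: either an experimental artifact
    # or a cleavage whose preceding loop was too short to call; the
    # trailing segment is truncated by the loss and carries no fate
    anomaly <- TRUE
    seg$censored[k] <- TRUE
  } else {
    seg$censored[k] <- TRUE
  }
  structure(seg, anomaly = anomaly)
}

#' Extract dwell records from called segments
#'
#' One record per looped segment, pooled irrespective of fate: `"CUT"`
#' when the loop is followed by cleavage, `"UNLOOP"` when it reverts to
#' the unlooped state, `"CENSORED"` when the observation window truncates
#' it.
#'
#' @param segments a segments `data.frame` from [call_states()] (one or
#'   several beads stacked).
#' @return a `data.frame` with columns `bead_id`, `duration_min`, `fate`.
#' @export
extract_dwells <- function(segments) {
  cols <- c("bead_id", "state", "t_start_min", "t_end_min", "censored")
  stopifnot(all(cols %in% names(segments)))
  out <- lapply(split(segments, segments$bead_id), function(seg) {
    seg <- seg[order(seg$t_start_min), , drop = FALSE]
    idx <- which(seg$state == "LOOPED")
    if (length(idx) == 0L) return(NULL)
    fate <- vapply(idx, function(i) {
      if (seg$censored[i]) return("CENSORED")
      if (i == nrow(seg)) return("CENSORED")
      switch(seg$state[i + 1L], CLEAVED = "CUT", UNLOOPED = "UNLOOP",
             "CENSORED")
    }, character(1L))
    data.frame(bead_id = seg$bead_id[idx],
               duration_min = seg$t_end_min[idx] - seg$t_start_min[idx],
               fate = fate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(bead_id = character(0), duration_min = numeric(0),
                      fate = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Filter beads on their protein-free baseline
#'
#' Accepts beads whose baseline (pre-protein) RMSD sits in the unlooped
#' band and shows no looping; every rejection carries a reason. Beads with
#' no baseline frames are rejected outright.
#'
#' @param trajectories stacked trajectory `data.frame` (columns `bead_id`,
#'   `time_s`, `rmsd_nm`) for one or more beads.
#' @param cfg a [state_call_config()].
#' @param baseline_s baseline duration in seconds; frames with
#'   `time_s < baseline_s` form the baseline.
#' @return a list with `accepted` (character bead ids) and `rejected`
#'   (`data.frame` of `bead_id`, `reason`).
#' @export
filter_beads <- function(trajectories, cfg, baseline_s) {
  stopifnot(inherits(cfg, "state_call_config"), baseline_s >= 0)
  accepted <- character(0)
  rej_id <- character(0)
  rej_why <- character(0)
  reject <- function(id, why) {
    rej_id <<- c(rej_id, id); rej_why <<- c(rej_why, why)
  }
  for (piece in split(trajectories, trajectories$bead_id)) {
    id <- piece$bead_id[1L]
    base <- piece[piece$time_s < baseline_s, , drop = FALSE]
    if (nrow(base) < 2L) {
      reject(id, "missing_baseline")
      next
    }
    dt <- frame_interval_of(base$time_s)
    smoothed <- gaussian_smooth(base$rmsd_nm, cfg$filter_sd / dt)
    if (abs(mean(smoothed) - cfg$unlooped_level) >
        abs(mean(smoothed) - cfg$looped_level)) {
      reject(id, "baseline_not_unlooped")
      next
    }
    looped <- merge_short_runs(
      ifelse(smoothed < cfg$threshold, "LOOPED", "UNLOOPED"),
      max(1, cfg$min_dwell / dt)
    )
    if (any(looped == "LOOPED")) {
      reject(id, "baseline_looping")
      next
    }
    accepted <- c(accepted, id)
  }
  list(accepted = accepted,
       rejected = data.frame(bead_id = rej_id, reason = rej_why,
                             stringsAsFactors = FALSE))
}

#' Per-bead loop and cut counts from dwell records
#'
#' Tallies, for each bead, the number of distinct observed loops
#' (censored included), the number of cleavage events, and the number of
#' fate-resolved loops (loops whose fate is known, i.e. not censored).
#'
#' @param dwells a dwell `data.frame` from [extract_dwells()].
#' @param bead_ids character vector of all monitored beads (beads with no
#'   loops get zero counts).
#' @return a `data.frame` with columns `bead_id`, `n_loops`, `n_cuts`,
#'   `n_resolved`.
#' @export
count_loops <- function(dwells, bead_ids) {
  tab <- function(ids) {
    out <- table(factor(ids, levels = bead_ids))
    as.integer(out)
  }
  data.frame(
    bead_id = bead_ids,
    n_loops = tab(dwells$bead_id),
    n_cuts = tab(dwells$bead_id[dwells$fate == "CUT"]),
    n_resolved = tab(dwells$bead_id[dwells$fate != "CENSORED"]),
    stringsAsFactors = FALSE
  )
}
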