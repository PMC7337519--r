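# RMSD computation, state calling, dwell extraction and bead filtering.

test_that("RMSD of positions matches the chi-distribution identity", {
  # constant position gives identically zero RMSD
  n <- 2000
  expect_equal(compute_rmsd(rep(3, n), rep(-1, n), frame_interval = 1),
               rep(0, n))

  # i.i.d. isotropic Gaussian positions with per-axis sd sigma have
  # long-run root-mean-square displacement sigma * sqrt(2)
  set.seed(21)
  sigma <- 50
  r <- compute_rmsd(rnorm(20000, 100, sigma), rnorm(20000, -40, sigma),
                    frame_interval = 1)
  expect_lt(abs(mean(r) / (sigma * sqrt(2)) - 1), 0.05)
})

test_that("heavier smoothing never increases the variance of the series", {
  set.seed(22)
  x <- 200 + rnorm(5000, 0, 20) + 30 * sin(seq(0, 20, length.out = 5000))
  vars <- vapply(c(2, 4, 8, 16, 32),
                 function(s) stats::var(gaussian_smooth(x, s)), numeric(1))
  expect_true(all(diff(vars) <= 1e-9))
})

test_that("zero-noise trajectories segment back to the generating path", {
  cfg <- quick_config(seed = 11, noise_sd = 0, k_cut = 0.1, k_unloop = 0.2,
                      release_duration = 0)
  ccfg <- default_call_config()
  checked <- 0
  for (b in 1:12) {
    p <- simulate_state_path(cfg, bead = b)
    true_loops <- p[p$state == "LOOPED", , drop = FALSE]
    all_durs <- p$t_end_min - p$t_start_min
    # only paths where every segment (loops and the unlooped gaps
    # between them) outlasts the 30-s minimum dwell filter
    if (nrow(true_loops) == 0 || any(all_durs < 2 * 30 / 60)) next
    tr <- render_trajectory(p, cfg, bead = b)
    seg <- call_states(tr, ccfg)
    called <- seg[seg$state == "LOOPED", , drop = FALSE]
    expect_identical(nrow(called), nrow(true_loops))
    # boundaries exact up to one frame (1 s) at zero noise
    expect_lt(max(abs(called$t_start_min - true_loops$t_start_min)), 2 / 60)
    expect_lt(max(abs(called$t_end_min - true_loops$t_end_min)), 2 / 60)
    expect_identical("CLEAVED" %in% seg$state, "CLEAVED" %in% p$state)
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("excursions shorter than min_dwell are suppressed", {
  cfg <- quick_config(seed = 1, noise_sd = 0)
  # a true 10-s loop with min_dwell = 30 s is not called
  path <- data.frame(state = c("UNLOOPED", "LOOPED", "UNLOOPED"),
                     t_start_min = c(0, 30, 30 + 10 / 60),
                     t_end_min = c(30, 30 + 10 / 60, 70))
  tr <- render_trajectory(path, cfg)
  seg <- call_states(tr, default_call_config(min_dwell = 30))
  expect_false("LOOPED" %in% seg$state)
  # but it is called with a permissive min_dwell
  seg2 <- call_states(tr, default_call_config(min_dwell = 4, filter_sd = 1))
  expect_true("LOOPED" %in% seg2$state)
})

test_that("noisy ensembles recover loops with bounded duration error", {
  # SNR = 90 / 15 = 6; loops longer than 2 * min_dwell must be recovered
  # with duration error at most two filter widths (16 s). A sparse
  # looping rate keeps unlooped gaps long relative to min_dwell, so loop
  # merging is a rare event rather than the norm.
  cfg <- quick_config(seed = 31, noise_sd = 15, k_loop = 0.08,
                      k_unloop = 0.2, k_cut = 0.05)
  ccfg <- default_call_config()
  n_true <- 0; n_found <- 0; errs <- numeric(0)
  for (b in 1:40) {
    p <- simulate_state_path(cfg, bead = b)
    tr <- render_trajectory(p, cfg, bead = b)
    seg <- call_states(tr, ccfg)
    called <- seg[seg$state == "LOOPED", , drop = FALSE]
    tl_i <- which(p$state == "LOOPED")
    for (i in tl_i) {
      dur <- p$t_end_min[i] - p$t_start_min[i]
      if (dur < 1) next       # below 2 * min_dwell: not required
      n_true <- n_true + 1
      hit <- which(called$t_start_min < p$t_end_min[i] &
                     called$t_end_min > p$t_start_min[i])
      if (length(hit) == 0) next
      n_found <- n_found + 1
      # duration error is only meaningful when the loop's flanking
      # segments are themselves resolvable (no merging possible)
      flanks <- c(i - 1L, i + 1L)
      flanks <- flanks[flanks >= 1 & flanks <= nrow(p)]
      well_sep <- all(p$t_end_min[flanks] - p$t_start_min[flanks] >= 1)
      if (well_sep && length(hit) == 1) {
        errs <- c(errs,
                  abs((called$t_end_min[hit] - called$t_start_min[hit]) - dur))
      }
    }
  }
  expect_gt(n_true, 25)
  expect_gte(n_found / n_true, 0.95)
  expect_gt(length(errs), 20)
  expect_lt(stats::quantile(errs, 0.95),
            2 * 8 / 60 + cfg$release_duration / 60)
})

test_that("segment time is conserved and dwell fates follow the segments", {
  # hand-built segments: loop(3 min) -> unloop, loop(1 min) -> cut
  seg <- data.frame(
    bead_id = "b1",
    state = c("UNLOOPED", "LOOPED", "UNLOOPED", "LOOPED", "CLEAVED"),
    t_start_min = c(0, 12, 15, 20, 21),
    t_end_min = c(12, 15, 20, 21, 70),
    censored = FALSE
  )
  d <- extract_dwells(seg)
  expect_equal(d$duration_min, c(3, 1))
  expect_equal(d$fate, c("UNLOOP", "CUT"))

  # ongoing loop at the observation end is censored
  seg2 <- data.frame(bead_id = "b2",
                     state = c("UNLOOPED", "LOOPED"),
                     t_start_min = c(0, 60), t_end_min = c(60, 70),
                     censored = c(FALSE, TRUE))
  d2 <- extract_dwells(seg2)
  expect_equal(d2$fate, "CENSORED")
  expect_equal(d2$duration_min, 10)

  # called segments tile the whole observation for a real trajectory
  cfg <- quick_config(seed = 41)
  tr <- render_trajectory(simulate_state_path(cfg, bead = 2), cfg, bead = 2)
  seg3 <- call_states(tr, default_call_config())
  expect_equal(seg3$t_start_min[1], 0)
  expect_equal(seg3$t_start_min[-1], seg3$t_end_min[-nrow(seg3)])
  span_min <- if ("CLEAVED" %in% seg3$state) 70 else
    s_to_min(max(tr$time_s) + 1)
  expect_equal(sum(seg3$t_end_min - seg3$t_start_min), span_min)
  # at most one cut per bead, nothing after cleavage
  expect_lte(sum(seg3$state == "CLEAVED"), 1)
})

test_that("bead filtering accepts compliant baselines and explains rejections", {
  ccfg <- default_call_config()
  cfg <- quick_config(seed = 51)
  ex <- simulate_experiment(cfg, n_beads = 6, corrupt_fraction = 0)
  res <- filter_beads(ex$trajectories, ccfg, ex$meta$baseline_s)
  expect_setequal(res$accepted, unique(ex$trajectories$bead_id))

  # a bead whose baseline sits at the looped level is rejected
  stuck <- data.frame(bead_id = "stuck", time_s = 0:2399,
                      rmsd_nm = 160 + rnorm(2400, 0, 10))
  res2 <- filter_beads(stuck, ccfg, baseline_s = 600)
  expect_identical(res2$rejected$reason, "baseline_not_unlooped")

  # a bead with no baseline frames is rejected with an explicit reason
  late <- data.frame(bead_id = "late", time_s = 700:2399,
                     rmsd_nm = 250 + rnorm(1700, 0, 10))
  res3 <- filter_beads(late, ccfg, baseline_s = 600)
  expect_identical(res3$rejected$reason, "missing_baseline")

  # an ensemble with 10% corrupted baselines is rejected at about 10%
  cfg2 <- quick_config(seed = 52, observation_duration = 20)
  ex2 <- simulate_experiment(cfg2, n_beads = 60, corrupt_fraction = 0.1)
  res4 <- filter_beads(ex2$trajectories, ccfg, ex2$meta$baseline_s)
  expect_identical(sort(res4$rejected$bead_id),
                   sort(names(which(ex2$corrupt))))
})

test_that("loop counting tallies per-bead loops, cuts and resolved fates", {
  dwells <- data.frame(
    bead_id = c("a", "a", "b", "c"),
    duration_min = c(2, 1, 3, 4),
    fate = c("UNLOOP", "CUT", "CENSORED", "UNLOOP")
  )
  counts <- count_loops(dwells, bead_ids = c("a", "b", "c", "d"))
  expect_equal(counts$n_loops, c(2L, 1L, 1L, 0L))
  expect_equal(counts$n_cuts, c(1L, 0L, 0L, 0L))
  expect_equal(counts$n_resolved, c(2L, 0L, 1L, 0L))
})
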