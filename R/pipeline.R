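# Project glue: YAML configuration, the end-to-end driver on synthetic
# data, and CSV schema validation. All randomness flows from one global
# seed through named substreams so stages re-run reproducibly.

pipeline_sections <- list(
  simulation = c("k_loop", "k_unloop", "k_cut", "rmsd_unlooped",
                 "rmsd_looped", "noise_sd", "frame_interval",
                 "baseline_duration", "observation_duration",
                 "deadend_fraction", "release_duration"),
  state_calling = c("threshold", "min_dwell", "filter_sd", "cleavage_gap"),
  metrics = c("n_boot", "level"),
  kinetics = c("prior_a", "prior_b", "chains", "warmup", "draws",
               "include_censored", "detection_min"),
  comparison = c("n_perm")
)

#' Assemble and validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent nested list) with sections
#' `simulation`, `state_calling`, `metrics`, `kinetics`, optional
#' `comparison`, plus top-level `label`, `n_beads`, `corrupt_fraction`,
#' `seed` and `output_dir`. Unknown keys are rejected. The configuration
#' round-trips losslessly through [write_pipeline_config()].
#'
#' @param x path to a YAML file, or a named list with the same structure.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    yaml::read_yaml(x)
  } else if (is.list(x)) {
    x
  } else {
    stop("`x` must be a YAML path or a named list")
  }
  top_known <- c("label", "n_beads", "corrupt_fraction", "seed",
                 "output_dir", names(pipeline_sections))
  unknown <- setdiff(names(cfg), top_known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (sec in names(pipeline_sections)) {
    bad <- setdiff(names(cfg[[sec]]), pipeline_sections[[sec]])
    if (length(bad)) {
      stop(sprintf("unknown keys in `%s`: %s", sec,
                   paste(bad, collapse = ", ")))
    }
  }
  if (is.null(cfg$simulation)) stop("config needs a `simulation` section")
  defaults <- list(label = "synthetic", n_beads = 50L, corrupt_fraction = 0,
                   seed = 1L, output_dir = NULL,
                   state_calling = list(), metrics = list(),
                   kinetics = list(), comparison = list())
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$n_beads <- as.integer(cfg$n_beads)
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$n_beads < 1L) stop("`n_beads` must be >= 1")
  if (cfg$corrupt_fraction < 0 || cfg$corrupt_fraction > 1) {
    stop("`corrupt_fraction` must lie in [0, 1]")
  }
  # validate the simulation section by constructing the sim_config
  sim <- do.call(sim_config, c(cfg$simulation, list(seed = cfg$seed)))
  met <- utils::modifyList(list(n_boot = 10000L, level = 0.95), cfg$metrics)
  kin <- utils::modifyList(list(prior_a = 2, prior_b = 1, chains = 4L,
                                warmup = 1000L, draws = 1000L,
                                include_censored = FALSE), cfg$kinetics)
  # NULL means "use the state-calling min_dwell"; kept as an explicit
  # element so configs round-trip through YAML
  if (!"detection_min" %in% names(kin)) kin["detection_min"] <- list(NULL)
  cmp <- utils::modifyList(list(n_perm = 10000L), cfg$comparison)
  structure(list(label = cfg$label, n_beads = cfg$n_beads,
                 corrupt_fraction = cfg$corrupt_fraction,
                 seed = cfg$seed, output_dir = cfg$output_dir,
                 simulation = cfg$simulation, sim = sim,
                 state_calling = cfg$state_calling,
                 metrics = met, kinetics = kin, comparison = cmp),
            class = "pipeline_config")
}

#' Write a pipeline configuration back to YAML
#'
#' @param config a [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(label = config$label, n_beads = config$n_beads,
              corrupt_fraction = config$corrupt_fraction,
              seed = config$seed, output_dir = config$output_dir,
              simulation = config$simulation,
              state_calling = config$state_calling,
              metrics = config$metrics, kinetics = config$kinetics,
              comparison = config$comparison)
  out <- out[!vapply(out, is.null, logical(1L))]
  out <- lapply(out, function(v) if (is.list(v) && !length(v)) NULL else v)
  out <- out[!vapply(out, is.null, logical(1L))]
  yaml::write_yaml(out, path)
  invisible(path)
}

state_cfg_from <- function(config) {
  sim <- config$sim
  args <- utils::modifyList(
    list(unlooped_level = sim$rmsd_unlooped, looped_level = sim$rmsd_looped),
    config$state_calling
  )
  do.call(state_call_config, args)
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> filter beads -> call states -> extract dwells -> metrics
#' -> kinetic fit -> goodness of fit, writing every table as CSV plus a
#' JSON manifest carrying the config hash, the seed, per-stage counts and
#' an md5 digest of every file. Re-running with an identical configuration
#' reproduces byte-identical CSVs.
#'
#' @param config a [pipeline_config()].
#' @param output_dir where to write outputs; overrides the config's
#'   `output_dir`.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(output_dir)) output_dir <- config$output_dir
  if (is.null(output_dir)) stop("no `output_dir` given")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    sim <- config$sim
    expt <- simulate_experiment(sim, config$n_beads,
                                config$corrupt_fraction)
    ccfg <- state_cfg_from(config)

    stage <- "filter_beads"
    filt <- filter_beads(expt$trajectories, ccfg, expt$meta$baseline_s)

    stage <- "call_states"
    # beads whose trace terminates while called unlooped are flagged but
    # their pre-termination segments are kept: the terminal loss carries
    # no fate, and dropping the bead's earlier resolved loops would
    # select against unlooping fates and bias the cut fraction upward
    segs <- list()
    anomalous <- character(0)
    for (id in filt$accepted) {
      tr <- expt$trajectories[expt$trajectories$bead_id == id, , drop = FALSE]
      s <- call_states(tr, ccfg, expected_end_s = expt$meta$expected_end_s)
      if (isTRUE(attr(s, "anomaly"))) anomalous <- c(anomalous, id)
      segs[[id]] <- s
    }
    segments <- do.call(rbind, segs)
    if (is.null(segments) || nrow(segments) == 0L) {
      stop("no usable beads after filtering")
    }
    rownames(segments) <- NULL

    stage <- "extract_dwells"
    dwells <- extract_dwells(segments)
    counts <- count_loops(dwells, filt$accepted)
    data <- rss_dataset(config$label,
                        stats::setNames(counts[c("bead_id", "n_loops",
                                                 "n_cuts", "n_resolved")],
                                        c("bead_id", "n_loops", "n_cuts",
                                          "n_resolved")),
                        dwells = dwells)

    stage <- "metrics"
    boot <- bootstrap_loop_frequency(data, n_boot = config$metrics$n_boot,
                                     level = config$metrics$level,
                                     seed = bead_seed(config$seed, 0L, 21L))
    quart <- if (any(dwells$fate != "CENSORED")) {
      dwell_quartiles(dwells)
    } else {
      list(q1 = NA_real_, median = NA_real_, q3 = NA_real_)
    }
    pcut <- cut_posterior(data$n_resolved, data$n_cuts)
    metrics_row <- data.frame(
      label = config$label, n_beads = data$n_beads,
      n_loops = data$n_loops, n_cuts = data$n_cuts,
      n_resolved = data$n_resolved,
      loop_freq = boot$estimate,
      ci_low = boot$ci[["lower"]], ci_high = boot$ci[["upper"]],
      q1 = quart$q1, median = quart$median, q3 = quart$q3,
      pcut_map = pcut$map, pcut_sd = pcut$sd,
      pcut_prior_only = pcut$prior_only,
      stringsAsFactors = FALSE
    )

    stage <- "kinetics"
    obs <- dwells$fate != "CENSORED"
    fit <- NULL; gof <- NULL; band <- NULL
    if (sum(obs) >= 5L) {
      kin <- config$kinetics
      # the state caller cannot see loops shorter than min_dwell, so the
      # likelihood is offset by that detection threshold (in minutes)
      dmin <- if (is.null(kin$detection_min)) s_to_min(ccfg$min_dwell)
              else kin$detection_min
      if (kin$include_censored) {
        fit <- fit_leave_rate(dwells$duration_min, censored = !obs,
                              prior_a = kin$prior_a, prior_b = kin$prior_b,
                              detection_min = dmin,
                              chains = kin$chains, warmup = kin$warmup,
                              draws = kin$draws,
                              seed = bead_seed(config$seed, 0L, 22L))
      } else {
        fit <- fit_leave_rate(dwells$duration_min[obs],
                              prior_a = kin$prior_a, prior_b = kin$prior_b,
                              detection_min = dmin,
                              chains = kin$chains, warmup = kin$warmup,
                              draws = kin$draws,
                              seed = bead_seed(config$seed, 0L, 22L))
      }
      # goodness of fit and bands act on the threshold-offset lifetimes
      shifted <- pmax(dwells$duration_min[obs] - dmin, 1e-9)
      gof <- gof_exponential(shifted, fit,
                             seed = bead_seed(config$seed, 0L, 23L))
      grid <- seq(0, max(shifted) * 1.2, length.out = 200L)
      band <- ecdf_credible_band(fit, grid)
    }

    stage <- "report"
    files <- character(0)
    files["segments"] <- write_stage_csv(segments, output_dir, "segments.csv")
    files["dwells"] <- write_stage_csv(dwells, output_dir, "dwells.csv")
    files["counts"] <- write_stage_csv(counts, output_dir, "counts.csv")
    files["metrics"] <- write_stage_csv(metrics_row, output_dir, "metrics.csv")
    if (!is.null(fit)) {
      fit_row <- data.frame(k_leave_mean = fit$mean, k_leave_sd = fit$sd,
                            ci_low = fit$ci[1L], ci_high = fit$ci[2L],
                            rhat = fit$rhat, ess = fit$ess,
                            converged = fit$converged,
                            n_obs = fit$n_obs, sum_t = fit$sum_t,
                            detection_min = fit$detection_min)
      files["fit_summary"] <- write_stage_csv(fit_row, output_dir,
                                              "fit_summary.csv")
      files["posterior_samples"] <- write_stage_csv(
        data.frame(k_leave = fit$samples), output_dir,
        "posterior_samples.csv")
      files["gof"] <- write_stage_csv(
        data.frame(stat = gof$stat, p_value = gof$p_value, n = gof$n,
                   low_power = gof$low_power),
        output_dir, "gof.csv")
      files["band"] <- write_stage_csv(
        data.frame(t_min = band$grid, lower = band$lower,
                   upper = band$upper),
        output_dir, "band.csv")
    }
    manifest <- list(
      label = config$label,
      seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "sim")]),
      counts = list(
        beads_simulated = config$n_beads,
        beads_accepted = length(filt$accepted),
        beads_anomalous = length(anomalous),
        beads_rejected = nrow(filt$rejected),
        loops = data$n_loops, cuts = data$n_cuts,
        resolved = data$n_resolved
      ),
      files = as.list(basename(files)),
      md5 = as.list(unname(tools::md5sum(files)))
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

table_schemas <- list(
  trajectory = c("bead_id", "time_s", "rmsd_nm"),
  segments = c("bead_id", "state", "t_start_min", "t_end_min", "censored"),
  dwells = c("bead_id", "duration_min", "fate"),
  counts = c("bead_id", "n_loops", "n_cuts")
)

#' Validate a CSV table against a pipeline schema
#'
#' Checks column presence, value domains and ordering invariants
#' (strictly increasing timestamps per bead, non-overlapping segments, no
#' segment after cleavage, positive durations, count consistency) and
#' reports each violation with its row number.
#'
#' @param path CSV file path.
#' @param schema one of `"trajectory"`, `"segments"`, `"dwells"`,
#'   `"counts"`.
#' @return a list with `ok` (logical) and `violations` (`data.frame` of
#'   `row`, `message`; row `NA` for file-level problems).
#' @export
validate_tables <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse CSV: ",
                                          conditionMessage(e)))
  rows <- integer(0); msgs <- character(0)
  flag <- function(row, msg) {
    rows <<- c(rows, row); msgs <<- c(msgs, msg)
  }
  need <- table_schemas[[schema]]
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    flag(NA_integer_, paste("missing columns:",
                            paste(missing, collapse = ", ")))
  } else if (schema == "trajectory") {
    bad <- which(df$rmsd_nm < 0)
    for (i in bad) flag(i, "negative rmsd_nm")
    for (piece in split(seq_len(nrow(df)), df$bead_id)) {
      t <- df$time_s[piece]
      dec <- which(diff(t) <= 0)
      for (j in dec) flag(piece[j + 1L], "time_s not strictly increasing")
    }
  } else if (schema == "segments") {
    bad <- which(df$t_end_min <= df$t_start_min)
    for (i in bad) flag(i, "t_end_min must exceed t_start_min")
    bad <- which(!df$state %in% c("UNLOOPED", "LOOPED", "CLEAVED"))
    for (i in bad) flag(i, "unknown state")
    for (piece in split(seq_len(nrow(df)), df$bead_id)) {
      ord <- piece[order(df$t_start_min[piece])]
      if (length(ord) > 1L) {
        overlap <- which(df$t_start_min[ord][-1L] <
                           df$t_end_min[ord][-length(ord)] - 1e-9)
        for (j in overlap) flag(ord[j + 1L], "overlapping segments for bead")
      }
      cl <- which(df$state[ord] == "CLEAVED")
      if (length(cl) && cl[1L] < length(ord)) {
        for (j in (cl[1L] + 1L):length(ord)) {
          flag(ord[j], "segment after CLEAVED")
        }
      }
    }
  } else if (schema == "dwells") {
    bad <- which(df$duration_min <= 0)
    for (i in bad) flag(i, "non-positive duration_min")
    bad <- which(!df$fate %in% c("UNLOOP", "CUT", "CENSORED"))
    for (i in bad) flag(i, "unknown fate")
  } else if (schema == "counts") {
    bad <- which(df$n_loops < 0 | df$n_cuts < 0)
    for (i in bad) flag(i, "negative count")
    bad <- which(df$n_cuts > df$n_loops)
    for (i in bad) flag(i, "n_cuts exceeds n_loops")
    bad <- which(df$n_cuts > 1)
    for (i in bad) flag(i, "more than one cut for a bead")
  }
  violations <- data.frame(row = rows, message = msgs,
                           stringsAsFactors = FALSE)
  list(ok = nrow(violations) == 0L, violations = violations)
}
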