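# Per-RSS summary metrics: looping frequency with bootstrap CIs,
# dwell-time quartiles, and the Beta posterior of the cutting probability.

#' Bundle one RSS / condition dataset
#'
#' Collects per-bead loop and cut counts and the pooled dwell records for
#' one recombination signal sequence (or buffer condition) into a single
#' object carrying the derived totals.
#'
#' @param label dataset label, e.g. the RSS name or `"Ca2+"`.
#' @param counts `data.frame` with columns `bead_id`, `n_loops`, `n_cuts`
#'   and optionally `n_resolved` (defaults to `n_loops` when absent, i.e.
#'   no censored loops).
#' @param dwells optional dwell `data.frame` (`bead_id`, `duration_min`,
#'   `fate`).
#' @return an object of class `rss_dataset` with totals `n_beads`,
#'   `n_loops`, `n_cuts`, `n_resolved`.
#' @export
rss_dataset <- function(label, counts, dwells = NULL) {
  stopifnot(is.character(label), length(label) == 1L,
            is.data.frame(counts),
            all(c("bead_id", "n_loops", "n_cuts") %in% names(counts)))
  if (!"n_resolved" %in% names(counts)) counts$n_resolved <- counts$n_loops
  if (anyDuplicated(counts$bead_id)) stop("duplicate bead ids in `counts`")
  if (any(counts$n_loops < 0) || any(counts$n_cuts < 0)) {
    stop("counts must be non-negative")
  }
  if (any(counts$n_cuts > 1L)) {
    stop("a bead can be cleaved at most once (per-bead cuts <= 1)")
  }
  if (any(counts$n_cuts > counts$n_resolved) ||
      any(counts$n_resolved > counts$n_loops)) {
    stop("need n_cuts <= n_resolved <= n_loops for every bead")
  }
  if (!is.null(dwells)) {
    stopifnot(all(c("bead_id", "duration_min", "fate") %in% names(dwells)))
    if (any(dwells$duration_min <= 0)) stop("dwell durations must be > 0")
  }
  structure(list(label = label, counts = counts, dwells = dwells,
                 n_beads = nrow(counts),
                 n_loops = sum(counts$n_loops),
                 n_cuts = sum(counts$n_cuts),
                 n_resolved = sum(counts$n_resolved)),
            class = "rss_dataset")
}

#' @export
print.rss_dataset <- function(x, ...) {
  cat(sprintf("RSS dataset '%s': %d beads, %d loops (%d fate-resolved), %d cuts\n",
              x$label, x$n_beads, x$n_loops, x$n_resolved, x$n_cuts))
  invisible(x)
}

#' Looping frequency point estimate
#'
#' The ratio of distinct paired complexes observed to the number of beads
#' monitored. A tether can loop repeatedly, so the frequency ranges over
#' \[0, Inf).
#'
#' @param data an [rss_dataset()].
#' @return numeric scalar, loops per bead.
#' @export
looping_frequency <- function(data) {
  stopifnot(inherits(data, "rss_dataset"))
  if (data$n_beads < 1L) stop("need at least one monitored bead")
  data$n_loops / data$n_beads
}

#' Bootstrap confidence interval for the looping frequency
#'
#' Resamples beads (with their per-bead loop counts) with replacement,
#' recomputing total loops / n_beads for each replicate, and reports
#' percentile intervals of the replicate distribution. The resampling
#' unit is the bead.
#'
#' @param data an [rss_dataset()].
#' @param n_boot number of bootstrap replicates (default `1e6`).
#' @param level confidence level for the percentile interval.
#' @param seed integer RNG seed; fixed seed gives bit-identical
#'   replicates.
#' @return an object of class `loop_frequency_estimate`: point `estimate`,
#'   `ci` (named lower/upper), `boot_mean`, `boot_sd`, `level`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_loop_frequency <- function(data, n_boot = 1e6, level = 0.95,
                                     seed = 1L) {
  stopifnot(inherits(data, "rss_dataset"))
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  n_boot <- as.integer(n_boot)
  counts <- data$counts$n_loops
  n <- length(counts)
  if (n < 1L) stop("need at least one monitored bead")
  set.seed(as.integer(seed))
  reps <- numeric(n_boot)
  chunk <- max(1L, as.integer(floor(4e6 / n)))
  done <- 0L
  while (done < n_boot) {
    m <- min(chunk, n_boot - done)
    idx <- sample.int(n, n * m, replace = TRUE)
    reps[done + seq_len(m)] <- colSums(matrix(counts[idx], nrow = n)) / n
    done <- done + m
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(estimate = sum(counts) / n,
                 ci = c(lower = ci[1L], upper = ci[2L]),
                 boot_mean = mean(reps), boot_sd = stats::sd(reps),
                 level = level, n_boot = n_boot, seed = as.integer(seed)),
            class = "loop_frequency_estimate")
}

#' @export
print.loop_frequency_estimate <- function(x, ...) {
  cat(sprintf("Looping frequency %.4g loops/bead  [%g%% CI %.4g, %.4g]  (%d bootstrap replicates)\n",
              x$estimate, 100 * x$level, x$ci[["lower"]], x$ci[["upper"]],
              x$n_boot))
  invisible(x)
}

#' Posterior distribution of the cutting probability
#'
#' Treats the fate of each fate-resolved paired complex as a Bernoulli
#' trial with cleavage probability `p_cut`. Under a uniform Beta(1, 1)
#' prior the posterior is proportional to
#' `p^n_cuts * (1 - p)^(n_loops - n_cuts)`, i.e.
#' Beta(`n_cuts + 1`, `n_loops - n_cuts + 1`); the reported most-likely
#' value is the mode `n_cuts / n_loops` and the uncertainty is the
#' analytic posterior standard deviation.
#'
#' @param n_loops number of observed (fate-resolved) paired complexes.
#' @param n_cuts number of those ending in cleavage; `<= n_loops`.
#' @param grid_n number of evaluation points of the normalised posterior
#'   density on \[0, 1\].
#' @return an object of class `cut_posterior`: Beta parameters `alpha`,
#'   `beta`, mode `map`, `sd`, `mean`, the evaluation `grid` and `density`
#'   (normalised to unit trapezoidal integral), and `prior_only` (`TRUE`
#'   when `n_loops = 0`, in which case the posterior is the prior and the
#'   MAP is undefined).
#' @export
cut_posterior <- function(n_loops, n_cuts, grid_n = 10001L) {
  stopifnot(length(n_loops) == 1L, length(n_cuts) == 1L,
            n_loops >= 0, n_cuts >= 0)
  if (n_cuts > n_loops) stop("`n_cuts` cannot exceed `n_loops`")
  prior_only <- n_loops == 0
  if (prior_only) {
    warning("no observed loops: posterior for p_cut equals the prior")
  }
  alpha <- n_cuts + 1
  beta <- n_loops - n_cuts + 1
  grid <- seq(0, 1, length.out = as.integer(grid_n))
  density <- stats::dbeta(grid, alpha, beta)
  # renormalise the trapezoidal integral on the grid
  h <- grid[2L] - grid[1L]
  z <- h * (sum(density) - (density[1L] + density[length(density)]) / 2)
  density <- density / z
  structure(list(
    alpha = alpha, beta = beta,
    map = if (prior_only) NA_real_ else n_cuts / n_loops,
    sd = sqrt(alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1))),
    mean = alpha / (alpha + beta),
    grid = grid, density = density,
    n_loops = n_loops, n_cuts = n_cuts, prior_only = prior_only
  ), class = "cut_posterior")
}

#' @export
print.cut_posterior <- function(x, ...) {
  if (x$prior_only) {
    cat("Cutting probability posterior: prior only (no observed loops)\n")
  } else {
    cat(sprintf("Cutting probability: MAP %.4f, sd %.4f  (n_loops = %d, n_cuts = %d)\n",
                x$map, x$sd, x$n_loops, x$n_cuts))
  }
  invisible(x)
}

#' Quartiles of the pooled dwell-time distribution
#'
#' Median and first/third quartiles of the pooled paired-complex
#' lifetimes, irrespective of fate. Censored dwells (unknown fate,
#' truncated by the observation end) are excluded by default. Quartiles
#' interpolate linearly between order statistics.
#'
#' @param records a dwell `data.frame` (`duration_min`, `fate`) or a bare
#'   numeric vector of durations in minutes.
#' @param include_censored include censored records in the pool.
#' @return named list `q1`, `median`, `q3` in minutes.
#' @export
dwell_quartiles <- function(records, include_censored = FALSE) {
  if (is.data.frame(records)) {
    stopifnot(all(c("duration_min", "fate") %in% names(records)))
    keep <- include_censored | records$fate != "CENSORED"
    x <- records$duration_min[keep]
  } else {
    x <- as.numeric(records)
  }
  if (length(x) < 1L) stop("no (non-censored) dwell records")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(q1 = q[1L], median = q[2L], q3 = q[3L])
}
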