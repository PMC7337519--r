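# Permutation tests comparing a variant dataset against a reference for
# the three per-RSS metrics.

metric_units <- function(metric, data) {
  # extract the permutation units for a metric from an rss_dataset or a
  # bare numeric vector
  if (inherits(data, "rss_dataset")) {
    switch(metric,
      loop_frequency = data$counts$n_loops,
      median_dwell = {
        d <- data$dwells
        if (is.null(d)) stop("dataset carries no dwell records")
        d$duration_min[d$fate != "CENSORED"]
      },
      cut_fraction = rep(c(1, 0),
                         c(data$n_cuts, data$n_resolved - data$n_cuts))
    )
  } else {
    as.numeric(data)
  }
}

metric_fun <- function(metric) {
  switch(metric,
    loop_frequency = mean,   # per-bead loop counts -> loops per bead
    median_dwell = stats::median,
    cut_fraction = mean      # per-loop cut indicators -> cut fraction
  )
}

#' Permutation test of a metric between two datasets
#'
#' Tests the null hypothesis that the variant's metric is drawn from the
#' same distribution as the reference's by permuting the pooled units
#' between the two groups (beads with their loop counts for the looping
#' frequency; fate-resolved dwell times for the median dwell; per-loop
#' cleavage indicators for the cut fraction). The two-sided p-value uses
#' the add-one estimator `p = (1 + #{|null| >= |observed|}) / (1 + n_perm)`
#' and is deterministic under a fixed seed.
#'
#' @param metric one of `"loop_frequency"`, `"median_dwell"`,
#'   `"cut_fraction"`.
#' @param data_a,data_b [rss_dataset()] objects, or bare numeric vectors
#'   of the metric's units.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return an object of class `tpm_test`: `metric`, `observed` difference
#'   (A minus B), `p_value`, `null_diffs`, `n_perm`, `seed`, and `status`
#'   (`"ok"` or `"undefined"` when the metric does not exist for a group,
#'   e.g. the cut fraction with zero loops; then `p_value` is `NA`).
#' @export
permutation_test <- function(metric = c("loop_frequency", "median_dwell",
                                        "cut_fraction"),
                             data_a, data_b, n_perm = 10000L, seed = 1L) {
  metric <- match.arg(metric)
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  n_perm <- as.integer(n_perm)
  a <- metric_units(metric, data_a)
  b <- metric_units(metric, data_b)
  if (length(a) == 0L || length(b) == 0L) {
    return(structure(list(metric = metric, observed = NA_real_,
                          p_value = NA_real_, null_diffs = numeric(0),
                          n_perm = n_perm, seed = as.integer(seed),
                          status = "undefined"),
                     class = "tpm_test"))
  }
  f <- metric_fun(metric)
  obs <- f(a) - f(b)
  pool <- c(a, b)
  na <- length(a)
  n <- length(pool)
  set.seed(as.integer(seed))
  null_diffs <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, na)
    f(pool[idx]) - f(pool[-idx])
  }, numeric(1L))
  tol <- 1e-12 * max(1, abs(obs))
  p <- (1 + sum(abs(null_diffs) >= abs(obs) - tol)) / (1 + n_perm)
  structure(list(metric = metric, observed = obs, p_value = p,
                 null_diffs = null_diffs, n_perm = n_perm,
                 seed = as.integer(seed), status = "ok"),
            class = "tpm_test")
}

#' @export
print.tpm_test <- function(x, ...) {
  if (x$status == "undefined") {
    cat(sprintf("Permutation test (%s): undefined (metric does not exist for a group)\n",
                x$metric))
  } else {
    cat(sprintf("Permutation test (%s): observed difference %.4g, p = %.4g (%d permutations)\n",
                x$metric, x$observed, x$p_value, x$n_perm))
  }
  invisible(x)
}

#' Benjamini-Hochberg adjustment of a set of test results
#'
#' Optional multiple-testing correction across several [permutation_test()]
#' results (per-sequence comparisons are reported unadjusted by default).
#'
#' @param tests a list of `tpm_test` objects.
#' @return numeric vector of BH-adjusted p-values (NA for undefined
#'   tests).
#' @export
adjust_tests <- function(tests) {
  p <- vapply(tests, function(t) t$p_value, numeric(1L))
  stats::p.adjust(p, method = "BH")
}
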