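#' Hierarchical group sample
#'
#' Long-format container for nested measurements: each value belongs to a
#' unit (typically a cell) and optionally to a higher-level animal, within a
#' labeled experimental group (e.g. WT vs mutant).
#'
#' @param values Numeric measurements.
#' @param group Group label(s), recycled if scalar.
#' @param unit_id Unit (cell) identifier per value.
#' @param animal_id Optional higher-level identifier per value.
#' @return An object of class `group_sample` (a data frame with columns
#'   `value`, `group`, `unit_id`, `animal_id`).
#' @export
group_sample <- function(values, group, unit_id, animal_id = NA) {
  if (!is.numeric(values) || !length(values))
    stop("'values' must be a non-empty numeric vector")
  df <- data.frame(value = as.numeric(values),
                   group = rep_len(as.character(group), length(values)),
                   unit_id = rep_len(as.character(unit_id), length(values)),
                   animal_id = rep_len(as.character(animal_id),
                                       length(values)))
  class(df) <- c("group_sample", "data.frame")
  df
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Partition of variance between and within units (cells or animals) from a
#' one-way random-effects ANOVA:
#' `ICC = (MS_between - MS_within) / (MS_between + (k - 1) MS_within)`,
#' with `k` the per-unit observation count. For unbalanced data `k` is
#' replaced by the standard one-way correction
#' `k0 = (N - sum(n_i^2) / N) / (a - 1)`. The reliability label follows the
#' conventional cut-points: poor (<= 0.50), moderate (0.50-0.75], good
#' (0.75-0.90], excellent (> 0.90).
#'
#' @param sample A [group_sample()] (or data frame with `value`, `unit_id`),
#'   or a numeric vector together with `unit_id`.
#' @param unit_id Unit identifiers when `sample` is a plain numeric vector.
#' @return An object of class `icc_result`: list with `icc`, `ms_between`,
#'   `ms_within`, `k_bar`, `label`, `n_units`, `n_obs`.
#' @examples
#' s <- group_sample(c(1, 2, 1.5, 5, 6, 5.5), group = "WT",
#'                   unit_id = rep(c("c1", "c2"), each = 3))
#' icc_1_1(s)
#' @export
icc_1_1 <- function(sample, unit_id = NULL) {
  if (is.numeric(sample)) {
    if (is.null(unit_id)) stop("'unit_id' required with a numeric vector")
    df <- data.frame(value = sample, unit_id = as.character(unit_id))
  } else {
    df <- as.data.frame(sample)
  }
  df$unit_id <- factor(df$unit_id)
  a <- nlevels(df$unit_id)
  if (a < 2L) stop("ICC undefined with a single unit")
  N <- nrow(df)
  ni <- as.numeric(table(df$unit_id))

  # only the mean squares are used; the F-test warning on zero-residual
  # fits is irrelevant here
  aov_tab <- suppressWarnings(stats::anova(stats::aov(value ~ unit_id,
                                                      data = df)))
  ms_b <- aov_tab["unit_id", "Mean Sq"]
  ms_w <- aov_tab["Residuals", "Mean Sq"]
  if (!is.finite(ms_w)) ms_w <- 0   # every unit has one observation

  k0 <- (N - sum(ni^2) / N) / (a - 1)
  icc <- if (ms_b + (k0 - 1) * ms_w == 0) 0 else
    (ms_b - ms_w) / (ms_b + (k0 - 1) * ms_w)
  label <- if (icc <= 0.50) "poor" else if (icc <= 0.75) "moderate"
           else if (icc <= 0.90) "good" else "excellent"
  structure(
    list(icc = icc, ms_between = ms_b, ms_within = ms_w, k_bar = k0,
         label = label, n_units = a, n_obs = N),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.4g  [%s reliability]\n", x$icc, x$label))
  cat(sprintf("  MS between %.4g, MS within %.4g, k %.4g (%d units, %d obs)\n",
              x$ms_between, x$ms_within, x$k_bar, x$n_units, x$n_obs))
  invisible(x)
}

#' Hedges' g standardized mean difference
#'
#' `(mean(a) - mean(b)) / s_pooled`, with the pooled SD using the
#' `(n1 - 1) + (n2 - 1)` denominator. Reports by how many standard
#' deviations the two groups differ; by convention the first argument is the
#' case group and the second the control, so a positive `g` means the case
#' group is larger.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @return Hedges' g (dimensionless).
#' @examples
#' hedges_g(c(3, 4, 5), c(1, 2, 3))   # 2
#' @export
hedges_g <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    ((n1 - 1) + (n2 - 1))
  if (sp2 <= 0) stop("zero pooled SD: Hedges' g undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

boot_result <- function(md_draws, g_draws, n_replicas, dropped, seed) {
  ci_md <- stats::quantile(md_draws, c(0.025, 0.975), names = FALSE)
  ci_g <- stats::quantile(g_draws, c(0.025, 0.975), names = FALSE)
  structure(
    list(mean_difference = mean(md_draws), hedges_g = mean(g_draws),
         ci_mean_difference = ci_md, ci_hedges_g = ci_g,
         meaningful_mean_difference = ci_md[1] > 0 || ci_md[2] < 0,
         meaningful_hedges_g = ci_g[1] > 0 || ci_g[2] < 0,
         n_replicas = n_replicas, n_dropped = dropped,
         distribution = list(mean_difference = md_draws, hedges_g = g_draws),
         seed = seed),
    class = "effect_size_result"
  )
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("Bootstrapped effect sizes (%d replicas%s)\n", x$n_replicas,
              if (x$n_dropped > 0)
                sprintf(", %d degenerate replicas dropped", x$n_dropped)
              else ""))
  cat(sprintf("  mean difference: %.4g  [95%% CI %.4g, %.4g]%s\n",
              x$mean_difference, x$ci_mean_difference[1],
              x$ci_mean_difference[2],
              if (x$meaningful_mean_difference) "  *" else ""))
  cat(sprintf("  Hedges' g      : %.4g  [95%% CI %.4g, %.4g]%s\n",
              x$hedges_g, x$ci_hedges_g[1], x$ci_hedges_g[2],
              if (x$meaningful_hedges_g) "  *" else ""))
  cat("  (* 95% CI excludes 0)\n")
  invisible(x)
}

#' Bootstrapped mean difference and Hedges' g
#'
#' Treats observations as independent: in each replica, each group is
#' resampled with replacement at its own size and the mean difference and
#' Hedges' g (first minus second group) are recomputed. Reports the
#' resampling distributions, their means, percentile 95% CIs, and whether
#' each CI excludes 0 ("statistically meaningful"). Replicas whose pooled SD
#' is zero leave `g` undefined; they are dropped and counted.
#'
#' @param a,b Numeric vectors (case group first).
#' @param n_replicas Number of bootstrap replicas (default 10000).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @param paired If `TRUE`, resample paired indices (requires equal lengths);
#'   used for within-cell latency/jitter comparisons.
#' @return An `effect_size_result`.
#' @export
bootstrap_effect <- function(a, b, n_replicas = 10000, seed = 1L,
                             paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (paired && length(a) != length(b))
    stop("paired resampling requires equal group sizes")
  n1 <- length(a); n2 <- length(b)
  withr::with_seed(seed, {
    md <- numeric(n_replicas)
    g <- numeric(n_replicas)
    ok <- logical(n_replicas)
    for (r in seq_len(n_replicas)) {
      if (paired) {
        i <- sample.int(n1, n1, replace = TRUE)
        ra <- a[i]; rb <- b[i]
      } else {
        ra <- a[sample.int(n1, n1, replace = TRUE)]
        rb <- b[sample.int(n2, n2, replace = TRUE)]
      }
      md[r] <- mean(ra) - mean(rb)
      sp2 <- ((n1 - 1) * stats::var(ra) + (n2 - 1) * stats::var(rb)) /
        (n1 + n2 - 2)
      if (sp2 > 0) {
        g[r] <- (mean(ra) - mean(rb)) / sqrt(sp2)
        ok[r] <- TRUE
      }
    }
  })
  boot_result(md[ok], g[ok], n_replicas, sum(!ok), seed)
}

#' Two-level hierarchical bootstrap of effect sizes
#'
#' Respects nesting (units, then events within units) to avoid
#' pseudo-replication when many events are recorded per cell. Per replica
#' and group: sample `n` units with replacement (`n` = number of units in
#' that group), then from each sampled unit sample `k` events with
#' replacement (`k` = the maximum events-per-unit in that group), pool the
#' resampled events, and compute the mean difference and Hedges' g between
#' the pooled groups. Every unit therefore carries equal expected weight
#' regardless of how many events it contributed.
#'
#' @param a,b [group_sample()] objects (case group first); grouping labels
#'   inside them are ignored - the two arguments define the comparison.
#' @param n_replicas Number of replicas (default 10000).
#' @param seed Integer seed.
#' @return An `effect_size_result`.
#' @export
hierarchical_bootstrap_effect <- function(a, b, n_replicas = 10000,
                                          seed = 1L) {
  split_units <- function(s) {
    df <- as.data.frame(s)
    if (!nrow(df)) stop("empty group sample")
    u <- split(df$value, df$unit_id)
    if (length(u) < 2L) stop("need at least 2 units per group")
    if (any(vapply(u, length, integer(1)) < 1L)) stop("empty unit")
    u
  }
  ua <- split_units(a)
  ub <- split_units(b)
  ka <- max(vapply(ua, length, integer(1)))
  kb <- max(vapply(ub, length, integer(1)))

  resample_group <- function(units, k) {
    picked <- sample.int(length(units), length(units), replace = TRUE)
    unlist(lapply(units[picked], function(v)
      v[sample.int(length(v), k, replace = TRUE)]), use.names = FALSE)
  }

  withr::with_seed(seed, {
    md <- numeric(n_replicas)
    g <- numeric(n_replicas)
    ok <- logical(n_replicas)
    for (r in seq_len(n_replicas)) {
      ra <- resample_group(ua, ka)
      rb <- resample_group(ub, kb)
      md[r] <- mean(ra) - mean(rb)
      n1 <- length(ra); n2 <- length(rb)
      sp2 <- ((n1 - 1) * stats::var(ra) + (n2 - 1) * stats::var(rb)) /
        (n1 + n2 - 2)
      if (sp2 > 0) {
        g[r] <- (mean(ra) - mean(rb)) / sqrt(sp2)
        ok[r] <- TRUE
      }
    }
  })
  boot_result(md[ok], g[ok], n_replicas, sum(!ok), seed)
}

#' Route a dataset to the appropriate group-comparison analysis
#'
#' Encodes the decision rule for nested data: when half or more of the
#' variance lies within units (ICC <= 0.50), observations are treated as
#' independent and the plain bootstrap applies; when ICC exceeds 0.50 and
#' units contribute many observations each (>= 20), the hierarchical
#' bootstrap is appropriate; with ICC above 0.50 but few observations per
#' unit a linear mixed model is recommended instead (routing only - no model
#' is fitted here).
#'
#' @param icc An [icc_1_1()] result (or a bare ICC value).
#' @param min_obs_per_unit Smallest number of observations any unit
#'   contributes.
#' @param total_obs Total number of observations (informational).
#' @return One of `"independent_bootstrap"`, `"hierarchical_bootstrap"`,
#'   `"lmm_recommended"`.
#' @export
choose_analysis_path <- function(icc, min_obs_per_unit, total_obs = NA) {
  icc_val <- if (inherits(icc, "icc_result")) icc$icc else as.numeric(icc)
  if (!is.finite(icc_val)) stop("invalid ICC value")
  if (icc_val <= 0.50) return("independent_bootstrap")
  if (min_obs_per_unit >= 20) "hierarchical_bootstrap" else "lmm_recommended"
}
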