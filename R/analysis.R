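#' Bundle repeated runs of one algorithm
#'
#' @param traces List of `run_trace` objects (typically 30), all with the
#'   same iteration count.
#' @param label Algorithm label for reports.
#' @return A list of class `run_set`.
#' @export
run_set <- function(traces, label = "run") {
  if (!length(traces)) stop("empty run set")
  lens <- vapply(traces, function(tr) nrow(tr$iterations), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all traces in a run set must have the same iteration count")
  }
  structure(list(traces = traces, label = label), class = "run_set")
}

trace_fitness <- function(x) {
  if (inherits(x, "run_trace")) x$iterations$best_fitness else as.numeric(x)
}

#' Standardize one run's fitness curve
#'
#' Converts a fitness trajectory to z-scores using the run's own mean and
#' (by default population) standard deviation:
#' `z_t = (f_t - mean(f)) / sd(f)`. Standardization erases scale
#' differences between algorithms so runs can be overlaid and averaged
#' fairly.
#'
#' @param trace A `run_trace` or numeric fitness vector with >= 2 values.
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return Numeric vector of z-scores with mean 0 and standard deviation 1.
#' @export
zscore_trace <- function(trace, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  f <- trace_fitness(trace)
  if (length(f) < 2L) stop("need at least 2 iterations to standardize")
  mu <- mean(f)
  sigma <- if (sd_type == "population") {
    sqrt(mean((f - mu)^2))
  } else {
    stats::sd(f)
  }
  if (sigma == 0) stop("constant trace: standardization undefined (sd = 0)")
  (f - mu) / sigma
}

#' Average standardized fitness curve over a run set
#'
#' @param runs A [run_set()].
#' @param sd_type Passed to [zscore_trace()].
#' @return Numeric vector: the elementwise mean of the per-run z-curves.
#' @export
mean_zcurve <- function(runs, sd_type = "population") {
  zs <- lapply(seq_along(runs$traces), function(k) {
    tryCatch(zscore_trace(runs$traces[[k]], sd_type),
             error = function(e) stop("run ", k, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  rowMeans(do.call(cbind, zs))
}

#' Iteration at which a run reaches a fraction of its best fitness
#'
#' Finds the first iteration whose best-so-far (running maximum) fitness
#' reaches `frac` of the run's overall best. When the fitness values span
#' zero or negative values the curve is min-max normalized first, since a
#' percentage of a non-positive best is not meaningful.
#'
#' @param trace A `run_trace` or numeric fitness vector.
#' @param frac Fraction of the best fitness, in `(0, 1]` (default 0.95).
#' @return The 1-based iteration index of the first crossing.
#' @export
convergence_iteration <- function(trace, frac = 0.95) {
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  f <- trace_fitness(trace)
  if (min(f) <= 0) {
    if (max(f) == min(f)) return(1L)
    f <- (f - min(f)) / (max(f) - min(f))
  }
  rm_ <- cummax(f)
  which(rm_ >= frac * max(f))[1L]
}

#' NFE needed to reach a pooled fitness threshold
#'
#' Implements the threshold-of-interest (tHi) comparison: the per-run best
#' fitnesses of both sets are pooled and their median (midpoint for an
#' even pool) defines tHi. For each run, the cumulative NFE at the first
#' iteration whose fitness reaches tHi is reported; runs that never reach
#' tHi are discarded (they carry no information about cost-to-target).
#'
#' @param set_a,set_b [run_set()] objects.
#' @return A list of class `threshold_nfe` with elements `thi`, `nfe_a`,
#'   `nfe_b` (NFE at first crossing, successful runs only), `discarded_a`,
#'   `discarded_b` (indices of discarded runs), and the set labels.
#' @export
threshold_nfe <- function(set_a, set_b) {
  bests <- function(s) vapply(s$traces, function(tr) max(trace_fitness(tr)),
                              numeric(1))
  ba <- bests(set_a)
  bb <- bests(set_b)
  thi <- stats::median(c(ba, bb))
  crossing <- function(s) {
    vapply(s$traces, function(tr) {
      t <- which(tr$iterations$best_fitness >= thi)[1L]
      if (is.na(t)) NA_real_ else tr$iterations$nfe[t]
    }, numeric(1))
  }
  na_ <- crossing(set_a)
  nb_ <- crossing(set_b)
  structure(
    list(thi = thi,
         nfe_a = na_[!is.na(na_)], nfe_b = nb_[!is.na(nb_)],
         discarded_a = which(is.na(na_)), discarded_b = which(is.na(nb_)),
         label_a = set_a$label, label_b = set_b$label),
    class = "threshold_nfe"
  )
}

#' @export
print.threshold_nfe <- function(x, ...) {
  cat(sprintf("threshold of interest (tHi): %.4f\n", x$thi))
  cat(sprintf("  %s: %d runs reached tHi (%d discarded), median NFE %.0f\n",
              x$label_a, length(x$nfe_a), length(x$discarded_a),
              if (length(x$nfe_a)) stats::median(x$nfe_a) else NA))
  cat(sprintf("  %s: %d runs reached tHi (%d discarded), median NFE %.0f\n",
              x$label_b, length(x$nfe_b), length(x$discarded_b),
              if (length(x$nfe_b)) stats::median(x$nfe_b) else NA))
  invisible(x)
}

#' Statistical comparison of two samples of run metrics
#'
#' Shapiro-Wilk normality is checked on both samples; if both look normal
#' (p > `alpha`) a Welch t-test compares the means, otherwise a
#' Mann-Whitney U (Wilcoxon rank-sum) test is used. Cohen's d
#' `(mean(b) - mean(a)) / pooled SD` is always reported as the effect
#' size.
#'
#' @param a,b Numeric samples (each of size >= 3), e.g. per-run best
#'   fitness, time, or NFE.
#' @param alpha Normality gate for choosing the test.
#' @param label_a,label_b Sample labels for printing.
#' @return A list of class `comparison_report`: `shapiro_p_a`,
#'   `shapiro_p_b`, `test` (`"welch_t"` or `"mann_whitney_u"`), `p_value`,
#'   `cohens_d`, `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`.
#' @export
compare_runs <- function(a, b, alpha = 0.05, label_a = "a", label_b = "b") {
  if (length(a) < 3L || length(b) < 3L) stop("each sample needs >= 3 values")
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      # identical constants: no effect, no test information
      return(structure(
        list(shapiro_p_a = NA_real_, shapiro_p_b = NA_real_,
             test = "none", p_value = 1, cohens_d = 0,
             mean_a = mean(a), mean_b = mean(b), sd_a = 0, sd_b = 0,
             n_a = length(a), n_b = length(b),
             label_a = label_a, label_b = label_b),
        class = "comparison_report"
      ))
    }
    stop("both samples have zero variance: effect size undefined")
  }
  sw <- function(x) {
    if (stats::var(x) == 0) 0 else stats::shapiro.test(x)$p.value
  }
  pa <- sw(a)
  pb <- sw(b)
  if (pa > alpha && pb > alpha) {
    test <- "welch_t"
    pv <- stats::t.test(a, b)$p.value
  } else {
    test <- "mann_whitney_u"
    pv <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  sp <- sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) /
               (length(a) + length(b) - 2))
  structure(
    list(shapiro_p_a = pa, shapiro_p_b = pb, test = test, p_value = pv,
         cohens_d = (mean(b) - mean(a)) / sp,
         mean_a = mean(a), mean_b = mean(b),
         sd_a = stats::sd(a), sd_b = stats::sd(b),
         n_a = length(a), n_b = length(b),
         label_a = label_a, label_b = label_b),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("%s: %.4f +/- %.4f (n=%d)\n", x$label_a, x$mean_a, x$sd_a, x$n_a))
  cat(sprintf("%s: %.4f +/- %.4f (n=%d)\n", x$label_b, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("test: %s, p = %.4g%s; Cohen's d = %.3f\n", x$test, x$p_value,
              if (is.finite(x$p_value) && x$p_value < 0.05) " (significant)"
              else " (ns)", x$cohens_d))
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' @param report A `comparison_report` (or list of them).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(report, path) {
  strip <- function(r) unclass(r)
  out <- if (inherits(report, "comparison_report")) strip(report) else {
    lapply(report, strip)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot averaged z-score convergence curves
#'
#' @param ... Named [run_set()] objects.
#' @param sd_type Passed to [zscore_trace()].
#' @return A ggplot object.
#' @export
plot_zcurves <- function(..., sd_type = "population") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  sets <- list(...)
  df <- do.call(rbind, lapply(sets, function(s) {
    z <- mean_zcurve(s, sd_type)
    data.frame(iteration = seq_along(z), z = z, algorithm = s$label)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = iteration, y = z,
                                   colour = algorithm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration / generation",
                  y = "mean standardized fitness (z)")
}

#' Boxplot of NFE-to-threshold
#'
#' @param x A [threshold_nfe()] result.
#' @return A ggplot object.
#' @export
plot_threshold_nfe <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- rbind(
    if (length(x$nfe_a)) data.frame(nfe = x$nfe_a, algorithm = x$label_a),
    if (length(x$nfe_b)) data.frame(nfe = x$nfe_b, algorithm = x$label_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = algorithm, y = nfe)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(y = "NFE at first threshold crossing")
}
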