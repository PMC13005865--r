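#' Incremental area under the curve
#'
#' Trapezoidal integral of a series minus its baseline value over a window,
#' on the measured grid with linear interpolation at the window endpoints.
#' The baseline is the series value at `baseline_time` (interpolated if not
#' sampled). With a shared baseline the summary is additive over adjacent
#' windows.
#'
#' @param series an [hf_ts].
#' @param window `c(t_start, t_end)`, within the series support.
#' @param baseline_time time whose value anchors the increment (default the
#'   window start).
#' @return list of class `summary_metric`: `name`, `window`,
#'   `baseline_time`, `value`, `unit` (source unit x min).
#' @export
iauc <- function(series, window, baseline_time = window[1]) {
  check_window(series, window)
  if (baseline_time < min(series$times) - 1e-9 ||
      baseline_time > max(series$times) + 1e-9)
    stop("iauc: baseline_time outside series support", call. = FALSE)
  value <- iauc_value(series, window,
                      baseline_value = ts_interp(series, baseline_time))
  structure(list(name = series$label, window = window,
                 baseline_time = baseline_time, value = value,
                 unit = paste(series$unit, "x min")),
            class = "summary_metric")
}

# numeric core shared with the flux summaries
iauc_value <- function(series, window, baseline_value) {
  tt <- sort(unique(c(window,
                      series$times[series$times > window[1] &
                                     series$times < window[2]])))
  vv <- ts_interp(series, tt) - baseline_value
  trapz(tt, vv)
}

#' @export
print.summary_metric <- function(x, ...) {
  cat(sprintf("<summary_metric> %s: iAUC[%g-%g] = %g %s (baseline at t=%g)\n",
              x$name, x$window[1], x$window[2], x$value, x$unit,
              x$baseline_time))
  invisible(x)
}

#' Peak and nadir of a series over the experimental period
#'
#' Maximum and minimum values attained at sampled times at or after
#' `exclude_before` (default 0, which keeps T0 and drops the T-60 sample,
#' following the convention that pre-dose excursions are not counted).
#' Ties are broken towards the earliest time.
#'
#' @param series an [hf_ts].
#' @param exclude_before minutes; samples strictly before this are ignored.
#' @return list with `peak_value`, `peak_time`, `nadir_value`, `nadir_time`.
#' @export
peak_nadir <- function(series, exclude_before = 0) {
  stopifnot(inherits(series, "hf_ts"))
  keep <- series$times >= exclude_before
  if (!any(keep))
    stop("peak_nadir: all samples excluded", call. = FALSE)
  tt <- series$times[keep]; vv <- series$values[keep]
  ip <- which.max(vv); iv <- which.min(vv)  # which.* take the first tie
  list(peak_value = vv[ip], peak_time = tt[ip],
       nadir_value = vv[iv], nadir_time = tt[iv])
}

#' Independent two-sample t test with summary statistics
#'
#' Pooled-variance Student t test (the package default; Welch via
#' `var_equal = FALSE`), returning the group means and SDs, the 95% CI of
#' the mean difference and the two-sided p value. Degenerate input with zero
#' pooled variance and equal means yields t = 0, p = 1.
#'
#' @param a,b numeric vectors, each of length >= 2, finite.
#' @param metric label carried through to reports.
#' @param var_equal pool the variances (default `TRUE`).
#' @return list of class `group_comparison` with `metric`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `difference`, `ci95`, `t`, `df`, `p`, `n_a`, `n_b`.
#' @export
two_sample_t <- function(a, b, metric = "", var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("two_sample_t: each group needs n >= 2", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("two_sample_t: values must be finite", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: no within-group variance; equal means give t = 0, p = 1,
    # distinct means are separated with certainty
    d <- mean(a) - mean(b)
    res <- if (d == 0) {
      list(statistic = 0, parameter = length(a) + length(b) - 2,
           p.value = 1, conf.int = c(0, 0))
    } else {
      list(statistic = sign(d) * Inf,
           parameter = length(a) + length(b) - 2,
           p.value = 0, conf.int = c(d, d))
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal, conf.level = 0.95)
    res <- list(statistic = unname(tt$statistic),
                parameter = unname(tt$parameter),
                p.value = tt$p.value, conf.int = as.numeric(tt$conf.int))
  }
  structure(list(metric = metric,
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 difference = mean(a) - mean(b),
                 ci95 = res$conf.int,
                 t = res$statistic, df = res$parameter, p = res$p.value,
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0("<group_comparison> %s: %.3g+/-%.3g (n=%d) vs ",
                     "%.3g+/-%.3g (n=%d); diff %.3g [%.3g, %.3g], ",
                     "t=%.3g, p=%.3g\n"),
              x$metric, x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
              x$difference, x$ci95[1], x$ci95[2], x$t, x$p))
  invisible(x)
}

#' Hierarchical subgroup discovery
#'
#' Agglomerative clustering of per-subject incremental-AUC features
#' (plasma D-Glc and hepatic D-Glc iAUC over 0–180 min): features are
#' z-scored, distances are Euclidean, linkage is Ward, and the tree is cut
#' at `k`. Cluster labels are renumbered so cluster 1 has the larger mean
#' (standardised) plasma D-Glc iAUC, matching the convention that
#' subgroup 1 is the steep-excursion phenotype. The mean silhouette width is
#' reported (`NA` for `k = 1`).
#'
#' @param features matrix or data.frame, one row per subject; first column
#'   the plasma D-Glc iAUC, second the hepatic D-Glc iAUC.
#' @param k number of clusters (default 2).
#' @param linkage `hclust` method (default `"ward.D2"`; exposed so the
#'   stability of a split can be probed).
#' @return list of class `cluster_result`: `labels`, `tree` (hclust),
#'   `silhouette` (mean width), `standardisation` (centers and scales),
#'   `k`.
#' @export
cluster_subgroups <- function(features, k = 2, linkage = "ward.D2") {
  x <- as.matrix(features)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("cluster_subgroups: features must be finite numerics", call. = FALSE)
  n <- nrow(x)
  if (n < k) stop("cluster_subgroups: need at least k subjects", call. = FALSE)
  if (nrow(unique(x)) < k)
    stop("cluster_subgroups: fewer than k distinct subjects; k clusters ",
         "impossible", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1  # constant feature carries no information
  z <- scale(x, center = ctr, scale = scl)
  d <- stats::dist(z, method = "euclidean")
  tree <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(tree, k = k)
  # relabel so cluster 1 has the larger mean plasma D-Glc iAUC
  ord <- order(tapply(z[, 1], labels, mean), decreasing = TRUE)
  labels <- match(labels, ord)
  sil <- if (k >= 2) mean_silhouette(as.matrix(d), labels) else NA_real_
  structure(list(labels = labels, tree = tree, silhouette = sil,
                 standardisation = list(center = ctr, scale = scl),
                 k = k), class = "cluster_result")
}

# mean silhouette width from a distance matrix and integer labels;
# singleton clusters contribute 0 by convention
mean_silhouette <- function(dm, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(dm[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
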