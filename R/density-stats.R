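#' Event density per square millimetre
#'
#' Converts a per-image count into a density using the image geometry and
#' pixel scale. For the nominal 1600 x 1200 px field at 2.828 px/um each
#' image covers 0.24 mm^2, so e.g. 13 particles correspond to 54.15 /mm^2.
#'
#' @param count Non-negative event count.
#' @param width_px,height_px Image dimensions in pixels.
#' @param scale A [pixel_scale()].
#' @return Density in events per mm^2.
#' @export
density_per_mm2 <- function(count, width_px, height_px,
                            scale = pixel_scale()) {
  if (count < 0) abort("`count` must be non-negative.")
  count / image_area_mm2(width_px, height_px, scale)
}

#' Two-sided two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] returning a tidy one-row tibble.
#' Welch's unequal-variance form is the default; set `pooled = TRUE` for
#' the classical equal-variance test.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance (classical) t-test?
#' @return A tibble with `t_statistic`, `p_value`, `df`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`, `pooled`.
#' @export
two_sided_t_test <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 observations.")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    # t.test() refuses constant data; the limit is well defined
    equal <- mean(group_a) == mean(group_b)
    return(tibble::tibble(
      t_statistic = if (equal) 0 else Inf * sign(mean(group_a) - mean(group_b)),
      p_value = if (equal) 1 else 0,
      df = length(group_a) + length(group_b) - 2,
      mean_a = mean(group_a), mean_b = mean(group_b),
      n_a = length(group_a), n_b = length(group_b),
      pooled = pooled
    ))
  }
  ht <- t.test(group_a, group_b, alternative = "two.sided",
               var.equal = pooled)
  tibble::tibble(
    t_statistic = unname(ht$statistic),
    p_value = ht$p.value,
    df = unname(ht$parameter),
    mean_a = mean(group_a), mean_b = mean(group_b),
    n_a = length(group_a), n_b = length(group_b),
    pooled = pooled
  )
}

#' Least-squares slope of automated on manual counts
#'
#' The scatter-plot regression used to compare counting methods: slope of
#' the ordinary least-squares line of `ac` on `mc`.
#'
#' @param mc,ac Paired manual and automated counts (equal length, n >= 2).
#' @return The slope (a single number).
#' @export
scatter_slope <- function(mc, ac) {
  if (length(mc) != length(ac)) abort("`mc` and `ac` must be paired.")
  if (length(mc) < 2) abort("Need at least 2 pairs.")
  if (var(mc) == 0) abort("Zero variance in `mc`; slope undefined.")
  unname(coef(lm(ac ~ mc))[2])
}

#' Bland-Altman agreement analysis
#'
#' Computes per-pair differences d = ac - mc and means m = (ac + mc)/2, the
#' mean difference (bias), 1.96-sd limits of agreement, and the
#' least-squares slope of d on m. The slope of the regression line fitted
#' through the Bland-Altman plot is non-classical but is the agreement
#' summary this workflow reports: a positive slope means the automated
#' method picks up proportionally more events where events are frequent.
#'
#' @param mc,ac Paired manual and automated counts (equal length, n >= 3).
#' @return A tibble with `n`, `mean_difference`, `sd_difference`,
#'   `loa_lower`, `loa_upper`, `slope`.
#' @export
bland_altman <- function(mc, ac) {
  if (length(mc) != length(ac)) abort("`mc` and `ac` must be paired.")
  if (length(mc) < 3) abort("Need at least 3 pairs.")
  d <- ac - mc
  m <- (ac + mc) / 2
  if (var(m) == 0) abort("Zero variance in pair means; slope undefined.")
  sd_d <- sd(d)
  tibble::tibble(
    n = length(d),
    mean_difference = mean(d),
    sd_difference = sd_d,
    loa_lower = mean(d) - 1.96 * sd_d,
    loa_upper = mean(d) + 1.96 * sd_d,
    slope = unname(coef(lm(d ~ m))[2])
  )
}

#' Coefficient of variation and signal-to-noise ratio
#'
#' CV = sample sd / mean (n-1 denominator); SNR = 1/CV. Used to compare
#' the precision of manual and automated counting per mouse or per group.
#' A zero-variance sample yields CV 0 with SNR flagged infinite.
#'
#' @param values Numeric vector, n >= 2, with non-zero mean.
#' @return A tibble with `n`, `mean`, `sd`, `cv`, `snr`.
#' @export
cv_snr <- function(values) {
  if (length(values) < 2) abort("Need at least 2 values.")
  mu <- mean(values)
  if (mu == 0) abort("Zero mean; CV undefined.")
  s <- sd(values)
  cv <- s / mu
  tibble::tibble(n = length(values), mean = mu, sd = s, cv = cv,
                 snr = if (cv == 0) Inf else 1 / cv)
}

#' Manual-vs-automated method comparison
#'
#' Assembles the full agreement analysis for paired per-image counts: a
#' two-sided t-test between the two methods' counts, the scatter-plot
#' regression slope of automated on manual, the Bland-Altman summary, and
#' per-method mean/sd/CV/SNR.
#'
#' @param data A data frame of paired counts.
#' @param manual,automated Column names (tidy-eval) holding the manual and
#'   automated counts.
#' @param pooled Use the pooled-variance t-test? Default Welch.
#' @return A `method_comparison` object; see [tidy.method_comparison()],
#'   [glance.method_comparison()] and [autoplot.method_comparison()].
#' @examples
#' counts <- tibble::tibble(mc = c(2, 5, 3, 8, 6, 4),
#'                          ac = c(4, 9, 5, 13, 11, 6))
#' cmp <- compare_methods(counts, mc, ac)
#' glance(cmp)
#' @export
compare_methods <- function(data, manual, automated, pooled = FALSE) {
  mc <- dplyr::pull(data, {{ manual }})
  ac <- dplyr::pull(data, {{ automated }})
  if (anyNA(mc) || anyNA(ac)) abort("Counts must not contain missing values.")
  ba <- bland_altman(mc, ac)
  tt <- two_sided_t_test(mc, ac, pooled = pooled)
  structure(list(
    n_images = length(mc),
    mc = mc, ac = ac,
    t_statistic = tt$t_statistic,
    p_value = tt$p_value,
    scatter_slope = scatter_slope(mc, ac),
    bland_altman = ba,
    summary_by_method = dplyr::bind_rows(
      dplyr::mutate(cv_snr(mc), method = "manual", .before = 1),
      dplyr::mutate(cv_snr(ac), method = "automated", .before = 1)
    ),
    pooled = pooled
  ), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison: %d image pairs>\n", x$n_images))
  cat(sprintf("  manual    mean %.2f (sd %.2f)\n",
              x$summary_by_method$mean[1], x$summary_by_method$sd[1]))
  cat(sprintf("  automated mean %.2f (sd %.2f)\n",
              x$summary_by_method$mean[2], x$summary_by_method$sd[2]))
  cat(sprintf("  t = %.3f, p = %.4g (%s)\n", x$t_statistic, x$p_value,
              if (x$pooled) "pooled" else "Welch"))
  cat(sprintf("  scatter slope (ac ~ mc): %.3f\n", x$scatter_slope))
  cat(sprintf("  Bland-Altman: bias %.3f [%.3f, %.3f], slope %.3f\n",
              x$bland_altman$mean_difference, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper, x$bland_altman$slope))
  invisible(x)
}

#' Tidiers for method comparisons
#'
#' `tidy()` returns one row per summary statistic; `glance()` returns a
#' one-row overview.
#'
#' @param x A `method_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy method_comparison
#' @export
tidy.method_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = c("t_statistic", "p_value", "scatter_slope",
                  "bland_altman_slope", "bland_altman_bias",
                  "loa_lower", "loa_upper",
                  "cv_manual", "cv_automated", "snr_manual", "snr_automated"),
    estimate = c(x$t_statistic, x$p_value, x$scatter_slope,
                 x$bland_altman$slope, x$bland_altman$mean_difference,
                 x$bland_altman$loa_lower, x$bland_altman$loa_upper,
                 x$summary_by_method$cv, x$summary_by_method$snr)
  )
}

#' @rdname tidy.method_comparison
#' @method glance method_comparison
#' @export
glance.method_comparison <- function(x, ...) {
  tibble::tibble(
    n_images = x$n_images,
    mean_manual = x$summary_by_method$mean[1],
    mean_automated = x$summary_by_method$mean[2],
    t_statistic = x$t_statistic,
    p_value = x$p_value,
    scatter_slope = x$scatter_slope,
    bland_altman_slope = x$bland_altman$slope,
    bland_altman_bias = x$bland_altman$mean_difference
  )
}

#' Tidiers for count results
#'
#' `tidy()` returns the per-particle measurements; `glance()` the one-row
#' count/density summary with stage thresholds.
#'
#' @param x A `count_result` from [count_fibers()] or [count_cells()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy count_result
#' @export
tidy.count_result <- function(x, ...) tibble::as_tibble(x$particles)

#' @rdname tidy.count_result
#' @method glance count_result
#' @export
glance.count_result <- function(x, ...) {
  th <- purrr::imap(x$thresholds, function(t, nm) {
    out <- tibble::tibble(t$threshold, t$method, t$degenerate)
    names(out) <- paste0("threshold_", nm, c("", "_method", "_degenerate"))
    out
  })
  base <- tibble::tibble(kind = x$kind, count = x$count,
                         density_per_mm2 = x$density_per_mm2,
                         image_area_mm2 = x$image_area_mm2)
  do.call(dplyr::bind_cols, c(list(base), unname(th)))
}
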