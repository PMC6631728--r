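#' Aggregate replicate temperature series
#'
#' Pointwise mean and sample standard deviation (n-1 denominator) over
#' replicates, on the intersection of the replicate temperature grids.
#' With a single replicate the standard deviation is reported as zero and
#' the result carries attribute `single_replicate = TRUE`.
#'
#' @param series Either a long tibble with columns `temperature`, `alpha`,
#'   `replicate`, or a list of per-replicate tibbles with columns
#'   `temperature`, `alpha`.
#' @return A tibble with columns `temperature`, `mean_alpha`, `sd_alpha`,
#'   `n`.
#' @export
#' @examples
#' tibble::tibble(temperature = rep(100, 3), alpha = c(10, 12, 14),
#'                replicate = 1:3) |> aggregate_replicates()
aggregate_replicates <- function(series) {
  if (is.data.frame(series)) {
    if (!all(c("temperature", "alpha") %in% names(series)))
      abort_class("series must have columns `temperature` and `alpha`",
                  "thztds_input_error")
    if (!"replicate" %in% names(series)) series$replicate <- 1L
    long <- series
  } else if (is.list(series)) {
    if (length(series) == 0)
      abort_class("empty replicate list", "thztds_input_error")
    long <- purrr::imap_dfr(series, function(s, i)
      dplyr::mutate(s[, c("temperature", "alpha")], replicate = as.integer(i)))
  } else {
    abort_class("series must be a data frame or a list of data frames",
                "thztds_input_error")
  }
  if (nrow(long) == 0) abort_class("empty series", "thztds_input_error")

  n_rep <- length(unique(long$replicate))
  common <- long |>
    dplyr::count(.data$temperature) |>
    dplyr::filter(.data$n == n_rep)
  if (nrow(common) == 0)
    abort_class("replicates share no common temperature grid",
                "thztds_grid_error")
  out <- long |>
    dplyr::semi_join(common, by = "temperature") |>
    dplyr::group_by(.data$temperature) |>
    dplyr::summarise(mean_alpha = mean(.data$alpha),
                     sd_alpha = if (dplyr::n() > 1) sd(.data$alpha) else 0,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$temperature)
  attr(out, "single_replicate") <- n_rep == 1
  out
}

# O(1) least-squares statistics for any contiguous run of points, from
# cumulative sums; `starts`/`ends` are equal-length index vectors
segment_ols <- function(cs, starts, ends) {
  take <- function(v) v[ends] - ifelse(starts > 1, v[starts - 1], 0)
  k <- ends - starts + 1
  sx <- take(cs$x); sy <- take(cs$y)
  sxx <- take(cs$xx); sxy <- take(cs$xy); syy <- take(cs$yy)
  xbar <- sx / k
  Sxx <- sxx - sx^2 / k
  Sxy <- sxy - sx * sy / k
  Syy <- syy - sy^2 / k
  m <- Sxy / Sxx
  b <- (sy - m * sx) / k
  sse <- pmax(Syy - m * Sxy, 0)
  list(m = m, b = b, sse = sse, k = k, xbar = xbar, Sxx = Sxx)
}

# variance/covariance of (slope, intercept) for one fitted segment
segment_cov <- function(seg) {
  s2 <- ifelse(seg$k > 2, seg$sse / (seg$k - 2), 0)
  list(var_m = s2 / seg$Sxx,
       var_b = s2 * (1 / seg$k + seg$xbar^2 / seg$Sxx),
       cov_mb = -s2 * seg$xbar / seg$Sxx)
}

#' Intersection temperature of two fitted lines
#'
#' The glass-transition temperatures are defined as the intersection points
#' of adjacent best-fit lines: `T = (b2 - b1) / (m1 - m2)`.
#'
#' @param line1,line2 Either lists with elements `slope_m` and
#'   `intercept_b` (as stored in a fit's regions) or numeric vectors
#'   `c(slope, intercept)`.
#' @param parallel_tol Slopes closer than this are treated as parallel and
#'   raise a degenerate-fit error.
#' @return The intersection temperature, K.
#' @export
#' @examples
#' intersect_lines(c(0, 5), c(1, 0))  # 5
intersect_lines <- function(line1, line2, parallel_tol = 1e-12) {
  as_mb <- function(l) {
    if (is.numeric(l) && length(l) == 2) c(m = l[[1]], b = l[[2]])
    else c(m = l$slope_m, b = l$intercept_b)
  }
  l1 <- as_mb(line1); l2 <- as_mb(line2)
  dm <- l1[["m"]] - l2[["m"]]
  if (abs(dm) < parallel_tol)
    abort_class("fitted lines are parallel within tolerance; no intersection",
                "thztds_degenerate_fit_error")
  (l2[["b"]] - l1[["b"]]) / dm
}

#' Fit three linear segments and locate the two glass transitions
#'
#' Fits the absorption-versus-temperature curve with three independent
#' ordinary-least-squares lines over an exhaustively searched partition of
#' the (ordered) temperature points, and reports
#' `Tg_beta` = intersection of the region-1 and region-2 lines and
#' `Tg_alpha` = intersection of the region-2 and region-3 lines. The
#' segments are fitted independently -- they need not join at the partition
#' edges -- and the transitions are line intersections, not partition
#' midpoints.
#'
#' Every ordered boundary pair leaving at least `min_points_per_segment`
#' points per segment is evaluated; among partitions whose intersections
#' are admissible (finite, ordered `Tg_beta < Tg_alpha`, `Tg_beta` between
#' the start of region 1 and the end of region 2, `Tg_alpha` between the
#' start of region 2 and the end of region 3), the one with the smallest
#' total sum of squared errors wins; exact ties go to the
#' lowest-temperature boundary pair. Data lying on a single straight line
#' admit no such partition (all candidate lines are parallel) and raise a
#' degenerate-fit error.
#'
#' Standard errors of the slopes come from the per-segment OLS; standard
#' errors of the transition temperatures come from first-order propagation
#' of the two lines' parameter covariances.
#'
#' @param series A temperature series: a tibble with columns `temperature`
#'   and `alpha` (optionally `replicate`), or an aggregated series with
#'   `temperature` and `mean_alpha`. When several replicates are present
#'   the replicate-mean curve is fitted (the convention used for published
#'   mean-curve figures) unless `per_replicate = TRUE`.
#' @param min_points_per_segment Minimum points per segment (default 4, so
#'   slope, intercept and a standard error are all estimable).
#' @param per_replicate Fit each replicate separately and summarise the
#'   spread of the fitted parameters across replicates.
#' @param parallel_tol Slope difference below which adjacent lines are
#'   considered parallel.
#' @return An object of class `tg_fit` (see [tidy.tg_fit()],
#'   [glance.tg_fit()], [autoplot.tg_fit()]), or of class `tg_fit_list`
#'   when `per_replicate = TRUE`.
#' @export
#' @examples
#' make_temperature_series(
#'   transition_model(0.0026, 0.0237, 0.070, 167, 318, noise_sigma = 0),
#'   n_replicates = 1) |>
#'   fit_three_segments()
fit_three_segments <- function(series, min_points_per_segment = 4,
                               per_replicate = FALSE, parallel_tol = 1e-12) {
  if ("mean_alpha" %in% names(series)) {
    x <- series$temperature; y <- series$mean_alpha
    data <- series
  } else {
    if (!all(c("temperature", "alpha") %in% names(series)))
      abort_class("series must have columns `temperature` and `alpha`",
                  "thztds_input_error")
    if (per_replicate && "replicate" %in% names(series)) {
      fits <- series |>
        dplyr::group_by(.data$replicate) |>
        dplyr::group_map(~ fit_three_segments(
          .x, min_points_per_segment = min_points_per_segment,
          parallel_tol = parallel_tol))
      return(structure(list(fits = fits), class = "tg_fit_list"))
    }
    agg <- aggregate_replicates(series)
    x <- agg$temperature; y <- agg$mean_alpha
    data <- agg
  }
  minp <- as.integer(min_points_per_segment)
  if (minp < 2) abort_config("min_points_per_segment", "must be >= 2")
  n <- length(x)
  if (anyDuplicated(x) || is.unsorted(x))
    abort_class("temperatures must be unique and increasing",
                "thztds_input_error")
  if (n < 3 * minp)
    abort_class(sprintf(
      "need at least %d points for three segments of >= %d points, got %d",
      3 * minp, minp, n), "thztds_size_error")

  cs <- list(x = cumsum(x), y = cumsum(y), xx = cumsum(x^2),
             xy = cumsum(x * y), yy = cumsum(y^2))
  # enumerate boundary pairs (i, j): segments 1..i, (i+1)..j, (j+1)..n,
  # in (i asc, j asc) order so ties resolve to the earliest pair
  i_seq <- minp:(n - 2 * minp)
  ii <- rep(i_seq, times = (n - minp) - (i_seq + minp) + 1)
  jj <- unlist(lapply(i_seq, function(i) (i + minp):(n - minp)))
  s1 <- segment_ols(cs, rep(1L, length(ii)), ii)
  s2 <- segment_ols(cs, ii + 1L, jj)
  s3 <- segment_ols(cs, jj + 1L, rep(n, length(ii)))

  dm12 <- s1$m - s2$m
  dm23 <- s2$m - s3$m
  tb <- (s2$b - s1$b) / dm12
  ta <- (s3$b - s2$b) / dm23
  admissible <- is.finite(tb) & is.finite(ta) &
    abs(dm12) >= parallel_tol & abs(dm23) >= parallel_tol &
    tb < ta &
    tb >= x[1] & tb <= x[jj] &
    ta >= x[ii + 1] & ta <= x[n]
  if (!any(admissible))
    abort_class(paste("no admissible three-segment partition: adjacent",
                      "fitted lines are parallel or never intersect inside",
                      "the data range (data may lie on a single line)"),
                "thztds_degenerate_fit_error")
  tot <- s1$sse + s2$sse + s3$sse
  tot[!admissible] <- Inf
  best <- which.min(tot)
  i <- ii[best]; j <- jj[best]

  region <- function(s, lo, hi) {
    cv <- segment_cov(lapply(s, `[`, best))
    list(slope_m = s$m[best], intercept_b = s$b[best],
         slope_se = sqrt(cv$var_m), intercept_se = sqrt(cv$var_b),
         cov_mb = cv$cov_mb, n_points = s$k[best], sse = s$sse[best],
         t_range = c(x[lo], x[hi]))
  }
  r1 <- region(s1, 1, i)
  r2 <- region(s2, i + 1, j)
  r3 <- region(s3, j + 1, n)

  tg_se <- function(ra, rb, tg) {
    dm <- ra$slope_m - rb$slope_m
    v <- (tg^2 * (ra$slope_se^2 + rb$slope_se^2) +
            ra$intercept_se^2 + rb$intercept_se^2 +
            2 * tg * (ra$cov_mb + rb$cov_mb)) / dm^2
    sqrt(max(v, 0))
  }
  tg_beta <- tb[best]
  tg_alpha <- ta[best]

  structure(list(
    region1 = r1, region2 = r2, region3 = r3,
    tg_beta = tg_beta, tg_alpha = tg_alpha,
    tg_beta_se = tg_se(r1, r2, tg_beta),
    tg_alpha_se = tg_se(r2, r3, tg_alpha),
    total_sse = tot[best],
    boundary_indices = c(i, j),
    n_points = n,
    data = data
  ), class = "tg_fit")
}

#' @export
print.tg_fit <- function(x, ...) {
  cat("Three-segment linear fit of alpha(1 THz) vs temperature\n")
  cat(sprintf("  %d points, boundaries after points %d and %d, total SSE %.4g\n",
              x$n_points, x$boundary_indices[1], x$boundary_indices[2],
              x$total_sse))
  for (r in 1:3) {
    reg <- x[[paste0("region", r)]]
    cat(sprintf("  region %d: m = %.4g +/- %.2g cm^-1 K^-1 (n = %d)\n",
                r, reg$slope_m, reg$slope_se, reg$n_points))
  }
  cat(sprintf("  Tg_beta  = %.1f +/- %.1f K\n", x$tg_beta, x$tg_beta_se))
  cat(sprintf("  Tg_alpha = %.1f +/- %.1f K\n", x$tg_alpha, x$tg_alpha_se))
  invisible(x)
}

#' Tidy a three-segment fit
#'
#' One row per fitted region with slope, intercept, their standard errors,
#' the number of points and the segment sum of squared errors.
#'
#' @param x A `tg_fit`.
#' @param ... Unused.
#' @return A tibble with one row per region.
#' @export
tidy.tg_fit <- function(x, ...) {
  purrr::map_dfr(1:3, function(r) {
    reg <- x[[paste0("region", r)]]
    tibble(region = r, slope_m = reg$slope_m, slope_se = reg$slope_se,
           intercept_b = reg$intercept_b, intercept_se = reg$intercept_se,
           n_points = reg$n_points, sse = reg$sse,
           t_min = reg$t_range[1], t_max = reg$t_range[2])
  })
}

#' Glance at a three-segment fit
#'
#' @param x A `tg_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the two transition temperatures, their
#'   standard errors, the total SSE and the number of points.
#' @export
glance.tg_fit <- function(x, ...) {
  tibble(tg_beta = x$tg_beta, tg_beta_se = x$tg_beta_se,
         tg_alpha = x$tg_alpha, tg_alpha_se = x$tg_alpha_se,
         total_sse = x$total_sse, n_points = x$n_points)
}

#' @export
tidy.tg_fit_list <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, i)
    dplyr::mutate(glance(f), replicate = as.integer(i), .before = 1))
}

#' Plot a three-segment fit
#'
#' Shows the (mean) data points, the three fitted lines drawn out to their
#' intersections, and dashed verticals at `Tg_beta` and `Tg_alpha`.
#'
#' @param object A `tg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tg_fit <- function(object, ...) {
  dat <- object$data
  ycol <- if ("mean_alpha" %in% names(dat)) "mean_alpha" else "alpha"
  segs <- tidy(object)
  ends <- c(object$tg_beta, object$tg_alpha)
  segs$x_from <- c(segs$t_min[1], ends[1], ends[2])
  segs$x_to <- c(ends[1], ends[2], segs$t_max[3])
  segs$y_from <- segs$slope_m * segs$x_from + segs$intercept_b
  segs$y_to <- segs$slope_m * segs$x_to + segs$intercept_b
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$temperature,
                                         y = .data[[ycol]])) +
    ggplot2::geom_point()
  if ("sd_alpha" %in% names(dat) && any(dat$sd_alpha > 0))
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data[[ycol]] - .data$sd_alpha,
      ymax = .data[[ycol]] + .data$sd_alpha), width = 2)
  p +
    ggplot2::geom_segment(data = segs, ggplot2::aes(
      x = .data$x_from, xend = .data$x_to,
      y = .data$y_from, yend = .data$y_to,
      colour = factor(.data$region)), inherit.aes = FALSE) +
    ggplot2::geom_vline(xintercept = c(object$tg_beta, object$tg_alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Temperature (K)",
                  y = expression(alpha * " at 1 THz (" * cm^-1 * ")"),
                  colour = "Region") +
    ggplot2::theme_minimal()
}

#' Assemble a per-sample transition report
#'
#' One row per sample with the three region slopes (each with its standard
#' error), the two terahertz-derived transition temperatures, and an
#' optional externally measured calorimetric glass transition `Tg_DSC`
#' (supplied, never computed here).
#'
#' @param results Named list of `tg_fit` objects, one per sample.
#' @param dsc_values Optional named numeric vector / list of `Tg_DSC`
#'   values (K), matched to `results` by name.
#' @return A tibble with columns `sample`, `m1`, `m1_se`, `m2`, `m2_se`,
#'   `m3`, `m3_se`, `tg_beta_K`, `tg_beta_se_K`, `tg_alpha_K`,
#'   `tg_alpha_se_K`, `tg_dsc_K`.
#' @export
build_report <- function(results, dsc_values = NULL) {
  cols <- c("sample", "m1", "m1_se", "m2", "m2_se", "m3", "m3_se",
            "tg_beta_K", "tg_beta_se_K", "tg_alpha_K", "tg_alpha_se_K",
            "tg_dsc_K")
  if (length(results) == 0) {
    out <- tibble(sample = character(), m1 = double(), m1_se = double(),
                  m2 = double(), m2_se = double(), m3 = double(),
                  m3_se = double(), tg_beta_K = double(),
                  tg_beta_se_K = double(), tg_alpha_K = double(),
                  tg_alpha_se_K = double(), tg_dsc_K = double())
    return(out[, cols])
  }
  labels <- names(results) %||% as.character(seq_along(results))
  purrr::map2_dfr(results, labels, function(fit, lab) {
    tibble(sample = lab,
           m1 = fit$region1$slope_m, m1_se = fit$region1$slope_se,
           m2 = fit$region2$slope_m, m2_se = fit$region2$slope_se,
           m3 = fit$region3$slope_m, m3_se = fit$region3$slope_se,
           tg_beta_K = fit$tg_beta, tg_beta_se_K = fit$tg_beta_se,
           tg_alpha_K = fit$tg_alpha, tg_alpha_se_K = fit$tg_alpha_se,
           tg_dsc_K = if (!is.null(dsc_values) && lab %in% names(dsc_values))
             as.numeric(dsc_values[[lab]]) else NA_real_)
  })
}
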