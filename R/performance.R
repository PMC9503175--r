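# Generator performance analysis: time trend of the mean droplet
# diameter, a droplet-count frequency proxy, and threshold-sweep
# diagnostics for picking the binarization threshold.

summaries_to_df <- function(series) {
  if (is.data.frame(series)) return(series)
  do.call(rbind, lapply(series, function(s) {
    data.frame(frame_id = s$frame_id, t_s = s$timestamp,
               n_droplets = s$droplet_count,
               mean_diameter_px = s$mean_diameter_px,
               mean_diameter_mm = s$mean_diameter_mm)
  }))
}

#' Fit a polynomial time trend to per-frame mean diameters
#'
#' Ordinary least-squares fit of the per-frame mean diameter (mm) against
#' the capture time (s). The default degree is 2: the observed
#' mean-diameter decay over a run is well described by a second-order
#' polynomial `d(t) = a0 + a1 t + a2 t^2`.
#'
#' @param series List of `frame_summary` objects, or a data frame with
#'   columns `t_s` and `mean_diameter_mm`.
#' @param degree Polynomial degree (default 2).
#' @return A `trend_fit` object: coefficients `a0..a<degree>`, residual
#'   `rmse` (mm), `r_squared`, `n_points`, and the underlying `lm` fit.
#' @seealso [predict.trend_fit()], [coef.trend_fit()]
#' @export
fit_diameter_trend <- function(series, degree = 2) {
  df <- summaries_to_df(series)
  if (!is.null(df$mean_true_diameter_mm) && is.null(df$mean_diameter_mm)) {
    df$mean_diameter_mm <- df$mean_true_diameter_mm
  }
  df <- df[is.finite(df$mean_diameter_mm), , drop = FALSE]
  if (nrow(df) < degree + 1) {
    stop(sprintf("need at least %d frames with defined means for degree %d",
                 degree + 1, degree))
  }
  fit <- stats::lm(mean_diameter_mm ~ stats::poly(t_s, degree, raw = TRUE),
                   data = df)
  cf <- unname(stats::coef(fit))
  names(cf) <- paste0("a", seq_along(cf) - 1)
  res <- stats::residuals(fit)
  tss <- sum((df$mean_diameter_mm - mean(df$mean_diameter_mm))^2)
  structure(
    list(coefficients = cf,
         rmse = sqrt(mean(res^2)),
         r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
         n_points = nrow(df),
         degree = degree,
         lm = fit),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  terms <- c("", " t", paste0(" t^", seq_len(max(0, x$degree - 1)) + 1))
  poly_str <- paste(sprintf("%+.6g%s", x$coefficients,
                            terms[seq_along(x$coefficients)]),
                    collapse = " ")
  cat(sprintf("<trend_fit> d(t) = %s (mm), n = %d, RMSE %.4g mm\n",
              poly_str, x$n_points, x$rmse))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) object$coefficients

#' Predicted mean diameter at given times
#'
#' @param object A `trend_fit`.
#' @param t Times in seconds.
#' @param ... Unused.
#' @return Predicted mean diameters in mm.
#' @export
predict.trend_fit <- function(object, t, ...) {
  cf <- object$coefficients
  drop(outer(t, seq_along(cf) - 1, `^`) %*% cf)
}

#' @export
summary.trend_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  RMSE %.4g mm, R^2 %.4f, n = %d\n",
              object$rmse, object$r_squared, object$n_points))
  invisible(object)
}

#' Droplet-count series and its trend sign
#'
#' Returns the per-frame droplet counts and the sign of the least-squares
#' slope of count against time. This is only a proxy for the droplet
#' generation frequency: still images carry no flow velocity, so no rate
#' in Hz can be derived, but a falling count in a channel segment tracks
#' a falling generation frequency.
#'
#' @param series List of `frame_summary` objects or a data frame with
#'   `t_s` and `n_droplets` (or `droplet_count`).
#' @return List with `counts` (data frame `t_s`, `n_droplets`), `slope`
#'   (droplets/s) and `trend_sign` (-1, 0, 1).
#' @export
frequency_proxy <- function(series) {
  df <- summaries_to_df(series)
  if (is.null(df$n_droplets)) df$n_droplets <- df$droplet_count
  if (nrow(df) < 2) stop("need at least 2 frames")
  slope <- unname(stats::coef(stats::lm(n_droplets ~ t_s, data = df))[2])
  list(counts = df[, c("t_s", "n_droplets")],
       slope = slope,
       trend_sign = sign(round(slope, 12)))
}

#' Threshold sweep over a band image
#'
#' Runs binarize, opening and size filtering at each threshold of a grid
#' and records the droplet count and total foreground area. The count is
#' stable over the interval of thresholds lying between the droplet and
#' background intensity bands; the sweep locates that plateau (the
#' maximal contiguous run of thresholds whose count equals the modal
#' nonzero count) and recommends its midpoint as the operating threshold.
#'
#' @param band_image Numeric matrix in \[0, 1\] (normally the red band of
#'   an ROI-cropped frame).
#' @param thresholds Increasing grid in \[0, 1\] (default 0.1..0.9 in
#'   steps of 0.1, finer grids sharpen the recommendation).
#' @param polarity,se,min_area Pipeline settings (see [binarize()],
#'   [opening()], [remove_small_objects()]).
#' @return A `sweep_result`: data frame `sweep` (`thr`, `n_droplets`,
#'   `foreground_px`), `plateau` (threshold range or NULL), and
#'   `recommended_thr` (plateau midpoint or NA).
#' @export
threshold_sweep <- function(band_image, thresholds = seq(0.1, 0.9, by = 0.1),
                            polarity = "foreground_lt",
                            se = struct_elem(3), min_area = 25) {
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must lie in [0, 1]")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  res <- lapply(thresholds, function(thr) {
    mask <- remove_small_objects(
      opening(binarize(band_image, thr, polarity), se), min_area)
    lab <- label_components(mask)
    c(n = max(lab), area = sum(mask))
  })
  res <- do.call(rbind, res)
  sweep <- data.frame(thr = thresholds, n_droplets = as.integer(res[, "n"]),
                      foreground_px = as.integer(res[, "area"]))
  nz <- sweep$n_droplets[sweep$n_droplets > 0]
  plateau <- NULL
  rec <- NA_real_
  if (length(nz) > 0) {
    modal <- as.integer(names(which.max(table(nz))))
    runs <- rle(sweep$n_droplets == modal)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    i0 <- starts[best]
    i1 <- ends[best]
    plateau <- c(sweep$thr[i0], sweep$thr[i1])
    rec <- mean(plateau)
  }
  structure(list(sweep = sweep, plateau = plateau, recommended_thr = rec,
                 modal_count = if (length(nz) > 0) modal else NA_integer_),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d thresholds", nrow(x$sweep)))
  if (!is.null(x$plateau)) {
    cat(sprintf("; plateau [%g, %g] at count %d; recommended thr %g",
                x$plateau[1], x$plateau[2], x$modal_count, x$recommended_thr))
  } else {
    cat("; no plateau (no droplets at any threshold)")
  }
  cat("\n")
  invisible(x)
}
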