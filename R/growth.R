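#' Detect the exponential-growth window of an OD series
#'
#' Finds the longest contiguous window (>= `min_points` points) whose
#' regression of log2(OD600) on time has R^2 >= `r2_min`; ties are broken by
#' the earliest start. Points after the onset of a plateau therefore fall out
#' of the window.
#'
#' @param series A [growth_series()].
#' @param min_points Minimum points in the window (default 4).
#' @param r2_min Minimum R^2 (default 0.99).
#' @return List with `start_idx`, `end_idx`, `t_start`, `t_end`, `r_squared`.
#' @export
detect_exponential_window <- function(series, min_points = 4L, r2_min = 0.99) {
  t <- series$time; y <- log2(series$od600)
  n <- length(t)
  if (n < min_points) stop("series shorter than min_points")
  # prefix sums make the R^2/slope of any window O(1)
  ct <- c(0, cumsum(t)); cy <- c(0, cumsum(y))
  ctt <- c(0, cumsum(t * t)); cyy <- c(0, cumsum(y * y))
  cty <- c(0, cumsum(t * y))
  win_stats <- function(s, e) {
    m <- e - s + 1L
    st <- ct[e + 1L] - ct[s]; sy <- cy[e + 1L] - cy[s]
    stt <- ctt[e + 1L] - ctt[s]; syy <- cyy[e + 1L] - cyy[s]
    sty <- cty[e + 1L] - cty[s]
    sxx <- stt - st^2 / m; sYY <- syy - sy^2 / m; sxy <- sty - st * sy / m
    slope <- sxy / sxx
    r2 <- if (sYY <= 0) 1 else (sxy^2) / (sxx * sYY)
    c(slope = slope, r2 = r2)
  }
  best <- NULL
  for (len in n:min_points) {
    for (s in seq_len(n - len + 1L)) {
      e <- s + len - 1L
      w <- win_stats(s, e)
      if (w[["r2"]] >= r2_min && w[["slope"]] > 0) {
        best <- list(start_idx = s, end_idx = e,
                     t_start = t[s], t_end = t[e], r_squared = w[["r2"]])
        break
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    stop("no exponential window found with R^2 >= ", r2_min,
         "; consider lowering r2_min")
  }
  best
}

#' Fit the doubling time of an OD series
#'
#' Least-squares regression of log2(OD600) on time inside the exponential
#' window (auto-detected unless supplied). The slope is directly in
#' doublings per hour, so doubling_time = 1/slope and the specific growth
#' rate is `ln(2) * slope` per hour; the doubling-time standard error is
#' propagated from the slope standard error.
#'
#' @param series A [growth_series()].
#' @param window Optional window from [detect_exponential_window()].
#' @param min_points Minimum points (default 4).
#' @return A `growth_fit` list: `doubling_time_h`, `growth_rate_per_h`,
#'   `window` (t_start, t_end), `r_squared`, `stderr` (on the doubling time).
#' @export
fit_doubling_time <- function(series, window = NULL, min_points = 4L) {
  if (is.null(window)) window <- detect_exponential_window(series, min_points)
  idx <- window$start_idx:window$end_idx
  if (length(idx) < min_points) stop("window has fewer than ", min_points,
                                     " points")
  t <- series$time[idx]; y <- log2(series$od600[idx])
  fit <- lm(y ~ t)
  slope <- coef(fit)[[2L]]
  if (slope <= 0) stop("no growth detected (non-positive slope)")
  sm <- suppressWarnings(summary(fit))  # perfect fits warn benignly
  se_slope <- sm$coefficients[2L, 2L]
  r2 <- if (var(y) == 0) 1 else sm$r.squared
  structure(list(
    doubling_time_h = 1 / slope,
    growth_rate_per_h = log(2) * slope,
    window = c(t_start = window$t_start %||% t[1L],
               t_end = window$t_end %||% t[length(t)]),
    r_squared = r2,
    stderr = se_slope / slope^2),  # delta method on 1/slope
    class = "growth_fit")
}

#' Nitrate-to-nitrite conversion stoichiometry
#'
#' Regresses accumulated nitrite (`nitrite_t - nitrite_0`) on consumed
#' nitrate (`nitrate_0 - nitrate_t`) across all time points with positive
#' consumption. A slope of 1 indicates strict 1:1 conversion (nitrate
#' respired to nitrite with no further reduction).
#'
#' @param chem A [chem_series()].
#' @return A `stoich_result` list: `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
stoichiometry_fit <- function(chem) {
  consumed <- chem$nitrate_mM[1L] - chem$nitrate_mM
  produced <- chem$nitrite_mM - chem$nitrite_mM[1L]
  keep <- consumed > 0
  if (!any(keep)) stop("no nitrate consumption in series")
  x <- consumed[keep]; y <- produced[keep]
  fit <- lm(y ~ x)
  r2 <- if (var(y) == 0) {
    # degenerate: constant nitrite — slope is 0 and R^2 undefined
    NA_real_
  } else suppressWarnings(summary(fit))$r.squared
  structure(list(slope = coef(fit)[[2L]], intercept = coef(fit)[[1L]],
                 r_squared = r2, n_points = sum(keep)),
            class = "stoich_result")
}

#' Yield ratio between a treated and a control growth series
#'
#' `max(OD treated) / max(OD control)` — e.g. the half-yield observed when
#' 6 mM nitrite is added to a nitrate-respiring culture.
#'
#' @param treated,control [growth_series()] objects.
#' @return A single numeric ratio.
#' @export
yield_ratio <- function(treated, control) {
  max(treated$od600) / max(control$od600)
}
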