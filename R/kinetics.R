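#' Cumulative-labeling timecourse
#'
#' Observations from a cumulative S-phase labeling (EdU/BrdU) experiment:
#' per (exposure time, replicate) either labeled and total cell counts or a
#' labeling index directly. The labeling index (LI) is the percent of cells
#' positive for the label.
#'
#' @param data data frame with columns `time_h` (hours, >= 0), `replicate`,
#'   and either `labeled` + `total` counts or `li_percent` in [0, 100].
#' @return an object of class `"labeling_timecourse"` (a data frame with a
#'   guaranteed `li_percent` column).
#' @export
labeling_timecourse <- function(data) {
  df <- as.data.frame(data)
  need <- c("time_h", "replicate")
  if (!all(need %in% names(df)))
    stop("columns 'time_h' and 'replicate' are required")
  if (!"li_percent" %in% names(df)) {
    if (!all(c("labeled", "total") %in% names(df)))
      stop("need either 'li_percent' or 'labeled' + 'total' columns")
    if (any(df$total <= 0) || any(df$labeled < 0) ||
        any(df$labeled > df$total))
      stop("'labeled' must lie in [0, total] with positive totals")
    df$li_percent <- 100 * df$labeled / df$total
  }
  if (any(df$time_h < 0)) stop("times must be nonnegative")
  if (anyNA(df$li_percent) || any(df$li_percent < 0 | df$li_percent > 100))
    stop("labeling index must lie in [0, 100]")
  df <- df[order(df$time_h, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("labeling_timecourse", "data.frame")
  df
}

#' Fit rise and plateau lines to a cumulative-labeling timecourse
#'
#' Models the labeling index as an initial straight-line increase followed
#' by a horizontal plateau at the growth fraction, fitted as two independent
#' least-squares lines. Candidate breakpoints are the midpoints between
#' consecutive distinct observation times; for each candidate the rise line
#' is ordinary least squares on the points at or before it and the plateau
#' is the mean of the points after it. The split minimizing the pooled sum
#' of squared residuals wins, ties going to the smallest breakpoint.
#' Continuity is not enforced: the reported changepoint `t_star` is the
#' analytic intersection `(GF - b) / m` of the two lines, which need not
#' coincide with the search breakpoint.
#'
#' Replicates enter as individual points by default, preserving degrees of
#' freedom; set `average_replicates = TRUE` to fit per-time means.
#'
#' @param tc a [labeling_timecourse()] (or data frame accepted by it) with
#'   at least 4 distinct times.
#' @param min_rise_points minimum points in the rise segment (default 3, so
#'   the slope retains a residual degree of freedom).
#' @param min_plateau_points minimum points in the plateau segment
#'   (default 2).
#' @param average_replicates fit per-time replicate means instead of
#'   individual points.
#' @return an object of class `"two_segment_fit"`: list with `m` (slope,
#'   percent/h), `b` (intercept = Li0, percent), `GF` (plateau, percent),
#'   `t_star` (hours), `breakpoint` (the SSE-optimal split time), `sse`,
#'   `r2_rise`, and the data used.
#' @seealso [derive_kinetics()] for (GF, Tc, Ts).
#' @export
fit_two_segment <- function(tc, min_rise_points = 3, min_plateau_points = 2,
                            average_replicates = FALSE) {
  if (!inherits(tc, "labeling_timecourse")) tc <- labeling_timecourse(tc)
  if (min_rise_points < 2) stop("'min_rise_points' must be at least 2")
  if (min_plateau_points < 2) stop("'min_plateau_points' must be at least 2")
  t <- tc$time_h
  y <- tc$li_percent
  if (average_replicates) {
    y <- as.numeric(tapply(y, t, mean))
    t <- sort(unique(t))
  }
  times <- sort(unique(t))
  if (length(times) < 4)
    stop("at least 4 distinct times are required for a two-segment fit")
  candidates <- (times[-length(times)] + times[-1]) / 2
  best <- NULL
  for (bp in candidates) {
    rise <- t <= bp
    if (sum(rise) < min_rise_points || sum(!rise) < min_plateau_points)
      next
    cf <- ols_line(t[rise], y[rise])
    plateau <- mean(y[!rise])
    sse <- sum((y[rise] - cf[1] - cf[2] * t[rise])^2) +
      sum((y[!rise] - plateau)^2)
    if (is.null(best) || sse < best$sse - 1e-12)  # ties keep smallest bp
      best <- list(bp = bp, b = cf[1], m = cf[2], GF = plateau, sse = sse,
                   rise = rise)
  }
  if (is.null(best))
    stop("too few points in every admissible rise/plateau split")
  if (best$m <= 0)
    stop("no increase: the optimal rise line has nonpositive slope; ",
         "cell-cycle kinetics are not derivable from this timecourse")
  ss_tot <- sum((y[best$rise] - mean(y[best$rise]))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y[best$rise] - best$b -
                                   best$m * t[best$rise])^2) / ss_tot else 1
  structure(list(m = best$m, b = best$b, GF = best$GF,
                 t_star = (best$GF - best$b) / best$m,
                 breakpoint = best$bp, sse = best$sse, r2_rise = r2,
                 n_rise = sum(best$rise), n_plateau = sum(!best$rise),
                 data = data.frame(time_h = t, li_percent = y,
                                   segment = ifelse(best$rise, "rise",
                                                    "plateau"))),
            class = "two_segment_fit")
}

# simple least-squares line, returns c(intercept, slope)
ols_line <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  m <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(yb - m * xb, m)
}

#' @export
print.two_segment_fit <- function(x, ...) {
  cat("Two-segment cumulative-labeling fit\n")
  cat(sprintf("  rise:    LI = %.4g + %.4g t  (R^2 = %.3f, n = %d)\n",
              x$b, x$m, x$r2_rise, x$n_rise))
  cat(sprintf("  plateau: LI = %.4g (growth fraction, n = %d)\n",
              x$GF, x$n_plateau))
  cat(sprintf("  intersection t* = %.4g h;  pooled SSE = %.4g\n",
              x$t_star, x$sse))
  invisible(x)
}

#' @export
coef.two_segment_fit <- function(object, ...) {
  c(intercept = object$b, slope = object$m, plateau = object$GF,
    t_star = object$t_star)
}

#' @export
fitted.two_segment_fit <- function(object, ...) {
  with(object$data,
       ifelse(segment == "rise", object$b + object$m * time_h, object$GF))
}

#' @export
residuals.two_segment_fit <- function(object, ...) {
  object$data$li_percent - fitted(object)
}

#' Predicted labeling index from a two-segment fit
#'
#' Evaluates the rise line before the intersection time and the plateau
#' after it.
#'
#' @param object a `"two_segment_fit"`.
#' @param newdata hours; defaults to the observed times.
#' @param ... unused.
#' @export
predict.two_segment_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_h else newdata
  pmin(object$b + object$m * t, object$GF)
}

#' @export
plot.two_segment_fit <- function(x, ...) {
  graphics::plot(x$data$time_h, x$data$li_percent, pch = 16,
                 xlab = "EdU exposure (h)", ylab = "labeling index (%)", ...)
  tt <- seq(0, max(x$data$time_h), length.out = 200)
  graphics::lines(tt, pmin(x$b + x$m * tt, x$GF), lwd = 2)
  graphics::abline(v = x$t_star, lty = 2, col = "grey50")
  invisible(x)
}

#' Cell-cycle kinetics parameters
#'
#' Container for the growth fraction and cycle/S-phase lengths, with the
#' defining identities enforced: `Li0 = GF * Ts / Tc` and the rise/plateau
#' intersection at `Tc - Ts`.
#'
#' @param GF growth fraction, percent in (0, 100].
#' @param Tc cell-cycle length, hours (> 0).
#' @param Ts S-phase length, hours (0 <= Ts <= Tc).
#' @return an object of class `"cycle_kinetics"` with fields `GF`, `Tc`,
#'   `Ts`, `Li0`.
#' @export
cycle_kinetics <- function(GF, Tc, Ts) {
  if (GF <= 0 || GF > 100) stop("'GF' must be in (0, 100]")
  if (Tc <= 0) stop("'Tc' must be positive")
  if (Ts < 0 || Ts > Tc + 1e-12) stop("'Ts' must satisfy 0 <= Ts <= Tc")
  structure(list(GF = GF, Tc = Tc, Ts = min(Ts, Tc), Li0 = GF * Ts / Tc),
            class = "cycle_kinetics")
}

#' @export
print.cycle_kinetics <- function(x, ...) {
  cat("Cell-cycle kinetics from cumulative labeling\n")
  cat(sprintf("  growth fraction GF = %.4g %%\n", x$GF))
  cat(sprintf("  cell-cycle length Tc = %.4g h\n", x$Tc))
  cat(sprintf("  S-phase length Ts = %.4g h\n", x$Ts))
  cat(sprintf("  initial labeling index Li0 = %.4g %%  (= GF Ts / Tc)\n",
              x$Li0))
  invisible(x)
}

#' @export
coef.cycle_kinetics <- function(object, ...) {
  c(GF = object$GF, Tc = object$Tc, Ts = object$Ts, Li0 = object$Li0)
}

#' Derive cell-cycle parameters from a two-segment fit
#'
#' Inverts the rise-and-plateau model: with rise line `LI = b + m t` and
#' plateau `GF`, the cell-cycle length is `Tc = GF / m`, the S-phase length
#' `Ts = b / m`, and the initial labeling index `Li0 = b = GF * Ts / Tc`.
#' The lines intersect at `t* = Tc - Ts`.
#'
#' @param fit a `"two_segment_fit"`, or a list/vector with elements `m`,
#'   `b`, `GF` (see also [kinetics_from_lines()] for the slope/intercept/
#'   plateau-time parameterization).
#' @return a [cycle_kinetics()] object.
#' @examples
#' derive_kinetics(list(m = 0.6133, b = 7.996, GF = 16.257))
#' @export
derive_kinetics <- function(fit) {
  m <- fit$m; b <- fit$b; GF <- fit$GF
  if (is.null(m) || is.null(b) || is.null(GF))
    stop("'fit' must provide slope m, intercept b and plateau GF")
  if (m <= 0) stop("nonpositive slope: kinetics not derivable")
  if (GF <= 0) stop("nonpositive plateau: kinetics not derivable")
  if (b < 0) stop("negative intercept: kinetics not derivable")
  if (b > GF + 1e-9)
    stop("intercept above plateau: inconsistent fit (Li0 > GF)")
  cycle_kinetics(GF = GF, Tc = GF / m, Ts = min(b, GF) / m)
}

#' Kinetics from printed regression-line coefficients
#'
#' Convenience parameterization for published fits reported as a rise-line
#' slope and intercept plus the time at which the plateau is reached: the
#' plateau level is the rise line evaluated there,
#' `GF = intercept + slope * plateau_time`.
#'
#' @param slope rise-line slope, percent per hour (> 0).
#' @param intercept rise-line intercept Li0, percent (>= 0).
#' @param plateau_time hours at which the rise meets the plateau (Tc - Ts).
#' @return a [cycle_kinetics()] object.
#' @examples
#' kinetics_from_lines(0.6133, 7.996, 13.47)  # WT hippocampal NSPCs
#' @export
kinetics_from_lines <- function(slope, intercept, plateau_time) {
  if (plateau_time < 0) stop("'plateau_time' must be nonnegative")
  derive_kinetics(list(m = slope, b = intercept,
                       GF = intercept + slope * plateau_time))
}

#' Theoretical cumulative-labeling curve
#'
#' `LI(t) = GF * (Ts + t) / Tc` for `t <= Tc - Ts`, then the plateau `GF`.
#'
#' @param k a [cycle_kinetics()] object.
#' @param times hours (nonnegative).
#' @return labeling-index values, percent.
#' @export
forward_model <- function(k, times) {
  stopifnot(inherits(k, "cycle_kinetics"))
  if (any(times < 0)) stop("times must be nonnegative")
  pmin(k$GF * (k$Ts + times) / k$Tc, k$GF)
}

#' Bootstrap uncertainty for cell-cycle kinetics
#'
#' Nonparametric bootstrap over observations: resamples the timecourse rows
#' with replacement (stratified by timepoint), refits the two-segment model
#' and re-derives (GF, Tc, Ts, Li0). Resamples where the fit fails (e.g.
#' nonpositive slope) are dropped.
#'
#' @param tc a [labeling_timecourse()].
#' @param n_boot number of resamples (default 1000).
#' @param seed integer RNG seed.
#' @param level confidence level for the percentile intervals.
#' @param ... passed to [fit_two_segment()].
#' @return list with `estimates` (matrix of bootstrap draws), `ci`
#'   (percentile intervals) and `n_failed`.
#' @export
bootstrap_kinetics <- function(tc, n_boot = 1000, seed = 1L, level = 0.95,
                               ...) {
  if (!inherits(tc, "labeling_timecourse")) tc <- labeling_timecourse(tc)
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, n_boot, 4,
                  dimnames = list(NULL, c("GF", "Tc", "Ts", "Li0")))
  idx_by_time <- split(seq_len(nrow(tc)), tc$time_h)
  for (i in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by_time, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]))
    k <- tryCatch(derive_kinetics(fit_two_segment(tc[idx, , drop = FALSE],
                                                  ...)),
                  error = function(e) NULL)
    if (!is.null(k)) draws[i, ] <- coef(k)
  }
  ok <- stats::complete.cases(draws)
  alpha <- (1 - level) / 2
  list(estimates = draws[ok, , drop = FALSE],
       ci = apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                  probs = c(alpha, 1 - alpha)),
       n_failed = sum(!ok))
}
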