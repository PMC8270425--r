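#' Relative expression of a gene across cells
#'
#' Scales a gene between 0 and 1 as `log2(CPM + 1)` divided by its maximum
#' over cells, the normalization used before trend fitting along the
#' trajectory. A gene with all-zero CPM returns the all-zero vector (the
#' 0/0 convention).
#'
#' @param profile an [expression_profile()].
#' @param gene gene identifier present in the profile.
#' @return named numeric vector in [0, 1], one value per cell.
#' @examples
#' m <- matrix(c(0, 1, 3), 3, 1, dimnames = list(paste0("c", 1:3), "g"))
#' relative_expression(expression_profile(m), "g")  # 0, 0.5, 1
#' @export
relative_expression <- function(profile, gene) {
  x <- log2(gene_cpm(profile, gene) + 1)
  mx <- max(x)
  if (mx == 0) return(x)  # all-zero gene stays all-zero
  x / mx
}

#' Fit a local-regression expression trend along pseudotime
#'
#' Smooths the relative expression of one gene against pseudotime with local
#' polynomial (loess, degree 2, tricube weights) regression and evaluates
#' fit and 95% pointwise confidence bounds (normal approximation,
#' +/- 1.96 standard errors) on an evenly spaced pseudotime grid spanning
#' the observed range. The fitted object retains the per-cell pseudotime so
#' that a stage cutoff derived from the curve can label the cells.
#'
#' @param profile an [expression_profile()] with pseudotime.
#' @param gene gene identifier.
#' @param span loess smoothing fraction in (0, 1]; default 0.75.
#' @param n_grid number of grid points (>= 20; default 200).
#' @return an object of class `"trend_fit"` with elements `gene_id`, `grid`,
#'   `fitted`, `ci_low`, `ci_high`, `span`, `pseudotime` (per cell),
#'   `relative` (per-cell response) and the underlying `loess` fit.
#' @seealso [stage_cutoff()], [predict.trend_fit()]
#' @export
fit_trend <- function(profile, gene, span = 0.75, n_grid = 200) {
  pt <- profile_pseudotime(profile)
  if (length(pt) < 10) stop("trend fitting requires at least 10 cells")
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  if (n_grid < 20) stop("'n_grid' must be at least 20")
  if (diff(range(pt)) == 0)
    stop("degenerate pseudotime: all cells have the same value")
  y <- relative_expression(profile, gene)
  fit <- stats::loess(y ~ pt, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(pt), max(pt), length.out = as.integer(n_grid))
  pr <- stats::predict(fit, newdata = data.frame(pt = grid), se = TRUE)
  trend_fit(gene_id = gene, grid = grid, fitted = as.numeric(pr$fit),
            ci_low = as.numeric(pr$fit - 1.96 * pr$se.fit),
            ci_high = as.numeric(pr$fit + 1.96 * pr$se.fit),
            span = span, pseudotime = pt, relative = y, loess = fit)
}

#' Construct a trend-fit object from curve values
#'
#' Usually produced by [fit_trend()]; the constructor is exported so that an
#' analytic curve evaluated on a grid can be run through downstream stage
#' segmentation directly.
#'
#' @param gene_id gene identifier.
#' @param grid strictly increasing pseudotime grid.
#' @param fitted fitted relative expression on the grid.
#' @param ci_low,ci_high 95% pointwise bounds (defaults equal to `fitted`).
#' @param span smoothing parameter used (NA for analytic curves).
#' @param pseudotime optional per-cell pseudotime (needed for stage labels).
#' @param relative optional per-cell response values.
#' @param loess optional underlying `loess` object.
#' @return an object of class `"trend_fit"`.
#' @export
trend_fit <- function(gene_id, grid, fitted, ci_low = fitted,
                      ci_high = fitted, span = NA_real_, pseudotime = NULL,
                      relative = NULL, loess = NULL) {
  grid <- as.numeric(grid)
  fitted <- as.numeric(fitted)
  if (length(grid) != length(fitted))
    stop("'grid' and 'fitted' lengths differ")
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  vals <- c(fitted, ci_low, ci_high)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("trend values must be finite")
  if (any(ci_low > fitted + 1e-12) || any(ci_high < fitted - 1e-12))
    stop("confidence bounds must bracket the fitted curve")
  structure(list(gene_id = gene_id, grid = grid, fitted = fitted,
                 ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
                 span = span, pseudotime = pseudotime, relative = relative,
                 loess = loess),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend_fit: gene '%s', %d grid points on [%.4g, %.4g], span %s\n",
              x$gene_id, length(x$grid), min(x$grid), max(x$grid),
              format(x$span)))
  invisible(x)
}

#' Predict from a fitted expression trend
#'
#' @param object a `"trend_fit"` from [fit_trend()].
#' @param newdata pseudotime values; defaults to the fit grid.
#' @param ... unused.
#' @return numeric vector of fitted relative expression.
#' @export
predict.trend_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (!is.null(object$loess))
    return(as.numeric(stats::predict(object$loess,
                                     newdata = data.frame(pt = newdata))))
  stats::approx(object$grid, object$fitted, xout = newdata, rule = 2)$y
}

#' Plot an expression trend with its confidence band
#'
#' @param x a `"trend_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trend_fit <- function(x, ...) {
  graphics::plot(x$grid, x$fitted, type = "n",
                 ylim = range(x$ci_low, x$ci_high, x$relative),
                 xlab = "pseudotime", ylab = "relative expression",
                 main = x$gene_id, ...)
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$ci_low, rev(x$ci_high)),
                    col = "grey85", border = NA)
  if (!is.null(x$pseudotime))
    graphics::points(x$pseudotime, x$relative, pch = 16, cex = 0.5,
                     col = "grey40")
  graphics::lines(x$grid, x$fitted, lwd = 2)
  invisible(x)
}

#' Stage cutoff at the rightmost stationary point of a trend
#'
#' Segments the trajectory into an early stage T1 and a late stage T2 at the
#' rightmost stationary point of the fitted curve that precedes its final
#' increase — operationally, the onset of increasing expression of an
#' intermediate-progenitor marker such as Tbr2. The derivative is taken by
#' central finite differences on the grid; a grid point is stationary where
#' the derivative changes sign or its magnitude is at most `derivative_tol`.
#' Among stationary points followed by a positive derivative the rightmost
#' is the cutoff; if the curve ends flat, the last sign-change location is
#' used. A monotone curve with no such point raises an explicit no-cutoff
#' error rather than returning a boundary value.
#'
#' @param trend a `"trend_fit"` (from [fit_trend()], n_grid >= 20).
#' @param derivative_tol stationarity tolerance on the derivative; default
#'   `1e-4 * diff(range(fitted)) / grid_step`.
#' @return an object of class `"stage_cut"`: list with `cutoff` (pseudotime),
#'   `gene_id`, `derivative_tol`, and — when the trend carries per-cell
#'   pseudotime — `stage_of_cell`, a factor with levels `T1`, `T2` (cells at
#'   the cutoff are T1, the `<=` convention).
#' @export
stage_cutoff <- function(trend, derivative_tol = NULL) {
  stopifnot(inherits(trend, "trend_fit"))
  g <- trend$grid
  f <- trend$fitted
  n <- length(g)
  if (n < 20) stop("stage_cutoff requires a grid of at least 20 points")
  step <- g[2] - g[1]
  if (is.null(derivative_tol))
    derivative_tol <- 1e-4 * diff(range(f)) / step
  if (derivative_tol < 0) stop("'derivative_tol' must be nonnegative")
  # central differences; one-sided at the ends
  d <- c(f[2] - f[1], (f[3:n] - f[1:(n - 2)]) / 2, f[n] - f[n - 1]) / step
  flat <- abs(d) <= derivative_tol
  # sign changes between adjacent non-flat points, assigned to the smaller-
  # magnitude endpoint
  crossing <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    if (d[i] * d[i + 1] < 0) {
      j <- if (abs(d[i]) <= abs(d[i + 1])) i else i + 1L
      crossing[j] <- TRUE
    }
  }
  stationary <- which(flat | crossing)
  if (length(stationary) == 0L)
    stop("no-cutoff: the fitted curve has no stationary point")
  # keep stationary points whose next non-stationary derivative is positive
  followed_by_rise <- vapply(stationary, function(i) {
    later <- which(abs(d) > derivative_tol & seq_len(n) > i)
    length(later) > 0 && d[later[1]] > 0
  }, logical(1))
  if (any(followed_by_rise)) {
    idx <- max(stationary[followed_by_rise])
  } else if (flat[n]) {
    # curve ends flat: fall back to the last sign-change location
    if (!any(crossing))
      stop("no-cutoff: no stationary point precedes an increase")
    idx <- max(which(crossing))
  } else {
    stop("no-cutoff: no stationary point precedes an increase")
  }
  cutoff <- g[idx]
  out <- list(cutoff = cutoff, gene_id = trend$gene_id,
              derivative_tol = derivative_tol)
  if (!is.null(trend$pseudotime)) {
    out$stage_of_cell <- factor(ifelse(trend$pseudotime <= cutoff,
                                       "T1", "T2"),
                                levels = c("T1", "T2"))
    names(out$stage_of_cell) <- names(trend$pseudotime)
  }
  structure(out, class = "stage_cut")
}

#' @export
print.stage_cut <- function(x, ...) {
  cat(sprintf("stage_cut: T1/T2 cutoff at pseudotime %.4g (gene '%s')\n",
              x$cutoff, x$gene_id))
  if (!is.null(x$stage_of_cell))
    print(table(x$stage_of_cell))
  invisible(x)
}

#' Count expression-positive cells per trajectory stage
#'
#' Cross-tabulates positivity for a gene (CPM strictly above a threshold,
#' default 0) against the T1/T2 stage labels of a cutoff.
#'
#' @param profile an [expression_profile()] with pseudotime.
#' @param gene gene identifier.
#' @param cut a `"stage_cut"` covering the profile's cells, or a pseudotime
#'   cutoff value.
#' @param positivity_threshold CPM threshold; a cell is positive iff its CPM
#'   exceeds it.
#' @return 2x2 integer matrix, rows `T1`/`T2`, columns `positive`/`negative`;
#'   row sums equal the stage sizes.
#' @export
count_positive_by_stage <- function(profile, gene, cut,
                                    positivity_threshold = 0) {
  x <- gene_cpm(profile, gene)
  pt <- profile_pseudotime(profile)
  if (inherits(cut, "stage_cut")) {
    if (!is.null(cut$stage_of_cell) &&
        !all(names(pt) %in% names(cut$stage_of_cell)))
      stop("the stage cut does not cover every cell in the profile")
    cutoff <- cut$cutoff
  } else {
    cutoff <- as.numeric(cut)
  }
  stage <- factor(ifelse(pt <= cutoff, "T1", "T2"), levels = c("T1", "T2"))
  positive <- factor(ifelse(x > positivity_threshold, "positive", "negative"),
                     levels = c("positive", "negative"))
  tab <- table(stage, positive)
  out <- matrix(as.integer(tab), 2, 2,
                dimnames = list(c("T1", "T2"), c("positive", "negative")))
  attr(out, "gene_id") <- gene
  attr(out, "positivity_threshold") <- positivity_threshold
  out
}
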