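#' Trajectory straightness score
#'
#' Path length of a successful trial's cursor trajectory divided by the
#' straight-line distance from the start point to the target center.  A
#' score of 1 is a perfectly straight reach; larger is more curved.
#'
#' @param trajectory matrix or data frame of positions (columns x, y), cm,
#'   in time order, starting at the trial's start point.
#' @param target_center length-2 target center, cm.
#' @param start optional explicit start point; defaults to the first
#'   trajectory row.
#' @return dimensionless score >= path-chord ratio.
#' @examples
#' trajectory_score(rbind(c(0, 0), c(3, 0), c(3, 4)), target_center = c(3, 4))
#' @export
trajectory_score <- function(trajectory, target_center, start = NULL) {
  tr <- as.matrix(trajectory)
  if (ncol(tr) != 2L || nrow(tr) < 2L)
    stop("'trajectory' must be >= 2 positions with columns x, y")
  start <- start %||% tr[1L, ]
  chord <- sqrt(sum((target_center - start)^2))
  if (chord == 0) stop("degenerate trial: start coincides with target center")
  seg <- diff(tr)
  sum(sqrt(rowSums(seg^2))) / chord
}

#' Output-potent and output-null group activity
#'
#' For a trial toward a target in a given direction sector, the
#' output-potent value is the difference between the toward-target and
#' away-target action values (the component that drives cursor speed along
#' that axis), and the output-null value is their sum (which does not).
#' Optionally restricts to medium-speed bins, cursor speed within 25-75%
#' of the maximum speed, to exclude idling and artifactual fast movements.
#'
#' @param a matrix or data frame of per-bin action values with columns
#'   a1..a4 (right, left, up, down).
#' @param target_angle target direction, radians; its sector selects the
#'   group pair.
#' @param speed optional per-bin Euclidean cursor speed, cm/s (required
#'   when `speed_filter` is TRUE).
#' @param speed_filter apply the medium-speed filter?
#' @param v_max reference maximum speed for the filter, cm/s (the decoder's
#'   per-axis clamp by default).
#' @return list with per-bin `potent` and `null` series (filtered bins
#'   dropped), their per-trial means `potent_mean`/`null_mean` (NA with a
#'   `filtered_out` flag when no bin survives), and `sector`.
#' @export
potent_null_values <- function(a, target_angle, speed = NULL,
                               speed_filter = FALSE, v_max = 15) {
  a <- as.matrix(a)
  if (ncol(a) != 4L) stop("'a' must have 4 columns (a1..a4)")
  sec <- sector_of(target_angle)
  pair <- switch(sec,
                 right = c(1L, 2L), left = c(2L, 1L),
                 up = c(3L, 4L), down = c(4L, 3L))
  keep <- rep(TRUE, nrow(a))
  if (speed_filter) {
    if (is.null(speed) || length(speed) != nrow(a))
      stop("'speed' (one value per bin) is required for the medium-speed filter")
    keep <- speed >= 0.25 * v_max & speed <= 0.75 * v_max
  }
  potent <- a[keep, pair[1L]] - a[keep, pair[2L]]
  null <- a[keep, pair[1L]] + a[keep, pair[2L]]
  list(potent = potent, null = null,
       potent_mean = if (length(potent)) mean(potent) else NA_real_,
       null_mean = if (length(null)) mean(null) else NA_real_,
       filtered_out = !any(keep), sector = sec)
}

#' Fit cosine direction tuning to one unit
#'
#' Least squares of firing rate on `(1, cos(theta), sin(theta))`, the
#' linearized cosine tuning model.  The preferred direction is
#' `atan2(b2, b1)`, the tuning depth is the peak-to-trough range
#' `2 * sqrt(b1^2 + b2^2)` of the fitted curve, and `r2` is the coefficient
#' of determination.  For out-and-back tasks the caller supplies the
#' target direction relative to the cursor.
#'
#' @param rates per-bin firing rate, Hz.
#' @param angles per-bin target direction, radians.
#' @return object of class `direction_tuning` with fields `b0`, `b1`,
#'   `b2`, `pd_angle`, `tuning_depth`, `r2`, `n`.
#' @examples
#' th <- seq(-pi, pi, length.out = 100)
#' fit_direction_tuning(10 + 4 * cos(th - pi / 2), th)
#' @export
fit_direction_tuning <- function(rates, angles) {
  n <- length(rates)
  if (length(angles) != n) stop("'rates' and 'angles' must have equal length")
  if (n < 3L || length(unique(round(wrap_angle_lower(angles), 12L))) < 3L)
    stop("need at least 3 distinct target angles to fit direction tuning")
  X <- cbind(1, cos(angles), sin(angles))
  fit <- stats::lm.fit(X, rates)
  b <- unname(fit$coefficients)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((rates - mean(rates))^2)
  r2 <- if (ss_tot == 0) 0 else max(0, min(1, 1 - ss_res / ss_tot))
  mag <- sqrt(b[2L]^2 + b[3L]^2)
  structure(
    list(b0 = b[1L], b1 = b[2L], b2 = b[3L],
         pd_angle = if (mag > 0) wrap_angle_lower(atan2(b[3L], b[2L])) else NA_real_,
         tuning_depth = 2 * mag, r2 = r2, n = n),
    class = "direction_tuning"
  )
}

#' @export
print.direction_tuning <- function(x, ...) {
  cat(sprintf(
    "Direction tuning: PD = %.1f deg, depth = %.2f Hz, R2 = %.3f (n = %d)\n",
    x$pd_angle * 180 / pi, x$tuning_depth, x$r2, x$n))
  invisible(x)
}

#' Normalized distance between preferred and assigned direction
#'
#' Maps the absolute angular difference from \[-pi, pi\] to \[0, 1\]: 0 for
#' identical directions, 1 for opposite directions, and 0.25 at the edge
#' of the assigned 90-degree sector (45 degrees off).
#'
#' @param pd preferred direction, radians (vectorized).
#' @param ad assigned direction, radians.
#' @return dimensionless distance in \[0, 1\].
#' @examples
#' pd_ad_distance(pi, 0)       # 1
#' pd_ad_distance(pi / 4, 0)   # 0.25
#' @export
pd_ad_distance <- function(pd, ad) {
  if (any(!is.finite(pd)) || any(!is.finite(ad)))
    stop("'pd' and 'ad' must be finite angles")
  abs(wrap_angle(pd - ad)) / pi
}

#' Logistic learning trend of trial success
#'
#' Logistic regression of per-trial binary outcome on session index, the
#' standard model for a learning curve over practice sessions.  Reports
#' the slope, its Wald test p-value and McFadden's pseudo-R2.  Complete
#' separation (including all-success or all-failure data) is flagged and a
#' pseudo-count-penalized fit (half a success and half a failure added per
#' session) is used instead.
#'
#' @param trials data frame with columns `session_index` and `outcome`
#'   ("success"/"fail", logical, or 0/1).
#' @return object of class `learning_trend` with fields `intercept`,
#'   `slope`, `slope_p`, `pseudo_r2`, `separation`,
#'   `per_session_success` (named proportion vector) and `n_trials`.
#' @export
fit_success_logistic <- function(trials) {
  s <- trials$session_index
  y <- trials$outcome
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "success"
  y <- as.numeric(y)
  if (length(unique(s)) < 2L) stop("need trials from at least 2 sessions")
  agg_n <- tapply(y, s, length)
  agg_k <- tapply(y, s, sum)
  ses <- as.numeric(names(agg_n))
  separation <- all(y == 1) || all(y == 0)
  fit <- NULL
  if (!separation) {
    withCallingHandlers(
      fit <- stats::glm(cbind(agg_k, agg_n - agg_k) ~ ses, family = stats::binomial()),
      warning = function(cond) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(cond)))
          invokeRestart("muffleWarning")
      })
    separation <- any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8) &&
      fit$deviance < 1e-6
  }
  if (separation) {
    # Penalized fallback: half-success/half-failure pseudo-counts per session
    k2 <- agg_k + 0.5
    n2 <- agg_n + 1
    fit <- suppressWarnings(
      stats::glm(k2 / n2 ~ ses, family = stats::binomial(), weights = n2))
  }
  co <- summary(fit)$coefficients
  null_dev <- fit$null.deviance
  pseudo_r2 <- if (null_dev > 0) 1 - fit$deviance / null_dev else NA_real_
  structure(
    list(intercept = co[1L, 1L], slope = co[2L, 1L], slope_p = co[2L, 4L],
         pseudo_r2 = pseudo_r2, separation = separation,
         per_session_success = stats::setNames(as.numeric(agg_k / agg_n),
                                               names(agg_n)),
         n_trials = length(y)),
    class = "learning_trend"
  )
}

#' @export
print.learning_trend <- function(x, ...) {
  cat(sprintf(
    "Logistic learning trend over %d sessions (%d trials): slope %.3f (p = %.3g), McFadden R2 = %.3f%s\n",
    length(x$per_session_success), x$n_trials, x$slope, x$slope_p, x$pseudo_r2,
    if (x$separation) " [complete separation: penalized fit]" else ""))
  invisible(x)
}

#' Cursor occupancy map
#'
#' Counts logged cursor positions in a regular spatial grid, pooling over
#' trials; used to visualize how trajectories compact as control improves.
#'
#' @param positions matrix or data frame of positions (columns x, y), cm.
#' @param xlim,ylim grid extent, cm (must cover the positions).
#' @param nx,ny number of grid cells per axis.
#' @return `nx` by `ny` integer matrix of visit counts (x indexes rows).
#' @export
occupancy_map <- function(positions, xlim = c(-15, 15), ylim = c(-12.5, 12.5),
                          nx = 30L, ny = 25L) {
  p <- as.matrix(positions)
  if (any(p[, 1L] < xlim[1L] | p[, 1L] > xlim[2L] |
          p[, 2L] < ylim[1L] | p[, 2L] > ylim[2L]))
    stop("grid does not cover all positions")
  ix <- pmin(pmax(1L, ceiling((p[, 1L] - xlim[1L]) / diff(xlim) * nx)), nx)
  iy <- pmin(pmax(1L, ceiling((p[, 2L] - ylim[1L]) / diff(ylim) * ny)), ny)
  grid <- matrix(0L, nx, ny)
  for (i in seq_along(ix)) grid[ix[i], iy[i]] <- grid[ix[i], iy[i]] + 1L
  grid
}

#' Success proportion by target-direction bin
#'
#' Bins target angles into the four direction sectors (same convention as
#' neuron grouping) and reports the success proportion per bin.
#'
#' @param trials data frame with `target_angle` (radians) and `outcome`;
#'   center-target trials (NA angle) are dropped.
#' @return named numeric vector over right/up/left/down; sectors with no
#'   trials are NA.
#' @export
direction_binned_success <- function(trials) {
  tr <- trials[!is.na(trials$target_angle), , drop = FALSE]
  out <- stats::setNames(rep(NA_real_, 4L), c("right", "up", "left", "down"))
  if (!nrow(tr)) return(out)
  sec <- sector_of(tr$target_angle)
  y <- tr$outcome == "success"
  for (s in names(out)) if (any(sec == s)) out[s] <- mean(y[sec == s])
  out
}
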