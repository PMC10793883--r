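#' Fit a linear velocity-tuning model to one unit
#'
#' Ordinary least squares of firing rate on cursor velocity,
#' \eqn{fr = b_0 + b_1 v_x + b_2 v_y}.  The coefficient vector
#' \eqn{(b_1, b_2)} is the unit's preferred-direction vector.
#'
#' @param rates per-bin firing rate, Hz.
#' @param vx,vy per-bin cursor velocity components, cm/s.
#' @return an object of class `velocity_tuning` with fields `b0`, `b1`,
#'   `b2` and `r2`.
#' @examples
#' v <- seq(-5, 5, length.out = 50)
#' fit <- fit_velocity_tuning(5 + 2 * v, vx = v, vy = rev(v) * 0)
#' c(fit$b0, fit$b1, fit$b2, fit$r2)
#' @export
fit_velocity_tuning <- function(rates, vx, vy) {
  n <- length(rates)
  if (length(vx) != n || length(vy) != n)
    stop("'rates', 'vx' and 'vy' must have equal length")
  if (n < 3L) stop("need at least 3 bins to fit velocity tuning")
  X <- cbind(1, vx, vy)
  if (qr(X)$rank < 3L)
    stop("rank-deficient design: velocities are constant or collinear")
  fit <- stats::lm.fit(X, rates)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((rates - mean(rates))^2)
  r2 <- if (ss_tot == 0) 0 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(
    list(b0 = unname(fit$coefficients[1L]), b1 = unname(fit$coefficients[2L]),
         b2 = unname(fit$coefficients[3L]), r2 = r2, n = n),
    class = "velocity_tuning"
  )
}

#' @export
print.velocity_tuning <- function(x, ...) {
  cat(sprintf("Velocity tuning: fr = %.3f + %.3f vx + %.3f vy (R2 = %.3f, n = %d)\n",
              x$b0, x$b1, x$b2, x$r2, x$n))
  invisible(x)
}

#' Preferred direction from a velocity-tuning fit
#'
#' @param fit a `velocity_tuning` object, or anything with `b1`/`b2` fields.
#' @return list with `angle` (radians in \[-pi, pi)), `magnitude`
#'   (Hz per cm/s), and `untuned` (TRUE when (b1, b2) = (0, 0), in which
#'   case `angle` is NA and the unit is excluded from grouping).
#' @export
preferred_direction <- function(fit) {
  b1 <- fit$b1; b2 <- fit$b2
  mag <- sqrt(b1^2 + b2^2)
  if (mag == 0)
    return(list(angle = NA_real_, magnitude = 0, untuned = TRUE))
  list(angle = wrap_angle_lower(atan2(b2, b1)), magnitude = mag, untuned = FALSE)
}

#' Direction sector of an angle
#'
#' The 2D direction space is split into four equal sectors with divisions
#' at pi/4, 3pi/4, 5pi/4 and 7pi/4: right = \[-pi/4, pi/4), up =
#' \[pi/4, 3pi/4), left = \[3pi/4, 5pi/4), down = \[5pi/4, 7pi/4).  Sectors
#' are half-open counter-clockwise, so every angle has exactly one sector
#' (pi/4 itself is "up").
#'
#' @param angle angle(s) in radians (any range; wrapped internally).
#' @return character vector in `c("right", "left", "up", "down")`.
#' @examples
#' sector_of(c(0, pi / 2, pi / 4, pi, -pi / 2))
#' @export
sector_of <- function(angle) {
  if (any(!is.finite(angle))) stop("'angle' must be finite")
  # rotate by pi/4 so sector boundaries land on multiples of pi/2
  q <- floor(wrap_angle_lower(angle + pi / 4) / (pi / 2)) + 3L  # 1..4
  c("left", "down", "right", "up")[q]
}

#' Center angle of a named direction sector
#' @param sector character vector in `c("right", "left", "up", "down")`.
#' @return angle in radians (0, pi, pi/2, -pi/2).
#' @export
sector_center <- function(sector) {
  centers <- c(right = 0, left = pi, up = pi / 2, down = -pi / 2)
  unname(centers[sector])
}

#' Assign stable, strongly tuned units to the four direction groups
#'
#' Units are eligible when recorded for strictly more than `stability_days`
#' days and not flagged untuned.  Each sector receives the `n_per_group`
#' eligible units with the largest preferred-direction magnitude whose PD
#' falls inside the sector; a sector with a shortfall borrows the
#' unassigned eligible units nearest (by absolute angular distance) to its
#' center, ties broken by channel id.
#'
#' @param units data frame with columns `channel_id`, `days_recorded`,
#'   `pd_angle` (radians), `pd_magnitude`; rows with `NA` `pd_angle` are
#'   treated as untuned.
#' @param n_per_group units per group.
#' @param stability_days stability threshold in days (strict inequality).
#' @return a [group_spec()] with `mu`/`delta` unset; group entries are the
#'   selected `channel_id` values.
#' @export
select_groups <- function(units, n_per_group = 4L, stability_days = 5L) {
  req <- c("channel_id", "days_recorded", "pd_angle", "pd_magnitude")
  if (!all(req %in% names(units)))
    stop("'units' must have columns ", paste(req, collapse = ", "))
  eligible <- units[units$days_recorded > stability_days &
                      !is.na(units$pd_angle) & units$pd_magnitude > 0, ,
                    drop = FALSE]
  need <- 4L * n_per_group
  if (nrow(eligible) < need)
    stop(sprintf("only %d eligible units for %d group slots", nrow(eligible), need))
  eligible$sector <- sector_of(eligible$pd_angle)
  sectors <- c("right", "left", "up", "down")
  assigned <- stats::setNames(vector("list", 4L), sectors)
  taken <- rep(FALSE, nrow(eligible))
  # first pass: in-sector by descending tuning magnitude
  for (s in sectors) {
    in_sec <- which(eligible$sector == s)
    in_sec <- in_sec[order(-eligible$pd_magnitude[in_sec], eligible$channel_id[in_sec])]
    pick <- utils::head(in_sec, n_per_group)
    assigned[[s]] <- pick
    taken[pick] <- TRUE
  }
  # second pass: borrow nearest-by-angle unassigned eligible units
  for (s in sectors) {
    short <- n_per_group - length(assigned[[s]])
    if (short > 0L) {
      pool <- which(!taken)
      dist <- abs(wrap_angle_lower(eligible$pd_angle[pool] - sector_center(s)))
      pool <- pool[order(dist, eligible$channel_id[pool])]
      extra <- utils::head(pool, short)
      assigned[[s]] <- c(assigned[[s]], extra)
      taken[extra] <- TRUE
    }
  }
  group_spec(lapply(assigned, function(idx) eligible$channel_id[idx]))
}

#' Build a unit table from tuning fits
#'
#' Convenience constructor for the CSV-serializable unit table consumed by
#' [select_groups()].
#'
#' @param channel_id integer channel ids.
#' @param days_recorded days each unit was recorded.
#' @param fits list of `velocity_tuning` objects, one per unit.
#' @return data frame with tuning coefficients, PD angle/magnitude.
#' @export
unit_table <- function(channel_id, days_recorded, fits) {
  pd <- lapply(fits, preferred_direction)
  data.frame(
    channel_id = as.integer(channel_id),
    days_recorded = as.integer(days_recorded),
    b0 = vapply(fits, `[[`, numeric(1), "b0"),
    b1 = vapply(fits, `[[`, numeric(1), "b1"),
    b2 = vapply(fits, `[[`, numeric(1), "b2"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    pd_angle = vapply(pd, `[[`, numeric(1), "angle"),
    pd_magnitude = vapply(pd, `[[`, numeric(1), "magnitude")
  )
}
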