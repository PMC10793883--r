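#' Decoder configuration for the group-weight algorithm
#'
#' The group-weight decoder converts binned multi-unit spike counts into 2D
#' cursor velocity.  Firing rates are computed with a moving average of
#' non-overlapping 100 ms count bins; each of four channel groups is summed,
#' z-normalized against pre-experiment statistics, offset by `c` and
#' rectified at zero to give an action value \eqn{a_k}; opposing action
#' values are differenced and scaled by `w` to give the per-axis velocity,
#' clamped to `v_max`.
#'
#' @param bin_width width of a decoder count bin in seconds.
#' @param smoothing_bins number of trailing bins in the moving average.
#' @param c dimensionless offset added to the normalized group rate before
#'   rectification.
#' @param w gain from net action value to cursor velocity, cm/s per unit.
#' @param v_max per-axis speed limit in cm/s.
#' @param delta_floor minimum allowed normalization SD \eqn{\delta_k} in Hz;
#'   guards against division blow-up on near-constant pre-experiments.
#' @return an object of class `decoder_config`.
#' @examples
#' cfg <- decoder_config()
#' cfg$w
#' @export
decoder_config <- function(bin_width = 0.1, smoothing_bins = 5L, c = 1,
                           w = 0.375, v_max = 15, delta_floor = 0.1) {
  stopifnot_scalar_num(bin_width, "bin_width", positive = TRUE)
  stopifnot_scalar_num(v_max, "v_max", positive = TRUE)
  stopifnot_scalar_num(delta_floor, "delta_floor", positive = TRUE)
  stopifnot_scalar_num(c, "c")
  stopifnot_scalar_num(w, "w")
  smoothing_bins <- as.integer(smoothing_bins)
  if (is.na(smoothing_bins) || smoothing_bins < 1L)
    stop("'smoothing_bins' must be an integer >= 1")
  structure(
    list(bin_width = bin_width, smoothing_bins = smoothing_bins, c = c,
         w = w, v_max = v_max, delta_floor = delta_floor),
    class = "decoder_config"
  )
}

#' @export
print.decoder_config <- function(x, ...) {
  cat("Group-weight decoder configuration\n")
  cat(sprintf("  bin width      : %g s (smoothing over %d bins)\n",
              x$bin_width, x$smoothing_bins))
  cat(sprintf("  offset c       : %g\n", x$c))
  cat(sprintf("  gain w         : %g cm/s per action-value unit\n", x$w))
  cat(sprintf("  speed clamp    : +/- %g cm/s per axis\n", x$v_max))
  cat(sprintf("  delta floor    : %g Hz\n", x$delta_floor))
  invisible(x)
}

#' Group assignment and normalization constants
#'
#' Four ordered, pairwise-disjoint channel groups drive the cursor: group 1
#' pushes +x (right), group 2 -x (left), group 3 +y (up), group 4 -y (down).
#' `mu` and `delta` are per-group mean and SD (Hz) of the smoothed summed
#' firing rate, estimated from a pre-experiment segment with
#' [estimate_normalization()].
#'
#' @param groups list of four integer vectors of channel indices, in the
#'   fixed order right, left, up, down.
#' @param mu optional numeric length-4 vector of group means (Hz).
#' @param delta optional numeric length-4 vector of group SDs (Hz).
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(groups, mu = NULL, delta = NULL) {
  if (!is.list(groups) || length(groups) != 4L)
    stop("'groups' must be a list of exactly 4 channel-index vectors")
  groups <- lapply(groups, function(g) as.integer(sort(g)))
  all_ch <- unlist(groups)
  if (anyDuplicated(all_ch))
    stop("groups must be pairwise disjoint")
  if (any(all_ch < 1L))
    stop("channel indices must be positive")
  names(groups) <- c("right", "left", "up", "down")
  if (!is.null(mu)) {
    if (length(mu) != 4L || !is.numeric(mu)) stop("'mu' must be numeric length 4")
  }
  if (!is.null(delta)) {
    if (length(delta) != 4L || !is.numeric(delta)) stop("'delta' must be numeric length 4")
    if (any(delta <= 0)) stop("'delta' must be positive (estimate with a delta floor)")
  }
  structure(list(groups = groups, mu = mu, delta = delta), class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat("Group spec (right, left, up, down):\n")
  for (k in seq_len(4L)) {
    cat(sprintf("  %-5s channels [%s]", names(x$groups)[k],
                paste(x$groups[[k]], collapse = ", ")))
    if (!is.null(x$mu))
      cat(sprintf("  mu = %.2f Hz, delta = %.2f Hz", x$mu[k], x$delta[k]))
    cat("\n")
  }
  invisible(x)
}

is_normalized <- function(groups) {
  inherits(groups, "group_spec") && !is.null(groups$mu) && !is.null(groups$delta)
}

#' Initialize decoder smoothing state
#'
#' Holds the trailing window of per-channel count bins used by the moving
#' average.  The window starts zero-filled, i.e. the session is treated as
#' silent before its first bin.
#'
#' @param n_channels number of recorded channels.
#' @param cfg a [decoder_config()].
#' @return an object of class `decoder_state`.
#' @export
decoder_state <- function(n_channels, cfg = decoder_config()) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) stop("'n_channels' must be >= 1")
  structure(
    list(buffer = matrix(0, nrow = cfg$smoothing_bins, ncol = n_channels),
         pos = 0L, n_channels = n_channels),
    class = "decoder_state"
  )
}

#' Smooth per-channel firing rates with a trailing moving average
#'
#' Pushes one bin of per-channel spike counts into the trailing window and
#' returns the smoothed firing rate of every channel: the mean count over
#' the window (zero-padded at session start) divided by the bin width.
#'
#' @param state a [decoder_state()].
#' @param new_counts non-negative integer vector, one count per channel.
#' @param cfg a [decoder_config()].
#' @return list with elements `state` (updated) and `rates` (Hz per channel).
#' @examples
#' st <- decoder_state(2)
#' out <- smooth_firing_rates(st, c(2, 0))
#' out$rates  # (2/5)/0.1 = 4 Hz under zero-padding
#' @export
smooth_firing_rates <- function(state, new_counts, cfg = decoder_config()) {
  if (!inherits(state, "decoder_state")) stop("'state' must be a decoder_state")
  if (length(new_counts) != state$n_channels)
    stop(sprintf("channel-count mismatch: state has %d channels, got %d counts",
                 state$n_channels, length(new_counts)))
  if (any(new_counts < 0) || any(new_counts != round(new_counts)))
    stop("'new_counts' must be non-negative integers")
  pos <- state$pos %% nrow(state$buffer) + 1L
  state$buffer[pos, ] <- new_counts
  state$pos <- pos
  rates <- colSums(state$buffer) / nrow(state$buffer) / cfg$bin_width
  list(state = state, rates = rates)
}

#' Action value of one group
#'
#' The action value is the group's summed firing rate, z-normalized against
#' the pre-experiment mean `mu` and SD `delta`, offset by `c`, and rectified
#' at zero: \eqn{a_k = \max((\sum fr_i - \mu_k)/\delta_k + c,\ 0)}.
#'
#' @param summed_rate group-summed smoothed firing rate, Hz (vectorized).
#' @param mu pre-experiment mean of the summed rate, Hz.
#' @param delta pre-experiment SD of the summed rate, Hz; must be > 0.
#' @param c dimensionless offset.
#' @return non-negative dimensionless action value(s).
#' @examples
#' action_value(20, mu = 20, delta = 5)       # 1
#' action_value(25, mu = 20, delta = 5)       # 2
#' action_value(5, mu = 20, delta = 5)        # 0 (rectified)
#' @export
action_value <- function(summed_rate, mu, delta, c = 1) {
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop("'delta' must be > 0: normalization constants not estimated")
  pmax((summed_rate - mu) / delta + c, 0)
}

#' Convert action values to cursor velocity
#'
#' Each axis is driven by the difference of its opposing action values,
#' scaled by the gain `w` and clamped per axis to `v_max`:
#' \eqn{v_x = w (a_1 - a_2)}, \eqn{v_y = w (a_3 - a_4)}.
#'
#' @param a numeric length-4 vector of action values (right, left, up, down).
#' @param cfg a [decoder_config()].
#' @return named numeric vector `c(vx = , vy = )` in cm/s.
#' @examples
#' decode_velocity(c(2, 1, 1, 1))  # vx = 0.375, vy = 0
#' @export
decode_velocity <- function(a, cfg = decoder_config()) {
  if (length(a) != 4L || any(a < 0)) stop("'a' must be 4 non-negative action values")
  c(vx = clamp(cfg$w * (a[[1L]] - a[[2L]]), -cfg$v_max, cfg$v_max),
    vy = clamp(cfg$w * (a[[3L]] - a[[4L]]), -cfg$v_max, cfg$v_max))
}

#' Sum smoothed channel rates within each group
#' @keywords internal
group_sums <- function(rates, groups) {
  unname(vapply(groups$groups, function(g) sum(rates[g]), numeric(1)))
}

#' Estimate per-group normalization constants from a pre-experiment segment
#'
#' Replays the decoder's own smoothing over a segment of 100 ms count bins,
#' sums the smoothed channel rates within each group, and returns the mean
#' (`mu`) and population SD (`delta`, floored at `cfg$delta_floor`) of each
#' group's summed-rate series.  The statistics are computed on the same
#' smoothed signal the decoder sees at run time.
#'
#' @param counts matrix of spike counts, one row per 100 ms bin, one column
#'   per channel (sum 10 ms rows with [bin_decoder_counts()] first if
#'   starting from a 10 ms frame).
#' @param groups a [group_spec()] (mu/delta may be unset).
#' @param cfg a [decoder_config()].
#' @return the `group_spec` with `mu` and `delta` filled in.
#' @export
estimate_normalization <- function(counts, groups, cfg = decoder_config()) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L) stop("pre-experiment segment is empty")
  if (nrow(counts) < cfg$smoothing_bins)
    stop("pre-experiment segment shorter than one full smoothing window")
  if (!inherits(groups, "group_spec")) stop("'groups' must be a group_spec")
  if (max(c(0L, unlist(groups$groups))) > ncol(counts))
    stop("group channel index exceeds number of channels in segment")
  st <- decoder_state(ncol(counts), cfg)
  sums <- matrix(NA_real_, nrow(counts), 4L)
  for (b in seq_len(nrow(counts))) {
    sm <- smooth_firing_rates(st, counts[b, ], cfg)
    st <- sm$state
    sums[b, ] <- group_sums(sm$rates, groups)
  }
  # drop the zero-padded warm-up so the statistics describe the
  # steady-state smoothed signal
  sums <- sums[cfg$smoothing_bins:nrow(sums), , drop = FALSE]
  groups$mu <- colMeans(sums)
  groups$delta <- pmax(apply(sums, 2L, pop_sd), cfg$delta_floor)
  groups
}

#' Sum a 10 ms spike frame into decoder bins
#'
#' @param spikes matrix of counts on the 10 ms grid (rows = 10 ms bins,
#'   columns = channels).
#' @param factor number of 10 ms rows per decoder bin (10 for 100 ms bins).
#'   Trailing rows that do not fill a complete bin are dropped.
#' @return matrix of counts, one row per decoder bin.
#' @export
bin_decoder_counts <- function(spikes, factor = 10L) {
  spikes <- as.matrix(spikes)
  factor <- as.integer(factor)
  n_full <- nrow(spikes) %/% factor
  if (n_full < 1L) stop("fewer than one full decoder bin of spikes")
  idx <- rep(seq_len(n_full), each = factor)
  out <- rowsum(spikes[seq_len(n_full * factor), , drop = FALSE], idx, reorder = FALSE)
  dimnames(out) <- NULL
  out
}

#' One decoder step: counts in, action values and velocity out
#'
#' Composes smoothing, group summation, normalization/rectification and the
#' velocity map for one 100 ms bin.
#'
#' @param state a [decoder_state()].
#' @param new_counts per-channel counts for the new bin.
#' @param groups a normalized [group_spec()] (mu, delta set).
#' @param cfg a [decoder_config()].
#' @return list with `state`, `rates` (Hz per channel), `a` (action values),
#'   and `v` (named velocity vector, cm/s).
#' @export
decoder_step <- function(state, new_counts, groups, cfg = decoder_config()) {
  if (!is_normalized(groups))
    stop("groups are not normalized; run estimate_normalization() first")
  sm <- smooth_firing_rates(state, new_counts, cfg)
  s <- group_sums(sm$rates, groups)
  a <- action_value(s, groups$mu, groups$delta, cfg$c)
  list(state = sm$state, rates = sm$rates, a = a, v = decode_velocity(a, cfg))
}
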