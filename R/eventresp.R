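#' Peri-event window firing rates
#'
#' Mean spikes/frame in the window of `window_s` seconds before each event
#' onset (`F_before`, frames `[onset - w, onset)`) and from the onset
#' (`F_during`, frames `[onset, onset + w)`), with `w = round(window_s *
#' frame_rate_hz)` frames. Events whose windows would be truncated by the
#' recording edges are skipped with a warning.
#'
#' @param spikes Spike matrix, neurons x frames.
#' @param events An [event_timeline()] (all labels used as given).
#' @param frame_rate_hz Frames per second.
#' @param window_s Window length, seconds (default 2).
#' @return list: `F_before`, `F_during` (neurons x kept events), `events`
#'   (the kept rows).
#' @export
event_window_rates <- function(spikes, events, frame_rate_hz, window_s = 2.0) {
  spikes <- .as_spike_matrix(spikes)
  w <- round(window_s * frame_rate_hz)
  T <- ncol(spikes)
  onset_frame <- round(events$onset_s * frame_rate_hz)
  keep <- onset_frame - w >= 0 & onset_frame + w <= T
  if (!all(keep))
    warning(sprintf("%d event(s) with truncated windows skipped", sum(!keep)))
  if (!any(keep)) stop("no event has full pre/during windows")
  ev <- events[keep, , drop = FALSE]
  onset_frame <- onset_frame[keep]
  nb <- length(onset_frame)
  Fb <- matrix(0, nrow(spikes), nb)
  Fd <- matrix(0, nrow(spikes), nb)
  for (k in seq_len(nb)) {
    o <- onset_frame[k]
    Fb[, k] <- rowMeans(spikes[, (o - w + 1L):o, drop = FALSE])
    Fd[, k] <- rowMeans(spikes[, (o + 1L):(o + w), drop = FALSE])
  }
  rownames(Fb) <- rownames(Fd) <- rownames(spikes)
  list(F_before = Fb, F_during = Fd, events = ev,
       window_frames = w, onset_frames = onset_frame)
}

#' Normalized contrast score
#'
#' The shared form of the shock (SRC), freezing and social (SoRC) response
#' scores: `(a - b) / (a + b)`, bounded in \[-1, 1\], with 0 when both rates
#' are 0. A score of 1 means activity only under condition `a` ("maximally
#' activated"), -1 only under `b`.
#'
#' @param f_a,f_b Nonnegative mean rates (vectorized).
#' @return Scores in \[-1, 1\].
#' @export
contrast_score <- function(f_a, f_b) {
  if (any(f_a < 0) || any(f_b < 0)) stop("rates must be nonnegative")
  s <- f_a + f_b
  ifelse(s > 0, (f_a - f_b) / s, 0)
}

#' Mean shock response score (SRC)
#'
#' Per-event contrast of the during- vs before-onset window rates, averaged
#' over events (the "mean SRC").
#'
#' @param wr An [event_window_rates()] result.
#' @return Named numeric vector of mean SRC per neuron.
#' @export
shock_score <- function(wr) {
  s <- contrast_score(wr$F_during, wr$F_before)
  rowMeans(matrix(s, nrow(wr$F_during)))
}

#' Classify footshock responders by rotary-shuffle permutation
#'
#' Builds a null mean-SRC distribution per neuron by rotary-shuffling its
#' whole spike train (`n_shuffles` random circular offsets) and recomputing
#' the mean SRC each time. A neuron is `pro` if its observed mean SRC strictly
#' exceeds the upper `tail` empirical quantile of its null, `anti` if below
#' the lower quantile, otherwise `neutral`. Constant trains are neutral by
#' construction.
#'
#' @param spikes Spike matrix, neurons x frames.
#' @param events Shock [event_timeline()].
#' @param frame_rate_hz Frames per second.
#' @param cfg A [tuning_config()] (`n_shuffles`, `tail`, `seed` are used).
#' @param window_s Window length, seconds (default 2).
#' @param method `"fft"` (window sums for all offsets via circular
#'   cross-correlation, then subset at the sampled offsets) or `"direct"`
#'   (explicit index shifting); identical classifications.
#' @return Object of class `"shock_response"` with `$results` (neuron_id,
#'   score, class) and the per-neuron null quantiles.
#' @export
classify_shock_responders <- function(spikes, events, frame_rate_hz,
                                      cfg = tuning_config(), window_s = 2.0,
                                      method = c("fft", "direct")) {
  method <- match.arg(method)
  spikes <- .as_spike_matrix(spikes)
  wr <- event_window_rates(spikes, events, frame_rate_hz, window_s)
  obs <- shock_score(wr)
  T <- ncol(spikes)
  w <- wr$window_frames
  # 1-based frame indices of every (event, before/during) window
  idx_b <- lapply(wr$onset_frames, function(o) (o - w + 1L):o)
  idx_d <- lapply(wr$onset_frames, function(o) (o + 1L):(o + w))
  n_ev <- length(idx_b)
  cls <- character(nrow(spikes)); lo <- numeric(nrow(spikes)); hi <- numeric(nrow(spikes))
  for (i in seq_len(nrow(spikes))) {
    x <- spikes[i, ]
    offs <- withr::with_seed(
      .neuron_seed(cfg$seed, .neuron_key(rownames(spikes), i)),
      sample.int(T - 1L, cfg$n_shuffles, replace = TRUE))
    if (method == "fft") {
      fx <- fft(x)
      sb <- vapply(idx_b, function(J) .corr_all_offsets(fx, J, T)[offs + 1L],
                   numeric(length(offs)))
      sd_ <- vapply(idx_d, function(J) .corr_all_offsets(fx, J, T)[offs + 1L],
                    numeric(length(offs)))
      # per-shuffle mean SRC over events from the window sums (rate = sum/w)
      tot <- sd_ + sb
      sc <- ifelse(tot > 1e-9, (sd_ - sb) / tot, 0)
      null_src <- rowMeans(matrix(sc, length(offs)))
    } else {
      null_src <- vapply(offs, function(k) {
        sc <- vapply(seq_len(n_ev), function(e) {
          fb <- mean(x[((idx_b[[e]] - 1L - k) %% T) + 1L])
          fd <- mean(x[((idx_d[[e]] - 1L - k) %% T) + 1L])
          contrast_score(fd, fb)
        }, numeric(1))
        mean(sc)
      }, numeric(1))
    }
    lo[i] <- unname(quantile(null_src, cfg$tail, type = 1))
    hi[i] <- unname(quantile(null_src, 1 - cfg$tail, type = 1))
    cls[i] <- if (obs[i] > hi[i] + 1e-9) "pro"
              else if (obs[i] < lo[i] - 1e-9) "anti" else "neutral"
  }
  ids <- rownames(spikes)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(nrow(spikes)))
  structure(list(results = data.frame(neuron_id = ids, score = obs,
                                      class = cls, stringsAsFactors = FALSE),
                 null_lower = lo, null_upper = hi, config = cfg),
            class = "shock_response")
}

#' @export
print.shock_response <- function(x, ...) {
  tab <- table(factor(x$results$class, levels = c("pro", "neutral", "anti")))
  cat(sprintf("Shock responders (%d neurons, %d shuffles, %.1f%% tails): ",
              nrow(x$results), x$config$n_shuffles, 100 * x$config$tail))
  cat(paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Detect social-interaction frames
#'
#' A frame is social when the animal is within `max_dist_cm` of the wired
#' container's center AND its heading points at the container within
#' `max_angle_deg`.
#'
#' @param traj Trajectory with a `heading_deg` column.
#' @param arena [arena_spec()] whose target is the container center.
#' @param max_dist_cm Distance criterion, cm (default 10).
#' @param max_angle_deg Orientation criterion, degrees (default 45).
#' @return Logical vector, one per frame.
#' @export
detect_social_frames <- function(traj, arena, max_dist_cm = 10,
                                 max_angle_deg = 45) {
  if (is.null(traj$heading_deg) || all(is.na(traj$heading_deg)))
    stop("trajectory has no heading information")
  dx <- arena$target_x_cm - traj$x_cm
  dy <- arena$target_y_cm - traj$y_cm
  d <- sqrt(dx^2 + dy^2)
  to_target <- atan2(dy, dx) * 180 / pi
  ang <- abs(((traj$heading_deg - to_target + 180) %% 360) - 180)
  d < max_dist_cm & ang <= max_angle_deg
}

#' Masked contrast scores (social / freezing)
#'
#' Mean rate inside vs outside a boolean frame mask, combined by
#' [contrast_score()]. Social neurons are classed `ON` when the score is
#' strictly positive, `OFF` otherwise.
#'
#' @param spikes Spike matrix, neurons x frames.
#' @param mask Logical vector per frame (social-interaction or freezing
#'   frames); both the mask and its complement must be nonempty.
#' @param kind `"social"` or `"freezing"`.
#' @return data.frame: neuron_id, kind, score, class (`ON`/`OFF` for social,
#'   `NA` for freezing).
#' @export
masked_score <- function(spikes, mask, kind = c("social", "freezing")) {
  kind <- match.arg(kind)
  spikes <- .as_spike_matrix(spikes)
  mask <- as.logical(mask)
  if (length(mask) != ncol(spikes))
    stop("mask length must equal the frame count")
  if (!any(mask) || all(mask))
    stop("mask and its complement must both be nonempty")
  f_in <- rowMeans(spikes[, mask, drop = FALSE])
  f_out <- rowMeans(spikes[, !mask, drop = FALSE])
  score <- contrast_score(f_in, f_out)
  cls <- if (kind == "social") ifelse(score > 0, "ON", "OFF") else NA_character_
  ids <- rownames(spikes)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(nrow(spikes)))
  data.frame(neuron_id = ids, kind = kind, score = score, class = cls,
             stringsAsFactors = FALSE)
}

#' Drop sub-minimum bouts from a frame mask
#'
#' Enforces a minimum bout duration (default 2 s, the convention for scored
#' freezing) by clearing runs of `TRUE` shorter than
#' `round(min_duration_s * frame_rate_hz)` frames.
#'
#' @param mask Logical vector per frame.
#' @param frame_rate_hz Frames per second.
#' @param min_duration_s Minimum bout duration, seconds (default 2).
#' @return Filtered logical vector.
#' @export
filter_short_bouts <- function(mask, frame_rate_hz, min_duration_s = 2) {
  mask <- as.logical(mask)
  min_frames <- round(min_duration_s * frame_rate_hz)
  r <- rle(mask)
  r$values[r$values & r$lengths < min_frames] <- FALSE
  inverse.rle(r)
}

#' Ordinary least-squares fit of y on x
#'
#' Simple linear regression via [stats::lm()], reporting the slope,
#' intercept, R-squared and the two-sided t-test p-value on the slope. Used
#' for the score-vs-score and freezing-vs-responder-fraction regressions.
#'
#' @param x,y Numeric vectors, `length >= 3`; `x` must not be constant.
#' @return list: slope, intercept, r_squared, p_value, n.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need n >= 3")
  if (sd(x) == 0) stop("x is constant; slope undefined")
  if (sd(y) == 0)
    return(list(slope = 0, intercept = y[1], r_squared = 0,
                p_value = NA_real_, n = length(x)))
  fit <- lm(y ~ x)
  # summary.lm warns on an exactly collinear y; a perfect fit is fine here
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]), n = length(x))
}
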