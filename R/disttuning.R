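#' Tuning-test configuration
#'
#' Parameters of the distance-tuning permutation analysis: 31 equal-width bins
#' on normalized distance, 1000 rotary shuffles per neuron, Benjamini-Hochberg
#' FDR at 5%, and 2.5% tails for the two-tailed resampling tests.
#'
#' @param n_bins Number of distance bins (>= 2; default 31).
#' @param n_shuffles Rotary shuffles / resamples (default 1000).
#' @param fdr_q BH false-discovery-rate level (default 0.05).
#' @param tail One-sided tail probability of the two-tailed tests
#'   (default 0.025).
#' @param min_occupancy Minimum frames a distance bin must hold to enter the
#'   peak statistic (default 20, about 1.3 s at 15 Hz). A bin visited for
#'   only a handful of frames has so noisy a rate estimate that it dominates
#'   the max under both the observed and the shuffled trains; excluding such
#'   bins (identically for observed and null, so the permutation test stays
#'   exact) keeps the statistic about tuning rather than sampling noise. Set
#'   to 1 to use every occupied bin.
#' @param seed Integer seed; each neuron derives its own stream from
#'   `(seed, neuron id)` so results do not depend on neuron order.
#' @return Object of class `"tuning_config"`.
#' @export
tuning_config <- function(n_bins = 31, n_shuffles = 1000, fdr_q = 0.05,
                          tail = 0.025, min_occupancy = 20, seed = 1) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (!(fdr_q > 0 && fdr_q < 1)) stop("fdr_q must lie in (0, 1)")
  if (!(tail > 0 && tail < 0.5)) stop("tail must lie in (0, 0.5)")
  if (min_occupancy < 1) stop("min_occupancy must be >= 1")
  structure(list(n_bins = as.integer(n_bins),
                 n_shuffles = as.integer(n_shuffles),
                 fdr_q = fdr_q, tail = tail,
                 min_occupancy = as.integer(min_occupancy),
                 seed = as.integer(seed)),
            class = "tuning_config")
}

# Bins eligible for the peak statistic: occupancy floor, falling back to all
# occupied bins when the floor would leave none.
.eligible_bins <- function(occ, min_occupancy) {
  el <- occ >= min_occupancy
  if (!any(el)) el <- occ > 0
  el
}

# Deterministic per-neuron substream seed, independent of neuron order.
.neuron_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(i) * 7919) %% 2147483647)
}

# Stable per-neuron key: a hash of the neuron id when row names exist (so
# shuffling or subsetting rows leaves each neuron's stream unchanged), else
# the row index.
.neuron_key <- function(ids, i) {
  if (is.null(ids)) return(i)
  h <- 0
  for (c in utf8ToInt(ids[i])) h <- (h * 31 + c) %% 1048573
  h + 1
}

#' Distance of each frame to the arena target
#'
#' Euclidean distance per frame, plus the normalized distance
#' `min(dist / norm_radius_cm, 1)`.
#'
#' @param traj A trajectory data.frame (`x_cm`, `y_cm`).
#' @param arena An [arena_spec()] with the target set.
#' @return data.frame of class `"distance_series"`: `distance_cm`,
#'   `distance_norm`.
#' @export
compute_distance_series <- function(traj, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  if (is.null(arena$target_x_cm) || is.null(arena$target_y_cm))
    stop("arena target is not set")
  d <- sqrt((traj$x_cm - arena$target_x_cm)^2 +
            (traj$y_cm - arena$target_y_cm)^2)
  ds <- data.frame(distance_cm = d,
                   distance_norm = pmin(d / arena$norm_radius_cm, 1))
  class(ds) <- c("distance_series", "data.frame")
  ds
}

# Bin index per frame: equal-width bins on [0,1], left-closed/right-open,
# last bin right-closed.
.bin_index <- function(d_norm, n_bins) {
  pmin(as.integer(floor(d_norm * n_bins)) + 1L, n_bins)
}

#' Binned firing rate by distance
#'
#' Mean spikes/frame per equal-width normalized-distance bin, with per-bin
#' occupancy (frame counts). Unoccupied bins are `NA`.
#'
#' @param spikes Spike matrix, neurons x frames (nonnegative reals).
#' @param ds A [compute_distance_series()] result aligned to the spikes.
#' @param cfg A [tuning_config()].
#' @return list: `rates` (neurons x bins), `occupancy` (length `n_bins`),
#'   `bin_centers_norm`.
#' @export
bin_firing_by_distance <- function(spikes, ds, cfg = tuning_config()) {
  spikes <- .as_spike_matrix(spikes)
  if (ncol(spikes) != nrow(ds))
    stop(sprintf("alignment error: %d spike frames vs %d distance frames",
                 ncol(spikes), nrow(ds)))
  nb <- cfg$n_bins
  bi <- .bin_index(ds$distance_norm, nb)
  occ <- tabulate(bi, nb)
  # rowsum groups come back in sorted order of unique(bi)
  sums <- matrix(0, nrow(spikes), nb, dimnames = list(rownames(spikes), NULL))
  present <- sort(unique(bi))
  sums[, present] <- t(rowsum(t(spikes), group = bi))
  rates <- sweep(sums, 2, ifelse(occ > 0, occ, 1), "/")
  rates[, occ == 0] <- NA_real_
  list(rates = rates, occupancy = occ,
       bin_centers_norm = (seq_len(nb) - 0.5) / nb)
}

#' Zone of a peak firing distance
#'
#' `pro` if the peak distance is at or inside the inner zone radius, `anti`
#' if strictly beyond the outer radius, `neutral` in between.
#'
#' @param peak_distance_cm Numeric vector of peak distances, cm.
#' @param arena An [arena_spec()] carrying the zone radii.
#' @return Character vector in `{"pro","neutral","anti"}`.
#' @export
classify_peak_zone <- function(peak_distance_cm, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  ifelse(peak_distance_cm <= arena$zone_inner_cm, "pro",
         ifelse(peak_distance_cm > arena$zone_outer_cm, "anti", "neutral"))
}

#' Rotary shuffle of a spike train
#'
#' Circular shift by a random offset drawn uniformly from `{1, ..., T-1}`:
#' element `i` (0-based) moves to `(i + k) mod T`. Preserves the value
#' multiset and the train's autocorrelation while breaking its alignment with
#' behaviour.
#'
#' @param train Numeric vector.
#' @param offset Explicit shift; if `NULL`, drawn from `seed`.
#' @param seed Integer seed (used only when `offset` is `NULL`).
#' @return Shifted vector.
#' @export
rotary_shuffle <- function(train, offset = NULL, seed = NULL) {
  T <- length(train)
  if (T < 2) {
    warning("train of length < 2: returning it unchanged")
    return(train)
  }
  if (is.null(offset)) {
    if (is.null(seed)) stop("provide offset or seed")
    offset <- withr::with_seed(seed, sample.int(T - 1L, 1L))
  }
  k <- offset %% T
  train[((seq_len(T) - 1L - k) %% T) + 1L]
}

# sum_{j in J} x[(j - k) mod T] for every offset k = 0..T-1 at once, via
# circular cross-correlation (FFT); fx = fft(x). Exact up to FFT round-off
# (~1e-12 on these scales), which the callers absorb with a 1e-9 tolerance:
# the exact statistics are ratios of bounded integers whose distinct values
# are separated by far more than that.
.corr_all_offsets <- function(fx, idx, T) {
  ind <- numeric(T); ind[idx] <- 1
  y <- Re(fft(fx * Conj(fft(ind)), inverse = TRUE)) / T
  y[c(1L, T:2L)]                     # reorder to k = 0..T-1
}

# Binned sums of the rotary-shuffled train for all offsets: row b, column
# k+1 holds the bin-b sum of the train shifted by offset k.
.binned_sums_all_offsets <- function(x, bin_idx, n_bins) {
  T <- length(x)
  fx <- fft(x)
  out <- matrix(NA_real_, n_bins, T)
  for (b in seq_len(n_bins)) {
    idx <- which(bin_idx == b)
    if (!length(idx)) next
    out[b, ] <- .corr_all_offsets(fx, idx, T)
  }
  out
}

#' Rotary-shuffle permutation p-values for distance tuning
#'
#' The statistic is the maximum binned mean firing rate over occupied bins.
#' The null rotary-shuffles each neuron's own train `n_shuffles` times
#' against the fixed distance series and recomputes the statistic; the
#' add-one p-value is `(1 + #\{null >= observed\}) / (1 + n_shuffles)`, never
#' exactly 0. A constant (e.g. all-zero) train gives p = 1.
#'
#' @param spikes Spike matrix, neurons x frames.
#' @param ds Aligned [compute_distance_series()].
#' @param cfg A [tuning_config()].
#' @param method `"fft"` (circular cross-correlation over all offsets, then
#'   subset at the sampled offsets) or `"direct"` (explicit shifting);
#'   identical results, `"fft"` is much faster.
#' @return Numeric vector of p-values, one per neuron.
#' @export
tuning_pvalues <- function(spikes, ds, cfg = tuning_config(),
                           method = c("fft", "direct")) {
  method <- match.arg(method)
  spikes <- .as_spike_matrix(spikes)
  T <- ncol(spikes)
  if (T != nrow(ds))
    stop(sprintf("alignment error: %d spike frames vs %d distance frames",
                 T, nrow(ds)))
  nb <- cfg$n_bins
  bi <- .bin_index(ds$distance_norm, nb)
  occ <- tabulate(bi, nb)
  eligible <- .eligible_bins(occ, cfg$min_occupancy)
  el_groups <- which(sort(unique(bi)) %in% which(eligible))
  pv <- numeric(nrow(spikes))
  for (i in seq_len(nrow(spikes))) {
    x <- spikes[i, ]
    obs_sums <- rowsum(x, bi)[, 1]
    obs <- max(obs_sums[el_groups] / occ[eligible])
    offs <- withr::with_seed(
      .neuron_seed(cfg$seed, .neuron_key(rownames(spikes), i)),
      sample.int(T - 1L, cfg$n_shuffles, replace = TRUE))
    if (method == "fft") {
      all_sums <- .binned_sums_all_offsets(x, bi, nb)
      rates <- all_sums[eligible, offs + 1L, drop = FALSE] / occ[eligible]
      null_stat <- apply(rates, 2, max)
    } else {
      null_stat <- vapply(offs, function(k) {
        xs <- x[((seq_len(T) - 1L - k) %% T) + 1L]
        max(rowsum(xs, bi)[el_groups, 1] / occ[eligible])
      }, numeric(1))
    }
    pv[i] <- (1 + sum(null_stat >= obs - 1e-9)) / (1 + cfg$n_shuffles)
  }
  names(pv) <- rownames(spikes)
  pv
}

#' Benjamini-Hochberg significance flags
#'
#' Standard step-up rule at FDR level `q`, via [stats::p.adjust()].
#'
#' @param pvalues Numeric vector in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical vector of rejections.
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH") <= q
}

#' Distance-tuning analysis of a recorded population
#'
#' The central fit: bins each neuron's firing rate into `n_bins` equal-width
#' normalized-distance bins, takes the peak bin as the preferred distance,
#' classifies its zone (pro/neutral/anti) from the arena's zone radii, tests
#' tuning with the rotary-shuffle permutation test and applies BH FDR across
#' the population.
#'
#' @param spikes Spike matrix, neurons x frames (nonnegative reals).
#' @param traj Aligned trajectory.
#' @param arena An [arena_spec()].
#' @param config A [tuning_config()].
#' @return Object of class `"distance_tuning"`: `$results` (per-neuron
#'   data.frame: neuron_id, peak_bin, peak_distance_cm, zone, p_value,
#'   significant), `$rates`, `$occupancy`, `$bin_centers_cm`, `$arena`,
#'   `$config`.
#' @export
distance_tuning <- function(spikes, traj, arena, config = tuning_config()) {
  spikes <- .as_spike_matrix(spikes)
  ds <- compute_distance_series(traj, arena)
  b <- bin_firing_by_distance(spikes, ds, config)
  eligible <- .eligible_bins(b$occupancy, config$min_occupancy)
  rates_el <- b$rates
  rates_el[, !eligible] <- NA_real_
  peak_bin <- apply(rates_el, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)  # first max: nearest bin
  })
  centers_cm <- b$bin_centers_norm * arena$norm_radius_cm
  peak_cm <- centers_cm[peak_bin]
  zone <- classify_peak_zone(peak_cm, arena)
  pv <- tuning_pvalues(spikes, ds, config)
  sig <- bh_adjust(pv, config$fdr_q)
  ids <- rownames(spikes)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(nrow(spikes)))
  res <- data.frame(neuron_id = ids, peak_bin = peak_bin,
                    peak_distance_cm = peak_cm, zone = zone,
                    p_value = pv, significant = sig,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = res, rates = b$rates, occupancy = b$occupancy,
                 bin_centers_cm = centers_cm, arena = arena, config = config),
            class = "distance_tuning")
}

#' @export
print.distance_tuning <- function(x, ...) {
  r <- x$results
  cat(sprintf("Distance tuning: %d neurons, %d bins, %d shuffles\n",
              nrow(r), x$config$n_bins, x$config$n_shuffles))
  cat(sprintf("Significant (BH %.0f%% FDR): %d (%.1f%%)\n",
              100 * x$config$fdr_q, sum(r$significant),
              100 * mean(r$significant)))
  tab <- table(factor(r$zone, levels = c("pro", "neutral", "anti")))
  cat("Zones: ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.distance_tuning <- function(object, ...) {
  r <- object$results
  zt <- table(factor(r$zone, levels = c("pro", "neutral", "anti")))
  out <- list(
    n_neurons = nrow(r),
    n_significant = sum(r$significant),
    pct_significant = 100 * mean(r$significant),
    zone_counts = zt,
    zone_pct = 100 * as.numeric(zt) / nrow(r),
    median_peak_cm = stats::median(r$peak_distance_cm, na.rm = TRUE),
    config = object$config
  )
  class(out) <- "summary.distance_tuning"
  out
}

#' @export
print.summary.distance_tuning <- function(x, ...) {
  cat(sprintf("%d neurons; %d significant (%.1f%%); median peak %.1f cm\n",
              x$n_neurons, x$n_significant, x$pct_significant,
              x$median_peak_cm))
  zp <- sprintf("%s %.1f%%", names(x$zone_counts), x$zone_pct)
  cat("Zone composition:", paste(zp, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.distance_tuning <- function(object, ...) {
  setNames(object$results$peak_distance_cm, object$results$neuron_id)
}

#' Heatmap of binned firing by distance
#'
#' Rows are neurons sorted by peak bin (the standard population display);
#' each row is max-normalized.
#'
#' @param x A [distance_tuning()] fit.
#' @param ... Passed to [graphics::image()].
#' @export
plot.distance_tuning <- function(x, ...) {
  r <- x$rates
  ord <- order(x$results$peak_bin)
  m <- r[ord, , drop = FALSE]
  mx <- apply(m, 1, max, na.rm = TRUE)
  m <- sweep(m, 1, ifelse(mx > 0, mx, 1), "/")
  graphics::image(x = x$bin_centers_cm, y = seq_len(nrow(m)), z = t(m),
                  xlab = "distance to target (cm)",
                  ylab = "neuron (sorted by peak)", ...)
  invisible(x)
}

#' Pooled-resampling population-composition test
#'
#' Tests whether one population's percentage of neurons in a zone differs
#' from what equal-size draws from the pooled populations produce. The null
#' resamples `N` labels (the target population's size) without replacement
#' from the pool `n_shuffles` times; the observed percentage is compared with
#' the empirical tail quantiles at `tail` and `1 - tail`.
#'
#' @param populations Named list of per-neuron zone-label character vectors
#'   (one element per population; the pool is their union).
#' @param target Name (or index) of the tested population.
#' @param zone Zone label whose percentage is tested (e.g. `"pro"`).
#' @param cfg A [tuning_config()] (`n_shuffles`, `tail`, `seed` are used).
#' @return Object of class `"composition_test"`: observed_pct, null_pct
#'   (vector), lower/upper thresholds, verdict in `{"above","below","ns"}`,
#'   n_selected.
#' @export
composition_test <- function(populations, target, zone,
                             cfg = tuning_config()) {
  stopifnot(is.list(populations))
  pool <- unlist(populations, use.names = FALSE)
  tgt <- populations[[target]]
  N <- length(tgt)
  if (N > length(pool)) stop("target population larger than the pool")
  observed <- 100 * mean(tgt == zone)
  is_zone <- pool == zone
  null_pct <- withr::with_seed(cfg$seed, vapply(seq_len(cfg$n_shuffles),
    function(i) 100 * mean(is_zone[sample.int(length(pool), N)]),
    numeric(1)))
  lo <- unname(quantile(null_pct, cfg$tail, type = 1))
  hi <- unname(quantile(null_pct, 1 - cfg$tail, type = 1))
  verdict <- if (observed > hi) "above" else if (observed < lo) "below" else "ns"
  structure(list(observed_pct = observed, null_pct = null_pct,
                 lower = lo, upper = hi, verdict = verdict, tail = cfg$tail,
                 n_selected = N, zone = zone,
                 target = if (is.character(target)) target else names(populations)[target]),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("Composition test (%s, zone '%s'): observed %.1f%%\n",
              x$target, x$zone, x$observed_pct))
  cat(sprintf("Null [%.1f, %.1f]%% (2 x %.1f%% tails) -> %s\n",
              x$lower, x$upper, 100 * x$tail, x$verdict))
  invisible(x)
}

# Coerce to a numeric matrix of nonnegative spikes.
.as_spike_matrix <- function(spikes) {
  m <- spikes
  if (inherits(m, "spike_matrix")) class(m) <- setdiff(class(m), "spike_matrix")
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("spike matrix has negative entries")
  m
}
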