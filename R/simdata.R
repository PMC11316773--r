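#' @importFrom stats rnorm rpois rnbinom runif quantile sd cor fft p.adjust
#'   prcomp lm coef dist hclust as.dist setNames aggregate pt var complete.cases
NULL

# Canonical BLA parcellation used throughout: eight subregions over four
# coronal sections (anterior to posterior).
#' Eight BLA subregion labels, anterior to posterior
#' @export
BLA_SUBREGIONS <- c("aLA", "pLA", "ppLA", "amBA", "alBA", "acBA", "pBA", "ppBA")

#' Four coronal section labels
#' @export
BLA_SECTIONS <- c("anterior", "anterior-middle", "posterior-middle", "posterior")

# Default section membership of each subregion (anterior to posterior order).
.SUBREGION_SECTION <- c(
  aLA = "anterior", amBA = "anterior", alBA = "anterior",
  pLA = "anterior-middle", acBA = "anterior-middle",
  pBA = "posterior-middle",
  ppLA = "posterior", ppBA = "posterior"
)

#' Event timeline constructor
#'
#' @param onset_s,offset_s Numeric vectors of interval bounds, seconds.
#' @param label Character vector; typically `"shock"`, `"social"` or
#'   `"freezing"`.
#' @return A data.frame of class `"event_timeline"`.
#' @export
event_timeline <- function(onset_s, offset_s, label) {
  stopifnot(length(onset_s) == length(offset_s), length(label) %in% c(1L, length(onset_s)))
  if (any(!is.finite(onset_s)) || any(!is.finite(offset_s)))
    stop("event bounds must be finite")
  if (any(onset_s >= offset_s)) stop("every event needs onset_s < offset_s")
  ev <- data.frame(onset_s = onset_s, offset_s = offset_s,
                   label = rep_len(as.character(label), length(onset_s)),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$label, ev$onset_s), , drop = FALSE]
  for (lb in unique(ev$label)) {
    e <- ev[ev$label == lb, ]
    if (nrow(e) > 1 && any(e$onset_s[-1] < e$offset_s[-nrow(e)]))
      stop(sprintf("overlapping '%s' events", lb))
  }
  rownames(ev) <- NULL
  class(ev) <- c("event_timeline", "data.frame")
  ev
}

#' Ground-truth table for simulated neurons
#'
#' One row per neuron. `preferred_distance_norm` is the normalized distance at
#' which a tuned neuron's rate peaks; `amplitude` and `baseline` are in
#' spikes/frame; `event_gain` is the multiplicative rate gain inside event
#' windows for responder neurons.
#'
#' @param n_neurons Number of neurons.
#' @param tuned Logical vector (recycled).
#' @param preferred_distance_norm Numeric in \[0, 1\] (recycled).
#' @param amplitude,baseline Nonnegative rates, spikes/frame (recycled).
#' @param responder Logical vector (recycled).
#' @param event_gain Nonnegative gain (recycled).
#' @return A data.frame of class `"sim_truth"`.
#' @export
sim_truth <- function(n_neurons, tuned = FALSE, preferred_distance_norm = 0.5,
                      amplitude = 0, baseline = 0.2,
                      responder = FALSE, event_gain = 1) {
  tr <- data.frame(
    neuron_id = sprintf("n%03d", seq_len(n_neurons)),
    tuned = rep_len(tuned, n_neurons),
    preferred_distance_norm = rep_len(preferred_distance_norm, n_neurons),
    amplitude = rep_len(amplitude, n_neurons),
    baseline = rep_len(baseline, n_neurons),
    responder = rep_len(responder, n_neurons),
    event_gain = rep_len(event_gain, n_neurons),
    stringsAsFactors = FALSE
  )
  if (any(tr$baseline < 0) || any(tr$amplitude < 0))
    stop("baseline and amplitude must be nonnegative")
  if (any(tr$preferred_distance_norm < 0 | tr$preferred_distance_norm > 1))
    stop("preferred_distance_norm must lie in [0, 1]")
  class(tr) <- c("sim_truth", "data.frame")
  tr
}

#' Simulate an arena trajectory
#'
#' Reflected Gaussian random walk at a fixed frame rate: each step adds
#' isotropic Gaussian noise to the position and reflects at the arena boundary,
#' so long runs occupy all distance bins. The heading of each frame is the
#' direction of the displacement into that frame (degrees counter-clockwise
#' from the +x axis).
#'
#' @param arena An [arena_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param step_sd_cm Per-frame step standard deviation, cm (> 0).
#' @param seed Integer seed; the generator is a pure function of its arguments.
#' @param frame_rate_hz Frames per second (default 15).
#' @return A data.frame of class `"trajectory"` with columns `frame_index`
#'   (0-based), `x_cm`, `y_cm`, `heading_deg` and attribute `frame_rate_hz`.
#' @export
gen_trajectory <- function(arena, n_frames, step_sd_cm, seed,
                           frame_rate_hz = 15) {
  stopifnot(inherits(arena, "arena_spec"))
  if (!is.numeric(n_frames) || n_frames < 1) stop("n_frames must be >= 1")
  if (!is.numeric(step_sd_cm) || step_sd_cm <= 0) stop("step_sd_cm must be > 0")
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0")
  n_frames <- as.integer(n_frames)
  withr::with_seed(seed, {
    dx <- rnorm(n_frames - 1, 0, step_sd_cm)
    dy <- rnorm(n_frames - 1, 0, step_sd_cm)
  })
  x <- numeric(n_frames); y <- numeric(n_frames)
  x[1] <- arena$center_x_cm; y[1] <- arena$center_y_cm
  for (i in seq_len(n_frames - 1L)) {
    p <- .arena_reflect(arena, x[i] + dx[i], y[i] + dy[i])
    x[i + 1L] <- p$x; y[i + 1L] <- p$y
  }
  heading <- rep(0, n_frames)
  if (n_frames > 1) {
    hx <- diff(x); hy <- diff(y)
    h <- atan2(hy, hx) * 180 / pi
    moved <- hx != 0 | hy != 0
    # frozen frames keep the previous heading
    for (i in seq_along(h)) if (!moved[i]) h[i] <- if (i > 1) h[i - 1] else 0
    heading <- c(h[1], h)
  }
  traj <- data.frame(frame_index = 0:(n_frames - 1L),
                     x_cm = x, y_cm = y, heading_deg = heading)
  attr(traj, "frame_rate_hz") <- frame_rate_hz
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Frame rate of a trajectory or explicit value
#' @param traj A trajectory.
#' @return Frames per second.
#' @export
frame_rate <- function(traj) {
  fr <- attr(traj, "frame_rate_hz")
  if (is.null(fr)) stop("trajectory has no frame_rate_hz attribute")
  fr
}

# Gaussian distance-tuned rate, spikes/frame.
.tuned_rate <- function(d_norm, baseline, amplitude, d0, sigma) {
  baseline + amplitude * exp(-(d_norm - d0)^2 / (2 * sigma^2))
}

#' Simulate distance-tuned Poisson spike trains
#'
#' Per-frame rate is `baseline + amplitude * exp(-(d - d0)^2 / (2 sigma^2))`
#' in normalized distance `d` to the arena target; counts are Poisson.
#'
#' @param traj A [gen_trajectory()] output (or compatible data.frame).
#' @param arena The [arena_spec()] the trajectory lives in.
#' @param truth A [sim_truth()] table, one row per neuron.
#' @param seed Integer seed.
#' @param tuning_sd Gaussian tuning width in normalized distance (default 0.1).
#' @return Numeric matrix neurons x frames of class `"spike_matrix"` (integer
#'   counts; downstream analyses accept any nonnegative reals).
#' @export
gen_tuned_spikes <- function(traj, arena, truth, seed, tuning_sd = 0.1) {
  stopifnot(inherits(truth, "data.frame"))
  ds <- compute_distance_series(traj, arena)
  n_frames <- nrow(traj)
  rate <- matrix(0, nrow(truth), n_frames)
  for (i in seq_len(nrow(truth))) {
    amp <- if (truth$tuned[i]) truth$amplitude[i] else 0
    rate[i, ] <- .tuned_rate(ds$distance_norm, truth$baseline[i], amp,
                             truth$preferred_distance_norm[i], tuning_sd)
  }
  withr::with_seed(seed, {
    spk <- matrix(rpois(length(rate), rate), nrow(truth), n_frames)
  })
  rownames(spk) <- truth$neuron_id
  class(spk) <- c("spike_matrix", class(spk))
  spk
}

#' Simulate event-locked Poisson spike trains
#'
#' Constant baseline rate with a multiplicative gain inside event windows:
#' planted responders for the shock-response analyses.
#'
#' @param n_frames Number of frames.
#' @param frame_rate_hz Frames per second.
#' @param events An [event_timeline()].
#' @param baseline Baseline rate, spikes/frame.
#' @param gain Multiplicative rate gain inside events (>= 0); 1 = no response.
#' @param seed Integer seed.
#' @param n_neurons Number of identically distributed neurons (default 1).
#' @return A `"spike_matrix"` of Poisson counts.
#' @export
gen_event_spikes <- function(n_frames, frame_rate_hz, events, baseline, gain,
                             seed, n_neurons = 1) {
  if (gain < 0) stop("gain must be >= 0")
  if (baseline < 0) stop("baseline must be >= 0")
  n_frames <- as.integer(n_frames)
  span_s <- n_frames / frame_rate_hz
  if (any(events$offset_s > span_s + 1e-9) || any(events$onset_s < 0))
    stop("events fall outside the recording span")
  in_event <- rep(FALSE, n_frames)
  for (k in seq_len(nrow(events))) {
    i0 <- floor(events$onset_s[k] * frame_rate_hz)
    i1 <- ceiling(events$offset_s[k] * frame_rate_hz) - 1L
    in_event[(i0:i1) + 1L] <- TRUE
  }
  rate <- ifelse(in_event, baseline * gain, baseline)
  withr::with_seed(seed, {
    spk <- matrix(rpois(n_neurons * n_frames, rep(rate, each = n_neurons)),
                  n_neurons, n_frames)
  })
  rownames(spk) <- sprintf("n%03d", seq_len(n_neurons))
  attr(spk, "in_event") <- in_event
  class(spk) <- c("spike_matrix", class(spk))
  spk
}

#' Simulate a labelled expression matrix from cluster profiles
#'
#' Negative-binomial counts around per-cluster mean profiles; the dispersion
#' parameter is the NB `size` (larger = closer to Poisson).
#'
#' @param profiles A [cluster_profile()] (scaled rows are used as relative
#'   means).
#' @param n_cells_per_cluster Cells per cluster.
#' @param library_scale Multiplier mapping scaled profile values to mean
#'   counts.
#' @param dispersion NB size parameter (> 0).
#' @param seed Integer seed.
#' @return A list with `expr` (an [expression_matrix()]) and `truth`
#'   (data.frame `cell_id`, `cluster`).
#' @export
gen_expression <- function(profiles, n_cells_per_cluster, library_scale = 50,
                           dispersion = 10, seed = 1) {
  stopifnot(inherits(profiles, "cluster_profile"))
  if (dispersion <= 0) stop("dispersion must be > 0")
  P <- profiles$scaled
  if (nrow(P) == 0 || ncol(P) == 0) stop("empty cluster profile")
  clusters <- rownames(P); genes <- colnames(P)
  n_cells <- n_cells_per_cluster * length(clusters)
  if (n_cells == 0) {
    counts <- matrix(0L, 0, length(genes), dimnames = list(NULL, genes))
    return(list(expr = expression_matrix(counts, character(0)),
                truth = data.frame(cell_id = character(0), cluster = character(0))))
  }
  lab <- rep(clusters, each = n_cells_per_cluster)
  mu <- library_scale * P[lab, , drop = FALSE]
  withr::with_seed(seed, {
    counts <- matrix(rnbinom(length(mu), size = dispersion, mu = as.vector(mu)),
                     nrow(mu), ncol(mu))
  })
  dimnames(counts) <- list(sprintf("c%05d", seq_len(n_cells)), genes)
  truth <- data.frame(cell_id = rownames(counts), cluster = lab,
                      stringsAsFactors = FALSE)
  list(expr = expression_matrix(counts, lab), truth = truth)
}

#' Default rectangular layout of the eight BLA subregions
#'
#' Subregions are laid out as side-by-side 800 x 800 um tiles within their
#' coronal section; purely a synthetic stand-in for real anatomy.
#'
#' @param tile_um Tile side length, um.
#' @return data.frame: subregion, section, x0_um, y0_um, x1_um, y1_um.
#' @export
subregion_tiles <- function(tile_um = 800) {
  sec <- .SUBREGION_SECTION[BLA_SUBREGIONS]
  off <- unlist(lapply(split(seq_along(sec), sec)[unique(sec)], seq_along))
  ord <- unlist(split(seq_along(sec), sec)[unique(sec)])
  x0 <- numeric(length(sec)); x0[ord] <- (off - 1) * tile_um
  data.frame(subregion = BLA_SUBREGIONS, section = unname(sec),
             x0_um = x0, y0_um = 0, x1_um = x0 + tile_um, y1_um = tile_um,
             stringsAsFactors = FALSE)
}

#' Simulate an smFISH cell table over the eight BLA subregions
#'
#' Cells are placed uniformly in rectangular subregion tiles across the four
#' coronal sections; each cell draws a true transcriptomic cluster from its
#' subregion's mixture row and its per-gene raw values from the cluster's
#' scaled profile times `library_scale`, plus optional Gaussian noise
#' (truncated at zero).
#'
#' @param profiles A [cluster_profile()].
#' @param layout Numeric matrix subregions x clusters of mixture weights; rows
#'   must sum to 1 (tolerance 1e-9). Rownames must be subregion labels,
#'   colnames cluster ids present in `profiles`.
#' @param n_cells Total number of cells; allocated to subregions roughly
#'   equally.
#' @param noise_sd Gaussian noise SD added to raw values.
#' @param seed Integer seed.
#' @param library_scale Multiplier mapping scaled profiles to raw values.
#' @return list with `cells` (a `"fish_cells"` data.frame) and `truth`
#'   (data.frame `cell_id`, `cluster`).
#' @export
gen_fish_dataset <- function(profiles, layout, n_cells, noise_sd = 0, seed = 1,
                             library_scale = 20) {
  stopifnot(inherits(profiles, "cluster_profile"))
  layout <- as.matrix(layout)
  if (is.null(rownames(layout)) || !all(rownames(layout) %in% BLA_SUBREGIONS))
    stop("layout rownames must be BLA subregion labels")
  if (!all(colnames(layout) %in% rownames(profiles$scaled)))
    stop("layout clusters missing from profiles")
  if (any(abs(rowSums(layout) - 1) > 1e-9))
    stop("each layout row must sum to 1")
  tiles <- subregion_tiles()
  rownames(tiles) <- tiles$subregion
  genes <- colnames(profiles$scaled)
  subs <- rep(rownames(layout), length.out = n_cells)
  withr::with_seed(seed, {
    u1 <- runif(n_cells); u2 <- runif(n_cells); u3 <- runif(n_cells)
    noise <- matrix(rnorm(n_cells * length(genes), 0, noise_sd),
                    n_cells, length(genes))
  })
  t <- tiles[subs, , drop = FALSE]
  x <- t$x0_um + u1 * (t$x1_um - t$x0_um)
  y <- t$y0_um + u2 * (t$y1_um - t$y0_um)
  # inverse-CDF draw of the true cluster from each subregion's mixture row
  cl <- character(n_cells)
  for (i in seq_len(n_cells)) {
    p <- cumsum(layout[subs[i], ])
    cl[i] <- colnames(layout)[which(u3[i] <= p + 1e-12)[1]]
  }
  raw <- library_scale * profiles$scaled[cl, , drop = FALSE] + noise
  raw[raw < 0] <- 0
  cells <- data.frame(cell_id = sprintf("f%05d", seq_len(n_cells)),
                      section = t$section, subregion = subs,
                      x_um = x, y_um = y, stringsAsFactors = FALSE)
  cells <- cbind(cells, as.data.frame(raw, row.names = NULL))
  attr(cells, "genes") <- genes
  class(cells) <- c("fish_cells", "data.frame")
  list(cells = cells,
       truth = data.frame(cell_id = cells$cell_id, cluster = cl,
                          stringsAsFactors = FALSE))
}
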