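#' @importFrom utils read.delim write.table packageVersion
NULL

# Canonical interchange: tab-separated UTF-8 text, '.' decimal, units in
# column names, 0-based frame indices.
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}
.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a trajectory table
#'
#' Columns: `frame_index` (0-based, contiguous), `x_cm`, `y_cm`, optional
#' `heading_deg`; the frame rate travels in a `# frame_rate_hz:` header line.
#'
#' @param traj A trajectory data.frame.
#' @param path File path.
#' @return `read_trajectory()` returns the validated trajectory.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(sprintf("# frame_rate_hz: %.10g", frame_rate(traj)), con)
  close(con)
  suppressWarnings(write.table(as.data.frame(traj), path, sep = "\t",
                               quote = FALSE, row.names = FALSE,
                               append = TRUE, fileEncoding = "UTF-8"))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1)
  fr <- 15
  skip <- 0
  if (startsWith(hdr, "#")) {
    fr <- as.numeric(sub(".*frame_rate_hz:\\s*", "", hdr))
    skip <- 1
  }
  df <- read.delim(path, sep = "\t", skip = skip, stringsAsFactors = FALSE)
  need <- c("frame_index", "x_cm", "y_cm")
  if (!all(need %in% colnames(df)))
    stop("trajectory file must have columns ", paste(need, collapse = ", "))
  if (!identical(as.integer(df$frame_index), 0:(nrow(df) - 1L)))
    stop("frame_index must be contiguous from 0")
  if (any(!is.finite(df$x_cm)) || any(!is.finite(df$y_cm)))
    stop("positions must be finite")
  attr(df, "frame_rate_hz") <- fr
  class(df) <- c("trajectory", "data.frame")
  df
}

#' Write / read a spike matrix
#'
#' Wide table: `neuron_id` column then one `f<k>` column per frame (0-based).
#' Values must be nonnegative; a violation is reported with its row and
#' column.
#'
#' @param spikes Numeric matrix neurons x frames.
#' @param path File path.
#' @return `read_spike_matrix()` returns the matrix with neuron-id rownames.
#' @export
write_spike_matrix <- function(spikes, path) {
  m <- .as_spike_matrix(spikes)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(nrow(m)))
  df <- data.frame(neuron_id = ids, m, check.names = FALSE)
  colnames(df)[-1] <- sprintf("f%d", 0:(ncol(m) - 1L))
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_spike_matrix
#' @export
read_spike_matrix <- function(path) {
  df <- .read_tsv(path)
  if (colnames(df)[1] != "neuron_id")
    stop("spike file must start with a neuron_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative spike value at neuron '%s', frame column '%s'",
                 df$neuron_id[bad[1]], colnames(df)[-1][bad[2]]))
  }
  rownames(m) <- df$neuron_id
  class(m) <- c("spike_matrix", class(m))
  m
}

#' Write / read an event timeline
#'
#' Columns `onset_s`, `offset_s`, `label`.
#' @param events An [event_timeline()].
#' @param path File path.
#' @return `read_events()` returns a validated [event_timeline()].
#' @export
write_events <- function(events, path) {
  .write_tsv(as.data.frame(events), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- .read_tsv(path)
  event_timeline(df$onset_s, df$offset_s, df$label)
}

#' Write / read an smFISH cell table
#'
#' Columns: `cell_id`, `section`, `subregion`, `x_um`, `y_um`, one raw-value
#' column per gene, and optional logical `pos_<gene>` flag columns.
#'
#' @param cells A `"fish_cells"` data.frame.
#' @param path File path.
#' @return `read_fish_cells()` returns the validated table.
#' @export
write_fish_cells <- function(cells, path) {
  .write_tsv(as.data.frame(cells), path)
  invisible(path)
}

#' @rdname write_fish_cells
#' @export
read_fish_cells <- function(path) {
  df <- .read_tsv(path)
  need <- c("cell_id", "section", "subregion", "x_um", "y_um")
  if (!all(need %in% colnames(df)))
    stop("fish cell file must have columns ", paste(need, collapse = ", "))
  if (!all(df$subregion %in% BLA_SUBREGIONS))
    stop("unknown subregion label(s)")
  if (!all(df$section %in% BLA_SECTIONS))
    stop("unknown section label(s)")
  genes <- setdiff(colnames(df), need)
  genes <- genes[!startsWith(genes, "pos_")]
  pos_cols <- colnames(df)[startsWith(colnames(df), "pos_")]
  for (pc in pos_cols) df[[pc]] <- as.logical(df[[pc]])
  attr(df, "genes") <- genes
  class(df) <- c("fish_cells", "data.frame")
  df
}

#' Read a labelled expression matrix
#'
#' Either a dense delimited table (rows = cells, a `cell_id` column, a
#' `cluster` column, remaining columns = genes) or a Matrix-Market sparse
#' triplet (`.mtx`, cells x genes) plus plain-text id/label files.
#'
#' @param path Dense TSV path, or `.mtx` path when `genes_path` is given.
#' @param genes_path,cells_path One id per line (for `.mtx` input).
#' @param clusters_path One cluster label per cell per line (for `.mtx`
#'   input).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, genes_path = NULL, cells_path = NULL,
                            clusters_path = NULL) {
  if (!is.null(genes_path)) {
    m <- as.matrix(Matrix::readMM(path))
    colnames(m) <- readLines(genes_path)
    rownames(m) <- if (!is.null(cells_path)) readLines(cells_path)
                   else sprintf("c%05d", seq_len(nrow(m)))
    cl <- readLines(clusters_path)
    return(expression_matrix(m, cl))
  }
  df <- .read_tsv(path)
  if (!all(c("cell_id", "cluster") %in% colnames(df)))
    stop("dense expression table needs cell_id and cluster columns")
  genes <- setdiff(colnames(df), c("cell_id", "cluster"))
  m <- as.matrix(df[, genes, drop = FALSE])
  rownames(m) <- df$cell_id
  expression_matrix(m, df$cluster)
}

#' Write a dense labelled expression table
#' @param expr An [expression_matrix()].
#' @param path File path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(cell_id = rownames(expr$counts), cluster = expr$clusters,
                   expr$counts, check.names = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Load an aligned recording session
#'
#' Reads the trajectory, spike matrix and (optionally) events of one session
#' and checks frame alignment and event span.
#'
#' @param trajectory_path,spikes_path,events_path File paths (`events_path`
#'   may be `NULL`).
#' @return list: `traj`, `spikes`, `events` (or `NULL`).
#' @export
load_session <- function(trajectory_path, spikes_path, events_path = NULL) {
  traj <- read_trajectory(trajectory_path)
  spikes <- read_spike_matrix(spikes_path)
  if (ncol(spikes) != nrow(traj))
    stop(sprintf("alignment error: %d spike frames vs %d trajectory frames",
                 ncol(spikes), nrow(traj)))
  events <- NULL
  if (!is.null(events_path)) {
    events <- read_events(events_path)
    span <- nrow(traj) / frame_rate(traj)
    if (any(events$offset_s > span + 1e-9))
      stop("events extend past the recording span")
  }
  list(traj = traj, spikes = spikes, events = events)
}

#' Default pipeline configuration
#'
#' A fully populated configuration for an end-to-end synthetic run; any field
#' can be overridden from a YAML file with the same structure. Zone radii
#' default to the feeding convention (5/17 cm); the social convention is
#' 10/20 cm.
#'
#' @return Nested list understood by [run_pipeline()].
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    outdir = "blamap-run",
    stages = c("simulate", "markers", "spatial", "tuning", "events"),
    arena = list(shape = "rectangle", width_cm = 40, height_cm = 40,
                 target_x_cm = -12, target_y_cm = -12,
                 norm_radius_cm = 20, zone_inner_cm = 5, zone_outer_cm = 17),
    simulate = list(n_frames = 9000, frame_rate_hz = 15, step_sd_cm = 1.5,
                    n_neurons = 30, frac_tuned = 0.3, baseline = 0.2,
                    amplitude = 0.6, tuning_sd = 0.1,
                    n_clusters = 5, n_genes = 10, n_cells_per_cluster = 60,
                    library_scale = 50, dispersion = 10,
                    n_fish_cells = 400, fish_noise_sd = 1,
                    shock_onsets_s = c(198, 278, 358), shock_duration_s = 2,
                    event_baseline = 0.3, event_gain = 3),
    tuning = list(n_bins = 31, n_shuffles = 1000, fdr_q = 0.05, tail = 0.025),
    spatial = list(neighbor_radius_um = 50, pixel_size_um = 50,
                   smoothing_sigma_px = 1, threshold_method = "otsu"),
    markers = list(auc_min = 0.5, pct_in_min = 20, pct_out_max = 20, top_n = 5)
  )
}

.check_config <- function(config) {
  base <- default_run_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(base[[k]]))
      if (length(bad))
        stop(sprintf("unknown config key(s) under '%s': %s", k,
                     paste(bad, collapse = ", ")))
      base[[k]][names(config[[k]])] <- config[[k]]
    } else base[[k]] <- config[[k]]
  }
  tx <- base$arena$target_x_cm; ty <- base$arena$target_y_cm
  if (!is.numeric(tx) || !is.numeric(ty) || anyNA(c(tx, ty)))
    stop("config error: arena target missing")
  base
}

#' Run the full synthetic-data pipeline
#'
#' Executes the requested stages (simulate, markers, spatial, tuning, events)
#' on seeded synthetic data, writes every result as a TSV under the output
#' directory, and records a JSON run manifest (inputs, seeds, thresholds,
#' package version). Identical config + seed reproduce every output
#' byte-for-byte.
#'
#' @param config A nested list (see [default_run_config()]) or the path of a
#'   YAML file with the same structure. Unknown keys are rejected.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .check_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  sim <- cfg$simulate
  arena <- do.call(arena_spec, cfg$arena)
  tcfg <- tuning_config(cfg$tuning$n_bins, cfg$tuning$n_shuffles,
                        cfg$tuning$fdr_q, cfg$tuning$tail, seed = cfg$seed)
  scfg <- spatial_config(cfg$spatial$neighbor_radius_um,
                         cfg$spatial$pixel_size_um,
                         cfg$spatial$smoothing_sigma_px,
                         cfg$spatial$threshold_method)

  if ("simulate" %in% cfg$stages) {
    message("stage: simulate")
    traj <- gen_trajectory(arena, sim$n_frames, sim$step_sd_cm,
                           seed = cfg$seed, frame_rate_hz = sim$frame_rate_hz)
    n_tuned <- round(sim$frac_tuned * sim$n_neurons)
    truth <- sim_truth(sim$n_neurons,
                       tuned = rep(c(TRUE, FALSE),
                                   c(n_tuned, sim$n_neurons - n_tuned)),
                       preferred_distance_norm =
                         seq(0.05, 0.95, length.out = sim$n_neurons),
                       amplitude = sim$amplitude, baseline = sim$baseline)
    spikes <- gen_tuned_spikes(traj, arena, truth, seed = cfg$seed + 1,
                               tuning_sd = sim$tuning_sd)
    events <- event_timeline(sim$shock_onsets_s,
                             sim$shock_onsets_s + sim$shock_duration_s,
                             "shock")
    ev_spikes <- gen_event_spikes(sim$n_frames, sim$frame_rate_hz, events,
                                  sim$event_baseline, sim$event_gain,
                                  seed = cfg$seed + 2,
                                  n_neurons = sim$n_neurons)
    profs <- cluster_profile(.demo_profiles(sim$n_clusters, sim$n_genes))
    expr <- gen_expression(profs, sim$n_cells_per_cluster, sim$library_scale,
                           sim$dispersion, seed = cfg$seed + 3)
    layout <- .demo_layout(rownames(profs$scaled))
    fish <- gen_fish_dataset(profs, layout, sim$n_fish_cells,
                             noise_sd = sim$fish_noise_sd, seed = cfg$seed + 4)
    write_trajectory(traj, file.path(cfg$outdir, "trajectory.tsv"))
    write_spike_matrix(spikes, file.path(cfg$outdir, "spikes.tsv"))
    write_spike_matrix(ev_spikes, file.path(cfg$outdir, "event_spikes.tsv"))
    write_events(events, file.path(cfg$outdir, "events.tsv"))
    write_expression(expr$expr, file.path(cfg$outdir, "expression.tsv"))
    write_fish_cells(fish$cells, file.path(cfg$outdir, "fish_cells.tsv"))
    .write_tsv(expr$truth, file.path(cfg$outdir, "truth_cells.tsv"))
    .write_tsv(fish$truth, file.path(cfg$outdir, "truth_fish.tsv"))
    .write_tsv(as.data.frame(truth), file.path(cfg$outdir, "truth_neurons.tsv"))
    out$sim <- list(traj = traj, spikes = spikes, ev_spikes = ev_spikes,
                    events = events, expr = expr$expr, profiles = profs,
                    fish = fish, truth = truth)
  }

  if ("markers" %in% cfg$stages) {
    message("stage: markers")
    expr <- out$sim$expr %||%
      read_expression(file.path(cfg$outdir, "expression.tsv"))
    mk <- compute_auc_markers(expr, cfg$markers$auc_min, cfg$markers$pct_in_min,
                              cfg$markers$pct_out_max, cfg$markers$top_n)
    .write_tsv(mk, file.path(cfg$outdir, "markers.tsv"))
    prof <- aggregate_profiles(expr)
    .write_tsv(data.frame(cluster = rownames(prof$scaled), prof$scaled,
                          check.names = FALSE),
               file.path(cfg$outdir, "cluster_profiles_scaled.tsv"))
    out$markers <- mk; out$profiles <- prof
  }

  if ("spatial" %in% cfg$stages) {
    message("stage: spatial")
    cells <- if (!is.null(out$sim)) out$sim$fish$cells
             else read_fish_cells(file.path(cfg$outdir, "fish_cells.tsv"))
    prof <- out$profiles %||% out$sim$profiles
    cells <- call_positive_cells(cells, scfg)
    fr <- subregion_fractions(cells)
    .write_tsv(data.frame(subregion = rownames(fr), unclass(fr),
                          n_cells = attr(fr, "n_cells"), check.names = FALSE),
               file.path(cfg$outdir, "subregion_fractions.tsv"))
    feats <- local_normalize(cells, scfg)
    asg <- assign_cells_to_clusters(feats, prof)
    .write_tsv(asg, file.path(cfg$outdir, "cell_assignments.tsv"))
    ei <- compute_eigen_images(cells, scfg, section = cells$section[1])
    .write_tsv(data.frame(pc = seq_along(ei$variance_fraction),
                          variance_fraction = ei$variance_fraction),
               file.path(cfg$outdir, "eigen_variance.tsv"))
    out$spatial <- list(cells = cells, fractions = fr, assignments = asg,
                        eigen = ei)
  }

  if ("tuning" %in% cfg$stages) {
    message("stage: tuning")
    traj <- out$sim$traj %||% read_trajectory(file.path(cfg$outdir, "trajectory.tsv"))
    spikes <- out$sim$spikes %||% read_spike_matrix(file.path(cfg$outdir, "spikes.tsv"))
    fit <- distance_tuning(spikes, traj, arena, tcfg)
    .write_tsv(fit$results, file.path(cfg$outdir, "tuning.tsv"))
    out$tuning <- fit
  }

  if ("events" %in% cfg$stages) {
    message("stage: events")
    ev_spikes <- out$sim$ev_spikes %||%
      read_spike_matrix(file.path(cfg$outdir, "event_spikes.tsv"))
    events <- out$sim$events %||% read_events(file.path(cfg$outdir, "events.tsv"))
    resp <- classify_shock_responders(ev_spikes, events, sim$frame_rate_hz, tcfg)
    .write_tsv(resp$results, file.path(cfg$outdir, "shock_responses.tsv"))
    out$events <- resp
  }

  manifest <- list(
    package = "blamap",
    version = as.character(packageVersion("blamap")),
    seed = cfg$seed,
    stages = cfg$stages,
    config = cfg,
    outputs = list.files(cfg$outdir, pattern = "\\.tsv$")
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Well-separated demo cluster profiles: each cluster peaks on its own genes.
.demo_profiles <- function(n_clusters, n_genes) {
  m <- matrix(1, n_clusters, n_genes,
              dimnames = list(sprintf("cl%d", seq_len(n_clusters)),
                              sprintf("g%02d", seq_len(n_genes))))
  for (k in seq_len(n_clusters)) {
    own <- which((seq_len(n_genes) - 1L) %% n_clusters == (k - 1L))
    m[k, own] <- 10
  }
  m
}

# Demo subregion -> cluster mixture: cycle clusters over the 8 subregions.
.demo_layout <- function(clusters) {
  L <- matrix(0, length(BLA_SUBREGIONS), length(clusters),
              dimnames = list(BLA_SUBREGIONS, clusters))
  for (i in seq_along(BLA_SUBREGIONS))
    L[i, ((i - 1L) %% length(clusters)) + 1L] <- 1
  L
}
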