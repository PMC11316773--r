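#' Spatial analysis configuration
#'
#' @param neighbor_radius_um Radius of the local normalization neighbourhood,
#'   um (default 50, boundary inclusive, self included).
#' @param pixel_size_um Pixel size for eigen-image rasterization, um
#'   (default 50).
#' @param smoothing_sigma_px Gaussian smoothing SD in pixels for eigen-images
#'   (default 1).
#' @param threshold_method Positive-cell threshold rule: `"otsu"` (between-
#'   class variance on log1p values, default), `"quantile"` or `"fixed"`.
#' @param fixed_thresholds Named numeric vector of raw-scale thresholds, one
#'   per gene (method `"fixed"`).
#' @param quantile_prob Probability for method `"quantile"` (default 0.9, on
#'   log1p values).
#' @return An object of class `"spatial_config"`.
#' @export
spatial_config <- function(neighbor_radius_um = 50, pixel_size_um = 50,
                           smoothing_sigma_px = 1.0,
                           threshold_method = c("otsu", "quantile", "fixed"),
                           fixed_thresholds = NULL, quantile_prob = 0.9) {
  if (neighbor_radius_um <= 0 || pixel_size_um <= 0)
    stop("radii and pixel size must be > 0")
  structure(list(neighbor_radius_um = neighbor_radius_um,
                 pixel_size_um = pixel_size_um,
                 smoothing_sigma_px = smoothing_sigma_px,
                 threshold_method = match.arg(threshold_method),
                 fixed_thresholds = fixed_thresholds,
                 quantile_prob = quantile_prob),
            class = "spatial_config")
}

.fish_genes <- function(cells) {
  g <- attr(cells, "genes")
  if (is.null(g)) {
    g <- setdiff(colnames(cells),
                 c("cell_id", "section", "subregion", "x_um", "y_um"))
    g <- g[!startsWith(g, "pos_")]
  }
  g
}

#' Otsu threshold for a numeric vector
#'
#' Exhaustive search over midpoints between sorted unique values, maximizing
#' the between-class variance of the induced two-group split.
#'
#' @param v Numeric vector.
#' @return Threshold (classify as positive when value > threshold), or 0 if
#'   `v` has fewer than two distinct values.
#' @export
otsu_threshold <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2) return(0)
  cand <- (u[-1] + u[-length(u)]) / 2
  n <- length(v)
  bcv <- vapply(cand, function(th) {
    hi <- v > th
    w1 <- mean(hi); w0 <- 1 - w1
    if (w1 == 0 || w0 == 0) return(0)
    w0 * w1 * (mean(v[hi]) - mean(v[!hi]))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

#' Call gene-positive cells
#'
#' Computes a per-gene threshold (Otsu or quantile on log1p raw values, or a
#' user-fixed raw-scale value) and flags a cell positive for a gene when its
#' raw value strictly exceeds the threshold. Replaces the double-blind visual
#' thresholding of the original workflow with a reproducible automatic rule.
#'
#' @param cells A `"fish_cells"` data.frame (see [gen_fish_dataset()] or
#'   [read_fish_cells()]).
#' @param cfg A [spatial_config()].
#' @return `cells` with one logical `pos_<gene>` column per gene and a
#'   `"thresholds"` attribute (raw scale).
#' @export
call_positive_cells <- function(cells, cfg = spatial_config()) {
  genes <- .fish_genes(cells)
  thr <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    v <- cells[[g]]
    if (any(v < 0) || any(!is.finite(v))) stop("raw values must be finite and nonnegative")
    thr[g] <- switch(cfg$threshold_method,
      otsu = {
        if (all(v == 0)) {
          warning(sprintf("gene %s has all-zero values; no positives", g))
          0
        } else expm1(otsu_threshold(log1p(v)))
      },
      quantile = expm1(unname(quantile(log1p(v), cfg$quantile_prob, type = 7))),
      fixed = {
        if (is.null(cfg$fixed_thresholds) || is.na(cfg$fixed_thresholds[g]))
          stop(sprintf("no fixed threshold for gene %s", g))
        unname(cfg$fixed_thresholds[g])
      })
    cells[[paste0("pos_", g)]] <- v > thr[g]
  }
  attr(cells, "thresholds") <- thr
  attr(cells, "genes") <- genes
  cells
}

#' Positive-cell fractions per subregion
#'
#' Percentage of cells positive for each gene within each of the eight BLA
#' subregions. Cells positive for several genes count once per gene, so
#' column sums per subregion may exceed 100. Empty subregions are reported as
#' `NA` and flagged.
#'
#' @param cells Output of [call_positive_cells()].
#' @return Numeric matrix subregion x gene of percentages, with attributes
#'   `n_cells` (per subregion) and `empty_subregions`.
#' @export
subregion_fractions <- function(cells) {
  genes <- .fish_genes(cells)
  pos_cols <- paste0("pos_", genes)
  if (!all(pos_cols %in% colnames(cells)))
    stop("positive flags missing; run call_positive_cells() first")
  subs <- BLA_SUBREGIONS
  frac <- matrix(NA_real_, length(subs), length(genes),
                 dimnames = list(subs, genes))
  n <- setNames(integer(length(subs)), subs)
  for (s in subs) {
    idx <- cells$subregion == s
    n[s] <- sum(idx)
    if (n[s] > 0)
      frac[s, ] <- 100 * colMeans(as.matrix(cells[idx, pos_cols, drop = FALSE]))
  }
  attr(frac, "n_cells") <- n
  attr(frac, "empty_subregions") <- subs[n == 0]
  class(frac) <- c("subregion_fractions", class(frac))
  frac
}

#' Pearson correlation between subregions
#'
#' Correlates the gene-fraction vectors of the defined subregions and orders
#' them by average-linkage clustering of `1 - r`.
#'
#' @param fr A [subregion_fractions()] matrix.
#' @return list: `r` (symmetric correlation matrix, `NA` where undefined),
#'   `order` (leaf order of the clustered, variable subregions), `excluded`
#'   (empty or zero-variance subregions).
#' @export
subregion_correlation <- function(fr) {
  m <- unclass(fr)
  defined <- rowSums(is.na(m)) == 0
  m <- m[defined, , drop = FALSE]
  if (nrow(m) < 2) stop("need >= 2 defined subregions")
  sds <- apply(m, 1, sd)
  ok <- sds > 0
  r <- matrix(NA_real_, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (sum(ok) >= 2)
    r[ok, ok] <- cor(t(m[ok, , drop = FALSE]))
  diag(r) <- 1
  ord <- rownames(m)[ok]
  if (sum(ok) >= 2) {
    hc <- hclust(as.dist(1 - r[ok, ok]), method = "average")
    ord <- rownames(m)[ok][hc$order]
  }
  list(r = r, order = ord,
       excluded = c(rownames(fr)[!defined], rownames(m)[!ok]))
}

# Separable Gaussian smoothing of a matrix; kernel truncated at 3 sigma and
# renormalized at the borders so constants are preserved.
.gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  smooth1 <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      w <- k[j - i + r + 1]
      out[i] <- sum(x[j] * w) / sum(w)
    }
    out
  }
  for (j in seq_len(ncol(m))) m[, j] <- smooth1(m[, j])
  for (i in seq_len(nrow(m))) m[i, ] <- smooth1(m[i, ])
  m
}

#' Eigen-image decomposition of marker maps
#'
#' Rasterizes each gene's positive cells of one coronal section onto a pixel
#' grid (counts per pixel), Gaussian-smooths each map, and eigendecomposes the
#' gene-by-gene covariance of the pixels x genes matrix (columns centered).
#' The principal-component score maps are the "eigen-images"; the cumulative
#' variance of the top 4 PCs summarizes how compactly the maps are described.
#'
#' @param cells Output of [call_positive_cells()].
#' @param cfg A [spatial_config()].
#' @param section One of the four section labels.
#' @return Object of class `"eigen_images"`: `loadings` (genes x PC),
#'   `variance_fraction`, `scores` (pixels x PC), `grid` (origin, nx, ny,
#'   pixel_size_um), `genes`, `top4_variance` and the smoothed `maps`.
#' @export
compute_eigen_images <- function(cells, cfg = spatial_config(), section) {
  genes <- .fish_genes(cells)
  pos_cols <- paste0("pos_", genes)
  if (!all(pos_cols %in% colnames(cells)))
    stop("positive flags missing; run call_positive_cells() first")
  sel <- cells$section == section
  if (!any(sel)) stop(sprintf("no cells in section '%s'", section))
  cs <- cells[sel, , drop = FALSE]
  px <- cfg$pixel_size_um
  x0 <- min(cs$x_um); y0 <- min(cs$y_um)
  nx <- as.integer(floor((max(cs$x_um) - x0) / px)) + 1L
  ny <- as.integer(floor((max(cs$y_um) - y0) / px)) + 1L
  ix <- pmin(as.integer(floor((cs$x_um - x0) / px)) + 1L, nx)
  iy <- pmin(as.integer(floor((cs$y_um - y0) / px)) + 1L, ny)
  X <- matrix(0, nx * ny, length(genes), dimnames = list(NULL, genes))
  for (gi in seq_along(genes)) {
    pos <- cs[[pos_cols[gi]]]
    if (!any(pos)) next
    img <- matrix(0, ny, nx)
    tab <- table(factor(iy[pos], levels = 1:ny), factor(ix[pos], levels = 1:nx))
    img[] <- as.numeric(tab)
    X[, gi] <- as.vector(.gauss_smooth(img, cfg$smoothing_sigma_px))
  }
  nonzero <- colSums(X != 0) > 0
  if (sum(nonzero) < 1) stop("no gene has a nonzero map in this section")
  if (sum(nonzero) == 1)
    warning("only one gene has a nonzero map; single PC at 100% variance")
  Xn <- X[, nonzero, drop = FALSE]
  Xc <- sweep(Xn, 2, colMeans(Xn))
  cv <- crossprod(Xc) / (nrow(Xc) - 1)
  ei <- eigen(cv, symmetric = TRUE)
  ev <- pmax(ei$values, 0)
  vf <- ev / sum(ev)
  loadings <- ei$vectors
  dimnames(loadings) <- list(colnames(Xn), paste0("PC", seq_along(ev)))
  scores <- Xc %*% loadings
  structure(list(
    loadings = loadings, variance_fraction = vf, scores = scores,
    grid = list(x0_um = x0, y0_um = y0, nx = nx, ny = ny, pixel_size_um = px),
    genes = colnames(Xn), maps = X, section = section,
    top4_variance = sum(vf[seq_len(min(4, length(vf)))])
  ), class = "eigen_images")
}

#' @export
print.eigen_images <- function(x, ...) {
  cat(sprintf("Eigen-images (%s): %d genes on a %d x %d grid (%g um px)\n",
              x$section, length(x$genes), x$grid$nx, x$grid$ny,
              x$grid$pixel_size_um))
  cat(sprintf("Top-4 PC variance: %.1f%%\n", 100 * x$top4_variance))
  invisible(x)
}

#' Locally normalized per-cell marker features
#'
#' For each cell and gene, sums the raw values of all cells of the same
#' section within `neighbor_radius_um` (Euclidean, boundary inclusive, self
#' included), then z-scores each gene across the cells of the section. Genes
#' with zero variance in a section get z-scores of 0; sections with fewer than
#' two cells yield `NA` features (those cells stay unassigned downstream).
#'
#' @param cells A `"fish_cells"` data.frame with raw values.
#' @param cfg A [spatial_config()].
#' @return Numeric matrix cells x genes of z-scored neighbourhood sums,
#'   rownames = cell ids.
#' @export
local_normalize <- function(cells, cfg = spatial_config()) {
  genes <- .fish_genes(cells)
  feat <- matrix(NA_real_, nrow(cells), length(genes),
                 dimnames = list(cells$cell_id, genes))
  r2 <- cfg$neighbor_radius_um^2
  for (sec in unique(cells$section)) {
    idx <- which(cells$section == sec)
    if (length(idx) < 2) next
    xs <- cells$x_um[idx]; ys <- cells$y_um[idx]
    raw <- as.matrix(cells[idx, genes, drop = FALSE])
    d2 <- outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2
    A <- (d2 <= r2 + 1e-9) * 1       # self distance 0 -> included
    sums <- A %*% raw
    mu <- colMeans(sums)
    sdv <- apply(sums, 2, sd)
    z <- sweep(sums, 2, mu)
    z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), "/")
    feat[idx, ] <- z
  }
  feat
}

#' Assign smFISH cells to transcriptomic clusters
#'
#' Pearson-correlates each cell's feature vector against every cluster's
#' scaled profile row and assigns the cluster with the highest coefficient
#' (ties broken by the lowest cluster id, in row order of the profile).
#' Cells with zero-variance or missing features stay unassigned, as do cells
#' when a cluster row itself has zero variance (that row is skipped).
#'
#' @param features Numeric matrix cells x genes (e.g. [local_normalize()]).
#' @param profile A [cluster_profile()]; its genes must match the feature
#'   columns.
#' @param keep_r_matrix Keep the full cell x cluster correlation matrix as an
#'   attribute.
#' @return data.frame: cell_id, cluster (NA when unassigned), r.
#' @export
assign_cells_to_clusters <- function(features, profile, keep_r_matrix = FALSE) {
  stopifnot(inherits(profile, "cluster_profile"))
  P <- profile$scaled
  if (!setequal(colnames(features), colnames(P)))
    stop("feature genes do not match profile genes")
  features <- features[, colnames(P), drop = FALSE]
  ok_cl <- apply(P, 1, sd) > 0
  Pok <- P[ok_cl, , drop = FALSE]
  R <- matrix(NA_real_, nrow(features), nrow(P),
              dimnames = list(rownames(features), rownames(P)))
  usable <- complete.cases(features) & apply(features, 1, sd) > 0
  if (any(usable) && nrow(Pok) > 0)
    R[usable, ok_cl] <- cor(t(features[usable, , drop = FALSE]), t(Pok))
  cluster <- rep(NA_character_, nrow(features))
  r <- rep(NA_real_, nrow(features))
  for (i in which(usable)) {
    ri <- R[i, ]
    if (all(is.na(ri))) next
    j <- which.max(ri)                  # first max = lowest cluster id in row order
    cluster[i] <- rownames(P)[j]
    r[i] <- ri[j]
  }
  res <- data.frame(cell_id = rownames(features), cluster = cluster, r = r,
                    stringsAsFactors = FALSE)
  if (keep_r_matrix) attr(res, "r_matrix") <- R
  res
}
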