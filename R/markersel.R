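#' Labelled expression matrix
#'
#' A nonnegative count matrix (cells x genes) with exactly one cluster label
#' per cell.
#'
#' @param counts Numeric matrix cells x genes, nonnegative, with dimnames.
#' @param clusters Character/factor vector of cluster labels, one per cell.
#' @return An object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(counts, clusters) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(clusters))
    stop("one cluster label per cell required")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("c%05d", seq_len(nrow(counts)))
  structure(list(counts = counts, clusters = as.character(clusters)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d cells x %d genes, %d clusters\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$clusters))))
  invisible(x)
}

# One-vs-rest AUC from mid-rank Mann-Whitney; ties get half credit.
.auc_rank <- function(values, in_cluster) {
  r <- rank(values)                      # mid-ranks
  n_in <- sum(in_cluster); n_out <- sum(!in_cluster)
  (sum(r[in_cluster]) - n_in * (n_in + 1) / 2) / (n_in * n_out)
}

#' AUROC marker-gene selection
#'
#' For every (gene, cluster) pair, computes the one-vs-rest AUC of the gene's
#' counts (Mann-Whitney with mid-rank ties), the percentage of cells with
#' count > 0 inside (`pct_in`) and outside (`pct_out`) the cluster, and a pass
#' flag `auc > auc_min & pct_in >= pct_in_min & pct_out <= pct_out_max`. The
#' top `top_n` passing genes per cluster (by AUC) are ranked; remaining rows
#' carry `rank = NA`. Defaults mirror the thresholds commonly used for
#' cluster-marker screens (`auc_min = 0.5`, `pct_in_min = 20`,
#' `pct_out_max = 20`, `top_n = 5`). A gene with identical values everywhere
#' has AUC 0.5 and can never pass (strict inequality).
#'
#' @param expr An [expression_matrix()].
#' @param auc_min AUC must strictly exceed this.
#' @param pct_in_min Minimum percentage of expressing cells in the cluster.
#' @param pct_out_max Maximum percentage of expressing cells outside.
#' @param top_n Passing genes retained per cluster.
#' @return data.frame: gene, cluster, auc, pct_in, pct_out, pass, rank.
#' @export
compute_auc_markers <- function(expr, auc_min = 0.5, pct_in_min = 20,
                                pct_out_max = 20, top_n = 5) {
  stopifnot(inherits(expr, "expression_matrix"))
  cl <- expr$clusters
  clusters <- sort(unique(cl))
  if (length(clusters) < 2) stop("marker selection needs >= 2 clusters")
  counts <- expr$counts
  genes <- colnames(counts)
  ranks <- apply(counts, 2, rank)        # mid-ranks per gene, cells x genes
  expressed <- counts > 0
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    inn <- cl == clusters[ci]
    n_in <- sum(inn); n_out <- sum(!inn)
    auc <- (colSums(ranks[inn, , drop = FALSE]) - n_in * (n_in + 1) / 2) /
      (n_in * n_out)
    pct_in <- 100 * colMeans(expressed[inn, , drop = FALSE])
    pct_out <- 100 * colMeans(expressed[!inn, , drop = FALSE])
    pass <- auc > auc_min & pct_in >= pct_in_min & pct_out <= pct_out_max
    rk <- rep(NA_integer_, length(genes))
    idx <- which(pass)
    if (length(idx)) {
      idx <- idx[order(-auc[idx])][seq_len(min(top_n, length(idx)))]
      rk[idx] <- seq_along(idx)
    }
    out[[ci]] <- data.frame(gene = genes, cluster = clusters[ci], auc = auc,
                            pct_in = pct_in, pct_out = pct_out, pass = pass,
                            rank = rk, stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster profile constructor
#'
#' Builds the per-cluster reference used for spatial cell assignment: an
#' aggregate value per (cluster, gene) and a per-gene max-scaled copy in
#' \[0, 1\] (each gene divided by its maximum over clusters; all-zero genes
#' stay 0).
#'
#' @param aggregate Numeric matrix clusters x genes of nonnegative aggregates,
#'   with dimnames.
#' @return An object of class `"cluster_profile"` with elements `aggregate`
#'   and `scaled`.
#' @export
cluster_profile <- function(aggregate) {
  aggregate <- as.matrix(aggregate)
  if (any(aggregate < 0)) stop("aggregates must be nonnegative")
  if (is.null(rownames(aggregate)))
    rownames(aggregate) <- sprintf("cl%d", seq_len(nrow(aggregate)))
  if (is.null(colnames(aggregate)))
    colnames(aggregate) <- sprintf("g%03d", seq_len(ncol(aggregate)))
  mx <- apply(aggregate, 2, max)
  scaled <- sweep(aggregate, 2, ifelse(mx > 0, mx, 1), "/")
  structure(list(aggregate = aggregate, scaled = scaled),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("Cluster profile: %d clusters x %d genes (scaled to [0,1] per gene)\n",
              nrow(x$scaled), ncol(x$scaled)))
  invisible(x)
}

#' Aggregate cluster expression profiles
#'
#' Sums the read counts of the requested genes per cluster and max-scales each
#' gene across clusters, yielding the reference profile for smFISH cell
#' assignment.
#'
#' @param expr An [expression_matrix()].
#' @param genes Character vector of gene ids to keep (default: all genes).
#' @return A [cluster_profile()].
#' @export
aggregate_profiles <- function(expr, genes = colnames(expr$counts)) {
  stopifnot(inherits(expr, "expression_matrix"))
  missing <- setdiff(genes, colnames(expr$counts))
  if (length(missing))
    stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  counts <- expr$counts[, genes, drop = FALSE]
  agg <- rowsum(counts, group = expr$clusters)
  cluster_profile(agg[sort(rownames(agg)), , drop = FALSE])
}

#' Dendrogram of transcriptomic clusters
#'
#' Agglomerative clustering of the cluster profile rows on Euclidean
#' distances. Average linkage by default; the linkage is configurable since
#' only the metric is fixed by convention.
#'
#' @param profile A [cluster_profile()].
#' @param use `"scaled"` (default) or `"aggregate"` rows.
#' @param linkage Passed to [stats::hclust()] `method`.
#' @return An `hclust` object whose leaves are clusters.
#' @export
cluster_dendrogram <- function(profile, use = c("scaled", "aggregate"),
                               linkage = "average") {
  stopifnot(inherits(profile, "cluster_profile"))
  use <- match.arg(use)
  m <- profile[[use]]
  if (nrow(m) < 2) stop("dendrogram needs >= 2 clusters")
  hclust(dist(m, method = "euclidean"), method = linkage)
}
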