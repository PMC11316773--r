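# Shared fixtures built in code.

feeding_arena <- function() {
  arena_spec("rectangle", width_cm = 40, height_cm = 40,
             target_x_cm = -12, target_y_cm = -12,
             norm_radius_cm = 20, zone_inner_cm = 5, zone_outer_cm = 17)
}

social_arena <- function() {
  arena_spec("circle", radius_cm = 24.5, target_x_cm = 10, target_y_cm = 0,
             norm_radius_cm = 24.5, zone_inner_cm = 10, zone_outer_cm = 20)
}

# Well-separated cluster profiles (genes_per_cluster exclusive genes each).
toy_profiles <- function(n_clusters = 4, genes_per_cluster = 2, hi = 10,
                         lo = 0.5) {
  n_genes <- n_clusters * genes_per_cluster
  m <- matrix(lo, n_clusters, n_genes,
              dimnames = list(sprintf("cl%d", seq_len(n_clusters)),
                              sprintf("g%02d", seq_len(n_genes))))
  for (k in seq_len(n_clusters))
    m[k, ((k - 1) * genes_per_cluster + 1):(k * genes_per_cluster)] <- hi
  cluster_profile(m)
}

# One-cluster-per-subregion layout over the first n clusters (cycled).
cycled_layout <- function(clusters) {
  L <- matrix(0, length(BLA_SUBREGIONS), length(clusters),
              dimnames = list(BLA_SUBREGIONS, clusters))
  for (i in seq_along(BLA_SUBREGIONS))
    L[i, ((i - 1L) %% length(clusters)) + 1L] <- 1
  L
}

# Independent brute-force oracles ------------------------------------------

# Pairwise-count AUC: (wins + 0.5 ties) / (n_in * n_out).
auc_bruteforce <- function(values_in, values_out) {
  wins <- 0; ties <- 0
  for (a in values_in) for (b in values_out) {
    if (a > b) wins <- wins + 1 else if (a == b) ties <- ties + 1
  }
  (wins + 0.5 * ties) / (length(values_in) * length(values_out))
}

# BH step-up by direct enumeration of k* = max{i : p(i) <= i q / m}.
bh_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

pearson_bruteforce <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

ols_bruteforce <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}
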