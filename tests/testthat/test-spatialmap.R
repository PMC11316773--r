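# Minimal hand-built cell table: 6 cells, one section, two subregions.
toy_cells <- function(gA = c(1, 1, 1, 9, 9, 9), gB = c(0, 0, 0, 0, 5, 5),
                      x = c(0, 40, 80, 200, 240, 280)) {
  df <- data.frame(cell_id = sprintf("f%d", 1:6),
                   section = "anterior",
                   subregion = rep(c("aLA", "amBA"), each = 3),
                   x_um = x, y_um = 0, gA = gA, gB = gB,
                   stringsAsFactors = FALSE)
  attr(df, "genes") <- c("gA", "gB")
  class(df) <- c("fish_cells", "data.frame")
  df
}

test_that("positive-cell calling honours fixed thresholds and Otsu splits", {
  cells <- toy_cells()
  cfg <- spatial_config(threshold_method = "fixed",
                        fixed_thresholds = c(gA = 2, gB = 1))
  out <- call_positive_cells(cells, cfg)
  expect_identical(out$pos_gA, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(out$pos_gB, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  # fixed threshold above all values -> zero positives
  out2 <- call_positive_cells(cells, spatial_config(
    threshold_method = "fixed", fixed_thresholds = c(gA = 100, gB = 100)))
  expect_false(any(out2$pos_gA))

  # Otsu on {1,1,1,9,9,9}: threshold strictly between 1 and 9, 3 positives
  out3 <- call_positive_cells(cells, spatial_config(threshold_method = "otsu"))
  thr <- attr(out3, "thresholds")["gA"]
  expect_gt(thr, 1); expect_lt(thr, 9)
  expect_equal(sum(out3$pos_gA), 3)
  # all-zero gene warns and yields no positives
  cells0 <- toy_cells(gB = rep(0, 6))
  expect_warning(out4 <- call_positive_cells(cells0), "all-zero")
  expect_false(any(out4$pos_gB))
})

test_that("otsu_threshold maximizes between-class variance (exhaustive oracle)", {
  set.seed(3)
  for (rep in 1:10) {
    v <- round(c(rnorm(15, 2, 1), rnorm(10, 8, 1)), 2)
    th <- otsu_threshold(v)
    # oracle: try every midpoint, track the best between-class variance
    u <- sort(unique(v))
    cand <- (u[-1] + u[-length(u)]) / 2
    bcv <- sapply(cand, function(t) {
      hi <- v > t; if (!any(hi) || all(hi)) return(0)
      mean(hi) * mean(!hi) * (mean(v[hi]) - mean(v[!hi]))^2
    })
    expect_equal(max(sapply(th, function(t) {
      hi <- v > t
      mean(hi) * mean(!hi) * (mean(v[hi]) - mean(v[!hi]))^2
    })), max(bcv))
  }
})

test_that("subregion fractions count positives per subregion and flag empties", {
  cells <- call_positive_cells(toy_cells(), spatial_config(
    threshold_method = "fixed", fixed_thresholds = c(gA = 2, gB = 1)))
  fr <- subregion_fractions(cells)
  expect_equal(fr["aLA", "gA"], 0)
  expect_equal(fr["amBA", "gA"], 100)
  expect_equal(fr["amBA", "gB"], 100 * 2 / 3, tolerance = 1e-12)
  expect_setequal(attr(fr, "empty_subregions"),
                  setdiff(BLA_SUBREGIONS, c("aLA", "amBA")))
  expect_true(all(is.na(fr["pBA", ])))
  # a multi-positive cell counts once per gene; sums can exceed 100
  one <- toy_cells()[5, , drop = FALSE]
  one$subregion <- "aLA"
  attr(one, "genes") <- c("gA", "gB")
  class(one) <- c("fish_cells", "data.frame")
  one <- call_positive_cells(one, spatial_config(
    threshold_method = "fixed", fixed_thresholds = c(gA = 2, gB = 1)))
  fr1 <- subregion_fractions(one)
  expect_equal(fr1["aLA", "gA"] + fr1["aLA", "gB"], 200)
  # invariant to cell order
  shuf <- cells[sample(nrow(cells)), ]
  attr(shuf, "genes") <- c("gA", "gB")
  class(shuf) <- c("fish_cells", "data.frame")
  expect_equal(unclass(subregion_fractions(shuf)), unclass(fr))
})

test_that("subregion correlation matches the direct Pearson formula", {
  fr <- matrix(NA_real_, 8, 3, dimnames = list(BLA_SUBREGIONS, c("a", "b", "c")))
  fr["aLA", ] <- c(10, 20, 30)
  fr["pLA", ] <- c(30, 20, 10)
  fr["amBA", ] <- c(5, 50, 20)
  class(fr) <- c("subregion_fractions", class(fr))
  attr(fr, "n_cells") <- setNames(c(rep(10, 3), rep(0, 5)), BLA_SUBREGIONS)
  sc <- subregion_correlation(fr)
  expect_equal(sc$r["aLA", "pLA"], -1)
  expect_equal(sc$r["aLA", "amBA"],
               pearson_bruteforce(c(10, 20, 30), c(5, 50, 20)))
  expect_equal(diag(sc$r), setNames(rep(1, 3), c("aLA", "pLA", "amBA")))
  # zero-variance subregion reported as excluded with NA correlations
  fr2 <- fr
  fr2["acBA", ] <- c(7, 7, 7)
  sc2 <- subregion_correlation(fr2)
  expect_true("acBA" %in% sc2$excluded)
  expect_true(all(is.na(sc2$r["acBA", c("aLA", "pLA")])))
})

test_that("eigen-images: variance fractions are a sorted partition of unity", {
  prof <- toy_profiles()
  fish <- gen_fish_dataset(prof, cycled_layout(rownames(prof$scaled)),
                           n_cells = 300, noise_sd = 0.5, seed = 31)
  cells <- call_positive_cells(fish$cells)
  ei <- compute_eigen_images(cells, spatial_config(), section = "anterior")
  vf <- ei$variance_fraction
  expect_true(all(vf >= 0))
  expect_true(all(diff(vf) <= 1e-12))
  expect_equal(sum(vf), 1, tolerance = 1e-9)
  expect_equal(ei$top4_variance, sum(vf[1:4]))
  # reconstruction from all PCs reproduces the centered pixel matrix
  Xc <- sweep(ei$maps[, ei$genes, drop = FALSE], 2,
              colMeans(ei$maps[, ei$genes, drop = FALSE]))
  expect_equal(ei$scores %*% t(ei$loadings), Xc,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate eigen-image cases: one gene, identical maps", {
  # a single nonzero gene -> single PC at 100% variance
  cells <- toy_cells(gA = c(5, 5, 0, 9, 0, 9), gB = rep(0, 6))
  cells$pos_gA <- cells$gA > 1
  cells$pos_gB <- cells$gB > 1
  expect_warning(ei <- compute_eigen_images(cells, spatial_config(), "anterior"),
                 "one gene")
  expect_equal(ei$variance_fraction[1], 1.0)
  # two genes with identical maps -> PC1 carries all variance
  cells2 <- toy_cells(gA = c(5, 5, 0, 9, 0, 9), gB = c(5, 5, 0, 9, 0, 9))
  cells2$pos_gA <- cells2$gA > 1
  cells2$pos_gB <- cells2$gB > 1
  ei2 <- compute_eigen_images(cells2, spatial_config(), "anterior")
  expect_equal(ei2$variance_fraction[1], 1.0, tolerance = 1e-9)
})

test_that("local normalization sums neighbours within 50 um then z-scores", {
  # 3 collinear cells 40 um apart: neighbourhoods {1,2}, {1,2,3}, {2,3}
  df <- data.frame(cell_id = c("a", "b", "c"), section = "anterior",
                   subregion = "aLA", x_um = c(0, 40, 80), y_um = 0,
                   g1 = c(1, 2, 4), stringsAsFactors = FALSE)
  attr(df, "genes") <- "g1"
  class(df) <- c("fish_cells", "data.frame")
  f <- local_normalize(df, spatial_config(neighbor_radius_um = 50))
  sums <- c(1 + 2, 1 + 2 + 4, 2 + 4)
  expect_equal(unname(f[, "g1"]), (sums - mean(sums)) / sd(sums))
  # isolated cells: neighbourhood sum is the cell's own value (self inclusive)
  df2 <- df; df2$x_um <- c(0, 1000, 2000)
  attr(df2, "genes") <- "g1"; class(df2) <- c("fish_cells", "data.frame")
  f2 <- local_normalize(df2, spatial_config(neighbor_radius_um = 50))
  v <- c(1, 2, 4)
  expect_equal(unname(f2[, "g1"]), (v - mean(v)) / sd(v))
  # identical values and identical neighbourhoods -> all z-scores 0
  df3 <- df; df3$g1 <- c(3, 3, 3); df3$x_um <- c(0, 20, 40)
  attr(df3, "genes") <- "g1"; class(df3) <- c("fish_cells", "data.frame")
  expect_true(all(local_normalize(df3) == 0))
})

test_that("cell assignment equals the brute-force argmax-Pearson oracle", {
  prof <- toy_profiles()
  set.seed(17)
  feats <- matrix(rnorm(200 * 8), 200,
                  dimnames = list(sprintf("c%d", 1:200),
                                  colnames(prof$scaled)))
  asg <- assign_cells_to_clusters(feats, prof, keep_r_matrix = TRUE)
  for (i in sample(200, 25)) {
    rs <- apply(prof$scaled, 1, function(p) pearson_bruteforce(feats[i, ], p))
    expect_equal(asg$cluster[i], names(which.max(rs)))
    expect_equal(asg$r[i], max(rs))
  }
  # an affine copy of a profile row correlates perfectly with it
  feats2 <- rbind(copy = 3 * prof$scaled["cl2", ] + 1,
                  flat = rep(1, 8))
  colnames(feats2) <- colnames(prof$scaled)
  asg2 <- assign_cells_to_clusters(feats2, prof)
  expect_equal(asg2$cluster[1], "cl2")
  expect_equal(asg2$r[1], 1.0)
  expect_true(is.na(asg2$cluster[2]))  # constant vector stays unassigned
  expect_error(assign_cells_to_clusters(feats[, 1:5], prof), "genes")
})

test_that("noiseless cells are assigned to their true clusters exactly", {
  prof <- toy_profiles()
  fish <- gen_fish_dataset(prof, cycled_layout(rownames(prof$scaled)),
                           n_cells = 200, noise_sd = 0, seed = 3)
  genes <- attr(fish$cells, "genes")
  feats <- as.matrix(fish$cells[, genes])
  rownames(feats) <- fish$cells$cell_id
  asg <- assign_cells_to_clusters(feats, prof)
  expect_equal(asg$cluster, fish$truth$cluster)
})
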