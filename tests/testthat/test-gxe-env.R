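# GxE diagnostics: interaction effects, distances, clustering, PCA, Mantel
# tests and vegetation condition indices.

test_that("interaction-effect BLUPs respond to the generating GxE structure", {
  # zero GxE variance: all interaction effects shrink to ~0
  tab0 <- balanced_hybrid_fixture(3, v = list(F = 6, M = 4, FM = 2, FL = 1e-8,
                                              ML = 1e-8, FML = 1e-8, L = 5,
                                              B = 1, E = 2))
  fit0 <- fit_variance_components(tab0)
  m0 <- interaction_effects(fit0)
  expect_lt(max(abs(m0)), 0.5)

  # duplicated environments: their interaction columns nearly coincide
  set.seed(4)
  tab <- balanced_hybrid_fixture(4, nl = 3,
                                 v = list(F = 6, M = 4, FM = 2, FL = 6,
                                          ML = 1, FML = 1, L = 5, B = 1,
                                          E = 1))
  dup <- tab[tab$location == "L3", ]
  dup$location <- "L4"
  dup$genotype_id <- dup$genotype_id
  dup$value <- dup$value + rnorm(nrow(dup), 0, 0.2)  # near-copy environment
  fit <- fit_variance_components(rbind(tab, dup))
  m <- interaction_effects(fit)
  d <- as.matrix(euclidean_distances(m))
  expect_lt(d["L3", "L4"], min(d["L3", c("L1", "L2")]))

  # shrinkage: BLUP magnitudes below raw two-way interaction residuals
  cell <- with(tab, tapply(value, list(female_parent, location), mean))
  raw <- sweep(sweep(cell, 1, rowMeans(cell)), 2, colMeans(cell)) +
    mean(cell)
  mm <- interaction_effects(fit_variance_components(tab))
  expect_lt(mean(abs(mm)), mean(abs(raw)))
})

test_that("euclidean distances match hand values and the brute-force oracle", {
  m <- cbind(a = c(0, 0), b = c(3, 4))
  expect_equal(as.matrix(euclidean_distances(m))["a", "b"], 5)
  m2 <- cbind(x = 1:3, y = 1:3)
  expect_equal(as.matrix(euclidean_distances(m2))["x", "y"], 0)

  set.seed(5)
  m3 <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("c", 1:4)))
  d <- as.matrix(euclidean_distances(m3))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(d[i, j], sqrt(sum((m3[, i] - m3[, j])^2)))
  }
  # triangle inequality on every output
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
  m3[2, 2] <- NA
  expect_error(euclidean_distances(m3), "missing")
})

test_that("complete linkage merges in hand-checkable order", {
  d <- stats::as.dist(matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3,
                             dimnames = list(letters[1:3], letters[1:3])))
  cl <- complete_linkage(d, k = 2)
  expect_equal(cl$hclust$height, c(1, 3))  # pair at 1 merges first
  expect_equal(cl$clusters[["a"]], cl$clusters[["b"]])
  expect_true(all(diff(cl$hclust$height) >= 0))

  # two well-separated clusters are recovered by the 2-cut
  set.seed(6)
  pts <- rbind(matrix(rnorm(10, 0, 0.3), 5), matrix(rnorm(10, 8, 0.3), 5))
  rownames(pts) <- paste0("p", 1:10)
  cl2 <- complete_linkage(stats::dist(pts), k = 2)
  expect_equal(length(unique(cl2$clusters[1:5])), 1)
  expect_equal(length(unique(cl2$clusters[6:10])), 1)
  expect_false(cl2$clusters[[1]] == cl2$clusters[[10]])

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(complete_linkage(asym), "symmetric")

  # newick export is readable and preserves the tips
  tn <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl2, tn)
  tree <- ape::read.tree(tn)
  expect_setequal(tree$tip.label, rownames(pts))
})

test_that("PCA explains variance with a fixed sign convention", {
  r1 <- outer(c(1, 2, 3, 4), c(2, -1, 0.5))
  p1 <- pca_decomp(r1, center = TRUE)
  expect_equal(p1$explained[1], 1)

  set.seed(7)
  m <- matrix(rnorm(30), 6, 5)
  p <- pca_decomp(m)
  expect_equal(sum(p$explained), 1)
  expect_true(all(diff(p$explained) <= 1e-12))
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(p$loadings))) {
    v <- p$loadings[, j]
    expect_gte(v[which.max(abs(v))], 0)
  }
  # eigendecomposition oracle on a small matrix
  m3 <- matrix(c(2, 0, 1, 1, 1, 0, 0, 2, 2), 3, 3)
  p3 <- pca_decomp(m3)
  ev <- eigen(stats::cov(m3))$values
  expect_equal(p3$explained, ev / sum(ev), tolerance = 1e-10)

  # projection: reference rows reproduce their scores; mean row hits origin
  expect_equal(project_onto(p, m), p$scores, ignore_attr = TRUE)
  expect_equal(drop(project_onto(p, matrix(colMeans(m), 1))),
               rep(0, 5), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(project_onto(p, m[, 1:3]), "mismatch")
  expect_error(pca_decomp(matrix(1, 3, 3)), "constant")
})

test_that("Mantel tests are exact for small panels and calibrated at the null", {
  set.seed(8)
  pts1 <- matrix(rnorm(8), 4, 2)
  pts2 <- matrix(rnorm(8), 4, 2)
  d1 <- stats::dist(pts1); d2 <- stats::dist(pts2)
  mt <- mantel_test(d1, d2, n_permutations = 999)
  expect_equal(mt$method, "exact")
  # brute-force oracle over all 24 permutations
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  lower <- lower.tri(m1)
  perms <- rrgskit:::all_permutations(4)
  rp <- apply(perms, 1, function(p) cor(m1[lower], m2[p, p][lower]))
  expect_equal(mt$p, mean(rp >= mt$r - 1e-12))

  # identical matrices, sampled mode: p = 1/(n_perm + 1)
  set.seed(9)
  pts <- matrix(rnorm(16), 8, 2)
  d <- stats::dist(pts)
  mts <- mantel_test(d, d, n_permutations = 199, seed = 1)
  expect_equal(mts$r, 1)
  expect_equal(mts$p, 1 / 200)

  expect_error(mantel_test(d1, stats::dist(pts)), "size")
  expect_error(mantel_test(d1, d2, n_permutations = 10), "99")

  # cross-check of the statistic against an independent implementation
  if (requireNamespace("vegan", quietly = TRUE)) {
    d3 <- stats::dist(matrix(rnorm(12), 6, 2))
    d4 <- stats::dist(matrix(rnorm(12), 6, 2))
    ours <- mantel_test(d3, d4, n_permutations = 99, seed = 2)
    ref <- vegan::mantel(d3, d4, permutations = 99)
    expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("VCI rescales EVI between reference extremes with clamping", {
  pr <- env_profile("X", as.Date("2019-01-01") + 0:4,
                    evi = c(0.05, 0.8, 0.425, 0.9, 0.01),
                    evi_min = 0.05, evi_max = 0.8)
  v <- vci(pr)
  expect_equal(v[1:3], c(0, 1, 0.5))
  expect_equal(v[4], 1)  # clamped above
  expect_equal(v[5], 0)  # clamped below
  pr$evi_max <- pr$evi_min
  expect_error(vci(pr), "exceed")
})

test_that("profile distances separate regimes and track GxE structure", {
  des <- trial_design(paste0("L", 1:6), stress_locations = c("L5", "L6"))
  pr <- simulate_env_profiles(des, n_timepoints = 20, seed = 10)
  expect_equal(as.matrix(profile_distances(list(pr$L1, pr$L1)))[1, 2], 0)
  d <- as.matrix(profile_distances(pr))
  within_stress <- d["L5", "L6"]
  between <- mean(d[c("L5", "L6"), paste0("L", 1:4)])
  expect_lt(within_stress, between)

  # stress-driven GxE: VCI distances correlate with interaction distances
  set.seed(11)
  gv <- stats::setNames(rnorm(40, 90, 3), sprintf("H%02d", 1:40))
  meta <- data.frame(genotype_id = names(gv), role = "hybrid",
                     female_parent = rep(sprintf("F%02d", 1:10), each = 4),
                     male_parent = rep(sprintf("M%d", 1:4), 10))
  des2 <- trial_design(paste0("L", 1:6), n_blocks = 2, var_loc = 4,
                       var_block = 1, var_gxe = 1, var_resid = 2,
                       stress_locations = c("L5", "L6"), stress_cor = 0.1)
  tab <- simulate_phenotypes(gv, design = des2, seed = 12, meta = meta)
  fit <- fit_variance_components(tab)
  dg <- as.matrix(euclidean_distances(interaction_effects(fit)))
  locs <- paste0("L", 1:6)
  mt <- mantel_test(dg[locs, locs], as.matrix(profile_distances(pr))[locs, locs],
                    n_permutations = 719)
  expect_gt(mt$r, 0)
})
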