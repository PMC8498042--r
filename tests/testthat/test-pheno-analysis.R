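# BLUEs, robust outlier control, variance components, heritability and
# heterosis.

make_line_table <- function(seed, n_geno = 25, locs = paste0("L", 1:3),
                            var_loc = 4, var_block = 1, var_gxe = 0,
                            var_resid = 1) {
  set.seed(seed)
  gv <- stats::setNames(rnorm(n_geno, 90, 3), sprintf("G%03d", 1:n_geno))
  des <- trial_design(locs, n_blocks = 2, var_loc = var_loc,
                      var_block = var_block, var_gxe = var_gxe,
                      var_resid = var_resid)
  list(tab = simulate_phenotypes(gv, design = des, seed = seed + 1), gv = gv)
}

test_that("BLUEs equal genotype means on balanced noise-free data", {
  x <- make_line_table(1, var_loc = 0, var_block = 0, var_resid = 0)
  b <- compute_blues(x$tab, vc = list(var_env = 1e-8, var_block = 1e-8,
                                      var_resid = 1))
  expect_equal(stats::setNames(b$blue, b$genotype_id)[names(x$gv)], x$gv,
               tolerance = 1e-6)
})

test_that("environment shifts leave BLUE differences unchanged", {
  x <- make_line_table(2, var_resid = 2)
  b1 <- compute_blues(x$tab)
  tab2 <- x$tab
  tab2$value[tab2$location == "L1"] <- tab2$value[tab2$location == "L1"] + 25
  b2 <- compute_blues(tab2)
  d1 <- diff(b1$blue)
  d2 <- diff(b2$blue)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("BLUEs on unbalanced data match an explicit GLS oracle", {
  x <- make_line_table(3, n_geno = 8, var_resid = 2)
  tab <- x$tab[-c(2, 9, 17, 30), ]  # unbalance
  vc <- list(var_env = 4, var_block = 1, var_resid = 2)
  b <- compute_blues(tab, vc = vc)
  # independent oracle: build V from scratch and invert
  env <- as.character(tab$location)
  blk <- paste(env, tab$block)
  X <- outer(tab$genotype_id, sort(unique(tab$genotype_id)), `==`) * 1
  V <- vc$var_env * outer(env, env, `==`) +
    vc$var_block * outer(blk, blk, `==`) +
    diag(vc$var_resid, nrow(tab))
  beta <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, tab$value))
  expect_equal(b$blue, drop(beta), tolerance = 1e-8)
})

test_that("disconnected designs are reported", {
  x <- make_line_table(4, n_geno = 10)
  tab <- x$tab
  keep <- !(tab$genotype_id %in% sprintf("G%03d", 1:5) &
              tab$location != "L1") &
    !(tab$genotype_id %in% sprintf("G%03d", 6:10) & tab$location == "L1")
  expect_warning(compute_blues(tab[keep, ]), "disconnected")
})

test_that("M4r flags planted contamination and respects the error level", {
  x <- make_line_table(5, n_geno = 30, var_resid = 1)
  tab <- x$tab
  tab$value[17] <- tab$value[17] + 10  # 10-sigma contamination
  out <- detect_outliers_m4r(tab, alpha = 0.05)
  expect_true(17 %in% as.integer(rownames(out)))
  expect_equal(nrow(out), 1)

  # family-wise flag rate on clean data stays at or below alpha
  flagged <- vapply(1:100, function(s) {
    xx <- make_line_table(100 + s, n_geno = 15, var_resid = 1)
    res <- attr(compute_blues(xx$tab, vc = list(var_env = 4, var_block = 1,
                                                var_resid = 1)), "residuals")
    nrow(detect_outliers_m4r(xx$tab, residuals = res, alpha = 0.05)) > 0
  }, TRUE)
  rate <- mean(flagged)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 100))

  # constant residuals: MAD = 0, no flags, warning
  expect_warning(res0 <- detect_outliers_m4r(x$tab, residuals = rep(0, nrow(x$tab))),
                 "MAD")
  expect_equal(nrow(res0), 0)
})

test_that("REML variance components match the balanced ANOVA oracle", {
  tab <- balanced_hybrid_fixture(1)
  oracle <- anova_vc_oracle(tab, 12, 6, 4, 2)
  expect_true(all(oracle > 0))  # interior: estimators must coincide
  fit <- fit_variance_components(tab)
  est <- fit$components[names(oracle)]
  expect_lt(max(abs(est - oracle) / oracle), 0.01)
  # derived sums are consistent
  expect_equal(unname(fit$derived["hybrids"]),
               unname(sum(fit$components[c("gca_female", "gca_male", "sca")])))
  expect_equal(unname(fit$l["hybrids"]), 4)
})

test_that("zero-residual data yields a near-zero residual estimate", {
  set.seed(6)
  gv <- stats::setNames(rnorm(30, 90, 3), sprintf("G%03d", 1:30))
  des <- trial_design(paste0("L", 1:3), n_blocks = 2, var_loc = 2,
                      var_block = 0.5, var_gxe = 2, var_resid = 0)
  tab <- simulate_phenotypes(gv, design = des, seed = 7)
  fit <- fit_variance_components(tab)
  expect_lt(fit$components[["residual"]], 0.05 * var(tab$value))
})

test_that("heritability follows its closed form and monotonicities", {
  expect_equal(round(heritability(17.21, 14.01, 5.73, 6), 2), 0.84)
  expect_equal(heritability(3.3, 0, 0, 4), 1.0)
  expect_equal(round(heritability(17.91, 10.05, 5.77, 4), 2), 0.82)
  # monotone in l and in genetic variance; bounded in [0, 1]
  h <- vapply(1:10, function(l) heritability(10, 8, 4, l), 0)
  expect_true(all(diff(h) > 0) && all(h > 0 & h < 1))
  h2 <- vapply(seq(1, 30, by = 3), function(s) heritability(s, 8, 4, 5), 0)
  expect_true(all(diff(h2) > 0))
  expect_error(heritability(1, 1, 1, 0), "positive")
})

test_that("GxE ratios reproduce the reported arithmetic", {
  expect_equal(round(gxe_ratio(14.01, 17.21), 2), 0.81)
  expect_equal(gxe_ratio(0, 5), 0)
  expect_equal(round(gxe_ratio(2.20, 2.14), 2), 1.03)
  expect_error(gxe_ratio(1, 0), "positive")
})

test_that("heterosis arithmetic and ordering hold", {
  h <- heterosis(99, 80, 100)
  expect_equal(h$mph, 10)
  expect_equal(h$bph, -1)
  expect_equal(heterosis(90, 80, 100)$mph, 0)
  # BPH <= MPH, equality iff parents equal
  set.seed(8)
  hv <- runif(50, 80, 120); p1 <- runif(50, 70, 110); p2 <- runif(50, 70, 110)
  hh <- heterosis(hv, p1, p2)
  expect_true(all(hh$bph <= hh$mph + 1e-12))
  he <- heterosis(105, 95, 95)
  expect_equal(he$mph, he$bph)
  expect_warning(heterosis(10, -5, 2), "non-positive")

  # additive-only trait: exact zero midparent heterosis of F1 genetic values
  set.seed(9)
  g <- make_founders(12, 100, 2, 100, 0.2, 0.5)
  arch <- sample_architecture(100, 40, mu = 100, mean_k = 0, sd_k = 0)
  plan <- round_robin(rownames(g$dosage))
  mph <- vapply(seq_len(nrow(plan)), function(i) {
    p1 <- genetic_value(g$dosage[plan$female[i], ], arch)
    p2 <- genetic_value(g$dosage[plan$male[i], ], arch)
    f1 <- genetic_value(cross(g$dosage[plan$female[i], ],
                              g$dosage[plan$male[i], ]), arch)
    heterosis(f1, p1, p2)$mph
  }, 0)
  expect_equal(mph, rep(0, 12), tolerance = 1e-10)
})
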