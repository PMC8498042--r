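# GRM, ridge-BLUP with dominance, GBLUP and combining-ability prediction.

test_that("VanRaden GRM matches a scalar-loop oracle", {
  d <- matrix(c(0, 2, 2, 0,
                2, 2, 0, 0,
                0, 0, 2, 2), 3, 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("M", 1:4)))
  G <- vanraden_grm(d)
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  want <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    want[i, j] <- sum((d[i, ] - 2 * p) * (d[j, ] - 2 * p)) / denom
  }
  expect_equal(unname(G), want)
  expect_true(isSymmetric(G))

  # identical individuals: identical rows, off-diagonal equals diagonal
  d2 <- rbind(d, A2 = d["A", ])
  G2 <- vanraden_grm(d2)
  expect_equal(G2["A", ], G2["A2", ], ignore_attr = TRUE)
  expect_equal(G2["A", "A2"], G2["A", "A"])

  # monomorphic markers contribute nothing
  d3 <- cbind(d, M5 = c(2, 2, 2))
  expect_equal(unname(vanraden_grm(d3)), unname(G))

  expect_error(vanraden_grm(matrix(2, 3, 4)), "monomorphic")
})

test_that("hybrid design matrices encode expected additive and dominance rows", {
  set.seed(1)
  g <- make_founders(6, 50, 2, 100, 0.2, 0.5)
  ids <- rownames(g$dosage)
  plan <- data.frame(female = ids[c(1, 1, 2)], male = ids[c(1, 2, 3)])
  dm <- hybrid_design_matrices(g, plan)
  # self-cross: no heterozygous loci
  expect_true(all(dm$ZD[1, ] == 0))
  expect_equal(dm$ZA[1, ], g$dosage[ids[1], ] - 1, ignore_attr = TRUE)
  # brute-force per-locus construction
  for (r in 2:3) {
    p1 <- g$dosage[plan$female[r], ]
    p2 <- g$dosage[plan$male[r], ]
    expect_equal(dm$ZA[r, ], ((p1 - 1) + (p2 - 1)) / 2, ignore_attr = TRUE)
    expect_equal(dm$ZD[r, ], as.numeric(p1 != p2), ignore_attr = TRUE)
  }
  expect_error(hybrid_design_matrices(g, data.frame(female = "nope",
                                                    male = ids[1])),
               "not in")
})

test_that("ridge solutions match closed forms and degenerate limits", {
  # constant phenotype with fixed variances: mu recovers it, effects vanish
  set.seed(2)
  Z <- matrix(rnorm(40), 10, 4)
  m0 <- fit_rrblup_ad(rep(7, 10), Z, vc = list(sa2 = 1, se2 = 1))
  expect_equal(m0$mu, 7)
  expect_equal(unname(m0$a), rep(0, 4))

  # one centred marker: effect equals (x'x + lambda)^-1 x'y
  x <- drop(scale(rnorm(30), scale = FALSE))
  y <- drop(0.8 * x + rnorm(30, 0, 0.5))
  y <- y - mean(y)
  sa2 <- 0.3; se2 <- 0.9
  m1 <- fit_rrblup_ad(y, matrix(x), vc = list(sa2 = sa2, se2 = se2))
  expect_equal(unname(m1$a), sum(x * y) / (sum(x^2) + se2 / sa2),
               tolerance = 1e-10)

  expect_error(fit_rrblup_ad(rep(1, 10), Z, vc = "reml"), "distinct")
})

test_that("RRBLUP and GBLUP are equivalent on additive models", {
  set.seed(3)
  sim <- line_trial_sim(3, n = 120, m = 200)
  d <- sim$geno$dosage
  p <- colMeans(d) / 2
  W <- sweep(d, 2, 2 * p)
  cc <- 2 * sum(p * (1 - p))
  sa2 <- 0.02; se2 <- 1.5
  mr <- fit_rrblup_ad(sim$y, W, vc = list(sa2 = sa2, se2 = se2))
  fit_r <- mr$mu + drop(W %*% mr$a)
  mg <- fit_gblup(sim$y, tcrossprod(W) / cc,
                  vc = list(sg2 = sa2 * cc, se2 = se2))
  expect_lt(max(abs(fit_r - (mg$mu + mg$g))), 1e-6)
})

test_that("GBLUP limits behave: shrinkage to zero and duplicate symmetry", {
  set.seed(4)
  sim <- line_trial_sim(4, n = 60, m = 120)
  G <- vanraden_grm(sim$geno)
  f0 <- fit_gblup(sim$y, G, vc = list(sg2 = 1e-10, se2 = 1))
  expect_lt(max(abs(f0$g)), 1e-6)

  # duplicated individuals with identical phenotypes get identical BLUPs
  d2 <- rbind(sim$geno$dosage, dup = sim$geno$dosage[1, ])
  y2 <- c(sim$y, sim$y[1])
  f2 <- fit_gblup(y2, vanraden_grm(d2), vc = list(sg2 = 5, se2 = 5))
  expect_equal(unname(f2$g[1]), unname(f2$g[61]), tolerance = 1e-8)

  # strong genetic signal: predictions track phenotypes
  g_big <- fit_gblup(sim$gv + rnorm(60, 0, 0.01), G, vc = "reml")
  expect_gt(cor(g_big$mu + g_big$g, sim$gv), 0.97)
})

test_that("EM-REML recovers a 1:1 variance ratio on simulated data", {
  ratios <- vapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 500; m <- 400
    Z <- matrix(rnorm(n * m), n, m) / sqrt(m)
    u <- rnorm(m, 0, sqrt(1 / m) * sqrt(m))  # effects with total var 1
    y <- drop(Z %*% u) + rnorm(n, 0, 1)
    fit <- fit_rrblup_ad(y, Z, vc = "reml")
    (fit$vc$sa2 * mean(diag(tcrossprod(Z)))) / fit$vc$se2
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.2)
})

test_that("hybrid and GCA predictions obey additive coding identities", {
  set.seed(5)
  g <- make_founders(8, 80, 2, 100, 0.2, 0.5)
  ids <- rownames(g$dosage)
  plan <- expand.grid(female = ids[1:5], male = ids[6:8],
                      stringsAsFactors = FALSE)
  dm <- hybrid_design_matrices(g, plan)
  arch <- sample_architecture(80, 30, mu = 0, mean_k = 0.4, sd_k = 0.2)
  y <- genetic_value((g$dosage[plan$female, ] + g$dosage[plan$male, ]) / 2,
                     arch) + rnorm(15, 0, 0.5)
  model <- fit_rrblup_ad(y, dm$ZA, dm$ZD,
                         vc = list(sa2 = 0.05, sd2 = 0.02, se2 = 0.5))

  # brute-force locus loop for one hybrid
  f <- ids[2]; m <- ids[7]
  want <- model$mu
  for (l in seq_len(80)) {
    za <- ((g$dosage[f, l] - 1) + (g$dosage[m, l] - 1)) / 2
    zd <- as.numeric(g$dosage[f, l] != g$dosage[m, l])
    want <- want + za * model$a[l] + zd * model$d[l]
  }
  expect_equal(predict_hybrid(model, f, m, g), unname(want))

  # self-cross equals the line prediction; no dominance contribution
  ld <- line_design_matrices(g)
  line_pred <- model$mu + drop(ld$ZA %*% model$a) + drop(ld$ZD %*% model$d)
  expect_equal(predict_hybrid(model, f, f, g), unname(line_pred[f]))

  # with zero dominance, hybrid prediction is the parent-line mean
  model0 <- model
  model0$d[] <- 0
  lp0 <- model0$mu + drop(ld$ZA %*% model0$a)
  expect_equal(predict_hybrid(model0, f, m, g),
               unname((lp0[f] + lp0[m]) / 2))

  # GCA: exhaustive 5 x 3 factorial oracle
  gca <- predict_gca(model, ids[1:5], ids[6:8], g)
  preds <- outer(ids[1:5], ids[6:8],
                 Vectorize(function(a, b) predict_hybrid(model, a, b, g)))
  want_gca <- rowMeans(preds) - mean(preds)
  expect_equal(as.numeric(gca), unname(want_gca))

  # identical candidates get identical GCA
  g2 <- g
  g2$dosage <- rbind(g2$dosage, twin = g2$dosage[ids[1], ])
  gca2 <- predict_gca(model, c(ids[1], "twin"), ids[6:8], g2)
  expect_equal(unname(gca2[1]), unname(gca2[2]))

  # one tester, zero dominance: GCA differences are half the additive diff
  gca1 <- predict_gca(model0, ids[1:5], ids[6], g)
  add_val <- drop((g$dosage[ids[1:5], ] - 1) %*% model0$a)
  expect_equal(unname(diff(gca1)), unname(diff(add_val)) / 2)

  expect_error(predict_gca(model, ids[1], character(0), g), "empty tester")
})

test_that("shrinkage is monotone and monomorphic markers are irrelevant", {
  set.seed(6)
  sim <- line_trial_sim(6, n = 80, m = 100)
  Z <- sim$geno$dosage - 1
  norms <- vapply(c(1, 10, 100), function(lam) {
    fit <- fit_rrblup_ad(sim$y, Z, vc = list(sa2 = 1 / lam, se2 = 1))
    sqrt(sum(fit$a^2))
  }, 0)
  expect_true(all(diff(norms) < 0))

  # adding a monomorphic marker leaves predictions unchanged
  m1 <- fit_rrblup_ad(sim$y, Z, vc = list(sa2 = 0.05, se2 = 1))
  Zm <- cbind(Z, mono = 1)
  m2 <- fit_rrblup_ad(sim$y, Zm, vc = list(sa2 = 0.05, se2 = 1))
  expect_equal(m1$mu + drop(Z %*% m1$a), m2$mu + drop(Zm %*% m2$a),
               tolerance = 1e-8)

  # translation: adding a constant shifts mu only, GCA untouched
  g <- sim$geno
  ids <- rownames(g$dosage)
  da <- fit_rrblup_ad(sim$y, Z, vc = list(sa2 = 0.05, se2 = 1))
  db <- fit_rrblup_ad(sim$y + 50, Z, vc = list(sa2 = 0.05, se2 = 1))
  expect_equal(db$mu - da$mu, 50, tolerance = 1e-8)
  expect_equal(da$a, db$a, tolerance = 1e-8)
  da$marker_ids <- db$marker_ids <- colnames(g$dosage)
  names(da$a) <- names(db$a) <- colnames(g$dosage)
  expect_equal(as.numeric(predict_gca(da, ids[1:4], ids[5:6], g)),
               as.numeric(predict_gca(db, ids[1:4], ids[5:6], g)),
               tolerance = 1e-7)
})
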