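# Founder simulation, crossing designs, meiosis and single-seed descent.

test_that("founder panels are inbred with frequencies inside the bounds", {
  g <- make_founders(135, 4031, 21, 150, 0.05, 0.5, seed = 1)
  expect_equal(dim(g$dosage), c(135, 4031))
  expect_false(any(g$dosage == 1))
  expect_true(all(g$dosage %in% c(0, 2)))

  g2 <- make_founders(2, 10, 1, 100, 0.5, 0.5, seed = 7)
  expect_true(all(abs(colMeans(g2$dosage) / 2 - 0.5) <= 0.5))

  g3 <- make_founders(50, 200, 3, 100, 0.1, 0.4, seed = 3)
  p_hat <- colMeans(g3$dosage) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  se3 <- 3 * sqrt(0.4 * 0.6 / 50)
  expect_true(all(maf >= 0.1 - se3 & maf <= 0.4 + se3))
  # positions non-decreasing and evenly spaced within chromosomes
  for (ch in unique(g3$map$chrom)) {
    pos <- g3$map$pos_cM[g3$map$chrom == ch]
    expect_true(all(diff(pos) >= 0))
    expect_lt(diff(range(diff(pos))), 1e-8)
  }

  expect_error(make_founders(0, 10), "positive")
  expect_error(make_founders(5, 10, maf_low = 0.4, maf_high = 0.2), "maf")
})

test_that("round robin chains every parent into exactly two crosses", {
  plan <- round_robin(LETTERS[1:20])
  expect_equal(nrow(plan), 20)
  expect_equal(c(plan$female[20], plan$male[20]), c("T", "A"))

  expect_equal(round_robin(c("A", "B", "C")),
               data.frame(female = c("A", "B", "C"),
                          male = c("B", "C", "A")),
               ignore_attr = TRUE)

  for (n in 3:30) {
    p <- round_robin(sprintf("P%02d", 1:n))
    expect_equal(nrow(p), n)
    usage <- table(c(p$female, p$male))
    expect_true(all(usage == 2))
  }

  expect_error(round_robin(c("A", "B")), "at least 3")
  expect_error(round_robin(c("A", "B", "A")), "duplicate")
})

test_that("F1 crosses of inbreds follow Mendelian dosage rules", {
  expect_equal(cross(c(0, 2, 2), c(2, 2, 0)), c(1, 2, 1))
  p <- c(0, 2, 0, 2, 2)
  expect_equal(cross(p, p), p)

  set.seed(2)
  g <- make_founders(2, 500, 5, 100, 0.2, 0.5)
  f1 <- cross(g$dosage[1, ], g$dosage[2, ])
  expect_equal(mean(f1 == 1), mean(g$dosage[1, ] != g$dosage[2, ]))

  expect_error(cross(c(0, 1, 2), c(0, 0, 2)), "inbred")
})

test_that("meiosis reproduces the Haldane map function", {
  map <- data.frame(marker = paste0("M", 1:6), chrom = "01",
                    pos_cM = c(0, 20, 40, 60, 80, 100))
  # homozygous parent: gamete deterministic
  hom <- rep(2, 6)
  expect_equal(meiosis(hom, map, seed = 1), rep(1, 6))

  # fully heterozygous phased F1: adjacent-marker recombination ~ Haldane
  f1 <- list(h1 = rep(1L, 6), h2 = rep(0L, 6))
  set.seed(10)
  gams <- replicate(10000, meiosis(f1, map))
  rec <- rowMeans(apply(gams, 2, function(g) diff(g) != 0))
  c_haldane <- (1 - exp(-2 * 0.2)) / 2
  tol <- 3 * sqrt(c_haldane * (1 - c_haldane) / 10000)
  expect_true(all(abs(rec - c_haldane) < tol + 0.005))

  # mean observable crossover count on a 1-Morgan chromosome ~ 1
  dense <- data.frame(marker = paste0("D", 1:51), chrom = "01",
                      pos_cM = seq(0, 100, by = 2))
  f1d <- list(h1 = rep(1L, 51), h2 = rep(0L, 51))
  set.seed(11)
  switches <- replicate(4000, sum(diff(meiosis(f1d, dense)) != 0))
  expect_gt(mean(switches), 0.9)
  expect_lt(mean(switches), 1.1)

  expect_error(meiosis(rep(2, 4), map), "conformable")
})

test_that("selfing halves heterozygosity per generation and segregates 1:2:1", {
  set.seed(3)
  map <- data.frame(marker = paste0("M", 1:40),
                    chrom = rep(sprintf("%02d", 1:4), each = 10),
                    pos_cM = rep(seq(0, 135, length.out = 10), 4))
  f1 <- list(h1 = rep(1L, 40), h2 = rep(0L, 40))
  het3 <- replicate(10000, heterozygosity(self_ssd(f1, map, 3)))
  expect_lt(abs(mean(het3) - 1 / 8) / (1 / 8), 0.05)

  # fully inbred input is invariant
  inb <- rep(0, 40)
  out <- self_ssd(inb, map, 2, seed = 5)
  expect_equal(dosage_of(out), inb, ignore_attr = TRUE)

  # single-locus F2 segregation 1:2:1
  set.seed(4)
  f2_dos <- replicate(3000, dosage_of(self_once(f1, map))[1])
  freq <- table(factor(f2_dos, levels = 0:2)) / 3000
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.03))

  expect_error(self_ssd(f1, map, 0), "n_generations")
})

test_that("genetic values decompose into additive and dominance parts", {
  arch0 <- trait_arch(5, rep(0, 4), rep(0, 4))
  expect_equal(genetic_value(c(0, 1, 2, 2), arch0), 5)

  arch1 <- trait_arch(0, 1, 0.5)
  expect_equal(genetic_value(0, arch1), -1)
  expect_equal(genetic_value(2, arch1), 1)
  expect_equal(genetic_value(1, arch1), 0.5)

  set.seed(6)
  d <- matrix(sample(0:2, 60, replace = TRUE), 5, 12)
  arch <- trait_arch(2, rnorm(12), rnorm(12))
  got <- genetic_value(d, arch)
  want <- vapply(1:5, function(i) {
    v <- arch$mu
    for (m in 1:12) {
      v <- v + arch$add[m] * (d[i, m] - 1) + arch$dom[m] * (d[i, m] == 1)
    }
    v
  }, 0)
  expect_equal(unname(got), want)

  expect_error(genetic_value(c(0, NA, 2), trait_arch(0, rep(1, 3))),
               "missing")
})

test_that("midparent heterosis of F1s vanishes without dominance", {
  set.seed(8)
  g <- make_founders(10, 100, 2, 100, 0.2, 0.5)
  arch <- sample_architecture(100, 30, mu = 50, mean_k = 0, sd_k = 0)
  expect_true(all(arch$dom == 0))
  plan <- round_robin(rownames(g$dosage))
  for (i in seq_len(nrow(plan))) {
    p1 <- g$dosage[plan$female[i], ]
    p2 <- g$dosage[plan$male[i], ]
    f1v <- genetic_value(cross(p1, p2), arch)
    mid <- (genetic_value(p1, arch) + genetic_value(p2, arch)) / 2
    expect_equal(f1v, mid)
  }
})
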