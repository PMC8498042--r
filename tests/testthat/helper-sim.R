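# Shared fixture builders. Everything is generated in code at test time.

# Balanced hybrid factorial with known variance components; every effect is
# drawn once so the ANOVA and REML estimators see the same realisation.
balanced_hybrid_fixture <- function(seed, nf = 12, nm = 6, nl = 4, nb = 2,
                                    v = list(F = 6, M = 4, FM = 2, FL = 3,
                                             ML = 2, FML = 2, L = 5, B = 1,
                                             E = 2)) {
  set.seed(seed)
  f <- sprintf("F%02d", seq_len(nf))
  m <- sprintf("M%02d", seq_len(nm))
  locs <- paste0("L", seq_len(nl))
  blks <- paste0("B", seq_len(nb))
  gf <- stats::setNames(rnorm(nf, 0, sqrt(v$F)), f)
  gm <- stats::setNames(rnorm(nm, 0, sqrt(v$M)), m)
  sca <- matrix(rnorm(nf * nm, 0, sqrt(v$FM)), nf, nm, dimnames = list(f, m))
  fl <- matrix(rnorm(nf * nl, 0, sqrt(v$FL)), nf, nl, dimnames = list(f, locs))
  ml <- matrix(rnorm(nm * nl, 0, sqrt(v$ML)), nm, nl, dimnames = list(m, locs))
  sl <- array(rnorm(nf * nm * nl, 0, sqrt(v$FML)), c(nf, nm, nl),
              dimnames = list(f, m, locs))
  le <- stats::setNames(rnorm(nl, 0, sqrt(v$L)), locs)
  blk <- matrix(rnorm(nl * nb, 0, sqrt(v$B)), nl, nb,
                dimnames = list(locs, blks))
  tab <- expand.grid(female = f, male = m, location = locs, block = blks,
                     stringsAsFactors = FALSE)
  tab$value <- 50 + gf[tab$female] + gm[tab$male] +
    sca[cbind(tab$female, tab$male)] + le[tab$location] +
    blk[cbind(tab$location, tab$block)] +
    fl[cbind(tab$female, tab$location)] + ml[cbind(tab$male, tab$location)] +
    sl[cbind(tab$female, tab$male, tab$location)] +
    rnorm(nrow(tab), 0, sqrt(v$E))
  tab$genotype_id <- paste(tab$female, tab$male, sep = ":")
  tab$role <- "hybrid"
  tab$female_parent <- tab$female
  tab$male_parent <- tab$male
  tab$year <- "Y1"
  tab
}

# Henderson-III / expected-mean-squares estimator for the balanced fixture
# (independent of the package's REML machinery; uses aov sums of squares).
anova_vc_oracle <- function(tab, nf, nm, nl, nb) {
  a <- stats::aov(value ~ location + location:block + female * male * location,
                  data = tab)
  s <- summary(a)[[1]]
  ms <- s[, "Mean Sq"]
  nms <- trimws(rownames(s))
  g <- function(x) ms[match(x, nms)]
  c(gca_female = (g("female") - g("female:male") - g("location:female") +
                    g("location:female:male")) / (nm * nl * nb),
    gca_male = (g("male") - g("female:male") - g("location:male") +
                  g("location:female:male")) / (nf * nl * nb),
    sca = (g("female:male") - g("location:female:male")) / (nl * nb),
    gca_female_x_e = (g("location:female") - g("location:female:male")) /
      (nm * nb),
    gca_male_x_e = (g("location:male") - g("location:female:male")) /
      (nf * nb),
    sca_x_e = (g("location:female:male") - g("Residuals")) / nb,
    residual = g("Residuals"))
}

# Reduced-scale experiment configuration used by the pipeline tests: the
# programme structure (two genomic selection steps within a round robin of
# 10 families, visual selection, 3 testers, 6 environments with 2 stressed)
# is preserved while counts are shrunk for replicated runs.
test_rrgs_config <- function(...) {
  rrgs_config(n_females = 30, n_males = 6, n_markers = 240,
              n_chromosomes = 6, n_qtl = 60, train_frac = 1,
              n_train_envs = 6, n_c0 = 10, f2_total = 120,
              f2_sel_per_family = 3, n_f5_per_f2 = 4,
              n_f5_per_f2_random = 4, visual_n = 60, visual_n_random = 30,
              n_c1s = 20, n_c1r = 12, n_testers = 3, n_checks = 3, ...)
}

# Simulated line trial: founders, sparse architecture, phenotypes.
line_trial_sim <- function(seed, n = 150, m = 240, n_qtl = 60,
                           h2 = 0.5, mean_k = 0, sd_k = 0) {
  set.seed(seed)
  g <- make_founders(n, m, 5, 120, 0.1, 0.5)
  arch <- sample_architecture(m, n_qtl, mu = 0, mean_k = mean_k, sd_k = sd_k)
  gv <- genetic_value(g, arch)
  y <- gv + rnorm(n, 0, sqrt(var(gv) * (1 - h2) / h2))
  list(geno = g, arch = arch, gv = gv, y = y)
}
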