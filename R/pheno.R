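# Phenotypic data analysis: BLUEs across environments, robust outlier
# control (median/MAD standardised residuals with Bonferroni-Holm), GCA/SCA
# variance components with role dummies, heritability and heterosis.
#
# "Environment" is a location x year combination throughout; single-year
# tables use the location as the environment.

env_label <- function(table) {
  if (length(unique(table$year)) <= 1) as.character(table$location) else
    paste(table$location, table$year, sep = "_")
}

check_pheno_table <- function(table) {
  need <- c("genotype_id", "role", "location", "block", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"year" %in% names(table)) table$year <- "Y1"
  table
}

# Bipartite connectivity of genotypes and environments.
design_connected <- function(geno, env) {
  geno <- as.character(geno)
  env <- as.character(env)
  gset <- geno[1]
  repeat {
    eset <- unique(env[geno %in% gset])
    gnew <- unique(geno[env %in% eset])
    if (length(gnew) == length(gset)) break
    gset <- gnew
  }
  length(gset) == length(unique(geno))
}

#' Best linear unbiased estimates of genotype means
#'
#' Fits phenotype = genotype (fixed) + environment (random) + block within
#' environment (random) + residual, and returns the fixed genotype means.
#' On balanced data with zero environment and block variance the BLUEs are
#' the arithmetic genotype means.
#'
#' @param table long-format phenotype table (`genotype_id`, `role`,
#'   `location`, `year`, `block`, `value`).
#' @param vc `"reml"` (lme4) or a list with `var_env`, `var_block`,
#'   `var_resid` for a generalised-least-squares solve at known variances.
#' @return data.frame (`genotype_id`, `blue`) with attributes `residuals`,
#'   `fitted` and (REML path) `fit`.
#' @export
compute_blues <- function(table, vc = "reml") {
  table <- check_pheno_table(table)
  env <- env_label(table)
  if (!design_connected(table$genotype_id, env)) {
    warning("disconnected design: some genotype groups share no environment")
  }
  table$.env <- factor(env)
  table$.blk <- interaction(table$.env, table$block, sep = ":")
  table$.gid <- factor(table$genotype_id)
  if (identical(vc, "reml")) {
    fit <- lme4::lmer(value ~ 0 + .gid + (1 | .env) + (1 | .blk),
                      data = table,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    b <- lme4::fixef(fit)
    out <- data.frame(genotype_id = sub("^\\.gid", "", names(b)), blue = unname(b),
                      stringsAsFactors = FALSE)
    attr(out, "residuals") <- stats::residuals(fit)
    attr(out, "fitted") <- stats::fitted(fit)
    attr(out, "fit") <- fit
    return(out)
  }
  X <- stats::model.matrix(~ 0 + .gid, table)
  Ze <- stats::model.matrix(~ 0 + .env, table)
  Zb <- stats::model.matrix(~ 0 + .blk, table)
  V <- vc$var_env * tcrossprod(Ze) + vc$var_block * tcrossprod(Zb) +
    diag(vc$var_resid, nrow(table))
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  b <- solve(XtVi %*% X, XtVi %*% table$value)
  fitted <- drop(X %*% b)
  out <- data.frame(genotype_id = levels(table$.gid), blue = drop(b),
                    stringsAsFactors = FALSE)
  attr(out, "residuals") <- table$value - fitted
  attr(out, "fitted") <- fitted
  out
}

#' Robust outlier flagging (median/MAD + Bonferroni-Holm)
#'
#' Residuals from the genotype-means model are standardised robustly by
#' their median and MAD, converted to two-sided normal p-values, and
#' flagged after Bonferroni-Holm control at `alpha`. Flagged records are
#' intended to be removed before downstream analysis.
#'
#' @param table phenotype table; the means model is fitted internally when
#'   `residuals` is not supplied.
#' @param residuals optional residual vector aligned with `table` rows.
#' @param alpha family-wise error level (default 0.05).
#' @return The flagged rows of `table` with extra columns `std_resid` and
#'   `p_adj`; attribute `n_tested` carries the family size.
#' @export
detect_outliers_m4r <- function(table, residuals = NULL, alpha = 0.05) {
  table <- check_pheno_table(table)
  if (is.null(residuals)) {
    residuals <- attr(compute_blues(table), "residuals")
  }
  md <- stats::median(residuals)
  s <- stats::mad(residuals)
  if (s == 0) {
    warning("MAD of residuals is zero; no outliers flagged")
    out <- table[integer(0), ]
    out$std_resid <- numeric(0)
    out$p_adj <- numeric(0)
    attr(out, "n_tested") <- nrow(table)
    return(out)
  }
  std <- (residuals - md) / s
  p <- 2 * stats::pnorm(-abs(std))
  padj <- stats::p.adjust(p, method = "holm")
  keep <- which(padj < alpha)
  out <- table[keep, , drop = FALSE]
  out$std_resid <- std[keep]
  out$p_adj <- padj[keep]
  attr(out, "n_tested") <- nrow(table)
  out
}

#' GCA/SCA variance components with role dummies
#'
#' Fits the across-environment mixed model with environment and
#' block-within-environment effects, a parental-line genetic term for
#' lines (and checks, unless excluded), female and male general combining
#' abilities and their specific combining ability for hybrids, and the
#' interactions of each genetic term with the environment. Role dummies
#' restrict each genetic term to the records of its role. Negative
#' estimates are floored at zero by the REML fit itself.
#'
#' @param table phenotype table with lines and/or hybrids (hybrids carry
#'   `female_parent` and `male_parent`).
#' @param exclude_checks give checks their own variance term instead of
#'   pooling them with the lines (default FALSE).
#' @return Object of class `vc_fit`: `components` (named vector with NA
#'   for terms absent from the design), `derived` (sigma2_hybrids and its
#'   GxE analogue), `l` (mean environment count per role), `blups`
#'   (including the female-GCA x environment matrix), `fit`.
#' @export
fit_variance_components <- function(table, exclude_checks = FALSE) {
  table <- check_pheno_table(table)
  if (!all(c("female_parent", "male_parent") %in% names(table))) {
    table$female_parent <- NA_character_
    table$male_parent <- NA_character_
  }
  tab <- table
  tab$.env <- factor(env_label(tab))
  tab$.blk <- interaction(tab$.env, tab$block, sep = ":")
  is_hyb <- tab$role == "hybrid"
  if (any(is_hyb & (is.na(tab$female_parent) | is.na(tab$male_parent)))) {
    stop("hybrids must carry both parent annotations")
  }
  line_roles <- if (exclude_checks) "line" else c("line", "check")
  tab$d_line <- as.numeric(tab$role %in% line_roles)
  tab$d_check <- as.numeric(exclude_checks & tab$role == "check")
  tab$d_hyb <- as.numeric(is_hyb)
  lvl <- function(x, use) factor(ifelse(use, x, "none"))
  tab$.line <- lvl(tab$genotype_id, tab$d_line == 1)
  tab$.chk <- lvl(tab$genotype_id, tab$d_check == 1)
  tab$.fem <- lvl(tab$female_parent, is_hyb)
  tab$.mal <- lvl(tab$male_parent, is_hyb)
  tab$.fm <- interaction(tab$.fem, tab$.mal, sep = ":")
  tab$.line_e <- interaction(tab$.line, tab$.env, sep = "@")
  tab$.fem_e <- interaction(tab$.fem, tab$.env, sep = "@")
  tab$.mal_e <- interaction(tab$.mal, tab$.env, sep = "@")
  tab$.fm_e <- interaction(tab$.fm, tab$.env, sep = "@")

  terms <- c("(1 | .env)", "(1 | .blk)")
  has_lines <- any(tab$d_line == 1)
  has_hyb <- any(is_hyb)
  if (has_lines) terms <- c(terms, "(0 + d_line | .line)", "(0 + d_line | .line_e)")
  if (any(tab$d_check == 1)) terms <- c(terms, "(0 + d_check | .chk)")
  if (has_hyb) terms <- c(terms,
                          "(0 + d_hyb | .fem)", "(0 + d_hyb | .mal)",
                          "(0 + d_hyb | .fm)", "(0 + d_hyb | .fem_e)",
                          "(0 + d_hyb | .mal_e)", "(0 + d_hyb | .fm_e)")
  if (!has_lines && !has_hyb) stop("table contains neither lines nor hybrids")
  form <- stats::as.formula(paste("value ~ 1 +", paste(terms, collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = tab,
               control = lme4::lmerControl(
                 calc.derivs = FALSE,
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.rankZ = "ignore",
                 check.nobs.vs.nRE = "ignore"))))
  vcd <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    i <- match(grp, vcd$grp)
    if (is.na(i)) NA_real_ else vcd$vcov[i]
  }
  comp <- c(env = getv(".env"), block = getv(".blk"),
            lines = getv(".line"), lines_x_e = getv(".line_e"),
            checks = getv(".chk"),
            gca_female = getv(".fem"), gca_female_x_e = getv(".fem_e"),
            gca_male = getv(".mal"), gca_male_x_e = getv(".mal_e"),
            sca = getv(".fm"), sca_x_e = getv(".fm_e"),
            residual = vcd$vcov[vcd$grp == "Residual"])
  derived <- c(
    hybrids = unname(comp["gca_female"] + comp["gca_male"] + comp["sca"]),
    hybrids_x_e = unname(comp["gca_female_x_e"] + comp["gca_male_x_e"] +
                           comp["sca_x_e"]))
  env_per <- tapply(tab$.env, tab$genotype_id,
                    function(e) length(unique(e)))
  role_of <- tapply(tab$role, tab$genotype_id, function(r) r[1])
  l <- c(lines = mean(env_per[role_of %in% line_roles]),
         hybrids = mean(env_per[role_of == "hybrid"]))
  re <- lme4::ranef(fit)
  blups <- list()
  if (has_hyb) {
    fe <- re$.fem_e
    ids <- do.call(rbind, strsplit(rownames(fe), "@", fixed = TRUE))
    keep <- ids[, 1] != "none"
    m <- stats::xtabs(fe[keep, 1] ~ factor(ids[keep, 1]) + factor(ids[keep, 2]))
    blups$gca_female_x_e <- matrix(m, nrow(m), ncol(m),
                                   dimnames = list(rownames(m), colnames(m)))
    gf <- re$.fem
    blups$gca_female <- stats::setNames(gf[, 1], rownames(gf))[rownames(gf) != "none"]
  }
  structure(list(components = comp, derived = derived, l = l,
                 blups = blups, fit = fit),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Variance components:\n")
  print(round(x$components, 4))
  cat("Derived:\n")
  print(round(x$derived, 4))
  invisible(x)
}

#' Broad-sense heritability across environments
#'
#' h2 = s2_G / (s2_G + (s2_GxE + s2_e) / l) with `l` the average number of
#' environments in which the genotypes were tested.
#'
#' @param s2_g genetic variance.
#' @param s2_gxe genotype-by-environment variance.
#' @param s2_e residual variance.
#' @param l average number of environments (> 0).
#' @export
heritability <- function(s2_g, s2_gxe, s2_e, l) {
  if (any(c(s2_g, s2_gxe, s2_e) < 0)) stop("variances must be non-negative")
  if (l <= 0) stop("l must be positive")
  s2_g / (s2_g + (s2_gxe + s2_e) / l)
}

#' Ratio of genotype-by-environment to genetic variance
#' @param s2_gxe,s2_g variances; `s2_g` must be positive.
#' @export
gxe_ratio <- function(s2_gxe, s2_g) {
  if (s2_g <= 0) stop("s2_g must be positive")
  s2_gxe / s2_g
}

#' Midparent and better-parent heterosis
#'
#' MPH = 100 (F1 - midparent) / midparent and
#' BPH = 100 (F1 - better parent) / better parent, in percent. Undefined
#' (NA, with a warning) when the midparent or better-parent mean is not
#' positive — heterosis percentages are not meaningful for such yields.
#'
#' @param hybrid,parent1,parent2 numeric vectors of means (recycled).
#' @return data.frame with columns `mph` and `bph`.
#' @export
heterosis <- function(hybrid, parent1, parent2) {
  mp <- (parent1 + parent2) / 2
  bp <- pmax(parent1, parent2)
  bad <- mp <= 0 | bp <= 0
  if (any(bad, na.rm = TRUE)) {
    warning("non-positive parent means: heterosis undefined, returned as NA")
  }
  mph <- ifelse(bad, NA_real_, 100 * (hybrid - mp) / mp)
  bph <- ifelse(bad, NA_real_, 100 * (hybrid - bp) / bp)
  data.frame(mph = mph, bph = bph)
}
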