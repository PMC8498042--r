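# Additive + dominance trait architectures and genetic values.
# Additive coding is heterozygote-centred: dosage - 1 in {-1, 0, 1}, so the
# dominance column is a pure heterozygosity indicator.

#' Trait architecture
#'
#' Per-marker additive and dominance effects plus intercept. The degree of
#' dominance at a marker is k = d/a (defined where a != 0).
#'
#' @param mu intercept in trait units.
#' @param add per-marker additive effect (trait units per allele copy).
#' @param dom per-marker dominance effect, applied to heterozygotes.
#' @return An object of class `trait_arch`.
#' @export
trait_arch <- function(mu, add, dom = rep(0, length(add))) {
  if (length(add) != length(dom)) stop("add and dom must have equal length")
  structure(list(mu = mu, add = as.numeric(add), dom = as.numeric(dom)),
            class = "trait_arch")
}

#' Sample a sparse additive + dominance architecture
#'
#' Draws `n_qtl` causal markers with additive effects a ~ N(0, sd_a^2) and
#' dominance effects d = k |a| with per-locus degree of dominance
#' k ~ N(mean_k, sd_k^2). A positive mean degree of dominance generates
#' midparent heterosis in hybrids of unrelated inbreds.
#'
#' @param n_markers total markers (non-causal markers get zero effects).
#' @param n_qtl number of causal markers.
#' @param mu intercept (e.g. a grain-yield level in dt/ha).
#' @param sd_a standard deviation of additive effects.
#' @param mean_k,sd_k mean and sd of the per-locus degree of dominance.
#' @param seed optional integer seed.
#' @export
sample_architecture <- function(n_markers, n_qtl, mu = 0, sd_a = 1,
                                mean_k = 0.5, sd_k = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_qtl > n_markers) stop("n_qtl must not exceed n_markers")
  add <- dom <- rep(0, n_markers)
  qtl <- sort(sample.int(n_markers, n_qtl))
  a <- stats::rnorm(n_qtl, 0, sd_a)
  k <- stats::rnorm(n_qtl, mean_k, sd_k)
  add[qtl] <- a
  dom[qtl] <- k * abs(a)
  trait_arch(mu, add, dom)
}

#' Rescale an architecture to a target genetic variance
#'
#' Multiplies additive and dominance effects by a common factor so that the
#' variance of genetic values in a reference panel equals `target_var`.
#'
#' @param arch a [trait_arch()].
#' @param geno reference [geno_matrix()].
#' @param target_var desired variance of genetic values in the panel.
#' @export
scale_architecture <- function(arch, geno, target_var) {
  g <- genetic_value(geno, arch)
  v <- stats::var(g)
  if (v <= 0) stop("reference panel has zero genetic variance")
  f <- sqrt(target_var / v)
  trait_arch(arch$mu, arch$add * f, arch$dom * f)
}

#' Genetic value of genotypes under an architecture
#'
#' Computes mu + sum_m a_m (dosage_m - 1) + sum_m d_m [dosage_m == 1].
#'
#' @param geno a [geno_matrix()], dosage matrix, or single dosage vector.
#' @param arch a [trait_arch()].
#' @return Numeric vector of genetic values (named by individual for matrix
#'   input).
#' @export
genetic_value <- function(geno, arch) {
  d <- if (inherits(geno, "geno_matrix")) geno$dosage else geno
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  if (ncol(d) != length(arch$add)) stop("marker dimensions do not match")
  if (anyNA(d)) stop("missing dosages must be imputed before scoring")
  v <- arch$mu + drop((d - 1) %*% arch$add) + drop((d == 1) %*% arch$dom)
  if (!is.null(rownames(d))) names(v) <- rownames(d)
  v
}

#' Expected hybrid value for a candidate x tester cross
#'
#' For a (possibly heterozygous) candidate crossed to an inbred tester the
#' expected offspring value under additive + dominance gene action is
#' mu + sum a z + sum d p_het, with z the mean of the parental centred
#' dosages and p_het the probability the offspring is heterozygous.
#'
#' @param cand dosage vector of the candidate (0/1/2).
#' @param tester dosage vector of the tester.
#' @param arch a [trait_arch()].
#' @export
expected_cross_value <- function(cand, tester, arch) {
  za <- ((cand - 1) + (tester - 1)) / 2
  pr_c <- cand / 2
  pr_t <- tester / 2
  phet <- pr_c * (1 - pr_t) + (1 - pr_c) * pr_t
  arch$mu + sum(za * arch$add) + sum(phet * arch$dom)
}

#' True general combining ability against a tester panel
#'
#' Mean expected hybrid value of each candidate over the testers, centred by
#' the grand mean over all candidate x tester combinations.
#'
#' @param cand_geno [geno_matrix()] or dosage matrix of candidates.
#' @param tester_geno [geno_matrix()] or dosage matrix of inbred testers.
#' @param arch a [trait_arch()].
#' @param center subtract the grand mean (default TRUE).
#' @export
true_gca <- function(cand_geno, tester_geno, arch, center = TRUE) {
  cd <- if (inherits(cand_geno, "geno_matrix")) cand_geno$dosage else cand_geno
  td <- if (inherits(tester_geno, "geno_matrix")) tester_geno$dosage else tester_geno
  zc <- cd - 1
  za_part <- drop(zc %*% arch$add) / 2
  out <- numeric(nrow(cd))
  for (t in seq_len(nrow(td))) {
    zt <- td[t, ] - 1
    phet <- sweep(cd / 2, 2, 1 - td[t, ] / 2, `*`) +
      sweep(1 - cd / 2, 2, td[t, ] / 2, `*`)
    out <- out + arch$mu + za_part + sum(zt * arch$add) / 2 +
      drop(phet %*% arch$dom)
  }
  out <- out / nrow(td)
  names(out) <- rownames(cd)
  if (center) out - mean(out) else out
}
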