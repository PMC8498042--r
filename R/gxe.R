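# Genotype-by-environment diagnostics: interaction-effect matrices,
# Euclidean-distance / complete-linkage clustering, PCA, Mantel tests, and
# environment characterisation via vegetation condition indices.

#' Female-GCA x environment interaction effects
#'
#' Extracts the BLUPs of the female-GCA-by-environment term from a
#' [fit_variance_components()] fit, arranged as a females x environments
#' matrix.
#'
#' @param vcfit a `vc_fit` object.
#' @export
interaction_effects <- function(vcfit) {
  if (!inherits(vcfit, "vc_fit")) stop("expected a vc_fit object")
  m <- vcfit$blups$gca_female_x_e
  if (is.null(m)) stop("female-GCA x environment term absent from the fit")
  m
}

#' Pairwise Euclidean distances between matrix columns
#'
#' @param m numeric matrix without missing cells.
#' @param axis `"columns"` (default) or `"rows"`.
#' @return A `dist` object.
#' @export
euclidean_distances <- function(m, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  if (anyNA(m)) stop("missing cells in input matrix")
  x <- if (axis == "columns") t(m) else m
  if (nrow(x) < 2) stop("need at least 2 ", axis)
  stats::dist(x, method = "euclidean")
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering under the maximum-linkage rule, with an
#' optional flat cut.
#'
#' @param d a `dist` object or symmetric distance matrix with zero
#'   diagonal.
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust` (the merge tree) and, when `k` is given,
#'   `clusters` (named membership vector).
#' @export
complete_linkage <- function(d, k = NULL) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m))) stop("distance matrix must be symmetric")
    d <- stats::as.dist(m)
  }
  hc <- stats::hclust(d, method = "complete")
  out <- list(hclust = hc)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}

#' Export a dendrogram as a Newick tree
#'
#' Branch lengths derive from the merge heights; Newick is a standard,
#' diff-able text format for tree output.
#'
#' @param hc an `hclust` object (or the list returned by
#'   [complete_linkage()]).
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  if (is.list(hc) && !inherits(hc, "hclust")) hc <- hc$hclust
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Principal component analysis with a fixed sign convention
#'
#' Singular-value decomposition of the (optionally centred / scaled)
#' matrix. Signs are fixed so that the largest-magnitude loading of every
#' component is positive; explained-variance fractions sum to 1.
#'
#' @param m numeric matrix (>= 2 rows and columns).
#' @param center,scale passed to the decomposition (default: centre, do
#'   not scale).
#' @return list of class `pca_decomp`: `scores`, `loadings`, `explained`,
#'   `center`, `scale`.
#' @export
pca_decomp <- function(m, center = TRUE, scale = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  if (stats::sd(as.vector(m)) == 0) stop("constant matrix")
  pr <- stats::prcomp(m, center = center, scale. = scale)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pr$rotation <- sweep(pr$rotation, 2, flip, `*`)
  pr$x <- sweep(pr$x, 2, flip, `*`)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x, loadings = pr$rotation, explained = expl,
                 center = if (isTRUE(center)) pr$center else FALSE,
                 scale = if (isTRUE(scale)) pr$scale else FALSE),
            class = "pca_decomp")
}

#' Project new rows onto a reference PCA
#'
#' New rows are centred (and scaled) with the reference statistics and
#' multiplied by the reference loadings.
#'
#' @param pca a [pca_decomp()] object.
#' @param newdata matrix with the same columns as the reference set.
#' @export
project_onto <- function(pca, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(pca$loadings)) stop("column mismatch")
  x <- newdata
  if (!isFALSE(pca$center)) x <- sweep(x, 2, pca$center)
  if (!isFALSE(pca$scale)) x <- sweep(x, 2, pca$scale, `/`)
  x %*% pca$loadings
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries; the one-sided (upper)
#' p-value comes from permuting the id order of the second matrix. When
#' the number of ids is small enough that all n! permutations fit within
#' `n_permutations`, the permutation distribution is enumerated exactly;
#' otherwise random permutations are drawn and
#' p = (1 + #\{r_perm >= r\}) / (n_permutations + 1).
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same ids.
#' @param n_permutations number of permutations (>= 99).
#' @param seed optional integer seed.
#' @return list with `r`, `p`, `n_permutations`, `method`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_permutations < 99) stop("need at least 99 permutations")
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("distance matrices must share the same ids in the same order")
  }
  n <- nrow(m1)
  lower <- lower.tri(m1)
  v1 <- m1[lower]
  r_obs <- stats::cor(v1, m2[lower])
  if (factorial(n) <= n_permutations) {
    perms <- all_permutations(n)
    rp <- apply(perms, 1, function(p) stats::cor(v1, m2[p, p][lower]))
    p <- mean(rp >= r_obs - 1e-12)
    method <- "exact"
    nper <- nrow(perms)
  } else {
    rp <- replicate(n_permutations, {
      p <- sample.int(n)
      stats::cor(v1, m2[p, p][lower])
    })
    p <- (1 + sum(rp >= r_obs - 1e-12)) / (n_permutations + 1)
    method <- "sampled"
    nper <- n_permutations
  }
  list(r = r_obs, p = p, n_permutations = nper, method = method)
}

#' Vegetation condition index
#'
#' VCI_i = (EVI_i - EVI_min) / (EVI_max - EVI_min), clamped to `[0, 1]`.
#' The reference extremes are the minimum and maximum EVI observed in the
#' area over the reference period; observed series may exceed them, hence
#' the clamp.
#'
#' @param profile an [env_profile()] (or a list with `evi`, `evi_min`,
#'   `evi_max`).
#' @return Numeric VCI series aligned with the profile dates.
#' @export
vci <- function(profile) {
  if (profile$evi_max <= profile$evi_min) stop("EVI_max must exceed EVI_min")
  v <- (profile$evi - profile$evi_min) / (profile$evi_max - profile$evi_min)
  pmin(pmax(v, 0), 1)
}

#' Euclidean distances between environment covariate profiles
#'
#' Profiles are linearly interpolated onto a common date grid spanning the
#' overlap of all series, then compared as vectors.
#'
#' @param profiles list of [env_profile()] objects.
#' @param on `"vci"` (default) or `"paw"`.
#' @param n_grid number of grid points for resampling.
#' @return A `dist` object over the locations.
#' @export
profile_distances <- function(profiles, on = c("vci", "paw"), n_grid = 50) {
  on <- match.arg(on)
  t0 <- max(vapply(profiles, function(p) min(as.numeric(p$dates)), 0))
  t1 <- min(vapply(profiles, function(p) max(as.numeric(p$dates)), 0))
  if (t0 >= t1) stop("profiles have non-overlapping date ranges")
  grid <- seq(t0, t1, length.out = n_grid)
  series <- vapply(profiles, function(p) {
    y <- if (on == "vci") vci(p) else p$paw
    if (is.null(y)) stop("profile lacks a ", on, " series")
    stats::approx(as.numeric(p$dates), y, xout = grid)$y
  }, numeric(n_grid))
  colnames(series) <- vapply(profiles, function(p) p$location_id, "")
  euclidean_distances(series, axis = "columns")
}
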