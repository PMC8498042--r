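# Genomic prediction: VanRaden GRM, ridge-regression BLUP with additive and
# dominance marker effects, GBLUP, and hybrid / GCA prediction.
#
# Variance components are estimated by an EM-type fixed-point REML whose
# stationary points solve the REML score equations; the single-kernel case
# runs in a spectral parameterisation (one eigendecomposition, then O(n)
# iterations). GBLUP uses an independent profiled-likelihood route over the
# variance ratio, which doubles as an internal cross-check of the EM path.

#' VanRaden genomic relationship matrix
#'
#' G = W W' / (2 sum p_m (1 - p_m)) with W the allele-frequency-centred
#' dosage matrix; allele frequencies are computed from the supplied panel.
#' Monomorphic markers contribute zero to both numerator and denominator.
#'
#' @param geno a [geno_matrix()] or dosage matrix (no missing values).
#' @return Symmetric relationship matrix with individual ids as dimnames.
#' @export
vanraden_grm <- function(geno) {
  d <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  if (nrow(d) < 2) stop("need at least 2 individuals")
  if (anyNA(d)) stop("impute missing dosages before computing the GRM")
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all markers are monomorphic")
  w <- sweep(d, 2, 2 * p)
  g <- tcrossprod(w) / denom
  dimnames(g) <- list(rownames(d), rownames(d))
  g
}

#' Additive / dominance design rows for lines
#'
#' Heterozygote-centred coding: additive column is dosage - 1 in
#' \{-1, 0, 1\}; dominance column is the heterozygosity indicator.
#'
#' @param geno a [geno_matrix()] or dosage matrix.
#' @return list with matrices `ZA` and `ZD`.
#' @export
line_design_matrices <- function(geno) {
  d <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  list(ZA = d - 1, ZD = (d == 1) * 1)
}

# Expected additive / dominance row of the cross candidate x tester.
# Valid for heterozygous candidates: the additive entry is the mean of the
# parental centred dosages, the dominance entry the probability that the
# offspring is heterozygous.
cross_design_row <- function(cand, tester) {
  pr_c <- cand / 2
  pr_t <- tester / 2
  list(za = ((cand - 1) + (tester - 1)) / 2,
       zd = pr_c * (1 - pr_t) + (1 - pr_c) * pr_t)
}

#' Hybrid design matrices for a crossing plan
#'
#' Per hybrid, the additive row is the mean of the parental centred dosages
#' and the dominance row indicates the loci at which the (inbred) parents
#' differ, i.e. the hybrid's heterozygous loci.
#'
#' @param geno a [geno_matrix()] holding all parents (inbred).
#' @param plan data.frame with columns `female`, `male` (ids in `geno`).
#' @return list with `ZA`, `ZD` (hybrids x markers, rownames "female:male")
#'   and `hybrid_ids`.
#' @export
hybrid_design_matrices <- function(geno, plan) {
  d <- geno$dosage
  miss <- setdiff(unique(c(plan$female, plan$male)), rownames(d))
  if (length(miss)) stop("parent ids not in genotype matrix: ",
                         paste(miss, collapse = ", "))
  pd <- d[unique(c(plan$female, plan$male)), , drop = FALSE]
  if (any(pd == 1, na.rm = TRUE)) stop("parents must be fully inbred")
  zf <- d[plan$female, , drop = FALSE] - 1
  zm <- d[plan$male, , drop = FALSE] - 1
  za <- (zf + zm) / 2
  zd <- (zf != zm) * 1
  ids <- paste(plan$female, plan$male, sep = ":")
  rownames(za) <- rownames(zd) <- ids
  list(ZA = za, ZD = zd, hybrid_ids = ids)
}

# ---- REML engines ---------------------------------------------------------

# Dense EM fixed-point REML for y = X b + sum_k u_k + e, u_k ~ N(0, s2_k K_k).
# q gives the effective effect count per kernel (ncol(Z) for K = Z Z').
fit_kernel_reml_dense <- function(y, Klist, q = NULL, X = NULL,
                                  tol = 1e-8, maxit = 500, start = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(q)) q <- rep(n, length(Klist))
  vy <- stats::var(y)
  if (vy == 0) stop("zero phenotypic variance: cannot estimate variance components")
  floor_v <- 1e-10 * vy
  nk <- length(Klist)
  kscale <- vapply(Klist, function(K) mean(diag(K)), numeric(1))
  s2 <- if (is.null(start)) vy / (nk + 1) / pmax(kscale, 1e-12) else start[seq_len(nk)]
  se2 <- if (is.null(start)) vy / (nk + 1) else start[nk + 1]
  ll_old <- -Inf
  converged <- FALSE
  it <- 0
  for (it in seq_len(maxit)) {
    V <- diag(se2, n)
    for (k in seq_len(nk)) V <- V + s2[k] * Klist[[k]]
    ch <- chol(V)
    Vinv <- chol2inv(ch)
    XtViX <- crossprod(X, Vinv %*% X)
    B <- Vinv %*% X %*% solve(XtViX, crossprod(X, Vinv))
    P <- Vinv - B
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
                    sum(y * Py))
    if (abs(ll - ll_old) <= tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    for (k in seq_len(nk)) {
      KPy <- Klist[[k]] %*% Py
      s2[k] <- max(s2[k] + (s2[k]^2 / q[k]) *
                     (sum(Py * KPy) - sum(P * Klist[[k]])), floor_v / kscale[k])
    }
    se2 <- max(se2 + (se2^2 / n) * (sum(Py * Py) - sum(diag(P))), floor_v)
  }
  list(vc = c(s2, se2), loglik = ll, converged = converged, iterations = it)
}

# Spectral EM REML for a single kernel with X = intercept. One
# eigendecomposition of S (K + I) S, then O(n) iterations.
fit_kernel_reml_spectral <- function(y, K, q = NULL, tol = 1e-8,
                                     maxit = 500) {
  n <- length(y)
  if (is.null(q)) q <- n
  vy <- stats::var(y)
  if (vy == 0) stop("zero phenotypic variance: cannot estimate variance components")
  floor_v <- 1e-10 * vy
  yc <- y - mean(y)
  M <- K + diag(n)
  M <- M - rep(colMeans(M), each = n)
  M <- M - rowMeans(M)  # S (K + I) S
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-8
  xi <- eg$values[keep] - 1
  xi[xi < 0] <- 0
  U <- eg$vectors[, keep, drop = FALSE]
  eta <- drop(crossprod(U, yc))
  kscale <- mean(diag(K))
  s2 <- vy / 2 / max(kscale, 1e-12)
  se2 <- vy / 2
  ll_old <- -Inf
  converged <- FALSE
  it <- 0
  for (it in seq_len(maxit)) {
    w <- s2 * xi + se2
    ll <- -0.5 * (sum(log(w)) + sum(eta^2 / w))
    if (abs(ll - ll_old) <= tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    s2 <- max(s2 + (s2^2 / q) * (sum(xi * eta^2 / w^2) - sum(xi / w)),
              floor_v / kscale)
    se2 <- max(se2 + (se2^2 / n) * (sum(eta^2 / w^2) - sum(1 / w)), floor_v)
  }
  list(vc = c(s2, se2), loglik = ll, converged = converged, iterations = it)
}

#' EM-REML for kernel variance components
#'
#' @param y numeric response.
#' @param Klist list of n x n positive semidefinite kernels.
#' @param q effective number of effects per kernel (`ncol(Z)` when
#'   `K = Z Z'`); defaults to n.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum iterations; non-convergence is reported in the
#'   result, not silent.
#' @return list with `vc` (kernel variances followed by the residual),
#'   `loglik`, `converged`, `iterations`.
#' @export
fit_kernel_reml <- function(y, Klist, q = NULL, tol = 1e-8, maxit = 500) {
  if (!is.list(Klist)) Klist <- list(Klist)
  if (length(Klist) == 1) {
    fit_kernel_reml_spectral(y, Klist[[1]], q = if (is.null(q)) NULL else q[1],
                             tol = tol, maxit = maxit)
  } else {
    fit_kernel_reml_dense(y, Klist, q = q, tol = tol, maxit = maxit)
  }
}

# Given variance components, compute mu (GLS) and Py for kernels.
kernel_solve <- function(y, Klist, vc, jitter = 0) {
  n <- length(y)
  V <- diag(vc[length(Klist) + 1] + jitter, n)
  for (k in seq_along(Klist)) V <- V + vc[k] * Klist[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(V + diag(1e-8, n))
  Vinv <- chol2inv(ch)
  one <- rep(1, n)
  Vi1 <- Vinv %*% one
  mu <- sum(Vi1 * y) / sum(Vi1)
  Py <- drop(Vinv %*% (y - mu))
  list(mu = mu, Py = Py, Vinv = Vinv)
}

#' Fit ridge-regression BLUP with additive and dominance effects
#'
#' Solves y = 1 mu + Z_A a + Z_D d + e with ridge penalties
#' lambda_a = s2_e / s2_a on additive and lambda_d = s2_e / s2_d on
#' dominance effects. Variance components are either supplied or estimated
#' by EM-REML on the equivalent kernel model.
#'
#' @param y named numeric phenotype vector.
#' @param ZA additive design matrix (individuals x markers).
#' @param ZD optional dominance design matrix (same shape).
#' @param vc `"reml"` or a list with `sa2`, `sd2` (ignored when `ZD` is
#'   NULL) and `se2`.
#' @param tol,maxit REML convergence control.
#' @return Object of class `rrblup_model` with elements `mu`, `a`, `d`,
#'   `vc`, `marker_ids`, `coding`, `converged`, `iterations`, `loglik`.
#' @export
fit_rrblup_ad <- function(y, ZA, ZD = NULL, vc = "reml", tol = 1e-8,
                          maxit = 500) {
  ZA <- as.matrix(ZA)
  n <- length(y)
  if (nrow(ZA) != n) stop("ZA not conformable with y")
  if (!is.null(ZD)) {
    ZD <- as.matrix(ZD)
    if (!any(ZD != 0)) ZD <- NULL
  }
  Klist <- list(tcrossprod(ZA))
  if (!is.null(ZD)) Klist$KD <- tcrossprod(ZD)
  est <- NULL
  if (identical(vc, "reml")) {
    if (length(unique(y)) < 2) stop("REML needs at least 2 distinct phenotypes")
    q <- c(ncol(ZA), if (!is.null(ZD)) ncol(ZD))
    est <- fit_kernel_reml(y, Klist, q = q, tol = tol, maxit = maxit)
    if (!est$converged) {
      warning("EM-REML did not converge in ", maxit, " iterations")
    }
    v <- est$vc
  } else {
    v <- c(vc$sa2, if (!is.null(ZD)) vc$sd2, vc$se2)
  }
  ks <- kernel_solve(y, Klist, v)
  a <- v[1] * drop(crossprod(ZA, ks$Py))
  d <- if (!is.null(ZD)) v[2] * drop(crossprod(ZD, ks$Py)) else
    rep(0, ncol(ZA))
  names(a) <- names(d) <- colnames(ZA)
  structure(list(mu = ks$mu, a = a, d = d,
                 vc = list(sa2 = v[1],
                           sd2 = if (!is.null(ZD)) v[2] else 0,
                           se2 = v[length(v)]),
                 marker_ids = colnames(ZA), coding = "het_centered",
                 converged = if (is.null(est)) TRUE else est$converged,
                 iterations = if (is.null(est)) 0L else est$iterations,
                 loglik = if (is.null(est)) NA_real_ else est$loglik),
            class = "rrblup_model")
}

#' @export
print.rrblup_model <- function(x, ...) {
  cat(sprintf("rrblup_model: %d markers, mu = %.4g, sa2 = %.4g, sd2 = %.4g, se2 = %.4g\n",
              length(x$a), x$mu, x$vc$sa2, x$vc$sd2, x$vc$se2))
  invisible(x)
}

#' Fit GBLUP from a genomic relationship matrix
#'
#' y = 1 mu + g + e with g ~ N(0, G s2_g). REML maximises the profiled
#' restricted likelihood over the variance ratio on the spectrum of the
#' projected GRM; a small diagonal jitter is added if the covariance fails
#' to factorise.
#'
#' @param y named numeric phenotype vector (names matching `grm`).
#' @param grm genomic relationship matrix, e.g. [vanraden_grm()].
#' @param vc `"reml"` or a list with `sg2`, `se2`.
#' @return list of class `gblup_fit` with `mu`, `g` (named BLUPs), `vc`.
#' @export
fit_gblup <- function(y, grm, vc = "reml") {
  n <- length(y)
  G <- as.matrix(grm)
  if (!all(dim(G) == n)) stop("grm not conformable with y")
  if (identical(vc, "reml")) {
    if (stats::var(y) == 0) stop("zero phenotypic variance: cannot run REML")
    yc <- y - mean(y)
    M <- G + diag(n)
    M <- M - rep(colMeans(M), each = n)
    M <- M - rowMeans(M)
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    keep <- eg$values > 1e-8
    xi <- pmax(eg$values[keep] - 1, 0)
    eta <- drop(crossprod(eg$vectors[, keep, drop = FALSE], yc))
    m <- length(eta)
    negll <- function(loglam) {
      lam <- exp(loglam)
      w <- xi + lam
      r <- sum(eta^2 / w)
      0.5 * (m * log(r) + sum(log(w)))
    }
    opt <- stats::optimize(negll, c(-14, 14))
    lam <- exp(opt$minimum)
    sg2 <- sum(eta^2 / (xi + lam)) / m
    se2 <- lam * sg2
    vc <- list(sg2 = sg2, se2 = se2)
  }
  ks <- kernel_solve(y, list(G), c(vc$sg2, vc$se2))
  g <- vc$sg2 * drop(G %*% ks$Py)
  names(g) <- names(y)
  structure(list(mu = ks$mu, g = g, vc = vc), class = "gblup_fit")
}

get_dosage_row <- function(geno, id) {
  d <- if (inherits(geno, "geno_matrix")) geno$dosage else geno
  if (!id %in% rownames(d)) stop("id not found in genotypes: ", id)
  d[id, ]
}

check_markers <- function(model, geno) {
  d <- if (inherits(geno, "geno_matrix")) geno$dosage else geno
  if (!identical(colnames(d), model$marker_ids)) {
    stop("marker set of genotypes does not match the trained model")
  }
}

#' Predict the performance of one hybrid
#'
#' mu + z_A' a + z_D' d for the expected design rows of the cross. Parents
#' may be heterozygous (e.g. F2 candidates): the additive row is the mean
#' of the parental centred dosages, the dominance row the expected
#' offspring heterozygosity per locus.
#'
#' @param model a fitted [fit_rrblup_ad()] model.
#' @param female,male individual ids.
#' @param geno a [geno_matrix()] holding both parents.
#' @export
predict_hybrid <- function(model, female, male, geno) {
  check_markers(model, geno)
  rowf <- get_dosage_row(geno, female)
  rowm <- get_dosage_row(geno, male)
  dr <- cross_design_row(rowf, rowm)
  model$mu + sum(dr$za * model$a) + sum(dr$zd * model$d)
}

#' Predict general combining abilities against a tester panel
#'
#' GCA(candidate) = mean over testers of the predicted hybrid value, minus
#' the grand mean over all candidate x tester combinations.
#'
#' @param model a fitted [fit_rrblup_ad()] model.
#' @param candidate_ids,tester_ids individual ids (candidates may be
#'   heterozygous, testers must be genotyped).
#' @param geno a [geno_matrix()] with all candidates and testers.
#' @param center subtract the grand mean (default TRUE).
#' @return Named numeric vector of GCA estimates.
#' @export
predict_gca <- function(model, candidate_ids, tester_ids, geno,
                        center = TRUE) {
  if (length(tester_ids) == 0) stop("empty tester panel")
  check_markers(model, geno)
  d <- geno$dosage
  cd <- d[candidate_ids, , drop = FALSE]
  preds <- matrix(0, length(candidate_ids), length(tester_ids),
                  dimnames = list(candidate_ids, tester_ids))
  zc <- cd - 1
  add_c <- drop(zc %*% model$a) / 2
  for (t in seq_along(tester_ids)) {
    td <- d[tester_ids[t], ]
    zt <- td - 1
    phet <- sweep(cd / 2, 2, 1 - td / 2, `*`) +
      sweep(1 - cd / 2, 2, td / 2, `*`)
    preds[, t] <- model$mu + add_c + sum(zt * model$a) / 2 +
      drop(phet %*% model$d)
  }
  out <- rowMeans(preds)
  if (center) out <- out - mean(preds)
  attr(out, "predictions") <- preds
  out
}

#' BLUP prediction of held-out individuals from kernel models
#'
#' Trains on `train`, predicts `test` through the cross-kernel blocks:
#' pred = mu + sum_k s2_k K_k[test, train] V_train^-1 (y_train - mu).
#'
#' @param y full phenotype vector.
#' @param Klist kernel matrix or list of kernels over all individuals.
#' @param vc numeric vector of kernel variances followed by the residual
#'   variance, or `"reml"` to estimate on the training set.
#' @param train,test index vectors.
#' @export
kernel_predict <- function(y, Klist, vc, train, test) {
  if (!is.list(Klist)) Klist <- list(Klist)
  Ktr <- lapply(Klist, function(K) K[train, train, drop = FALSE])
  if (identical(vc, "reml")) {
    vc <- fit_kernel_reml(y[train], Ktr)$vc
  }
  ks <- kernel_solve(y[train], Ktr, vc)
  pred <- rep(ks$mu, length(test))
  for (k in seq_along(Klist)) {
    pred <- pred + vc[k] * drop(Klist[[k]][test, train, drop = FALSE] %*% ks$Py)
  }
  pred
}
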