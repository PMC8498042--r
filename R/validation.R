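# Cross-validation: repeated k-fold genomic repeatability and the
# chessboard scheme for hybrid prediction (T0 / T1 / T2 test classes).

#' Prediction ability
#'
#' Pearson correlation between observed and predicted values.
#'
#' @param observed,predicted numeric vectors of equal length >= 3 with
#'   nonzero variance.
#' @export
prediction_ability <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("lengths differ")
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("zero variance input")
  }
  stats::cor(observed, predicted)
}

# Seeded permutation into k folds with sizes differing by at most 1.
make_folds <- function(n, k) {
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  split(idx, rep(seq_len(k), sizes))
}

#' Repeated k-fold cross-validation for kernel genomic models
#'
#' For each repeat a fresh random partition into k folds of near-equal size
#' (sizes differ by at most 1); each fold is predicted from the remaining
#' folds and the prediction ability is the fold-wise correlation between
#' observed and predicted values. The genomic repeatability is the grand
#' mean of the abilities. With `k = n` (leave-one-out) fold-wise
#' correlations are undefined; the correlation across all held-out
#' singletons is reported instead (one ability per repeat).
#'
#' @param y named phenotype vector.
#' @param Klist kernel matrix (e.g. a GRM) or list of kernels covering all
#'   individuals (additive, dominance, ...).
#' @param k number of folds.
#' @param repeats number of repeated partitions.
#' @param vc variance components passed to [kernel_predict()]: `"reml"`
#'   (re-estimated per training set) or a numeric vector.
#' @param seed optional integer seed.
#' @return list of class `cv_result`: `scheme`, `abilities` data.frame
#'   (`rep`, `fold`, `ability`), `mean`.
#' @export
kfold_cv <- function(y, Klist, k = 5, repeats = 1, vc = "reml",
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  res <- list()
  for (r in seq_len(repeats)) {
    folds <- make_folds(n, k)
    if (k == n) {
      pred <- numeric(n)
      for (f in seq_len(k)) {
        test <- folds[[f]]
        pred[test] <- kernel_predict(y, Klist, vc,
                                     train = setdiff(seq_len(n), test),
                                     test = test)
      }
      res[[length(res) + 1]] <- data.frame(rep = r, fold = NA_integer_,
                                           ability = stats::cor(y, pred))
      next
    }
    for (f in seq_len(k)) {
      test <- folds[[f]]
      ab <- if (stats::sd(y[test]) == 0) {
        message("fold with zero phenotypic variance: ability recorded as NA")
        NA_real_
      } else {
        pred <- kernel_predict(y, Klist, vc,
                               train = setdiff(seq_len(n), test), test = test)
        stats::cor(y[test], pred)
      }
      res[[length(res) + 1]] <- data.frame(rep = r, fold = f, ability = ab)
    }
  }
  ab <- do.call(rbind, res)
  structure(list(scheme = sprintf("%d-fold x %d", k, repeats),
                 abilities = ab, mean = mean(ab$ability, na.rm = TRUE)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: mean ability %.3f over %d fold evaluations\n",
              x$scheme, x$mean, nrow(x$abilities)))
  invisible(x)
}

#' Chessboard cross-validation for hybrids
#'
#' Females and males are partitioned into fold groups. For each
#' (female-fold, male-fold) cell the hybrids of that cell form the test
#' set, predicted from three nested training sets: T2 excludes only the
#' tested hybrids (both parents shared with training), T1 additionally
#' excludes every hybrid carrying a test-cell female (one parent — the
#' male — shared), and T0 excludes all hybrids carrying either a test-cell
#' female or a test-cell male (no parent shared).
#'
#' @param y named phenotype vector of hybrids.
#' @param female,male parent ids per hybrid (same length as `y`).
#' @param Klist kernel or list of kernels over the hybrids.
#' @param n_female_folds,n_male_folds fold counts per parent axis (>= 2).
#' @param vc variance components for [kernel_predict()].
#' @param seed optional integer seed.
#' @return list of class `chessboard_cv` with `abilities` data.frame
#'   (`class`, `female_fold`, `male_fold`, `n_test`, `n_train`, `ability`)
#'   and `means` (named per class T0/T1/T2).
#' @export
chessboard_cv <- function(y, female, male, Klist, n_female_folds = 5,
                          n_male_folds = 3, vc = "reml", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_female_folds < 2 || n_male_folds < 2) {
    stop("need at least 2 folds on each parent axis")
  }
  fem <- unique(female)
  mal <- unique(male)
  if (n_female_folds > length(fem) || n_male_folds > length(mal)) {
    stop("more folds than parents on one axis")
  }
  ffold <- rep(NA_integer_, length(female))
  mfold <- rep(NA_integer_, length(male))
  fgrp <- make_folds(length(fem), n_female_folds)
  mgrp <- make_folds(length(mal), n_male_folds)
  for (i in seq_along(fgrp)) ffold[female %in% fem[fgrp[[i]]]] <- i
  for (j in seq_along(mgrp)) mfold[male %in% mal[mgrp[[j]]]] <- j
  out <- list()
  for (i in seq_len(n_female_folds)) {
    for (j in seq_len(n_male_folds)) {
      test <- which(ffold == i & mfold == j)
      if (length(test) == 0) next
      trains <- list(
        T2 = which(!(ffold == i & mfold == j)),
        T1 = which(ffold != i),
        T0 = which(ffold != i & mfold != j))
      for (cl in names(trains)) {
        train <- trains[[cl]]
        ab <- if (length(train) < 3 || length(test) < 3 ||
                  stats::sd(y[test]) == 0) NA_real_ else {
          pred <- kernel_predict(y, Klist, vc, train = train, test = test)
          stats::cor(y[test], pred)
        }
        out[[length(out) + 1]] <- data.frame(
          class = cl, female_fold = i, male_fold = j,
          n_test = length(test), n_train = length(train), ability = ab)
      }
    }
  }
  ab <- do.call(rbind, out)
  if (is.null(ab)) stop("no populated test cells for the given fold counts")
  means <- tapply(ab$ability, ab$class, mean, na.rm = TRUE)
  empty <- names(means)[is.nan(means)]
  if (length(empty)) {
    warning("class(es) with no evaluable cell: ", paste(empty, collapse = ", "))
  }
  structure(list(abilities = ab, means = means[c("T0", "T1", "T2")]),
            class = "chessboard_cv")
}
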