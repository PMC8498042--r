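# Response-to-selection calculus: standardized selection differentials,
# finite-population selection intensities, generation-specific deflation of
# the GCA standard deviation, expected/observed response, and the
# negative-overdominance fixation threshold.

#' Standardized selection differential i(alpha)
#'
#' Mean of the selected upper fraction `p` of a standard normal trait:
#' i = phi(z) / p with z the upper-p quantile. Computed in closed form
#' from the truncated-normal mean rather than from printed tables.
#'
#' @param p selected proportion, 0 < p < 1.
#' @export
std_sel_differential <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly between 0 and 1")
  stats::dnorm(stats::qnorm(1 - p)) / p
}

#' Finite-population selection intensity i(N, G)
#'
#' i(N, G) = i(alpha) - (G - N) / (2 N (G + 1) i(alpha)) with
#' i(alpha) the standardized selection differential at p = N/G. The
#' correction penalises the infinite-population value for the finite
#' number of candidates actually drawn. i(G, G) is defined as 0 (no
#' selection; the correction would divide by i(alpha) = 0).
#'
#' @param N number selected (0 < N <= G).
#' @param G candidate-population size.
#' @export
selection_intensity <- function(N, G) {
  if (N <= 0 || G <= 0) stop("N and G must be positive")
  if (N > G) stop("N must not exceed G")
  if (N == G) return(0)
  ia <- std_sel_differential(N / G)
  ia - (G - N) / (2 * N * (G + 1) * ia)
}

#' GCA standard deviation exploitable within an F2 family
#'
#' Half of the genetic variance of a biparental cross is available to
#' selection among its F2 plants: sigma_GCA_F2 = sqrt(sigma2_GCA / 2),
#' with sigma2_GCA the GCA variance among fully inbred lines of the cross.
#'
#' @param s2_gca base GCA variance (>= 0).
#' @export
gca_sd_f2 <- function(s2_gca) {
  if (s2_gca < 0) stop("variance must be non-negative")
  sqrt(s2_gca / 2)
}

#' GCA standard deviation exploitable among F5:6 descendants
#'
#' The selfing generations F3-F5 release 1/2 + 1/4 + 1/8 = 7/8 of the
#' F2-stage variance among the descendants of a single F2 plant:
#' sigma_GCA_F5:6 = sqrt(7/8 sigma_GCA_F2^2).
#'
#' @param sd_gca_f2 F2-stage GCA standard deviation (>= 0).
#' @export
gca_sd_f56 <- function(sd_gca_f2) {
  if (sd_gca_f2 < 0) stop("input must be non-negative")
  sqrt(7 / 8 * sd_gca_f2^2)
}

#' One selection step
#'
#' @param N,G selected count and candidate count; may be omitted when a
#'   precomputed intensity `i` is supplied.
#' @param h selection accuracy (square root of heritability, or a
#'   prediction ability), in `[0, 1]`.
#' @param sigma_A standard deviation of the breeding values (trait units).
#' @param i optional precomputed selection intensity (overrides N, G).
#' @export
selection_step <- function(N = NULL, G = NULL, h, sigma_A, i = NULL) {
  if (is.null(i)) {
    if (is.null(N) || is.null(G)) stop("supply either (N, G) or i")
    i <- selection_intensity(N, G)
  }
  if (sigma_A < 0) stop("sigma_A must be non-negative")
  if (h < 0 || h > 1) stop("h must lie in [0, 1]")
  structure(list(N = N, G = G, h = h, sigma_A = sigma_A, i = i),
            class = "selection_step")
}

#' Expected response to multi-step selection
#'
#' R_exp = sum over steps of i(N, G) * h * sigma_A.
#'
#' @param steps list of [selection_step()] objects.
#' @return list of class `response_report` with the per-step table and the
#'   total expected response.
#' @export
expected_response <- function(steps) {
  if (length(steps) < 1) stop("need at least one step")
  if (inherits(steps, "selection_step")) steps <- list(steps)
  tab <- do.call(rbind, lapply(seq_along(steps), function(s) {
    st <- steps[[s]]
    data.frame(step = s, N = st$N %||% NA, G = st$G %||% NA, i = st$i,
               h = st$h, sigma_A = st$sigma_A,
               response = st$i * st$h * st$sigma_A)
  }))
  structure(list(steps = tab, R_exp = sum(tab$response)),
            class = "response_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.response_report <- function(x, ...) {
  print(x$steps, row.names = FALSE)
  cat(sprintf("Total expected response R_exp = %.3f\n", x$R_exp))
  invisible(x)
}

#' Observed response to selection
#'
#' R_obs = S_hat = mu_sel - mu_pop, the observed selection differential
#' between the mean of the selected group and the mean of the population
#' they were drawn from (in practice approximated by the base-cycle
#' hybrid mean).
#'
#' @param mu_sel,mu_pop group means.
#' @export
observed_response <- function(mu_sel, mu_pop) {
  if (anyNA(c(mu_sel, mu_pop))) stop("both means must be present")
  mu_sel - mu_pop
}

#' Fixation threshold under negative overdominance
#'
#' With degree of dominance k = d/a < -1, recurrent selection on combining
#' ability drives the favorable allele toward fixation only if its
#' frequency already exceeds p = (k + 1) / (2 k); below the threshold the
#' allele is lost.
#'
#' @param k degree of dominance; the threshold binds only for `k < -1`.
#' @export
fixation_threshold <- function(k) {
  if (k >= -1) {
    stop("threshold applies only under negative overdominance (k < -1)")
  }
  (k + 1) / (2 * k)
}
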