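# Multi-environment phenotype simulation and environmental covariate
# profiles (EVI / plant-available-water time series).

#' Multi-environment trial design
#'
#' Variance settings are in squared trait units. Stress locations draw their
#' genetic signal from a regime only weakly correlated (`stress_cor`) with
#' the genotypes' genetic values, so genotype rankings decorrelate there —
#' the mechanism behind an "outgroup" environment cluster.
#'
#' @param locations character vector of location ids.
#' @param years vector of year labels (default a single year).
#' @param n_blocks blocks per environment.
#' @param var_loc,var_block,var_gxe,var_resid variances of environment main
#'   effects, block-within-environment effects, genotype-by-environment
#'   deviations, and plot residuals.
#' @param stress_locations subset of `locations` under the stress regime.
#' @param stress_cor correlation between the stress-regime genetic vector
#'   and the genotypes' genetic values (default 0.1).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(locations, years = "Y1", n_blocks = 2,
                         var_loc = 0, var_block = 0, var_gxe = 0,
                         var_resid = 0, stress_locations = character(),
                         stress_cor = 0.1) {
  if (any(c(var_loc, var_block, var_gxe, var_resid) < 0)) {
    stop("variances must be non-negative")
  }
  if (!all(stress_locations %in% locations)) {
    stop("stress_locations must be a subset of locations")
  }
  structure(list(locations = as.character(locations),
                 years = as.character(years), n_blocks = n_blocks,
                 var_loc = var_loc, var_block = var_block,
                 var_gxe = var_gxe, var_resid = var_resid,
                 stress_locations = as.character(stress_locations),
                 stress_cor = stress_cor),
            class = "trial_design")
}

#' Simulate a long-format multi-environment phenotype table
#'
#' Each record is genetic signal + environment effect + block effect + GxE
#' deviation + residual. In stress locations the genetic signal g is
#' replaced by mean(g) + rho (g - mean(g)) + sqrt(1 - rho^2) sd(g) z, with
#' one standard-normal z per genotype shared across all stress
#' environments, so stress environments correlate with each other but only
#' weakly (rho) with the others.
#'
#' @param geno a [geno_matrix()] (scored with `arch`) or a named numeric
#'   vector of genetic values (then `arch` is ignored).
#' @param arch a [trait_arch()], required when `geno` is a geno_matrix.
#' @param design a [trial_design()].
#' @param seed optional integer seed.
#' @param meta optional data.frame with columns `genotype_id`, `role`,
#'   `female_parent`, `male_parent` supplying trial roles; defaults to role
#'   "line" with no parents.
#' @return data.frame with columns `genotype_id`, `role`, `female_parent`,
#'   `male_parent`, `location`, `year`, `block`, `value`.
#' @export
simulate_phenotypes <- function(geno, arch = NULL, design, seed = NULL,
                                meta = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(design$locations) == 0) stop("empty design")
  g <- if (inherits(geno, "geno_matrix")) genetic_value(geno, arch) else geno
  if (is.null(names(g))) names(g) <- sprintf("I%03d", seq_along(g))
  ids <- names(g)
  n <- length(g)
  if (is.null(meta)) {
    meta <- data.frame(genotype_id = ids, role = "line",
                       female_parent = NA_character_,
                       male_parent = NA_character_, stringsAsFactors = FALSE)
  }
  meta <- meta[match(ids, meta$genotype_id), ]
  envs <- expand.grid(location = design$locations, year = design$years,
                      stringsAsFactors = FALSE)
  sdg <- stats::sd(g)
  if (is.na(sdg)) sdg <- 0
  rho <- design$stress_cor
  z <- stats::rnorm(n)
  g_stress <- mean(g) + rho * (g - mean(g)) + sqrt(1 - rho^2) * sdg * z
  out <- vector("list", nrow(envs) * design$n_blocks)
  k <- 0
  for (e in seq_len(nrow(envs))) {
    loc <- envs$location[e]
    loc_eff <- stats::rnorm(1, 0, sqrt(design$var_loc))
    gsig <- if (loc %in% design$stress_locations) g_stress else g
    gxe <- stats::rnorm(n, 0, sqrt(design$var_gxe))
    for (b in seq_len(design$n_blocks)) {
      blk_eff <- stats::rnorm(1, 0, sqrt(design$var_block))
      val <- gsig + loc_eff + blk_eff + gxe +
        stats::rnorm(n, 0, sqrt(design$var_resid))
      k <- k + 1
      out[[k]] <- data.frame(genotype_id = ids, role = meta$role,
                             female_parent = meta$female_parent,
                             male_parent = meta$male_parent,
                             location = loc, year = envs$year[e],
                             block = sprintf("B%d", b), value = val,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Environment covariate profile
#'
#' @param location_id location label.
#' @param dates strictly increasing Date (or numeric) observation times.
#' @param evi enhanced vegetation index series (dimensionless).
#' @param evi_min,evi_max reference-period extremes of the EVI in the area.
#' @param paw optional plant-available-water series (percent).
#' @export
env_profile <- function(location_id, dates, evi, evi_min, evi_max,
                        paw = NULL) {
  if (any(diff(as.numeric(dates)) <= 0)) stop("dates must be strictly increasing")
  if (length(dates) != length(evi)) stop("dates and evi lengths differ")
  structure(list(location_id = location_id, dates = dates, evi = evi,
                 evi_min = evi_min, evi_max = evi_max, paw = paw),
            class = "env_profile")
}

#' Simulate seasonal EVI / PAW profiles per location
#'
#' Non-stress locations share a smooth seasonal EVI template (autumn
#' emergence, spring canopy peak) plus independent noise; stress locations
#' receive a depressed trajectory emulating drought. Plant-available water
#' declines over the season, faster and from a lower start under stress.
#'
#' @param design a [trial_design()] (at least 2 locations).
#' @param n_timepoints observations per profile over one growing season.
#' @param seed optional integer seed.
#' @param noise_sd standard deviation of EVI observation noise.
#' @return Named list of [env_profile()] objects, one per location.
#' @export
simulate_env_profiles <- function(design, n_timepoints = 24, seed = NULL,
                                  noise_sd = 0.02) {
  if (length(design$locations) < 2) stop("need at least 2 locations")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, 1, length.out = n_timepoints)
  dates <- as.Date("2018-09-01") + round(tt * 364)
  base <- 0.2 + 0.45 * exp(-((tt - 0.68) / 0.2)^2)
  stressed <- 0.12 + 0.2 * exp(-((tt - 0.68) / 0.2)^2)
  out <- lapply(design$locations, function(loc) {
    is_stress <- loc %in% design$stress_locations
    evi <- (if (is_stress) stressed else base) +
      stats::rnorm(n_timepoints, 0, noise_sd)
    paw <- (if (is_stress) 55 - 35 * tt else 85 - 25 * tt) +
      stats::rnorm(n_timepoints, 0, 3)
    env_profile(loc, dates, evi, evi_min = 0.05, evi_max = 0.8,
                paw = pmin(pmax(paw, 0), 100))
  })
  names(out) <- design$locations
  out
}
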