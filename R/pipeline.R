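# End-to-end in-silico RRGS experiment: training a genomic model on a
# factorial of founder hybrids, two genomic selection steps (F2 and F5:6)
# in the female pool plus a random control branch, hybrid production with
# testers, multi-environment evaluation with an optional stress-environment
# regime, and the downstream selection-gain / GxE analyses.

#' Configuration of the in-silico RRGS experiment
#'
#' Defaults mirror the reference breeding programme: 120 female and 15
#' male founders on 4,031 markers, 20 selected C0 females crossed in a
#' round robin, 629 F2 plants (3 selected per family), single-seed descent
#' to F5:6 with 382 visually retained families, 50 genomically selected
#' (C1S) against 30 randomly derived (C1R) lines, hybrids with 3 testers,
#' and evaluation at 6 locations of which 2 follow a stress regime.
#' Smaller values scale every stage down proportionally for fast
#' replicated runs.
#'
#' @param n_females,n_males founder pool sizes.
#' @param n_markers,n_chromosomes,chrom_length_cM,maf_low,maf_high founder
#'   genome settings (see [make_founders()]).
#' @param n_qtl,mu,mean_k,sd_k,target_line_var trait architecture: causal
#'   loci, intercept (dt/ha), degree-of-dominance distribution, and the
#'   genetic variance among founder female lines the effects are scaled
#'   to.
#' @param train_frac fraction of the female x male factorial phenotyped
#'   for training.
#' @param n_train_envs training environments (their means feed the model).
#' @param var_gxe,var_resid,var_loc,var_block evaluation-trial variance
#'   components (squared trait units).
#' @param n_blocks blocks per evaluation environment.
#' @param eval_locations,stress_locations evaluation locations and the
#'   stressed subset; `stress_cor` is the genetic correlation between the
#'   stress regime and the main regime.
#' @param n_c0 females selected to initiate the cycle.
#' @param f2_total F2 plants across all round-robin families.
#' @param f2_sel_per_family F2 plants genomically selected per family.
#' @param n_f5_per_f2,n_f5_per_f2_random SSD descendants carried per
#'   selected / randomly drawn F2 plant.
#' @param visual_n,visual_n_random,visual_cor size of the visually
#'   retained pools and the correlation of the visual score with the
#'   genetic value.
#' @param n_c1s,n_c1r sizes of the selected and random C1 fractions.
#' @param n_testers male testers used for hybrid production.
#' @param n_checks check entries added to the evaluation trial.
#' @param vc_mode `"oracle"` (marker-effect variances taken from the
#'   generating architecture) or `"reml"`.
#' @param random_selection replace both genomic selections by random
#'   draws (null control).
#' @param diagnostics run the mixed-model variance-component fit, GxE
#'   clustering, environmental profiles and bootstrap contrasts.
#' @param n_boot bootstrap draws for group contrasts.
#' @return list of class `rrgs_config`.
#' @export
rrgs_config <- function(n_females = 120, n_males = 15, n_markers = 4031,
                        n_chromosomes = 21, chrom_length_cM = 150,
                        maf_low = 0.05, maf_high = 0.5,
                        n_qtl = 300, mu = 90, mean_k = 0.5, sd_k = 0.3,
                        target_line_var = 17.2,
                        train_frac = 0.9, n_train_envs = 11,
                        var_gxe = 3, var_resid = 5.7, var_loc = 20,
                        var_block = 2, n_blocks = 2,
                        eval_locations = c("ADE", "BOE", "HAD", "MIN",
                                           "SOS", "WOH"),
                        stress_locations = c("BOE", "HAD"),
                        stress_cor = 0.1,
                        n_c0 = 20, f2_total = 629, f2_sel_per_family = 3,
                        n_f5_per_f2 = 48, n_f5_per_f2_random = 12,
                        visual_n = 382, visual_n_random = 30,
                        visual_cor = 0.2, n_c1s = 50, n_c1r = 30,
                        n_testers = 3, n_checks = 5,
                        vc_mode = c("oracle", "reml"),
                        random_selection = FALSE, diagnostics = FALSE,
                        n_boot = 1000) {
  cfg <- as.list(environment())
  cfg$vc_mode <- match.arg(vc_mode)
  stopifnot(cfg$n_c0 <= cfg$n_females,
            cfg$f2_sel_per_family * cfg$n_c0 <= cfg$f2_total,
            cfg$n_c1s <= cfg$visual_n,
            cfg$n_c1r <= cfg$visual_n_random,
            cfg$n_testers >= 1, cfg$n_testers <= cfg$n_males,
            all(cfg$stress_locations %in% cfg$eval_locations))
  structure(cfg, class = "rrgs_config")
}

# Distribute a total over n families as evenly as possible.
family_sizes <- function(total, n) {
  s <- rep(total %/% n, n)
  if (total %% n > 0) s[seq_len(total %% n)] <- s[seq_len(total %% n)] + 1
  s
}

# Pooled within-family correlation and sd (centred by family means).
within_family_stats <- function(pred, truth, fam) {
  cp <- pred - stats::ave(pred, fam)
  ct <- truth - stats::ave(truth, fam)
  list(r = stats::cor(cp, ct),
       sd = sqrt(sum(ct^2) / (length(ct) - length(unique(fam)))))
}

#' Run one in-silico RRGS experiment
#'
#' Executes founder simulation, training-population phenotyping, RRBLUP
#' training, genomic selection of C0 females, a round-robin cycle with
#' F2-stage and F5:6-stage genomic selection plus the random control
#' branch, hybrid production with testers, multi-environment evaluation,
#' and the selection-gain summaries. With `diagnostics = TRUE` the
#' GCA/SCA variance components, GxE clustering and environmental-profile
#' analyses are added.
#'
#' @param config an [rrgs_config()].
#' @param seed integer seed governing every stage.
#' @return list of class `rrgs_report`; see the package vignette.
#' @export
run_rrgs_experiment <- function(config = rrgs_config(), seed = 1) {
  stopifnot(inherits(config, "rrgs_config"))
  set.seed(seed)
  cfg <- config
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, note = msg)
  }

  ## founders ---------------------------------------------------------------
  founders <- make_founders(cfg$n_females + cfg$n_males, cfg$n_markers,
                            cfg$n_chromosomes, cfg$chrom_length_cM,
                            cfg$maf_low, cfg$maf_high)
  ids <- c(sprintf("F%03d", seq_len(cfg$n_females)),
           sprintf("M%03d", seq_len(cfg$n_males)))
  rownames(founders$dosage) <- ids
  fem_ids <- ids[seq_len(cfg$n_females)]
  mal_ids <- ids[-seq_len(cfg$n_females)]
  tester_ids <- mal_ids[seq_len(cfg$n_testers)]
  map <- founders$map
  note("founders", sprintf("%d females + %d males x %d markers",
                           cfg$n_females, cfg$n_males, cfg$n_markers))

  ## trait architecture -----------------------------------------------------
  arch <- sample_architecture(cfg$n_markers, cfg$n_qtl, mu = cfg$mu,
                              mean_k = cfg$mean_k, sd_k = cfg$sd_k)
  arch <- scale_architecture(arch, founders[fem_ids, ], cfg$target_line_var)

  ## training population ----------------------------------------------------
  plan_all <- expand.grid(female = fem_ids, male = mal_ids,
                          stringsAsFactors = FALSE)
  n_tr <- max(2, round(cfg$train_frac * nrow(plan_all)))
  plan_tr <- plan_all[sort(sample.int(nrow(plan_all), n_tr)), ]
  dm <- hybrid_design_matrices(founders, plan_tr)
  ldm <- line_design_matrices(founders)
  ZA <- rbind(dm$ZA, ldm$ZA)
  ZD <- rbind(dm$ZD, ldm$ZD)
  hyb_dos <- (founders$dosage[plan_tr$female, , drop = FALSE] +
                founders$dosage[plan_tr$male, , drop = FALSE]) / 2
  g_train <- c(genetic_value(hyb_dos, arch), genetic_value(founders, arch))
  var_train_noise <- (cfg$var_gxe + cfg$var_resid / cfg$n_blocks) /
    cfg$n_train_envs
  y_train <- g_train + stats::rnorm(length(g_train), 0,
                                    sqrt(var_train_noise))
  vc <- if (cfg$vc_mode == "oracle") {
    list(sa2 = mean(arch$add^2), sd2 = max(mean(arch$dom^2), 1e-10),
         se2 = max(var_train_noise, 1e-6))
  } else "reml"
  model <- fit_rrblup_ad(y_train, ZA, ZD, vc = vc)
  note("training", sprintf("%d hybrids + %d lines; sa2 = %.3g",
                           nrow(dm$ZA), cfg$n_females + cfg$n_males,
                           model$vc$sa2))

  ## C0 selection -----------------------------------------------------------
  gca_f <- predict_gca(model, fem_ids, tester_ids, founders)
  c0 <- if (cfg$random_selection) sample(fem_ids, cfg$n_c0) else
    fem_ids[order(-gca_f)][seq_len(cfg$n_c0)]
  note("c0", sprintf("selected %d of %d females", cfg$n_c0, cfg$n_females))

  ## round robin, F2 families ----------------------------------------------
  plan_rr <- round_robin(c0)
  fsz <- family_sizes(cfg$f2_total, nrow(plan_rr))
  f2 <- list()
  f2_fam <- character(0)
  for (f in seq_len(nrow(plan_rr))) {
    f1 <- phased_f1(founders$dosage[plan_rr$female[f], ],
                    founders$dosage[plan_rr$male[f], ])
    for (p in seq_len(fsz[f])) {
      f2[[length(f2) + 1]] <- self_once(f1, map)
      f2_fam <- c(f2_fam, sprintf("FAM%02d", f))
    }
  }
  names(f2) <- sprintf("F2_%03d", seq_along(f2))
  tester_rows <- stats::setNames(lapply(tester_ids, function(t)
    founders$dosage[t, ]), tester_ids)
  f2_geno <- as_geno_matrix(c(f2, tester_rows), map)
  gca_f2 <- predict_gca(model, names(f2), tester_ids, f2_geno)
  true_f2 <- true_gca(f2_geno[names(f2), ], founders[tester_ids, ], arch,
                      center = FALSE)
  pick_family <- function(scores) {
    unlist(lapply(split(seq_along(scores), f2_fam), function(i) {
      if (cfg$random_selection) sample(i, cfg$f2_sel_per_family) else
        i[order(-scores[i])][seq_len(cfg$f2_sel_per_family)]
    }), use.names = FALSE)
  }
  sel_f2 <- pick_family(gca_f2)
  rnd_f2 <- unlist(lapply(split(seq_along(f2), f2_fam), function(i)
    sample(i, cfg$f2_sel_per_family)), use.names = FALSE)
  wf <- within_family_stats(gca_f2, true_f2, f2_fam)
  i_fam <- mean(vapply(fsz, function(n)
    selection_intensity(cfg$f2_sel_per_family, n), 0))
  gain1 <- i_fam * wf$r * wf$sd
  note("f2", sprintf("%d F2 in %d families; within-family r = %.2f",
                     length(f2), nrow(plan_rr), wf$r))

  ## SSD to F5:6 ------------------------------------------------------------
  ssd_pool <- function(idx, per) {
    out <- list()
    fam <- par <- character(0)
    for (i in idx) {
      for (d in seq_len(per)) {
        out[[length(out) + 1]] <- self_ssd(f2[[i]], map, 3)
        fam <- c(fam, f2_fam[i])
        par <- c(par, names(f2)[i])
      }
    }
    list(inds = out, fam = fam, par = par)
  }
  pool_s <- ssd_pool(sel_f2, cfg$n_f5_per_f2)
  names(pool_s$inds) <- sprintf("S5_%04d", seq_along(pool_s$inds))
  pool_r <- ssd_pool(rnd_f2, cfg$n_f5_per_f2_random)
  names(pool_r$inds) <- sprintf("R5_%04d", seq_along(pool_r$inds))

  visual_pick <- function(truth, n_keep) {
    if (cfg$visual_cor == 0) return(sample(seq_along(truth), n_keep))
    aux <- cfg$visual_cor * scale(truth)[, 1] +
      sqrt(1 - cfg$visual_cor^2) * stats::rnorm(length(truth))
    order(-aux)[seq_len(n_keep)]
  }
  geno_s <- as_geno_matrix(c(pool_s$inds, tester_rows), map)
  true_s_all <- true_gca(geno_s[names(pool_s$inds), ],
                         founders[tester_ids, ], arch, center = FALSE)
  vis_s <- visual_pick(true_s_all, min(cfg$visual_n, length(true_s_all)))
  i_vis <- selection_intensity(length(vis_s), length(true_s_all))
  gain_vis <- i_vis * cfg$visual_cor * stats::sd(true_s_all)
  pool_ids <- names(pool_s$inds)[vis_s]
  gca_f5 <- predict_gca(model, pool_ids, tester_ids, geno_s)
  true_f5 <- true_s_all[vis_s]
  sel_idx <- if (cfg$random_selection) sample(seq_along(pool_ids), cfg$n_c1s)
  else order(-gca_f5)[seq_len(cfg$n_c1s)]
  c1s_ids <- pool_ids[sel_idx]
  r2 <- stats::cor(gca_f5, true_f5)
  gain2 <- selection_intensity(cfg$n_c1s, length(pool_ids)) * r2 *
    stats::sd(true_f5)
  note("f5", sprintf("pool %d -> visual %d -> selected %d; r = %.2f",
                     length(true_s_all), length(pool_ids), cfg$n_c1s, r2))

  true_r_all <- true_gca(as_geno_matrix(pool_r$inds, map),
                         founders[tester_ids, ], arch, center = FALSE)
  vis_r <- visual_pick(true_r_all, min(cfg$visual_n_random,
                                       length(true_r_all)))
  c1r_ids <- names(pool_r$inds)[vis_r][seq_len(cfg$n_c1r)]

  ## hybrid production and evaluation ---------------------------------------
  female_pool <- c(lapply(c0, function(id) as_phased(founders$dosage[id, ])),
                   pool_s$inds[c1s_ids], pool_r$inds[c1r_ids])
  names(female_pool) <- c(c0, c1s_ids, c1r_ids)
  fem_group <- c(rep("C0F", length(c0)), rep("S", length(c1s_ids)),
                 rep("R", length(c1r_ids)))
  names(fem_group) <- names(female_pool)

  hyb <- list()
  hyb_meta <- list()
  for (i in seq_along(female_pool)) {
    fid <- names(female_pool)[i]
    for (t in tester_ids) {
      gam_f <- meiosis(female_pool[[i]], map)
      gam_m <- as.integer(founders$dosage[t, ] / 2)
      hid <- paste(fid, t, sep = ":")
      hyb[[hid]] <- gam_f + gam_m
      hyb_meta[[hid]] <- data.frame(
        genotype_id = hid, role = "hybrid", female_parent = fid,
        male_parent = t,
        group = c(C0F = "C0H", S = "C1S", R = "C1R")[fem_group[fid]],
        stringsAsFactors = FALSE)
    }
  }
  hyb_meta <- do.call(rbind, hyb_meta)
  g_hyb <- vapply(hyb, function(d) genetic_value(d, arch), 0)

  line_ids <- c(names(female_pool), tester_ids)
  g_lines <- c(vapply(female_pool, function(ind)
    genetic_value(dosage_of(ind), arch), 0),
    genetic_value(founders[tester_ids, ], arch))
  names(g_lines) <- line_ids
  chk_ids <- character(0)
  g_chk <- numeric(0)
  if (cfg$n_checks > 0) {
    chk_ids <- sample(setdiff(fem_ids, c0), cfg$n_checks)
    g_chk <- genetic_value(founders[chk_ids, ], arch)
    names(g_chk) <- chk_ids
  }
  gvals <- c(g_hyb, g_lines, g_chk)
  meta <- rbind(
    hyb_meta[, c("genotype_id", "role", "female_parent", "male_parent")],
    data.frame(genotype_id = line_ids, role = "line",
               female_parent = NA_character_, male_parent = NA_character_),
    if (length(chk_ids)) data.frame(genotype_id = chk_ids, role = "check",
                                    female_parent = NA_character_,
                                    male_parent = NA_character_))
  line_groups <- c(fem_group[names(female_pool)],
                   stats::setNames(rep("tester", length(tester_ids)),
                                   tester_ids))
  groups <- c(stats::setNames(hyb_meta$group, hyb_meta$genotype_id),
              stats::setNames(line_groups, line_ids),
              stats::setNames(rep("check", length(chk_ids)), chk_ids))

  design <- trial_design(cfg$eval_locations, years = "2019",
                         n_blocks = cfg$n_blocks, var_loc = cfg$var_loc,
                         var_block = cfg$var_block, var_gxe = cfg$var_gxe,
                         var_resid = cfg$var_resid,
                         stress_locations = cfg$stress_locations,
                         stress_cor = cfg$stress_cor)
  plots <- simulate_phenotypes(gvals, design = design, meta = meta)
  plots$group <- groups[plots$genotype_id]
  note("evaluation", sprintf("%d genotypes x %d environments x %d blocks",
                             length(gvals), length(cfg$eval_locations),
                             cfg$n_blocks))

  ## summaries ---------------------------------------------------------------
  nonstress <- setdiff(cfg$eval_locations, cfg$stress_locations)
  mean_by_geno <- function(locs) {
    sub <- plots[plots$location %in% locs, ]
    tapply(sub$value, sub$genotype_id, mean)
  }
  env_sets <- list(all = cfg$eval_locations, nonstress = nonstress)
  group_means <- do.call(rbind, lapply(names(env_sets), function(es) {
    mg <- mean_by_geno(env_sets[[es]])
    data.frame(env_set = es, group = unname(groups[names(mg)]),
               genotype_id = names(mg), mean = unname(mg),
               stringsAsFactors = FALSE)
  }))
  gm_summary <- stats::aggregate(mean ~ env_set + group, group_means, mean)

  resp <- function(es) {
    gm <- group_means[group_means$env_set == es, ]
    observed_response(mean(gm$mean[gm$group == "C1S"]),
                      mean(gm$mean[gm$group == "C0H"]))
  }
  # predicted average hybrid performance per evaluation female (uncentred)
  eval_geno <- as_geno_matrix(c(lapply(female_pool, dosage_of), tester_rows),
                              map)
  pred_female <- predict_gca(model, names(female_pool), tester_ids,
                             eval_geno, center = FALSE)
  attributes(pred_female) <- list(names = names(pred_female))
  obs_female <- function(es) {
    gm <- group_means[group_means$env_set == es &
                        grepl(":", group_means$genotype_id), ]
    fem <- sub(":.*$", "", gm$genotype_id)
    tapply(gm$mean, fem, mean)
  }
  rpa <- function(es, grp) {
    fids <- names(fem_group)[fem_group == grp]
    obs <- obs_female(es)[fids]
    stats::cor(pred_female[fids], obs)
  }
  response <- list(
    R_obs_6E = resp("all"), R_obs_4E = resp("nonstress"),
    R_exp_realized = gain1 + gain_vis + gain2,
    steps = data.frame(step = c("F2 genomic", "visual", "F5 genomic"),
                       gain = c(gain1, gain_vis, gain2)))
  realized_pa <- c(all = rpa("all", "R"), nonstress = rpa("nonstress", "R"))

  report <- list(config = cfg, seed = seed,
                 log = do.call(rbind, log),
                 plots = plots, groups = groups,
                 group_means = group_means, group_summary = gm_summary,
                 response = response, realized_pa = realized_pa,
                 predictions = data.frame(female = names(pred_female),
                                          group = fem_group[names(pred_female)],
                                          predicted = unname(pred_female)),
                 accuracy = list(within_family_r = wf$r, f5_r = r2),
                 truth_stages = c(
                   c0_parents = mean(true_gca(founders[c0, ],
                                              founders[tester_ids, ], arch,
                                              center = FALSE)),
                   f2_all = mean(true_f2), f2_selected = mean(true_f2[sel_f2]),
                   f5_pool = mean(true_s_all), visual_pool = mean(true_f5),
                   c1s = mean(true_f5[sel_idx]),
                   c1r = mean(true_r_all[vis_r][seq_len(cfg$n_c1r)])),
                 selected = list(C0 = c0, C1S = c1s_ids, C1R = c1r_ids,
                                 testers = tester_ids))

  if (cfg$diagnostics) {
    report$contrasts <- group_contrasts(
      group_means[group_means$env_set == "nonstress", ],
      n_boot = cfg$n_boot)
    report$contrasts_all <- group_contrasts(
      group_means[group_means$env_set == "all", ], n_boot = cfg$n_boot)
    report$heterosis <- heterosis_by_group(group_means, hyb_meta)
    vcf_fit <- fit_variance_components(plots)
    gxe_m <- interaction_effects(vcf_fit)
    dist_gxe <- euclidean_distances(gxe_m, axis = "columns")
    cl <- complete_linkage(dist_gxe, k = 2)
    profiles <- simulate_env_profiles(design)
    dist_vci <- profile_distances(profiles, on = "vci")
    mt <- mantel_test(as.matrix(dist_gxe)[cfg$eval_locations,
                                          cfg$eval_locations],
                      as.matrix(dist_vci)[cfg$eval_locations,
                                          cfg$eval_locations],
                      n_permutations = 999)
    report$gxe <- list(vc = vcf_fit, interaction = gxe_m,
                       dist_gxe = dist_gxe, clusters = cl$clusters,
                       profiles = profiles, dist_vci = dist_vci,
                       mantel = mt)
  }
  structure(report, class = "rrgs_report")
}

#' @export
print.rrgs_report <- function(x, ...) {
  cat("rrgs_report (seed", x$seed, ")\n")
  print(x$group_summary, row.names = FALSE)
  cat(sprintf("R_obs (all envs) = %.2f; R_obs (non-stress) = %.2f; R_exp = %.2f\n",
              x$response$R_obs_6E, x$response$R_obs_4E,
              x$response$R_exp_realized))
  invisible(x)
}

# Mean MPH / BPH per hybrid group from per-genotype means.
heterosis_by_group <- function(group_means, hyb_meta) {
  do.call(rbind, lapply(unique(group_means$env_set), function(es) {
    gm <- group_means[group_means$env_set == es, ]
    mns <- stats::setNames(gm$mean, gm$genotype_id)
    hm <- hyb_meta[hyb_meta$genotype_id %in% names(mns), ]
    p1 <- mns[hm$female_parent]
    p2 <- mns[hm$male_parent]
    ok <- !is.na(p1) & !is.na(p2)
    het <- heterosis(mns[hm$genotype_id[ok]], p1[ok], p2[ok])
    stats::aggregate(cbind(mph, bph) ~ grp,
                     data.frame(het, grp = hm$group[ok]), mean) |>
      transform(env_set = es)
  }))
}

#' Realized prediction ability of a hybrid group
#'
#' Correlation, over the females of a group (default the random control
#' C1R), between the predicted average hybrid performance stored at
#' selection time and the observed average performance of their tester
#' hybrids.
#'
#' @param report an [run_rrgs_experiment()] report.
#' @param group female group (`"R"`, `"S"` or `"C0F"`).
#' @param env_set `"nonstress"` or `"all"`.
#' @export
realized_prediction_ability <- function(report, group = "R",
                                        env_set = c("nonstress", "all")) {
  env_set <- match.arg(env_set)
  preds <- report$predictions
  fids <- preds$female[preds$group == group]
  if (length(fids) < 3) stop("group smaller than 3")
  gm <- report$group_means
  gm <- gm[gm$env_set == env_set & grepl(":", gm$genotype_id), ]
  fem <- sub(":.*$", "", gm$genotype_id)
  obs <- tapply(gm$mean, fem, mean)[fids]
  stats::cor(preds$predicted[match(fids, preds$female)], obs)
}

#' Pairwise group contrasts with bootstrap intervals
#'
#' Differences of group means of per-genotype values, with nonparametric
#' bootstrap (resampling genotypes within groups) confidence intervals
#' and two-sided p-values.
#'
#' @param means data.frame with columns `group` and `mean` (one row per
#'   genotype), e.g. a slice of `report$group_means`.
#' @param n_boot bootstrap draws.
#' @param seed optional integer seed.
#' @return data.frame: `group1`, `group2`, `diff`, `lo`, `hi`, `p`.
#' @export
group_contrasts <- function(means, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grps <- split(means$mean, means$group)
  if (length(grps) < 2) stop("need at least 2 groups")
  if (any(vapply(grps, length, 0L) == 0)) stop("empty group")
  cmb <- utils::combn(names(grps), 2)
  do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- grps[[cmb[1, i]]]
    b <- grps[[cmb[2, i]]]
    d0 <- mean(a) - mean(b)
    bd <- replicate(n_boot, mean(sample(a, replace = TRUE)) -
                      mean(sample(b, replace = TRUE)))
    p <- 2 * min(mean(bd <= 0), mean(bd >= 0))
    data.frame(group1 = cmb[1, i], group2 = cmb[2, i], diff = d0,
               lo = stats::quantile(bd, 0.025), hi = stats::quantile(bd, 0.975),
               p = min(max(p, 1 / n_boot), 1), row.names = NULL)
  }))
}
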