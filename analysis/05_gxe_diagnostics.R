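#!/usr/bin/env Rscript
# Stage 5: genotype-by-environment diagnostics for the evaluated cycle.
#
# From the experiment's plot table: GCA/SCA variance components and
# heritabilities, female-GCA x environment interaction effects, their
# Euclidean-distance complete-linkage clustering and PCA, and the link
# between the interaction structure and satellite-style vegetation
# condition (VCI) profiles via a Mantel test.

library(rrgskit)

dir.create("results", showWarnings = FALSE)
report <- if (file.exists("scratch/04_report.rds")) {
  readRDS("scratch/04_report.rds")
} else {
  source("analysis/04_rrgs_experiment.R"); readRDS("scratch/04_report.rds")
}

vc <- report$gxe$vc
cat("Variance components (evaluation trial):\n")
print(round(vc$components, 3))
h2_hyb <- heritability(vc$derived[["hybrids"]],
                       vc$derived[["hybrids_x_e"]],
                       vc$components[["residual"]], vc$l[["hybrids"]])
ratio_f <- gxe_ratio(vc$components[["gca_female_x_e"]],
                     vc$components[["gca_female"]])
cat(sprintf("h2(hybrids) = %.2f; GCA(female)xE / GCA(female) = %.2f\n",
            h2_hyb, ratio_f))

vc_tab <- data.frame(component = names(vc$components),
                     estimate = as.numeric(vc$components))
write.csv(vc_tab, "results/05_variance_components.csv", row.names = FALSE)

## interaction-effect geometry
m <- report$gxe$interaction
write.csv(data.frame(female = rownames(m), m, check.names = FALSE),
          "results/05_gca_by_env_effects.csv", row.names = FALSE)
cl <- complete_linkage(report$gxe$dist_gxe, k = 2)
write_dendrogram_newick(cl, "results/05_env_dendrogram.nwk")
cat("Environment clusters (2-cut):\n")
print(cl$clusters)

pc <- pca_decomp(t(m))
cat(sprintf("PCA of environments in interaction space: PC1 %.1f%%, PC2 %.1f%%\n",
            100 * pc$explained[1], 100 * pc$explained[2]))
write.csv(data.frame(environment = rownames(pc$scores),
                     pc$scores[, 1:2],
                     explained_pc1 = pc$explained[1],
                     explained_pc2 = pc$explained[2]),
          "results/05_env_pca_scores.csv", row.names = FALSE)

## vegetation condition index profiles and their link to GxE
profiles <- report$gxe$profiles
write_env_profiles_csv(profiles, "results/05_env_profiles.csv")
vci_tab <- do.call(rbind, lapply(profiles, function(p)
  data.frame(location = p$location_id, date = as.character(p$dates),
             vci = vci(p))))
write.csv(vci_tab, "results/05_vci_profiles.csv", row.names = FALSE)
mt <- report$gxe$mantel
cat(sprintf("Mantel test, VCI distances vs GCAxE distances: r = %.2f, p = %.3f\n",
            mt$r, mt$p))
write.csv(data.frame(r = mt$r, p = mt$p, n_permutations = mt$n_permutations),
          "results/05_mantel.csv", row.names = FALSE)
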