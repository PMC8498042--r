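#!/usr/bin/env Rscript
# Stage 1: simulate the breeding material.
#
# Builds the founder panels (female and male heterotic pools), the
# round-robin crossing plan among selected females, an F2 generation and
# single-seed descent to F5, and writes small genotype artifacts plus a
# demographic summary. Later stages redo these steps inside the pipeline;
# this script exposes the raw material for inspection.

library(rrgskit)

dir.create("results", showWarnings = FALSE)
set.seed(11)

founders <- make_founders(n_individuals = 135, n_markers = 1200,
                          n_chromosomes = 21, chrom_length_cM = 150,
                          maf_low = 0.05, maf_high = 0.5, seed = 11)
ids <- c(sprintf("F%03d", 1:120), sprintf("M%03d", 1:15))
rownames(founders$dosage) <- ids

cat("Founders:", nrow(founders$dosage), "inbred lines x",
    ncol(founders$dosage), "markers;",
    "heterozygous calls:", sum(founders$dosage == 1), "\n")

plan <- round_robin(sprintf("F%03d", 1:20))
cat("Round robin: ", nrow(plan), "crosses; every parent used",
    unique(table(c(plan$female, plan$male))), "times\n")

# one family end to end: F1 -> 30 F2 plants -> SSD to F5
map <- founders$map
f1 <- phased_f1(founders$dosage[plan$female[1], ],
                founders$dosage[plan$male[1], ])
f2 <- lapply(1:30, function(i) self_once(f1, map))
f5 <- lapply(f2[1:3], function(x) self_ssd(x, map, 3))
het <- data.frame(
  generation = c("F1", "F2", "F5"),
  mean_heterozygosity = c(heterozygosity(dosage_of(f1)),
                          mean(sapply(f2, heterozygosity)),
                          mean(sapply(f5, heterozygosity))))
print(het)
write.csv(het, "results/01_heterozygosity_by_generation.csv",
          row.names = FALSE)

# genotype artifacts: a small female subset in both dialects
sub <- founders[sprintf("F%03d", 1:10), 1:60]
write_genotypes_vcf(sub, "results/01_founder_subset.vcf")
write_genotypes_csv(sub, "results/01_founder_subset.csv",
                    map_path = "results/01_founder_subset_map.csv")
write.csv(plan, "results/01_round_robin_plan.csv", row.names = FALSE)
cat("Wrote results/01_* artifacts\n")
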