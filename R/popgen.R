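# Forward-in-time population simulation: founder genomes, crossing designs,
# meiosis under the Haldane map function, and single-seed descent.

#' Genotype matrix with genetic map
#'
#' Container for a panel of individuals scored at biallelic markers. Dosage
#' counts copies of the reference allele (0, 1 or 2, `NA` for missing). The
#' map carries chromosome labels and genetic positions in centimorgans.
#'
#' @param dosage numeric matrix, individuals x markers, values in
#'   \{0, 1, 2\} or `NA`. Row and column names are used as individual and
#'   marker ids when present.
#' @param map data.frame with columns `marker`, `chrom`, `pos_cM`, one row
#'   per marker column of `dosage`.
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   and `map`.
#' @export
geno_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("I%03d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker
  stopifnot(is.data.frame(map), all(c("marker", "chrom", "pos_cM") %in% names(map)),
            nrow(map) == ncol(dosage))
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  bad <- tapply(map$pos_cM, map$chrom, function(p) any(diff(p) < 0))
  if (any(unlist(bad))) stop("pos_cM must be non-decreasing within chromosomes")
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a geno_matrix by individuals and/or markers
#' @param x a [geno_matrix()]
#' @param i individual index or names
#' @param j marker index or names
#' @param ... unused
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  d <- x$dosage
  m <- x$map
  if (!missing(j)) {
    jj <- if (is.character(j)) match(j, colnames(d)) else j
    d <- d[, jj, drop = FALSE]
    m <- m[jj, , drop = FALSE]
  }
  if (!missing(i)) d <- d[i, , drop = FALSE]
  geno_matrix(d, m)
}

#' Simulate fully inbred founder lines
#'
#' Draws a panel of homozygous founder genotypes. Per-marker reference-allele
#' frequencies are sampled uniformly within `[maf_low, maf_high]` (both at
#' most 0.5, so the bound is on the minor-allele frequency) and individuals
#' are drawn independently per marker: each inbred carries dosage 0 or 2.
#' Markers are evenly spaced along each chromosome.
#'
#' @param n_individuals number of founder lines.
#' @param n_markers total marker count, split as evenly as possible across
#'   chromosomes.
#' @param n_chromosomes number of chromosomes (wheat-like default 21).
#' @param chrom_length_cM genetic length of each chromosome in centimorgans.
#' @param maf_low,maf_high bounds on the per-marker allele frequency,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param seed optional integer seed.
#' @param prefix prefix for individual ids.
#' @return A [geno_matrix()] of fully inbred individuals.
#' @export
make_founders <- function(n_individuals, n_markers, n_chromosomes = 21,
                          chrom_length_cM = 150, maf_low = 0.05,
                          maf_high = 0.5, seed = NULL, prefix = "G") {
  if (n_individuals < 1 || n_markers < 1 || n_chromosomes < 1) {
    stop("counts must be positive")
  }
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("require 0 < maf_low <= maf_high <= 0.5")
  }
  if (!is.null(seed)) set.seed(seed)
  per <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  map <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ch) {
    k <- per[ch]
    pos <- if (k == 1) chrom_length_cM / 2 else
      seq(0, chrom_length_cM, length.out = k)
    data.frame(chrom = sprintf("%02d", ch), pos_cM = pos)
  }))
  map$marker <- sprintf("M%05d", seq_len(n_markers))
  map <- map[, c("marker", "chrom", "pos_cM")]
  p <- stats::runif(n_markers, maf_low, maf_high)
  dosage <- 2 * matrix(stats::rbinom(n_individuals * n_markers, 1,
                                     rep(p, each = n_individuals)),
                       nrow = n_individuals)
  rownames(dosage) <- sprintf("%s%03d", prefix, seq_len(n_individuals))
  colnames(dosage) <- map$marker
  geno_matrix(dosage, map)
}

#' Round-robin crossing plan
#'
#' Chains `n` parents into `n` crosses A x B, B x C, ..., last x first, so
#' that every parent is used in exactly two crosses.
#'
#' @param parent_ids ordered character vector of at least 3 distinct ids.
#' @return data.frame with columns `female`, `male` and attribute
#'   `kind = "round_robin"`.
#' @export
round_robin <- function(parent_ids) {
  parent_ids <- as.character(parent_ids)
  if (length(parent_ids) < 3) stop("need at least 3 parents")
  if (anyDuplicated(parent_ids)) stop("duplicate parent ids")
  n <- length(parent_ids)
  plan <- data.frame(female = parent_ids,
                     male = parent_ids[c(2:n, 1)],
                     stringsAsFactors = FALSE)
  attr(plan, "kind") <- "round_robin"
  plan
}

#' Exact F1 cross of two inbred parents
#'
#' @param parent1,parent2 dosage vectors of fully inbred individuals
#'   (values 0/2 only).
#' @return The F1 dosage vector `(parent1 + parent2) / 2`; heterozygous
#'   exactly where the parents carry different alleles.
#' @export
cross <- function(parent1, parent2) {
  if (any(parent1 == 1, na.rm = TRUE) || any(parent2 == 1, na.rm = TRUE)) {
    stop("exact F1 requires fully inbred parents (no dosage 1)")
  }
  if (length(parent1) != length(parent2)) stop("parent lengths differ")
  (parent1 + parent2) / 2
}

# Internal phased-individual representation: list(h1, h2) of 0/1 haplotype
# vectors (1 = reference allele). Inbred dosage vectors convert losslessly;
# for heterozygous dosage input the phase is resolved uniformly at random
# (documented approximation; exact for the inbred-derived F1s used here,
# whose phase is supplied by the pedigree-aware constructors).
as_phased <- function(ind) {
  if (is.list(ind) && all(c("h1", "h2") %in% names(ind))) return(ind)
  d <- ind
  h1 <- as.integer(d == 2)
  h2 <- h1
  het <- which(d == 1)
  if (length(het)) {
    pick <- stats::runif(length(het)) < 0.5
    h1[het] <- as.integer(pick)
    h2[het] <- as.integer(!pick)
  }
  list(h1 = h1, h2 = h2)
}

#' Phased F1 of two inbred parents
#'
#' The F1's first haplotype is parent 1's (single) haplotype, the second is
#' parent 2's, so downstream meioses see the true phase.
#'
#' @param parent1,parent2 dosage vectors of fully inbred individuals.
#' @return A phased individual: `list(h1, h2)` of 0/1 haplotypes.
#' @export
phased_f1 <- function(parent1, parent2) {
  list(h1 = as.integer(parent1 / 2), h2 = as.integer(parent2 / 2))
}

#' Dosage vector of an individual
#'
#' @param ind a phased individual (`list(h1, h2)`) or a dosage vector.
#' @return Numeric dosage vector (reference-allele copies).
#' @export
dosage_of <- function(ind) {
  if (is.list(ind)) ind$h1 + ind$h2 else ind
}

#' One meiosis under the Haldane (no-interference) model
#'
#' Crossover counts per chromosome are Poisson with mean equal to the map
#' extent in Morgans; crossover positions are uniform. The returned gamete
#' carries, at each marker, the allele of the currently active homolog.
#'
#' @param individual either a phased individual (`list(h1, h2)` of 0/1
#'   haplotypes) or a dosage vector; unphased heterozygous loci get a
#'   uniformly random phase.
#' @param map marker map (`marker`, `chrom`, `pos_cM`) conformable with the
#'   genotype.
#' @param seed optional integer seed.
#' @return Integer 0/1 haplotype vector (1 = reference allele).
#' @export
meiosis <- function(individual, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- as_phased(individual)
  if (length(ind$h1) != nrow(map)) stop("genotype and map not conformable")
  gam <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos_cM[idx]
    span <- max(pos) - min(pos)
    nxo <- stats::rpois(1, span / 100)
    xo <- if (nxo > 0) sort(stats::runif(nxo, min(pos), max(pos))) else numeric(0)
    start <- stats::rbinom(1, 1, 0.5)
    homolog <- (start + findInterval(pos, xo)) %% 2
    gam[idx] <- ifelse(homolog == 0, ind$h1[idx], ind$h2[idx])
  }
  gam
}

#' Self one individual
#'
#' Two independent meioses of the same parent form the offspring.
#' @inheritParams meiosis
#' @return A phased individual (`list(h1, h2)`).
#' @export
self_once <- function(individual, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- as_phased(individual)
  list(h1 = meiosis(ind, map), h2 = meiosis(ind, map))
}

#' Single-seed descent
#'
#' Advances one individual through `n_generations` of self-fertilisation,
#' keeping a single offspring per generation (the SSD scheme used to carry
#' F2 plants to the F5 generation).
#'
#' @inheritParams meiosis
#' @param n_generations number of selfing generations (>= 1).
#' @return A phased individual (`list(h1, h2)`).
#' @export
self_ssd <- function(individual, map, n_generations, seed = NULL) {
  if (n_generations < 1) stop("n_generations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ind <- as_phased(individual)
  for (g in seq_len(n_generations)) ind <- self_once(ind, map)
  ind
}

#' Proportion of heterozygous loci
#' @param x dosage vector or phased individual.
#' @export
heterozygosity <- function(x) mean(dosage_of(x) == 1, na.rm = TRUE)

#' Assemble phased individuals into a geno_matrix
#' @param inds named list of phased individuals or dosage vectors.
#' @param map marker map.
#' @export
as_geno_matrix <- function(inds, map) {
  d <- do.call(rbind, lapply(inds, dosage_of))
  rownames(d) <- names(inds)
  colnames(d) <- map$marker
  geno_matrix(d, map)
}
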