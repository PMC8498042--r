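# File formats: VCF and CSV dosage genotypes, phenotype and environment
# profile CSV dialects, marker filtering and dataset validation.
#
# Conventions: dosage counts reference-allele copies, so GT 0/0 maps to
# dosage 2 and 1/1 to 0. Genetic positions (cM) live in the INFO field
# (key cM); POS is the cM position scaled to an integer coordinate.
# Writers are deterministic (stable row/column order); CSVs use UTF-8,
# decimal point '.', missing token NA.

#' Write genotypes to a VCF (v4.2 subset)
#'
#' @param geno a [geno_matrix()].
#' @param path output file (plain text).
#' @export
write_genotypes_vcf <- function(geno, path) {
  d <- geno$dosage
  map <- geno$map
  gt <- function(x) c(`2` = "0/0", `1` = "0/1", `0` = "1/1")[as.character(x)]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=rrgskit",
    "##INFO=<ID=cM,Number=1,Type=Float,Description=\"Genetic map position in centimorgans\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"))
  pos <- round(map$pos_cM * 1e4) + seq_len(nrow(map))  # strictly increasing
  body <- vapply(seq_len(nrow(map)), function(j) {
    g <- gt(d[, j])
    g[is.na(g)] <- "./."
    paste(c(map$chrom[j], pos[j], map$marker[j], "A", "T", ".", "PASS",
            sprintf("cM=%.6g", map$pos_cM[j]), "GT", g), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write genotypes to a CSV dosage matrix
#'
#' Individuals as rows, a header row of marker ids, first column
#' `individual`. The map is written alongside when `map_path` is given.
#'
#' @param geno a [geno_matrix()].
#' @param path output CSV.
#' @param map_path optional CSV for the marker map.
#' @export
write_genotypes_csv <- function(geno, path, map_path = NULL) {
  df <- data.frame(individual = rownames(geno$dosage), geno$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(map_path)) {
    utils::write.csv(geno$map, map_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read genotypes from VCF or CSV
#'
#' VCF input is parsed with vcfR; multi-allelic sites are dropped with a
#' logged reason. CSV input follows the dialect of
#' [write_genotypes_csv()]; without a map file, markers are placed on one
#' nominal chromosome at index positions.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"csv"`.
#' @param map_path optional map CSV for CSV input.
#' @return A [geno_matrix()]; attribute `filter_log` records dropped
#'   sites.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "csv"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
    else "csv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                  dimnames = dimnames(vcfR::getFIX(v)))
    multi <- grepl(",", fix[, "ALT"])
    log <- data.frame(marker = as.character(fix[multi, "ID"]),
                      reason = rep("multi-allelic site dropped", sum(multi)),
                      stringsAsFactors = FALSE)
    gtm <- vcfR::extract.gt(v, element = "GT")
    keep <- which(!multi)
    gtm <- gtm[keep, , drop = FALSE]
    info <- vcfR::extract.info(v, element = "cM")
    cm <- suppressWarnings(as.numeric(info[keep]))
    cm[is.na(cm)] <- seq_along(cm)[is.na(cm)]
    to_dos <- function(g) {
      g <- gsub("\\|", "/", g)
      out <- rep(NA_real_, length(g))
      out[g %in% "0/0"] <- 2
      out[g %in% c("0/1", "1/0")] <- 1
      out[g %in% "1/1"] <- 0
      out
    }
    d <- t(apply(gtm, 1, to_dos))
    dimnames(d) <- dimnames(gtm)
    map <- data.frame(marker = fix[keep, "ID"], chrom = fix[keep, "CHROM"],
                      pos_cM = cm, stringsAsFactors = FALSE)
    g <- geno_matrix(t(d), map)
    attr(g, "filter_log") <- log
    return(g)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  mode(d) <- "numeric"
  rownames(d) <- df[[1]]
  map <- if (!is.null(map_path)) {
    utils::read.csv(map_path, stringsAsFactors = FALSE)
  } else {
    data.frame(marker = colnames(d), chrom = "1",
               pos_cM = seq_len(ncol(d)), stringsAsFactors = FALSE)
  }
  g <- geno_matrix(d, map)
  attr(g, "filter_log") <- data.frame(marker = character(0),
                                      reason = character(0))
  g
}

#' Filter markers by missingness, polymorphism and uniqueness
#'
#' Removes markers exceeding the missingness threshold, monomorphic
#' markers (when requested), and collapses duplicate marker columns to one
#' representative. The filter log fully accounts for the difference
#' between input and output marker counts.
#'
#' @param geno a [geno_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.05).
#' @param require_polymorphic drop monomorphic markers (default TRUE).
#' @return Filtered [geno_matrix()] with attribute `filter_log`
#'   (data.frame `marker`, `reason`).
#' @export
filter_markers <- function(geno, max_missing = 0.05,
                           require_polymorphic = TRUE) {
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0, 1]")
  d <- geno$dosage
  log <- list()
  miss <- colMeans(is.na(d))
  drop1 <- miss > max_missing
  if (any(drop1)) {
    log[[1]] <- data.frame(marker = colnames(d)[drop1],
                           reason = sprintf("missingness %.3f > %.3f",
                                            miss[drop1], max_missing))
  }
  keep <- !drop1
  if (require_polymorphic) {
    mono <- apply(d, 2, function(x) length(unique(stats::na.omit(x))) < 2)
    drop2 <- keep & mono
    if (any(drop2)) {
      log[[2]] <- data.frame(marker = colnames(d)[drop2],
                             reason = "monomorphic")
    }
    keep <- keep & !mono
  }
  kidx <- which(keep)
  sig <- apply(d[, kidx, drop = FALSE], 2, paste, collapse = ",")
  dup <- duplicated(sig)
  if (any(dup)) {
    first_of <- vapply(sig[dup], function(s) colnames(d)[kidx][match(s, sig)], "")
    log[[3]] <- data.frame(marker = colnames(d)[kidx][dup],
                           reason = sprintf("duplicate of %s", first_of))
  }
  kidx <- kidx[!dup]
  if (length(kidx) == 0) stop("all markers removed by filtering")
  out <- geno_matrix(d[, kidx, drop = FALSE], geno$map[kidx, , drop = FALSE])
  attr(out, "filter_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(marker = character(0), reason = character(0))
  out
}

#' Write / read the long-format phenotype CSV dialect
#'
#' Columns: genotype_id, role \{line|hybrid|check\}, female_parent,
#' male_parent, location, year, block, value.
#'
#' @param table phenotype data.frame.
#' @param path CSV path.
#' @export
write_phenotypes_csv <- function(table, path) {
  cols <- c("genotype_id", "role", "female_parent", "male_parent",
            "location", "year", "block", "value")
  for (cc in setdiff(cols, names(table))) table[[cc]] <- NA
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_pheno_table(df)
}

#' Write / read environment profiles as CSV
#'
#' Columns: location, date, evi, paw (one file may hold several
#' locations); reference extremes travel in `evi_min` / `evi_max` columns.
#'
#' @param profiles list of [env_profile()] objects.
#' @param path CSV path.
#' @export
write_env_profiles_csv <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(location = p$location_id, date = as.character(p$dates),
               evi = p$evi,
               paw = if (is.null(p$paw)) NA_real_ else p$paw,
               evi_min = p$evi_min, evi_max = p$evi_max,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_env_profiles_csv
#' @export
read_env_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$location), function(s) {
    s <- s[order(s$date), ]
    env_profile(s$location[1], as.Date(s$date), s$evi,
                evi_min = s$evi_min[1], evi_max = s$evi_max[1],
                paw = if (all(is.na(s$paw))) NULL else s$paw)
  })
}

#' Validate the cross-references of a dataset
#'
#' Checks, without throwing, that dosage values are legal, map and dosage
#' dimensions agree, and every phenotyped hybrid's parents are genotyped.
#'
#' @param dataset list with elements `genotypes` ([geno_matrix()]),
#'   optional `phenotypes` (phenotype table) and `profiles`.
#' @return data.frame (`rule`, `pass`, `detail`), one row per rule.
#' @export
validate_dataset <- function(dataset) {
  rules <- list()
  add <- function(rule, pass, detail = "") {
    rules[[length(rules) + 1]] <<- data.frame(rule = rule, pass = pass,
                                              detail = detail,
                                              stringsAsFactors = FALSE)
  }
  g <- dataset$genotypes
  if (!is.null(g)) {
    bad <- arrayInd(which(!(g$dosage %in% c(0, 1, 2)) & !is.na(g$dosage)),
                    dim(g$dosage))
    add("dosage_values_legal", nrow(bad) == 0,
        if (nrow(bad)) sprintf("illegal dosage at [%s]",
                               paste(sprintf("%d,%d", bad[, 1], bad[, 2]),
                                     collapse = "; ")) else "")
    add("map_dimensions_match", nrow(g$map) == ncol(g$dosage))
  } else {
    add("genotypes_present", FALSE, "no genotype matrix supplied")
  }
  p <- dataset$phenotypes
  if (!is.null(p) && !is.null(g)) {
    hyb <- p[p$role == "hybrid", , drop = FALSE]
    par <- unique(c(hyb$female_parent, hyb$male_parent))
    par <- par[!is.na(par)]
    miss <- setdiff(par, rownames(g$dosage))
    add("hybrid_parents_genotyped", length(miss) == 0,
        if (length(miss)) paste("ungenotyped parents:",
                                paste(miss, collapse = ", ")) else "")
  }
  do.call(rbind, rules)
}

#' Serialize / restore a fitted prediction model as JSON
#'
#' The container records the coding convention, intercept, marker ids,
#' additive and dominance effects and the shrinkage variance components,
#' so a trained model can be archived or exchanged as plain text.
#'
#' @param model an [fit_rrblup_ad()] model.
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "rrblup_model"))
  obj <- list(container = "rrblup_model", coding = model$coding,
              mu = model$mu, marker_ids = model$marker_ids,
              additive = unname(model$a), dominance = unname(model$d),
              vc = model$vc, converged = model$converged,
              iterations = model$iterations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "rrblup_model")) {
    stop("not an rrblup_model container")
  }
  structure(list(mu = obj$mu,
                 a = stats::setNames(obj$additive, obj$marker_ids),
                 d = stats::setNames(obj$dominance, obj$marker_ids),
                 vc = as.list(obj$vc), marker_ids = obj$marker_ids,
                 coding = obj$coding, converged = obj$converged,
                 iterations = obj$iterations, loglik = NA_real_),
            class = "rrblup_model")
}
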