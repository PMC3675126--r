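#' Read a genotype matrix into a cohort
#'
#' Two dialects are supported. `tsv`: variants as columns (header row of
#' variant ids), one individual per row, entries 0/1/2 minor-allele counts.
#' `vcf`: biallelic sites with GT fields; ALT counts are converted to
#' minor-allele counts with the minor allele determined in the loaded
#' sample (ties resolved to ALT); non-biallelic sites are skipped with a
#' warning. Missing genotypes are an error under `missing = "strict"` and
#' mean-imputed (rounded) under `missing = "impute"`.
#'
#' @param path Genotype file.
#' @param format `"tsv"` or `"vcf"`.
#' @param phenotypes Optional path of a companion phenotype TSV with
#'   columns `id` and `status` (0/1), one row per individual in file order.
#' @param missing Missing-genotype policy (VCF only).
#' @return A `cohort` (with `status = NA` when no phenotype file is given);
#'   variant metadata holds chromosome, position and sample MAF.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           phenotypes = NULL,
                           missing = c("strict", "impute")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (format == "tsv") {
    tab <- data.table::fread(path, sep = "\t", header = TRUE,
                             data.table = FALSE)
    X <- as.matrix(tab)
    storage.mode(X) <- "integer"
    if (anyNA(X) || any(X < 0 | X > 2))
      stop("genotype TSV entries must be 0/1/2", call. = FALSE)
    variants <- data.frame(id = colnames(X), chrom = NA_character_,
                           pos = NA_integer_, stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package", call. = FALSE)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    biallelic <- !grepl(",", fix[, "ALT"]) & nzchar(fix[, "ALT"]) &
      nchar(fix[, "REF"]) >= 1
    if (any(!biallelic))
      warning(sum(!biallelic), " non-biallelic site(s) skipped")
    gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
    fix <- fix[biallelic, , drop = FALSE]
    alt_count <- function(g) {
      alleles <- strsplit(g, "[/|]")
      vapply(alleles, function(a) {
        if (any(a == "." | is.na(a))) NA_integer_ else sum(a == "1")
      }, integer(1))
    }
    X <- t(apply(gt, 1, alt_count))     # sites x individuals
    if (anyNA(X)) {
      if (missing == "strict") {
        bad <- which(rowSums(is.na(X)) > 0)[1]
        stop("missing genotype at VCF record for ", fix[bad, "CHROM"], ":",
             fix[bad, "POS"], " (site line ", bad, ")", call. = FALSE)
      }
      for (i in which(rowSums(is.na(X)) > 0)) {
        X[i, is.na(X[i, ])] <- as.integer(round(mean(X[i, ], na.rm = TRUE)))
      }
    }
    # recode on the sample minor allele; ties keep ALT
    flip <- rowMeans(X) / 2 > 0.5
    X[flip, ] <- 2L - X[flip, , drop = FALSE]
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                           fix[, "POS"])[is.na(ids) | ids == "."]
    variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"]),
                           stringsAsFactors = FALSE)
    X <- t(X)
    storage.mode(X) <- "integer"
    colnames(X) <- variants$id
  }
  status <- rep(NA_integer_, nrow(X))
  if (!is.null(phenotypes)) {
    ph <- utils::read.table(phenotypes, header = TRUE, sep = "\t")
    if (nrow(ph) != nrow(X))
      stop("phenotype rows (", nrow(ph), ") do not match individuals (",
           nrow(X), ")", call. = FALSE)
    status <- as.integer(ph$status)
  }
  f <- colMeans(X) / 2
  variants$maf <- pmin(f, 1 - f)
  variants$pop_maf <- NA_real_
  variants$causal <- FALSE
  colnames(X) <- variants$id
  structure(list(genotypes = X, status = status, variants = variants),
            class = "cohort")
}

#' Write a cohort's genotypes (and phenotypes) as TSV
#'
#' @param cohort A `cohort`.
#' @param path Genotype TSV path (variants as columns).
#' @param phenotypes_path Optional phenotype TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(cohort, path, phenotypes_path = NULL) {
  df <- as.data.frame(cohort$genotypes)
  data.table::fwrite(df, path, sep = "\t")
  if (!is.null(phenotypes_path)) {
    utils::write.table(
      data.frame(id = seq_along(cohort$status), status = cohort$status),
      phenotypes_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

format6 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) signif(x, 6) else x
}

#' Write an analysis result as a TSV file
#'
#' Deterministic column order, documented headers, numeric columns at six
#' significant digits. Accepts a `bvlr_fit`, a `permutation_result`, or a
#' `power_report`.
#'
#' @param x Result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  tab <- if (inherits(x, "bvlr_fit")) {
    x$summary
  } else if (inherits(x, "permutation_result")) {
    x$table
  } else if (inherits(x, "power_report")) {
    data.frame(
      quantity = c(paste0("power_variant_", seq_along(x$per_variant)),
                   "p_at_least_1", "p_at_least_2", "p_all", "average_power",
                   "fpr_causal_chrom", "fpr_null_chrom", "mean_candidates",
                   "n_replicates"),
      value = c(x$per_variant, x$p_at_least_1, x$p_at_least_2, x$p_all,
                x$average, x$fpr_causal_chrom, x$fpr_null_chrom,
                x$mean_candidates, x$n_replicates),
      stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    x
  } else stop("unsupported result object", call. = FALSE)
  tab[] <- lapply(tab, format6)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
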