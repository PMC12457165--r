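#' Quality-control thresholds
#'
#' Defaults reproduce the standard PLINK-style pipeline used for the
#' reference dataset: variants with call rate less than 90%, samples with
#' call rate below 90%, variants out of Hardy-Weinberg equilibrium at
#' p < 1e-5, and variants with minor allele frequency less than 0.01 are
#' removed. All thresholds are strict inequalities on the failing side.
#'
#' @param min_variant_call_rate Variant call-rate threshold (default 0.90).
#' @param min_sample_call_rate Sample call-rate threshold (default 0.90).
#' @param hwe_alpha HWE exact-test p-value threshold (default 1e-5).
#' @param min_maf Minor-allele-frequency threshold (default 0.01).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_variant_call_rate = 0.90,
                          min_sample_call_rate = 0.90,
                          hwe_alpha = 1e-5, min_maf = 0.01) {
  vals <- c(min_variant_call_rate, min_sample_call_rate, hwe_alpha, min_maf)
  if (any(vals <= 0) || any(vals > 1)) stop("thresholds must lie in (0, 1]")
  structure(list(min_variant_call_rate = min_variant_call_rate,
                 min_sample_call_rate = min_sample_call_rate,
                 hwe_alpha = hwe_alpha, min_maf = min_maf),
            class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' probability of each possible heterozygote count follows the standard
#' conditional distribution, and the p-value sums the probabilities of all
#' outcomes no more probable than the observed one (the plain, non-mid-p
#' version, the conventional default). Monomorphic input returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (nonnegative, total > 0).
#' @return The exact two-sided p-value.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)  # most probable configuration: p = 1
#' hwe_exact_test(19, 2, 19)   # strong heterozygote deficit
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be positive")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (n_rare == 0 || n_rare == 2 * n) return(1)

  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hets, function(h) {
    n_r_hom <- (n_rare - h) / 2
    n_c_hom <- n - h - n_r_hom
    lgamma(n + 1) - lgamma(n_r_hom + 1) - lgamma(h + 1) - lgamma(n_c_hom + 1) +
      h * log(2) +
      lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}

# one removal record per filtered variant/sample
removal_tbl <- function(id = character(), reason = character(),
                        statistic = numeric()) {
  tibble::tibble(id = unname(id), reason = reason,
                 statistic = unname(statistic))
}

#' Filter variants on call rate
#'
#' Removes variants whose call rate is strictly below `threshold`, preserving
#' the order of survivors.
#'
#' @param geno A [new_geno()] object.
#' @param threshold Minimum call rate retained (default 0.90).
#' @return A list: `geno` (filtered), `removed` (tibble `id`, `reason`,
#'   `statistic`).
#' @export
variant_call_rate_filter <- function(geno, threshold = 0.90) {
  stopifnot(inherits(geno, "geno"))
  if (ncol(geno$dosage) == 0 || nrow(geno$dosage) == 0) stop("empty genotype matrix")
  cr <- colMeans(!is.na(geno$dosage))
  bad <- cr < threshold
  list(geno = subset_geno(geno, snps = !bad),
       removed = removal_tbl(geno$snps$snp[bad], "variant_call_rate", cr[bad]))
}

#' Filter samples on call rate
#'
#' @inheritParams variant_call_rate_filter
#' @return A list: `geno` (filtered), `removed` (tibble `id`, `reason`,
#'   `statistic` = call rate).
#' @export
sample_call_rate_filter <- function(geno, threshold = 0.90) {
  stopifnot(inherits(geno, "geno"))
  if (ncol(geno$dosage) == 0 || nrow(geno$dosage) == 0) stop("empty genotype matrix")
  cr <- rowMeans(!is.na(geno$dosage))
  bad <- cr < threshold
  list(geno = subset_geno(geno, samples = !bad),
       removed = removal_tbl(geno$samples$id[bad], "sample_call_rate", cr[bad]))
}

#' Filter variants out of Hardy-Weinberg equilibrium
#'
#' @inheritParams variant_call_rate_filter
#' @param alpha Exact-test p-value below which a variant is removed.
#' @return A list: `geno`, `removed` (statistic = HWE p-value).
#' @export
hwe_filter <- function(geno, alpha = 1e-5) {
  stopifnot(inherits(geno, "geno"))
  d <- geno$dosage
  pvals <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  bad <- pvals < alpha
  list(geno = subset_geno(geno, snps = !bad),
       removed = removal_tbl(geno$snps$snp[bad], "hwe", pvals[bad]))
}

#' Filter variants on minor allele frequency
#'
#' MAF is computed on non-missing dosages; variants with MAF strictly below
#' `min_maf` are removed.
#'
#' @inheritParams variant_call_rate_filter
#' @param min_maf Minimum MAF retained (default 0.01).
#' @return A list: `geno`, `removed` (statistic = MAF).
#' @export
maf_filter <- function(geno, min_maf = 0.01) {
  stopifnot(inherits(geno, "geno"))
  maf <- snp_stats(geno)$maf
  bad <- maf < min_maf
  list(geno = subset_geno(geno, snps = !bad),
       removed = removal_tbl(geno$snps$snp[bad], "maf", maf[bad]))
}

#' Run the full QC pipeline
#'
#' Applies, in order: variant call rate, sample call rate, Hardy-Weinberg
#' exact test, minor allele frequency (the conventional PLINK order). The
#' report accounts for every removed variant and sample.
#'
#' @param geno A [new_geno()] object.
#' @param thresholds A [qc_thresholds()].
#' @param keep_snps Optional character vector of variant ids to restrict to
#'   before filtering (e.g. an array-subset keep-list).
#' @return A list: `geno` (the filtered genotypes) and `report` (a
#'   `qc_report` with counts and removal tables).
#' @export
run_qc <- function(geno, thresholds = qc_thresholds(), keep_snps = NULL) {
  stopifnot(inherits(geno, "geno"), inherits(thresholds, "qc_thresholds"))
  if (!is.null(keep_snps)) geno <- subset_geno(geno, snps = keep_snps)
  n_var_in <- ncol(geno$dosage); n_samp_in <- nrow(geno$dosage)

  s1 <- variant_call_rate_filter(geno, thresholds$min_variant_call_rate)
  s2 <- sample_call_rate_filter(s1$geno, thresholds$min_sample_call_rate)
  s3 <- hwe_filter(s2$geno, thresholds$hwe_alpha)
  s4 <- maf_filter(s3$geno, thresholds$min_maf)

  removed_variants <- dplyr::bind_rows(s1$removed, s3$removed, s4$removed)
  removed_samples <- s2$removed
  report <- structure(list(
    n_variants_in = n_var_in, n_variants_out = ncol(s4$geno$dosage),
    n_samples_in = n_samp_in, n_samples_out = nrow(s4$geno$dosage),
    removed_variants = removed_variants, removed_samples = removed_samples,
    thresholds = thresholds
  ), class = "qc_report")
  stopifnot(report$n_variants_in - nrow(removed_variants) == report$n_variants_out,
            report$n_samples_in - nrow(removed_samples) == report$n_samples_out)
  list(geno = s4$geno, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> variants %d -> %d, samples %d -> %d\n",
              x$n_variants_in, x$n_variants_out,
              x$n_samples_in, x$n_samples_out))
  if (nrow(x$removed_variants) > 0) {
    tab <- table(x$removed_variants$reason)
    cat("  variant removals:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report` from [run_qc()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(list(
    n_variants_in = report$n_variants_in,
    n_variants_out = report$n_variants_out,
    n_samples_in = report$n_samples_in,
    n_samples_out = report$n_samples_out,
    removed_variants = report$removed_variants,
    removed_samples = report$removed_samples,
    thresholds = unclass(report$thresholds)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
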