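#' Construct a genotype matrix object
#'
#' Light container for biallelic SNP dosages: an individuals-by-SNPs numeric
#' matrix of counts of the A1 allele (0/1/2, `NA` = missing call) plus SNP and
#' sample annotation tables. All QC, GRM and I/O functions operate on this
#' class.
#'
#' @param dosage Numeric matrix, individuals in rows, SNPs in columns; values
#'   0, 1, 2 or `NA`. Row and column names are used as ids when `samples` /
#'   `snps` are not given.
#' @param snps Optional tibble with columns `snp`, `chr`, `pos`, `a1`, `a2`
#'   (one row per column of `dosage`).
#' @param samples Optional tibble with columns `id`, `sire`, `dam` (one row
#'   per row of `dosage`); `sire`/`dam` are `NA` for founders.
#' @return An object of class `geno`.
#' @export
new_geno <- function(dosage, snps = NULL, samples = NULL) {
  stopifnot(is.matrix(dosage))
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("id%0*d", nchar(nrow(dosage)), seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("snp%0*d", nchar(ncol(dosage)), seq_len(ncol(dosage)))
  }
  if (is.null(snps)) {
    snps <- tibble::tibble(
      snp = colnames(dosage), chr = 1L,
      pos = seq_len(ncol(dosage)), a1 = "A", a2 = "B"
    )
  }
  if (is.null(samples)) {
    samples <- tibble::tibble(id = rownames(dosage),
                              sire = NA_character_, dam = NA_character_)
  }
  stopifnot(nrow(snps) == ncol(dosage), nrow(samples) == nrow(dosage))
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad) > 0) stop("dosages must be 0, 1, 2 or NA")
  structure(list(dosage = dosage, snps = tibble::as_tibble(snps),
                 samples = tibble::as_tibble(samples)),
            class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("<geno> %d individuals x %d SNPs, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$dosage)

#' Subset a genotype object by individuals and/or SNPs
#'
#' @param geno A [new_geno()] object.
#' @param samples Character ids or logical/integer index over individuals.
#' @param snps Character ids or logical/integer index over SNPs.
#' @return A `geno` with the selected rows/columns and matching annotation.
#' @export
subset_geno <- function(geno, samples = NULL, snps = NULL) {
  stopifnot(inherits(geno, "geno"))
  ri <- seq_len(nrow(geno$dosage))
  ci <- seq_len(ncol(geno$dosage))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, geno$samples$id) else ri[samples]
    if (anyNA(ri)) stop("unknown sample id(s)")
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, geno$snps$snp) else ci[snps]
    if (anyNA(ci)) stop("unknown SNP id(s)")
  }
  new_geno(geno$dosage[ri, ci, drop = FALSE],
           snps = geno$snps[ci, ], samples = geno$samples[ri, ])
}

# Per-SNP call rate, allele frequency (of A1) and MAF on non-missing calls.
snp_stats <- function(geno) {
  d <- geno$dosage
  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  tibble::tibble(
    snp = geno$snps$snp,
    call_rate = n_obs / nrow(d),
    freq = ifelse(n_obs > 0, p, NA_real_),
    maf = pmin(p, 1 - p)
  )
}
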