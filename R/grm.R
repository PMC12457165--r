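#' Compute the additive genomic relationship matrix
#'
#' VanRaden's first method by default: missing dosages are mean-imputed per
#' SNP, the dosage matrix is centered by twice the sample allele frequency,
#' and G = M M' / sum(2 p (1 - p)) over the SNPs used. Monomorphic SNPs are
#' excluded from both numerator and denominator. Allele frequencies are
#' estimated from the analyzed sample itself.
#'
#' @param geno A [new_geno()] object (post-QC), at least 2 individuals and
#'   one polymorphic SNP.
#' @param method `"vanraden1"` (single ratio of sums, the default) or
#'   `"standardized"` (per-SNP unit-variance scaling before averaging).
#' @return A `grm` object: `matrix` (symmetric n x n), `ids`, `n_snps_used`,
#'   `method`; the eigendecomposition is computed lazily by [grm_eigen()].
#' @export
#' @examples
#' g <- new_geno(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'                      dimnames = list(c("a", "b", "c"), NULL)))
#' compute_grm(g)
compute_grm <- function(geno, method = c("vanraden1", "standardized")) {
  stopifnot(inherits(geno, "geno"))
  method <- match.arg(method)
  d <- geno$dosage
  if (nrow(d) < 2) stop("need at least 2 individuals")
  storage.mode(d) <- "double"

  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  poly <- n_obs > 0 & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]

  # mean-impute, then center by 2p
  M <- sweep(d, 2, 2 * p, "-")
  M[is.na(M)] <- 0
  if (method == "vanraden1") {
    G <- tcrossprod(M) / sum(2 * p * (1 - p))
  } else {
    M <- sweep(M, 2, sqrt(2 * p * (1 - p)), "/")
    G <- tcrossprod(M) / ncol(M)
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- list(geno$samples$id, geno$samples$id)
  structure(list(matrix = G, ids = geno$samples$id,
                 n_snps_used = sum(poly), method = method, eigen = NULL),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals, %d SNPs used (%s), mean diag %.3f\n",
              length(x$ids), x$n_snps_used, x$method,
              mean(diag(x$matrix))))
  invisible(x)
}

#' Eigendecomposition of a GRM, cached
#'
#' @param grm A [compute_grm()] result.
#' @return The `grm` with `eigen` filled (`values` descending, `vectors`).
#' @export
grm_eigen <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  if (is.null(grm$eigen)) grm$eigen <- eigen(grm$matrix, symmetric = TRUE)
  grm
}

#' Principal-component covariates from a GRM
#'
#' The top-k eigenvectors of G scaled by the square root of their
#' eigenvalues, with a deterministic sign convention (the largest-magnitude
#' coordinate of each component is positive), so repeated runs are
#' bit-identical.
#'
#' @param grm A [compute_grm()] result.
#' @param k Number of components (k < n).
#' @return A tibble: `id`, `pc1` ... `pck`.
#' @export
compute_pcs <- function(grm, k = 3) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$ids)
  if (k >= n) stop("k must be smaller than the number of individuals")
  grm <- grm_eigen(grm)
  ev <- grm$eigen$values[seq_len(k)]
  U <- grm$eigen$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) U[, j] <- -U[, j]
  }
  scores <- sweep(U, 2, sqrt(pmax(ev, 0)), "*")
  colnames(scores) <- paste0("pc", seq_len(k))
  dplyr::bind_cols(tibble::tibble(id = grm$ids), tibble::as_tibble(scores))
}

#' Write a GRM in the GCTA binary-triplet convention
#'
#' Writes `<prefix>.grm.bin` (float32 lower triangle including the diagonal,
#' row by row), `<prefix>.grm.N.bin` (float32 SNP counts per pair) and
#' `<prefix>.grm.id` (two-column id file).
#'
#' @param grm A [compute_grm()] result.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$ids)
  lower <- grm$matrix[upper.tri(grm$matrix, diag = TRUE)]
  # upper.tri by column = lower triangle row by row for a symmetric matrix
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_snps_used), length(lower)), con, size = 4)
  close(con)
  utils::write.table(data.frame(fid = grm$ids, iid = grm$ids),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary-triplet GRM
#'
#' @param prefix Path prefix (expects `.grm.bin` and `.grm.id`).
#' @return A `grm` object (float32 precision).
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           col.names = c("fid", "iid"),
                           colClasses = "character")$iid
  n <- length(ids)
  m <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  vals <- readBin(con, numeric(), n = m, size = 4)
  close(con)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[upper.tri(G, diag = TRUE)] <- vals
  G <- G + t(G) - diag(diag(G))
  nfile <- paste0(prefix, ".grm.N.bin")
  n_snps <- if (file.exists(nfile)) {
    con <- file(nfile, "rb")
    v <- readBin(con, numeric(), n = 1, size = 4)
    close(con)
    as.integer(round(v))
  } else NA_integer_
  structure(list(matrix = G, ids = ids, n_snps_used = n_snps,
                 method = "file", eigen = NULL), class = "grm")
}

#' Write a GRM as plain CSV (small matrices)
#'
#' @param grm A [compute_grm()] result.
#' @param path Output CSV path; first column `id`, then one column per
#'   individual.
#' @return `path`, invisibly.
#' @export
write_grm_csv <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  df <- data.frame(id = grm$ids, grm$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
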