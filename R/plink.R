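#' Write genotypes in PLINK format
#'
#' Writes either the text dialect (`.ped`/`.map`) or the binary dialect
#' (`.bed`/`.bim`/`.fam`, SNP-major). Dosages count copies of the A1 allele;
#' missing calls become `0 0` (ped) or the missing code (bed). Family id is
#' set equal to the individual id; sire/dam come from the sample table.
#'
#' @param geno A [new_geno()] object.
#' @param prefix Output path prefix (without extension).
#' @param format `"bed"` (default) or `"ped"`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix, format = c("bed", "ped")) {
  stopifnot(inherits(geno, "geno"))
  format <- match.arg(format)
  d <- geno$dosage
  n <- nrow(d); m <- ncol(d)
  snps <- geno$snps
  samples <- geno$samples
  fam <- data.frame(
    fid = samples$id, iid = samples$id,
    pat = ifelse(is.na(samples$sire), "0", samples$sire),
    mat = ifelse(is.na(samples$dam), "0", samples$dam),
    sex = 0L, pheno = -9L
  )

  if (format == "ped") {
    utils::write.table(
      data.frame(chr = snps$chr, snp = snps$snp, cm = 0, pos = snps$pos),
      paste0(prefix, ".map"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    a1 <- snps$a1; a2 <- snps$a2
    alle <- matrix("0", n, 2 * m)
    for (j in seq_len(m)) {
      x <- d[, j]
      g1 <- ifelse(is.na(x), "0", ifelse(x >= 1, a1[j], a2[j]))
      g2 <- ifelse(is.na(x), "0", ifelse(x == 2, a1[j], a2[j]))
      alle[, 2 * j - 1] <- g1
      alle[, 2 * j] <- g2
    }
    utils::write.table(cbind(fam, alle), paste0(prefix, ".ped"),
                       sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(
      data.frame(chr = snps$chr, snp = snps$snp, cm = 0, pos = snps$pos,
                 a1 = snps$a1, a2 = snps$a2),
      paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    # 2-bit codes per sample: 00 hom A1, 10 het, 11 hom A2, 01 missing
    code <- matrix(3L, n, m)
    code[!is.na(d) & d == 2] <- 0L
    code[!is.na(d) & d == 1] <- 2L
    code[is.na(d)] <- 1L
    nb <- ceiling(n / 4)
    pad <- matrix(0L, 4 * nb, m)
    pad[seq_len(n), ] <- code
    dim(pad) <- c(4, nb * m)
    bytes <- pad[1, ] + 4L * pad[2, ] + 16L * pad[3, ] + 64L * pad[4, ]
    con <- file(paste0(prefix, ".bed"), "wb")
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(bytes), con)
    close(con)
  }
  invisible(prefix)
}

#' Read genotypes from PLINK files
#'
#' Reads either dialect, auto-detected from the files present at `prefix`
#' (binary preferred). For the text dialect A1 is the alphabetically first
#' allele observed at each SNP; monomorphic text SNPs report the single
#' observed allele as A1 with dosage 2.
#'
#' @param prefix Path prefix (expects `.bed`/`.bim`/`.fam` or
#'   `.ped`/`.map`).
#' @return A [new_geno()] object.
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) {
    read_plink_bed(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    read_plink_ped(prefix)
  } else {
    stop("no PLINK files found at prefix: ", prefix)
  }
}

read_fam <- function(path) {
  fam <- utils::read.table(path, colClasses = "character",
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  tibble::tibble(id = fam$iid,
                 sire = ifelse(fam$pat == "0", NA_character_, fam$pat),
                 dam = ifelse(fam$mat == "0", NA_character_, fam$mat))
}

read_plink_bed <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), colClasses = "character",
                           col.names = c("chr", "snp", "cm", "pos",
                                         "a1", "a2"))
  samples <- read_fam(paste0(prefix, ".fam"))
  n <- nrow(samples); m <- nrow(bim)
  nb <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  magic <- readBin(con, raw(), n = 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    close(con)
    stop("not a SNP-major PLINK .bed file")
  }
  bytes <- as.integer(readBin(con, raw(), n = nb * m))
  close(con)
  if (length(bytes) != nb * m) stop("truncated .bed file")
  codes <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, (bytes %/% 64L) %% 4L)
  dim(codes) <- c(4 * nb, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(c(2L, NA_integer_, 1L, 0L)[codes + 1L], n, m)
  dimnames(dosage) <- list(samples$id, bim$snp)
  new_geno(dosage,
           snps = tibble::tibble(snp = bim$snp, chr = bim$chr,
                                 pos = as.integer(bim$pos),
                                 a1 = bim$a1, a2 = bim$a2),
           samples = samples)
}

read_plink_ped <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), colClasses = "character",
                           col.names = c("chr", "snp", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) stop(".ped column count does not match .map")
  samples <- tibble::tibble(
    id = ped[[2]],
    sire = ifelse(ped[[3]] == "0", NA_character_, ped[[3]]),
    dam = ifelse(ped[[4]] == "0", NA_character_, ped[[4]]))
  n <- nrow(ped)
  dosage <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    g1 <- ped[[6 + 2 * j - 1]]
    g2 <- ped[[6 + 2 * j]]
    obs <- sort(setdiff(unique(c(g1, g2)), "0"))
    if (length(obs) == 0) {
      a1[j] <- a2[j] <- "0"
      next
    }
    a1[j] <- obs[1]
    a2[j] <- if (length(obs) > 1) obs[2] else "0"
    miss <- g1 == "0" | g2 == "0"
    dosage[, j] <- (g1 == a1[j]) + (g2 == a1[j])
    dosage[miss, j] <- NA_integer_
  }
  dimnames(dosage) <- list(samples$id, map$snp)
  new_geno(dosage,
           snps = tibble::tibble(snp = map$snp, chr = map$chr,
                                 pos = as.integer(map$pos),
                                 a1 = a1, a2 = a2),
           samples = samples)
}
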