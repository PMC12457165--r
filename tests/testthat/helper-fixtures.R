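# Shared fixture builders: everything generated in code, nothing on disk.

# Small simulated population with one trait of each kind.
small_pop <- function(seed = 11, n_founders = 60, n_offspring = 40,
                      n_snps = 500, h2 = 0.4, missing_rate = 0.02) {
  simulate_population(sim_config(
    n_founders = n_founders, n_offspring = n_offspring,
    n_trio_offspring = min(20, n_offspring), n_snps = n_snps,
    n_causal_per_trait = 100,
    trait_specs = list(
      sim_trait_spec("sickly", "binary", h2, 0.3),
      sim_trait_spec("pace", "ordinal", h2, c(0.052, 0.705, 1)),
      sim_trait_spec("merit", "continuous", h2)),
    success_weights = c(merit = 0.5),
    missing_rate = missing_rate, seed = seed))
}

# Toy 40 x 20 genotype object with one planned violation per QC rule.
qc_toy_geno <- function() {
  n <- 40
  base <- rep(c(0L, 1L, 1L, 2L), 10)      # counts (10,20,10): HWE-perfect, MAF 0.5
  d <- matrix(rep(base, 20), nrow = n)
  d[31:35, 1] <- NA                        # snp01: call rate 35/40 = 0.875
  d[, 2] <- c(rep(0L, 19), rep(1L, 2), rep(2L, 18), 2L)  # snp02: HWE violation
  d[, 3] <- 0L                             # snp03: monomorphic, MAF 0
  d[37:40, 4] <- NA                        # snp04: call rate 36/40 = 0.90 (kept)
  d[36, 5:7] <- NA                         # sample 36: call rate drops below 0.9
  rownames(d) <- sprintf("s%02d", 1:n)
  colnames(d) <- sprintf("snp%02d", 1:20)
  new_geno(d)
}

# Brute-force metric oracles (pair enumeration / direct formula loops),
# deliberately independent of the package's rank-based implementations.
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hets, function(h) {
    a <- (nA - h) / 2; b <- n - h - a
    if (a < 0 || b < 0) return(0)
    exp(lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
          h * log(2) +
          lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hets)] * (1 + 1e-10)])
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tx <- tx; next }
    if (dx == 0) { tx <- tx + 1; next }
    if (dy == 0) { ty <- ty + 1; next }
    if (sign(dx) == sign(dy)) C <- C + 1 else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  # pairs tied in both count in neither tie term
  tied_both <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j] && y[i] == y[j]) tied_both <- tied_both + 1
  }
  n1 <- tx + tied_both; n2 <- ty + tied_both
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) return(NA_real_)
  (C - D) / denom
}

oracle_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    below <- sum(x < x[i]); ties <- sum(x == x[i])
    below + (ties + 1) / 2
  }, numeric(1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_ranks(x), oracle_ranks(y))

oracle_mcc <- function(pred, obs) {
  # phi coefficient: Pearson correlation of the two binary vectors
  r <- oracle_pearson(pred, obs)
  if (is.na(r)) 0 else r
}

oracle_nmse <- function(pred, obs) {
  n <- length(obs)
  mo <- sum(obs) / n
  v <- sum((obs - mo)^2) / n
  if (v == 0) return(NA_real_)
  sum((pred - obs)^2) / n / v
}

# Zero-diagnosis health-trait table for index tests.
empty_diagnoses <- function(n = 1) {
  defs <- trait_definitions()
  health <- defs$trait[defs$kind == "binary_health"]
  d <- as.data.frame(matrix(0L, n, length(health)))
  names(d) <- health
  d
}

# Complete behavior-score row with every trait at its best-scoring value.
neutral_behavior <- function(n = 1) {
  data.frame(neck = rep(0, n), distraction = 0, rating = 0, soundness = 0,
             trainability = 0, pace = 1, pull = 1)
}
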