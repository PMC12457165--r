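#' Specify a simulated trait
#'
#' @param name Trait name (a valid column name).
#' @param kind One of `"binary"`, `"ordinal"`, `"continuous"`.
#' @param heritability Narrow-sense heritability of the latent liability,
#'   in \[0, 1\].
#' @param prevalence_or_thresholds For binary traits, the case prevalence (a
#'   single fraction); for ordinal traits, the cumulative category frequencies
#'   in ascending score order (strictly increasing, ending at 1); ignored for
#'   continuous traits.
#' @return A `sim_trait_spec` list.
#' @export
#' @examples
#' sim_trait_spec("pace", "ordinal", 0.153, c(0.052, 0.705, 1))
sim_trait_spec <- function(name, kind = c("binary", "ordinal", "continuous"),
                           heritability, prevalence_or_thresholds = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(heritability) || heritability < 0 || heritability > 1) {
    stop("heritability must lie in [0, 1]")
  }
  if (kind == "binary") {
    p <- prevalence_or_thresholds
    if (is.null(p) || length(p) != 1 || p <= 0 || p >= 1) {
      stop("binary trait '", name, "' needs a prevalence in (0, 1)")
    }
  }
  if (kind == "ordinal") {
    cf <- prevalence_or_thresholds
    if (is.null(cf) || length(cf) < 2 || any(diff(cf) <= 0) ||
        abs(cf[length(cf)] - 1) > 1e-8) {
      stop("ordinal trait '", name,
           "' needs strictly increasing cumulative frequencies ending at 1")
    }
  }
  structure(list(name = name, kind = kind, heritability = heritability,
                 prevalence_or_thresholds = prevalence_or_thresholds),
            class = "sim_trait_spec")
}

#' Default simulated trait set
#'
#' The seven behavior traits (ordinal, with the observed condensed-category
#' frequencies; trainability is simulated on its continuous liability scale
#' because its raw ladder is program-internal) and the twenty binary health
#' conditions, each at the pseudo-heritability estimated in the reference
#' population and a default prevalence of 0.05 (the conditions are
#' low-prevalence incidental findings; per-trait prevalences are not
#' published).
#'
#' @return A list of [sim_trait_spec()] objects.
#' @export
default_sim_traits <- function() {
  defs <- trait_definitions()
  specs <- list()
  for (i in seq_len(nrow(defs))) {
    tr <- defs$trait[i]
    h2 <- max(0, defs$pseudo_h2[i])
    if (defs$kind[i] == "binary_health") {
      specs[[tr]] <- sim_trait_spec(tr, "binary", h2, defs$prevalence[i])
    } else if (tr == "trainability") {
      specs[[tr]] <- sim_trait_spec(tr, "continuous", h2)
    } else {
      specs[[tr]] <- sim_trait_spec(tr, "ordinal", h2, ordinal_cum_freq(tr))
    }
  }
  specs
}

#' Default success-correlation targets
#'
#' Target phenotypic correlations between each trait and the binary success
#' outcome, taken from the reference population's observed trait-to-success
#' correlations (e.g. trainability 0.531, rating -0.144).
#'
#' @return A named numeric vector, trait name -> target correlation.
#' @export
default_success_weights <- function() {
  defs <- trait_definitions()
  stats::setNames(defs$weight_r, defs$trait)
}

#' Simulation configuration
#'
#' Defaults emulate the reference guide-dog population: 844 genotyped dogs of
#' which 172 are offspring with both parents fully phenotyped, tens of
#' thousands of biallelic SNPs, behavior traits with the observed category
#' frequencies, low-prevalence health conditions, and a binary success
#' outcome correlated with the traits at the observed magnitudes.
#'
#' @param n_founders Number of founder individuals (simulated unrelated).
#' @param n_offspring Number of offspring produced by gene dropping from
#'   founder pairs.
#' @param n_trio_offspring Number of offspring flagged as the trio subset
#'   (both parents fully phenotyped); must not exceed `n_offspring`.
#' @param n_snps Number of unlinked biallelic SNPs.
#' @param n_causal_per_trait Causal SNPs drawn per trait.
#' @param maf_range Founder allele-frequency range, within (0, 0.5].
#' @param trait_specs List of [sim_trait_spec()]; default [default_sim_traits()].
#' @param success_weights Named vector of target trait-success correlations.
#' @param success_rate Fraction of dogs classified successful.
#' @param birth_year_range Integer range of birth years (uniform assignment).
#' @param year_effect Additive liability shift per year from the midpoint
#'   (default 0; exercises the birth-year fixed effect when nonzero).
#' @param missing_rate Fraction of genotype calls masked completely at random.
#' @param residual_trait_cor Correlation of environmental residuals shared
#'   across traits (default 0: independent residuals).
#' @param seed Integer seed; fully determines all outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 200, n_offspring = 644,
                       n_trio_offspring = 172, n_snps = 20000,
                       n_causal_per_trait = 500, maf_range = c(0.05, 0.5),
                       trait_specs = default_sim_traits(),
                       success_weights = default_success_weights(),
                       success_rate = 0.5,
                       birth_year_range = c(1998L, 2023L), year_effect = 0,
                       missing_rate = 0.02, residual_trait_cor = 0,
                       seed = 1L) {
  # YAML configs arrive as lists; coerce the vector-valued fields
  maf_range <- unlist(maf_range)
  success_weights <- unlist(success_weights)
  birth_year_range <- unlist(birth_year_range)
  if (n_founders < 2) stop("n_founders must be at least 2")
  if (n_trio_offspring > n_offspring) {
    stop("n_trio_offspring cannot exceed n_offspring")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  trait_specs <- lapply(trait_specs, function(s) {
    if (inherits(s, "sim_trait_spec")) s
    else sim_trait_spec(s$name, s$kind, s$heritability,
                        unlist(s$prevalence_or_thresholds))
  })
  trait_names <- vapply(trait_specs, function(s) s$name, character(1))
  names(trait_specs) <- trait_names
  unknown <- setdiff(names(success_weights), trait_names)
  if (length(unknown) > 0) {
    stop("success_weights name undefined trait(s): ",
         paste(unknown, collapse = ", "))
  }
  structure(list(
    n_founders = n_founders, n_offspring = n_offspring,
    n_trio_offspring = n_trio_offspring, n_snps = n_snps,
    n_causal_per_trait = n_causal_per_trait, maf_range = maf_range,
    trait_specs = trait_specs, success_weights = success_weights,
    success_rate = success_rate, birth_year_range = as.integer(birth_year_range),
    year_effect = year_effect, missing_rate = missing_rate,
    residual_trait_cor = residual_trait_cor, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Gene-drop genotypes and a pedigree
#'
#' Founder dosages are two Bernoulli(p) allele draws per SNP with p sampled
#' uniformly from `maf_range`. Each offspring receives, independently per SNP
#' (unlinked loci), one uniformly chosen allele from its sire and one from its
#' dam. Missing calls are masked completely at random at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `geno` (a [new_geno()] object, missing calls
#'   `NA`), `complete` (the unmasked dosage matrix, kept for trait
#'   simulation), and `pedigree` (tibble `id`, `sire`, `dam`, `is_founder`,
#'   `is_trio`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_founders; no <- config$n_offspring; m <- config$n_snps
  n <- nf + no
  ids <- sprintf("dog%04d", seq_len(n))
  founder_ids <- ids[seq_len(nf)]

  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dos <- matrix(0L, nrow = n, ncol = m, dimnames = list(ids, NULL))
  dos[seq_len(nf), ] <- matrix(
    stats::rbinom(nf * m, 2L, rep(p, each = nf)), nrow = nf)

  # alternate founder sexes so every offspring has a sire and a dam
  sex <- rep_len(c("M", "F"), nf)
  sires <- dams <- rep(NA_character_, n)
  if (no > 0) {
    sire_pool <- founder_ids[sex == "M"]
    dam_pool <- founder_ids[sex == "F"]
    sires[nf + seq_len(no)] <- sample(sire_pool, no, replace = TRUE)
    dams[nf + seq_len(no)] <- sample(dam_pool, no, replace = TRUE)
    for (i in seq_len(no)) {
      s <- dos[sires[nf + i], ]; d <- dos[dams[nf + i], ]
      dos[nf + i, ] <- stats::rbinom(m, 1L, s / 2) + stats::rbinom(m, 1L, d / 2)
    }
  }

  masked <- dos
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(masked)) < config$missing_rate
    masked[drop] <- NA_integer_
  }
  colnames(masked) <- colnames(dos) <- sprintf("snp%05d", seq_len(m))
  ped <- tibble::tibble(
    id = ids, sire = sires, dam = dams,
    is_founder = seq_len(n) <= nf,
    is_trio = seq_len(n) > nf & seq_len(n) <= nf + config$n_trio_offspring
  )
  geno <- new_geno(masked, samples = ped[, c("id", "sire", "dam")])
  list(geno = geno, complete = dos, pedigree = ped)
}

# Internal: simulate one trait on complete dosages.
# Returns liability, phenotype, true breeding values and the drawn effects.
simulate_trait_impl <- function(complete, spec, config, resid = NULL) {
  n <- nrow(complete); m <- ncol(complete)
  h2 <- spec$heritability
  if (h2 < 0 || h2 > 1) stop("heritability must lie in [0, 1]")
  if (is.null(resid)) resid <- stats::rnorm(n)
  if (h2 > 0) {
    idx <- sample.int(m, min(config$n_causal_per_trait, m))
    M <- complete[, idx, drop = FALSE]
    p <- colMeans(M) / 2
    het <- mean(2 * p * (1 - p))
    beta <- stats::rnorm(length(idx), 0, sqrt(h2 / (length(idx) * max(het, 1e-12))))
    g <- as.vector(scale(M, center = 2 * p, scale = FALSE) %*% beta)
    sg <- stats::sd(g)
    g <- if (sg > 0) (g - mean(g)) / sg * sqrt(h2) else rep(0, n)
  } else {
    g <- rep(0, n)
  }
  liab <- g + sqrt(1 - h2) * resid
  pheno <- switch(spec$kind,
    binary = as.integer(liab > stats::qnorm(1 - spec$prevalence_or_thresholds)),
    ordinal = {
      cf <- spec$prevalence_or_thresholds
      findInterval(liab, stats::qnorm(cf[-length(cf)]), left.open = TRUE)
    },
    continuous = liab
  )
  list(liability = liab, phenotype = pheno, true_bv = g)
}

#' Simulate one trait for an existing population
#'
#' Liability-threshold construction: `n_causal_per_trait` SNP effects are
#' drawn as Normal(0, h2 / (n_causal x mean 2p(1-p))), the genetic value is
#' standardized to variance exactly h2, and independent Normal(0, 1-h2)
#' environmental noise completes a unit-variance liability. Binary phenotypes
#' threshold the liability at the Normal (1-prevalence) quantile; ordinal
#' phenotypes cut at the Normal quantiles of the cumulative category
#' frequencies; continuous phenotypes are the liability itself.
#'
#' @param population Result of [simulate_genotypes()] (or a full
#'   [simulate_population()] result).
#' @param spec A [sim_trait_spec()].
#' @param config The [sim_config()] used to build the population.
#' @return A tibble with columns `id`, `liability`, `phenotype`, `true_bv`.
#' @export
simulate_trait <- function(population, spec, config) {
  res <- simulate_trait_impl(population$complete, spec, config)
  tibble::tibble(id = rownames(population$complete),
                 liability = res$liability,
                 phenotype = res$phenotype, true_bv = res$true_bv)
}

#' Simulate the binary success outcome
#'
#' Success liability is a weighted sum of trait liabilities plus independent
#' noise, dichotomized at `success_rate`. The liability-scale weights are the
#' target correlations inflated by the binormal point-biserial attenuation
#' factor sqrt(q(1-q))/phi(z_q), so the realized correlation of the binary
#' outcome with a continuous trait approaches the requested target.
#'
#' @param liabilities Individuals x traits matrix of trait liabilities.
#' @param success_weights Named vector of target trait-success correlations.
#' @param config A [sim_config()] (supplies `success_rate`).
#' @return A list: `success` (0/1 integer vector), `liability` (success
#'   liability), and `realized` (tibble of target vs realized correlations
#'   with each weighted trait's liability).
#' @export
simulate_success <- function(liabilities, success_weights, config) {
  unknown <- setdiff(names(success_weights), colnames(liabilities))
  if (length(unknown) > 0) {
    stop("unknown trait(s) in success_weights: ", paste(unknown, collapse = ", "))
  }
  q <- config$success_rate
  z <- stats::qnorm(1 - q)
  inflate <- sqrt(q * (1 - q)) / stats::dnorm(z)
  w <- success_weights * inflate
  ss <- sum(w^2)
  if (ss >= 0.99) w <- w * sqrt(0.99 / ss)
  L <- liabilities[, names(w), drop = FALSE]
  s <- as.vector(L %*% w) +
    stats::rnorm(nrow(L)) * sqrt(max(1 - sum(w^2), 0))
  success <- as.integer(s > z)
  realized <- tibble::tibble(
    trait = names(w),
    target_r = unname(success_weights),
    realized_r = vapply(names(w), function(tr) {
      suppressWarnings(stats::cor(success, L[, tr]))
    }, numeric(1))
  )
  list(success = success, liability = s, realized = realized)
}

#' Simulate a complete breeding population
#'
#' Runs [simulate_genotypes()], simulates every trait in
#' `config$trait_specs`, then the success outcome, and assembles the
#' phenotype table. Fully deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `sim_population` list: `geno` (masked genotypes), `complete`
#'   (unmasked dosage matrix), `pedigree`, `pheno` (tibble: `id`, `sire`,
#'   `dam`, `birth_year`, `is_trio`, `success`, one column per trait),
#'   `liabilities` and `true_bv` (individuals x traits matrices),
#'   `success_realized` (realized correlation report), and `config`.
#' @export
#' @examples
#' pop <- simulate_population(sim_config(
#'   n_founders = 30, n_offspring = 20, n_trio_offspring = 10,
#'   n_snps = 200, n_causal_per_trait = 50, seed = 7))
#' pop$pheno
simulate_population <- function(config = sim_config()) {
  base <- simulate_genotypes(config)
  n <- nrow(base$complete)
  birth_year <- sample(seq(config$birth_year_range[1],
                           config$birth_year_range[2]), n, replace = TRUE)
  year_dev <- birth_year - mean(config$birth_year_range)

  specs <- config$trait_specs
  k <- length(specs)
  liabs <- true_bv <- matrix(NA_real_, n, k,
                             dimnames = list(rownames(base$complete),
                                             names(specs)))
  pheno_cols <- vector("list", k); names(pheno_cols) <- names(specs)
  shared <- stats::rnorm(n)
  rho <- config$residual_trait_cor
  for (tr in names(specs)) {
    resid <- if (rho > 0) {
      sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n)
    } else stats::rnorm(n)
    res <- simulate_trait_impl(base$complete, specs[[tr]], config, resid = resid)
    res$liability <- res$liability + config$year_effect * year_dev
    liabs[, tr] <- res$liability
    true_bv[, tr] <- res$true_bv
    pheno_cols[[tr]] <- res$phenotype
  }
  succ <- simulate_success(liabs, config$success_weights, config)

  pheno <- tibble::tibble(
    id = base$pedigree$id, sire = base$pedigree$sire,
    dam = base$pedigree$dam, birth_year = birth_year,
    is_trio = base$pedigree$is_trio, success = succ$success
  )
  for (tr in names(pheno_cols)) pheno[[tr]] <- pheno_cols[[tr]]

  structure(list(
    geno = base$geno, complete = base$complete, pedigree = base$pedigree,
    pheno = pheno, liabilities = liabs, true_bv = true_bv,
    success_liability = succ$liability, success_realized = succ$realized,
    config = config
  ), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "<sim_population> %d individuals (%d founders, %d trio offspring), %d SNPs, %d traits\n",
    nrow(x$pheno), x$config$n_founders, x$config$n_trio_offspring,
    x$config$n_snps, length(x$config$trait_specs)))
  invisible(x)
}
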