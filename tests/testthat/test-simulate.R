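test_that("same seed reproduces the population bit-for-bit", {
  a <- small_pop(seed = 42)
  b <- small_pop(seed = 42)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$true_bv, b$true_bv)
  c <- small_pop(seed = 43)
  expect_false(identical(a$geno$dosage, c$geno$dosage))
})

test_that("founder genotypes follow Hardy-Weinberg at the drawn frequency", {
  cfg <- sim_config(n_founders = 4000, n_offspring = 0, n_trio_offspring = 0,
                    n_snps = 5, maf_range = c(0.5, 0.5),
                    trait_specs = list(sim_trait_spec("t", "continuous", 0.3)),
                    success_weights = c(t = 0.3), missing_rate = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  freqs <- table(factor(g$complete[, 1], levels = 0:2)) / 4000
  # HW at p = 0.5: 0.25 / 0.5 / 0.25, binomial se ~ 0.008
  expect_lt(max(abs(freqs - c(0.25, 0.5, 0.25))), 0.03)
})

test_that("founder allele frequencies stay inside maf_range", {
  cfg <- sim_config(n_founders = 500, n_offspring = 0, n_trio_offspring = 0,
                    n_snps = 200, maf_range = c(0.2, 0.3),
                    trait_specs = list(sim_trait_spec("t", "continuous", 0.3)),
                    success_weights = c(t = 0.3), missing_rate = 0, seed = 6)
  g <- simulate_genotypes(cfg)
  p_hat <- colMeans(g$complete[1:500, ]) / 2
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_true(all(p_hat > 0.2 - 3 * se))
  expect_true(all(p_hat < 0.3 + 3 * se))
})

test_that("gene dropping transmits parental alleles correctly", {
  pop <- small_pop(seed = 9, n_founders = 40, n_offspring = 200,
                   n_snps = 300, missing_rate = 0)
  d <- pop$complete
  ped <- pop$pedigree
  off <- ped$id[!ped$is_founder]
  s <- d[ped$sire[match(off, ped$id)], , drop = FALSE]
  m <- d[ped$dam[match(off, ped$id)], , drop = FALSE]
  o <- d[off, , drop = FALSE]
  # forced transmission: homozygous x homozygous parents
  expect_true(all(o[s == 2 & m == 2] == 2))
  expect_true(all(o[s == 0 & m == 0] == 0))
  expect_true(all(o[s == 2 & m == 0] == 1))
  # het x het: enumerating the four equiprobable gametic combinations
  # gives offspring dosage probabilities 0.25 / 0.5 / 0.25
  hh <- o[s == 1 & m == 1]
  expect_gt(length(hh), 2000)
  freqs <- table(factor(hh, levels = 0:2)) / length(hh)
  expect_lt(max(abs(freqs - c(0.25, 0.5, 0.25))), 3 * sqrt(0.5 * 0.5 / length(hh)))
})

test_that("missingness is applied at the configured rate", {
  pop <- small_pop(seed = 3, n_founders = 100, n_offspring = 0,
                   n_snps = 1000, missing_rate = 0.1)
  expect_lt(abs(mean(is.na(pop$geno$dosage)) - 0.1), 0.01)
  expect_false(anyNA(pop$complete))
})

test_that("trio offspring exceeding offspring count is rejected", {
  expect_error(sim_config(n_offspring = 10, n_trio_offspring = 20),
               "n_trio_offspring")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(
    sim_config(trait_specs = list(sim_trait_spec("a", "continuous", 0.5)),
               success_weights = c(b = 0.5)),
    "undefined trait")
})

test_that("zero-heritability traits carry no genetic signal", {
  pop <- small_pop(seed = 21, n_founders = 200, n_offspring = 0,
                   n_snps = 400, h2 = 0)
  expect_true(all(pop$true_bv == 0))
  expect_error(sim_trait_spec("bad", "binary", 1.2, 0.1), "heritability")
})

test_that("liability decomposition has the specified genetic variance", {
  pop <- small_pop(seed = 22, n_founders = 500, n_offspring = 500,
                   n_snps = 800, h2 = 0.5, missing_rate = 0)
  # genetic values are standardized to variance h2 exactly
  expect_equal(stats::var(pop$true_bv[, "merit"]), 0.5, tolerance = 1e-8)
  expect_lt(abs(stats::var(pop$liabilities[, "merit"]) - 1), 0.15)
})

test_that("binary prevalence and ordinal category frequencies are realized", {
  cfg <- sim_config(
    n_founders = 2500, n_offspring = 2500, n_trio_offspring = 0,
    n_snps = 400, n_causal_per_trait = 100,
    trait_specs = list(
      sim_trait_spec("dx", "binary", 0.3, 0.10),
      sim_trait_spec("pace", "ordinal", 0.3, c(0.052, 0.705, 1))),
    success_weights = c(dx = -0.1), missing_rate = 0, seed = 30)
  pop <- simulate_population(cfg)
  n <- nrow(pop$pheno)
  expect_lt(abs(mean(pop$pheno$dx) - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  freq <- cumsum(table(factor(pop$pheno$pace, levels = 0:2))) / n
  target <- c(0.052, 0.705, 1)
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(freq - target) <= pmax(3 * se, 1e-12)))
})

test_that("success is independent of traits when all weights are zero", {
  cfg <- sim_config(
    n_founders = 2000, n_offspring = 0, n_trio_offspring = 0,
    n_snps = 300, n_causal_per_trait = 100,
    trait_specs = list(sim_trait_spec("merit", "continuous", 0.4)),
    success_weights = c(merit = 0), missing_rate = 0, seed = 31)
  pop <- simulate_population(cfg)
  expect_lt(abs(cor(pop$pheno$success, pop$pheno$merit)), 0.05)
})

test_that("a single weighted trait realizes its target point-biserial correlation", {
  cfg <- sim_config(
    n_founders = 2500, n_offspring = 2500, n_trio_offspring = 0,
    n_snps = 400, n_causal_per_trait = 100,
    trait_specs = list(sim_trait_spec("trainability", "continuous", 0.3)),
    success_weights = c(trainability = 0.53), missing_rate = 0, seed = 32)
  pop <- simulate_population(cfg)
  r <- cor(pop$pheno$success, pop$pheno$trainability)
  expect_lt(abs(r - 0.53), 0.05)
})

test_that("realized success correlations carry the target signs", {
  # liability-level check at large n so even |r| ~ 0.05 targets are resolved
  set.seed(33)
  weights <- default_success_weights()
  weights <- weights[abs(weights) >= 0.05]
  L <- matrix(rnorm(30000 * length(weights)), 30000,
              dimnames = list(NULL, names(weights)))
  cfg <- sim_config(seed = 33)
  out <- simulate_success(L, weights, cfg)
  expect_true(all(sign(out$realized$realized_r) == sign(out$realized$target_r)))
  expect_error(simulate_success(L, c(nonexistent = 0.3), cfg), "unknown trait")
})
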