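test_that("pure-noise phenotypes estimate near-zero heritability", {
  pop <- small_pop(seed = 41, n_founders = 300, n_offspring = 200,
                   n_snps = 8000, missing_rate = 0)
  grm <- grm_eigen(compute_grm(pop$geno))
  X <- matrix(1, 500, 1, dimnames = list(NULL, "intercept"))
  set.seed(1)
  # the null estimate piles on the h2 = 0 boundary; average a few draws
  draws <- replicate(10, reml_fit(rnorm(500), X, grm)$pseudo_h2)
  expect_lt(mean(draws), 0.05)
  expect_true(all(draws >= 0))
  expect_gt(mean(draws == 0), 0.2)
})

test_that("the optimum dominates a grid of heritability values", {
  pop <- small_pop(seed = 42, n_founders = 100, n_offspring = 100,
                   n_snps = 1000, h2 = 0.5, missing_rate = 0)
  grm <- compute_grm(pop$geno)
  y <- pop$pheno$merit
  X <- build_design(pop$pheno, "birth_year")
  vc <- reml_fit(y, X, grm)
  # recompute the restricted likelihood by the direct dense formula
  direct_ll <- function(h2) {
    n <- length(y); p <- ncol(X)
    V <- h2 * grm$matrix + (1 - h2) * diag(n)
    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
    as.numeric(-0.5 * ((n - p) * log(2 * pi * s2) + (n - p) +
                         determinant(V)$modulus +
                         determinant(t(X) %*% Vi %*% X)$modulus -
                         determinant(crossprod(X))$modulus))
  }
  for (h2 in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
    expect_gte(vc$log_reml, direct_ll(h2) - 1e-4)
  }
  # and the eigen-rotated likelihood agrees with the dense-algebra form
  expect_equal(vc$log_reml, direct_ll(vc$pseudo_h2), tolerance = 1e-5)
})

test_that("REML recovers a moderate simulated heritability", {
  pop <- small_pop(seed = 43, n_founders = 400, n_offspring = 400,
                   n_snps = 5000, h2 = 0.5, missing_rate = 0)
  grm <- compute_grm(pop$geno)
  X <- matrix(1, 800, 1, dimnames = list(NULL, "intercept"))
  vc <- reml_fit(pop$pheno$merit, X, grm)
  expect_gt(vc$pseudo_h2, 0.3)
  expect_lt(vc$pseudo_h2, 0.7)
})

test_that("REML is shift-invariant and scale-equivariant", {
  pop <- small_pop(seed = 44, n_founders = 80, n_offspring = 40,
                   n_snps = 800, h2 = 0.4, missing_rate = 0)
  grm <- compute_grm(pop$geno)
  y <- pop$pheno$merit
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  base <- reml_fit(y, X, grm)
  shifted <- reml_fit(y + 100, X, grm)
  expect_equal(shifted$pseudo_h2, base$pseudo_h2, tolerance = 1e-5)
  expect_equal(shifted$sigma2_g, base$sigma2_g, tolerance = 1e-5)
  scaled <- reml_fit(3 * y, X, grm)
  expect_equal(scaled$pseudo_h2, base$pseudo_h2, tolerance = 1e-5)
  expect_equal(scaled$sigma2_g, 9 * base$sigma2_g, tolerance = 1e-3)
})

test_that("singular designs are rejected naming the collinear column", {
  pop <- small_pop(seed = 45, n_founders = 30, n_offspring = 0, n_snps = 300,
                   missing_rate = 0)
  grm <- compute_grm(pop$geno)
  X <- cbind(intercept = 1, a = 1:30, dup = 1:30)
  expect_error(reml_fit(rnorm(30), X, grm), "dup")
})

test_that("zero genetic variance gives zero breeding values and OLS betas", {
  pop <- small_pop(seed = 46, n_founders = 40, n_offspring = 0, n_snps = 400,
                   missing_rate = 0)
  grm <- compute_grm(pop$geno)
  set.seed(2)
  y <- rnorm(40)
  x <- rnorm(40)
  X <- cbind(intercept = 1, x = x)
  vc <- structure(list(sigma2_g = 0, sigma2_e = 1, pseudo_h2 = 0,
                       log_reml = NA_real_, boundary = TRUE),
                  class = "variance_components")
  fit <- solve_blup(y, X, grm, vc)
  expect_true(all(abs(fit$gebv) < 1e-10))
  ols <- coef(lm(y ~ x))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-8)
})

test_that("BLUP solutions match the direct matrix-formula oracle", {
  G <- matrix(c(1.0, 0.5, 0.2,
                0.5, 1.1, 0.3,
                0.2, 0.3, 0.9), 3, dimnames = list(letters[1:3], letters[1:3]))
  grm <- structure(list(matrix = G, ids = letters[1:3], n_snps_used = 10L,
                        method = "vanraden1", eigen = NULL), class = "grm")
  y <- c(1.2, -0.4, 0.7)
  X <- matrix(1, 3, 1, dimnames = list(NULL, "intercept"))
  vc <- structure(list(sigma2_g = 0.6, sigma2_e = 0.4, pseudo_h2 = 0.6,
                       log_reml = NA_real_, boundary = FALSE),
                  class = "variance_components")
  fit <- solve_blup(y, X, grm, vc)
  V <- 0.6 * G + 0.4 * diag(3)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- 0.6 * G %*% Vi %*% (y - X %*% beta)
  expect_equal(unname(fit$beta), as.vector(beta), tolerance = 1e-8)
  expect_equal(unname(fit$gebv), as.vector(u), tolerance = 1e-8)
  expect_equal(unname(fit$fitted), as.vector(X %*% beta + u), tolerance = 1e-8)
})

test_that("prediction accuracy increases with heritability", {
  cors <- sapply(c(0.1, 0.5), function(h2) {
    r <- sapply(1:4, function(rep) {
      pop <- small_pop(seed = 100 + rep, n_founders = 150, n_offspring = 150,
                       n_snps = 2000, h2 = h2, missing_rate = 0)
      grm <- compute_grm(pop$geno)
      X <- matrix(1, 300, 1, dimnames = list(NULL, "intercept"))
      vc <- reml_fit(pop$pheno$merit, X, grm)
      fit <- solve_blup(pop$pheno$merit, X, grm, vc)
      suppressWarnings(cor(fit$gebv, pop$true_bv[, "merit"]))
    })
    r[is.na(r)] <- 0  # boundary fits (u = 0) carry zero accuracy
    mean(r)
  })
  expect_gt(cors[2], cors[1])
})

test_that("holdout prediction matches the conditional-normal oracle", {
  pop <- small_pop(seed = 47, n_founders = 20, n_offspring = 0, n_snps = 500,
                   missing_rate = 0)
  grm <- compute_grm(pop$geno)
  set.seed(3)
  y <- rnorm(20) + 0.5
  X <- matrix(1, 20, 1, dimnames = list(NULL, "intercept"))
  train <- 1:15; test <- 16:20
  grm_tr <- structure(list(matrix = grm$matrix[train, train],
                           ids = grm$ids[train], n_snps_used = grm$n_snps_used,
                           method = grm$method, eigen = NULL), class = "grm")
  vc <- reml_fit(y[train], X[train, , drop = FALSE], grm_tr)
  fit <- solve_blup(y[train], X[train, , drop = FALSE], grm_tr, vc)
  pred <- predict_holdout(fit, grm, grm$ids[test], X[test, , drop = FALSE])
  # oracle: conditional expectation under the joint MVN, dense algebra
  V_tt <- vc$sigma2_g * grm$matrix[train, train] +
    vc$sigma2_e * diag(length(train))
  u_oracle <- vc$sigma2_g * grm$matrix[test, train] %*%
    solve(V_tt, y[train] - X[train, , drop = FALSE] %*% fit$beta)
  expect_equal(pred$gebv, as.vector(u_oracle), tolerance = 1e-5)
  expect_equal(pred$predicted, as.vector(u_oracle) + fit$beta[1],
               tolerance = 1e-5)
})

test_that("holdout prediction handles duplicates and null training signal", {
  pop <- small_pop(seed = 48, n_founders = 12, n_offspring = 0, n_snps = 400,
                   missing_rate = 0)
  d <- pop$geno$dosage
  d <- rbind(d, dup = d[1, ])
  rownames(d)[13] <- "dup"
  grm <- compute_grm(new_geno(d))
  set.seed(4)
  y <- rnorm(12)
  X <- matrix(1, 12, 1, dimnames = list(NULL, "intercept"))
  grm_tr <- structure(list(matrix = grm$matrix[1:12, 1:12],
                           ids = grm$ids[1:12], n_snps_used = grm$n_snps_used,
                           method = grm$method, eigen = NULL), class = "grm")
  vc <- reml_fit(y, X, grm_tr)
  fit <- solve_blup(y, X, grm_tr, vc)
  pred <- predict_holdout(fit, grm, "dup", X[1, , drop = FALSE])
  # genomically identical to training individual 1 -> same breeding value
  expect_equal(pred$gebv, unname(fit$gebv[1]), tolerance = 1e-6)

  vc0 <- structure(list(sigma2_g = 0, sigma2_e = 1, pseudo_h2 = 0,
                        log_reml = NA_real_, boundary = TRUE),
                   class = "variance_components")
  fit0 <- solve_blup(y, X, grm_tr, vc0)
  pred0 <- predict_holdout(fit0, grm, "dup", X[1, , drop = FALSE])
  expect_equal(pred0$gebv, 0, tolerance = 1e-10)
  expect_error(predict_holdout(fit, grm, "nosuch", X[1, , drop = FALSE]),
               "unknown id")
  expect_error(predict_holdout(fit, grm, grm$ids[1], X[1, , drop = FALSE]),
               "disjoint")
})

test_that("identity GRM keeps estimates inside the parameter space", {
  n <- 50
  grm <- structure(list(matrix = diag(n), ids = as.character(1:n),
                        n_snps_used = 1L, method = "vanraden1", eigen = NULL),
                   class = "grm")
  set.seed(5)
  y <- rnorm(n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  vc <- reml_fit(y, X, grm)
  expect_gte(vc$pseudo_h2, 0)
  expect_lte(vc$pseudo_h2, 1)
  fit <- solve_blup(y, X, grm, vc)
  # with G = I breeding values shrink the centered phenotype
  expect_true(all(abs(fit$gebv) <= abs(y - mean(y)) + 1e-8))
})

test_that("the tidy interface exposes terms, summary and per-dog values", {
  pop <- small_pop(seed = 49, n_founders = 40, n_offspring = 20, n_snps = 400,
                   missing_rate = 0)
  grm <- compute_grm(pop$geno)
  pcs <- compute_pcs(grm, 3)
  fit <- gblup(pop$pheno, grm, "merit",
               fixed_effects = c("birth_year", "pc1", "pc2", "pc3"),
               pcs = pcs)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_identical(td$term[1], "intercept")
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$pseudo_h2 >= 0 && gl$pseudo_h2 <= 1)
  au <- augment(fit)
  expect_identical(au$id, pop$pheno$id)
  expect_equal(au$fitted, unname(fit$fitted))
})
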