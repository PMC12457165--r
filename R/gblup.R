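#' Build a fixed-effect design matrix
#'
#' Assembles the design for the mixed model from a phenotype/covariate table.
#' `"intercept"` is always included. `"birth_year"` is coded as categorical
#' indicators with the first level dropped; every other name must be a
#' numeric column of `data` (principal components `pc1..pck`, index scores,
#' condition counts, parental scores, ...).
#'
#' @param data Data frame with one row per individual.
#' @param fixed_effects Character vector of effect names (besides the
#'   intercept).
#' @return A numeric design matrix with `nrow(data)` rows.
#' @export
build_design <- function(data, fixed_effects = character()) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  for (fe in setdiff(fixed_effects, "intercept")) {
    if (fe == "birth_year") {
      f <- factor(data$birth_year)
      if (nlevels(f) > 1) {
        B <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(B) <- paste0("birth_year", levels(f)[-1])
        X <- cbind(X, B)
      }
    } else {
      if (!fe %in% names(data)) stop("unknown fixed effect: ", fe)
      v <- data[[fe]]
      if (!is.numeric(v)) stop("fixed effect '", fe, "' must be numeric")
      X <- cbind(X, stats::setNames(data.frame(v), fe)[[1]])
      colnames(X)[ncol(X)] <- fe
    }
  }
  X
}

# Indices of a maximal linearly independent column subset (intercept kept).
independent_columns <- function(X, tol = 1e-8) {
  qr_x <- qr(X, tol = tol)
  sort(qr_x$pivot[seq_len(qr_x$rank)])
}

#' REML estimation of variance components under a GRM
#'
#' Fits y ~ N(X beta, sigma2_g G + sigma2_e I) by restricted maximum
#' likelihood. The GRM is eigendecomposed once; the restricted log-likelihood
#' is then profiled on the heritability ratio h2 = sigma2_g / (sigma2_g +
#' sigma2_e) and maximized over \[0, 1\] by Brent's method (tolerance 1e-8).
#' Boundary solutions are permitted and flagged. If the GRM has negative
#' eigenvalues a ridge of 1e-6 x mean diagonal is added.
#'
#' Binary and ordinal responses are fitted on their observed 0/1/k numeric
#' scale (linear mixed model, no threshold link), matching the analysis style
#' whose continuous breeding values are later thresholded for classification.
#'
#' @param y Numeric phenotype vector.
#' @param X Fixed-effect design matrix (see [build_design()]); must be full
#'   column rank.
#' @param grm A [compute_grm()] result covering the same individuals, in the
#'   same order.
#' @param h2_tol Optimization tolerance on h2 (default 1e-8).
#' @return A `variance_components` list: `sigma2_g`, `sigma2_e`, `pseudo_h2`,
#'   `log_reml`, `boundary` (logical).
#' @export
reml_fit <- function(y, X, grm, h2_tol = 1e-8) {
  stopifnot(inherits(grm, "grm"))
  y <- as.numeric(y)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, length(grm$ids) == n)
  if (n < p + 2) stop("need at least ncol(X) + 2 observations")
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  grm <- grm_eigen(grm)
  ev <- grm$eigen$values
  if (min(ev) < 0) ev <- pmax(ev + 1e-6 * mean(diag(grm$matrix)), 0)
  U <- grm$eigen$vectors
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)
  ld_xtx <- determinant(crossprod(X), logarithm = TRUE)$modulus

  restricted_ll <- function(h2) {
    w <- h2 * ev + (1 - h2)
    if (any(w <= 0)) return(-Inf)
    Xw <- Xr / w
    A <- crossprod(Xr, Xw)
    b <- crossprod(Xw, yr)
    beta <- solve(A, b)
    rss <- sum((yr - Xr %*% beta)^2 / w)
    sigma2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * sigma2) + (n - p) + sum(log(w)) +
              determinant(A, logarithm = TRUE)$modulus - ld_xtx)
  }

  opt <- stats::optimize(restricted_ll, interval = c(0, 1),
                         maximum = TRUE, tol = h2_tol)
  cand <- c(opt$maximum, 0, 1 - 1e-9)
  lls <- vapply(cand, restricted_ll, numeric(1))
  h2 <- cand[which.max(lls)]
  ll <- max(lls)
  boundary <- h2 < 1e-6 || h2 > 1 - 1e-6
  if (h2 < 1e-6) h2 <- 0

  w <- h2 * ev + (1 - h2)
  Xw <- Xr / w
  A <- crossprod(Xr, Xw)
  beta <- solve(A, crossprod(Xw, yr))
  sigma2 <- sum((yr - Xr %*% beta)^2 / w) / (n - p)
  structure(list(sigma2_g = h2 * sigma2, sigma2_e = (1 - h2) * sigma2,
                 pseudo_h2 = h2, log_reml = ll, boundary = boundary),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> sigma2_g=%.4f sigma2_e=%.4f pseudo_h2=%.4f%s\n",
    x$sigma2_g, x$sigma2_e, x$pseudo_h2,
    if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' GBLUP solutions for fixed effects and breeding values
#'
#' Generalized least squares for the fixed effects under V = sigma2_g G +
#' sigma2_e I, and genomic breeding values u = sigma2_g G V^-1 (y - X beta).
#'
#' @inheritParams reml_fit
#' @param vc A `variance_components` from [reml_fit()].
#' @return A `gblup_fit`: `vc`, `beta` (named vector), `gebv`, `fitted`
#'   (= X beta + gebv), `ids`, `X`, `grm`.
#' @export
solve_blup <- function(y, X, grm, vc) {
  stopifnot(inherits(grm, "grm"), inherits(vc, "variance_components"))
  y <- as.numeric(y)
  n <- length(y)
  grm <- grm_eigen(grm)
  ev <- grm$eigen$values
  if (min(ev) < 0) ev <- pmax(ev + 1e-6 * mean(diag(grm$matrix)), 0)
  U <- grm$eigen$vectors
  d <- vc$sigma2_g * ev + vc$sigma2_e
  if (min(d) <= 1e-12 * max(d)) {
    warning("V numerically singular; adding ridge")
    d <- d + 1e-8 * max(d)
  }
  yr <- crossprod(U, y); Xr <- crossprod(U, X)
  Xw <- Xr / d
  beta <- solve(crossprod(Xr, Xw), crossprod(Xw, yr))[, 1]
  names(beta) <- colnames(X)
  r <- yr - Xr %*% beta
  u <- as.vector(U %*% (vc$sigma2_g * ev / d * r))
  fitted <- as.vector(X %*% beta) + u
  structure(list(vc = vc, beta = beta, gebv = stats::setNames(u, grm$ids),
                 fitted = stats::setNames(fitted, grm$ids),
                 ids = grm$ids, X = X, grm = grm),
            class = "gblup_fit")
}

#' Fit a GBLUP model from a phenotype table
#'
#' Data-frame-first wrapper: aligns the phenotype table to the GRM ids,
#' joins principal-component covariates if supplied, builds the design
#' (dropping collinear columns with a message), runs [reml_fit()] then
#' [solve_blup()].
#'
#' @param pheno Tibble with an `id` column and the response/covariate
#'   columns.
#' @param grm A [compute_grm()] result; every `pheno$id` must be present.
#' @param response Name of the response column.
#' @param fixed_effects Character vector of fixed-effect names (see
#'   [build_design()]); default birth year plus the first three principal
#'   components.
#' @param pcs Optional tibble from [compute_pcs()] to join by `id`.
#' @return A `gblup_fit` (see [solve_blup()]), with the response name in
#'   `$response`.
#' @export
gblup <- function(pheno, grm, response,
                  fixed_effects = c("birth_year", "pc1", "pc2", "pc3"),
                  pcs = NULL) {
  stopifnot(inherits(grm, "grm"), "id" %in% names(pheno))
  if (!is.null(pcs)) pheno <- dplyr::left_join(pheno, pcs, by = "id")
  idx <- match(pheno$id, grm$ids)
  if (anyNA(idx)) stop("phenotyped individuals missing from GRM")
  if (length(idx) != length(grm$ids) || any(idx != seq_along(idx))) {
    sub <- grm$matrix[idx, idx, drop = FALSE]
    grm <- structure(list(matrix = sub, ids = pheno$id,
                          n_snps_used = grm$n_snps_used,
                          method = grm$method, eigen = NULL), class = "grm")
  }
  y <- pheno[[response]]
  X <- build_design(pheno, fixed_effects)
  keep <- independent_columns(X)
  if (length(keep) < ncol(X)) {
    message("dropping collinear design column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  grm <- grm_eigen(grm)
  vc <- reml_fit(y, X, grm)
  fit <- solve_blup(y, X, grm, vc)
  fit$response <- response
  fit$fixed_effects <- fixed_effects
  fit
}

#' Predict held-out individuals from a trained GBLUP fit
#'
#' Conditional-expectation prediction: u_test = G_test,train
#' G_train,train^-1 u_train (ridge-stabilized solve), and predicted
#' phenotype = X_test beta + u_test.
#'
#' @param fit_train A `gblup_fit` on the training individuals.
#' @param grm_full A GRM covering both training and test individuals.
#' @param test_ids Ids to predict; must be in `grm_full` and disjoint from
#'   the training ids.
#' @param X_test Fixed-effect design rows for the test individuals, with the
#'   same columns as the training design.
#' @return A tibble: `id`, `gebv`, `predicted`.
#' @export
predict_holdout <- function(fit_train, grm_full, test_ids, X_test) {
  stopifnot(inherits(fit_train, "gblup_fit"), inherits(grm_full, "grm"))
  tr <- match(fit_train$ids, grm_full$ids)
  te <- match(test_ids, grm_full$ids)
  if (anyNA(tr) || anyNA(te)) stop("unknown id(s) in GRM")
  if (length(intersect(fit_train$ids, test_ids)) > 0) {
    stop("test ids must be disjoint from training ids")
  }
  G_tt <- grm_full$matrix[tr, tr, drop = FALSE]
  G_st <- grm_full$matrix[te, tr, drop = FALSE]
  ridge <- 1e-8 * mean(diag(G_tt))
  u_train <- fit_train$gebv
  u_test <- as.vector(G_st %*% solve(G_tt + diag(ridge, nrow(G_tt)), u_train))
  X_test <- X_test[, names(fit_train$beta), drop = FALSE]
  pred <- as.vector(X_test %*% fit_train$beta) + u_test
  tibble::tibble(id = test_ids, gebv = u_test, predicted = pred)
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit>%s n=%d, pseudo_h2=%.3f, %d fixed-effect columns\n",
              if (!is.null(x$response)) paste0(" ", x$response) else "",
              length(x$ids), x$vc$pseudo_h2, length(x$beta)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy the fixed-effect solutions of a GBLUP fit
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`.
#' @method tidy gblup_fit
#' @export
tidy.gblup_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' One-row model summary of a GBLUP fit
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return A tibble: `nobs`, `sigma2_g`, `sigma2_e`, `pseudo_h2`,
#'   `log_reml`, `boundary`.
#' @method glance gblup_fit
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(nobs = length(x$ids), sigma2_g = x$vc$sigma2_g,
                 sigma2_e = x$vc$sigma2_e, pseudo_h2 = x$vc$pseudo_h2,
                 log_reml = x$vc$log_reml, boundary = x$vc$boundary)
}

#' Per-individual breeding values and fitted phenotypes
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return A tibble: `id`, `gebv`, `fitted`.
#' @method augment gblup_fit
#' @export
augment.gblup_fit <- function(x, ...) {
  tibble::tibble(id = x$ids, gebv = unname(x$gebv),
                 fitted = unname(x$fitted))
}
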