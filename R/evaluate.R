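#' Cross-validated GBLUP evaluation of one trait
#'
#' Five-fold (by default) cross-validation: for each fold the model is fit
#' by REML/GBLUP on the other folds, held-out individuals are predicted by
#' conditional expectation, and the metrics matching the trait's type are
#' computed per fold and pooled over all out-of-fold predictions (every
#' individual is predicted exactly once). Pseudo-heritability comes from a
#' full-data fit. Binary traits report MCC and AUROC; ordinal traits report
#' Kendall's tau-b and Spearman's rho; continuous traits report Pearson's R
#' and NMSE.
#'
#' @param pheno Tibble with `id`, the trait column, `birth_year` and any
#'   fixed-effect columns.
#' @param grm A [compute_grm()] result containing every `pheno$id`.
#' @param trait Name of the trait column to evaluate.
#' @param kind `"binary"`, `"ordinal"` or `"continuous"`.
#' @param fixed_effects Base fixed effects (default birth year + first three
#'   principal components).
#' @param extra_fixed Additional fixed-effect column names appended to the
#'   design (e.g. `"behavior_score"`, `"parent_total_score"`). These are
#'   observed phenotypic scores, available for test individuals.
#' @param pcs Optional tibble from [compute_pcs()], joined by `id`.
#' @param folds Optional [make_folds()] plan; built from `k` and `seed`
#'   otherwise.
#' @param k,seed Fold count and seed used when `folds` is `NULL`.
#' @param classify_threshold Binary classification threshold (default 0.5).
#' @return A `trait_report`: `trait`, `kind`, `pseudo_h2`, `pooled` (one-row
#'   metric tibble), `per_fold` (k-row metric tibble), `predictions`
#'   (tibble `id`, `fold`, `observed`, `gebv`, `predicted`, `classified`).
#' @export
evaluate_trait <- function(pheno, grm, trait,
                           kind = c("binary", "ordinal", "continuous"),
                           fixed_effects = c("birth_year", "pc1", "pc2", "pc3"),
                           extra_fixed = character(), pcs = NULL,
                           folds = NULL, k = 5, seed = 1,
                           classify_threshold = 0.5) {
  kind <- match.arg(kind)
  stopifnot(inherits(grm, "grm"), "id" %in% names(pheno),
            trait %in% names(pheno))
  if (!is.null(pcs)) pheno <- dplyr::left_join(pheno, pcs, by = "id")
  idx <- match(pheno$id, grm$ids)
  if (anyNA(idx)) stop("phenotyped individuals missing from GRM")
  grm_sub <- if (length(idx) != length(grm$ids) || any(idx != seq_along(idx))) {
    structure(list(matrix = grm$matrix[idx, idx, drop = FALSE],
                   ids = pheno$id, n_snps_used = grm$n_snps_used,
                   method = grm$method, eigen = NULL), class = "grm")
  } else grm
  y <- as.numeric(pheno[[trait]])
  X <- build_design(pheno, c(fixed_effects, extra_fixed))
  if (is.null(folds)) folds <- make_folds(pheno$id, k = k, seed = seed)
  fold_of <- folds$fold[match(pheno$id, folds$id)]
  if (anyNA(fold_of)) stop("fold plan does not cover all individuals")

  keep_full <- independent_columns(X)
  vc_full <- reml_fit(y, X[, keep_full, drop = FALSE], grm_sub)

  preds <- vector("list", max(fold_of))
  for (f in sort(unique(fold_of))) {
    tr_i <- which(fold_of != f)
    te_i <- which(fold_of == f)
    grm_tr <- structure(list(
      matrix = grm_sub$matrix[tr_i, tr_i, drop = FALSE],
      ids = pheno$id[tr_i], n_snps_used = grm_sub$n_snps_used,
      method = grm_sub$method, eigen = NULL), class = "grm")
    grm_tr <- grm_eigen(grm_tr)  # shared by the REML and BLUP steps
    X_tr <- X[tr_i, , drop = FALSE]
    keep <- independent_columns(X_tr)
    fit <- solve_blup(y[tr_i], X_tr[, keep, drop = FALSE], grm_tr,
                      reml_fit(y[tr_i], X_tr[, keep, drop = FALSE], grm_tr))
    out <- predict_holdout(fit, grm_sub, pheno$id[te_i],
                           X[te_i, keep, drop = FALSE])
    out$fold <- f
    out$observed <- y[te_i]
    preds[[f]] <- out
  }
  preds <- dplyr::bind_rows(preds)
  preds$classified <- if (kind %in% c("binary", "ordinal")) {
    classify_prediction(preds$predicted, if (kind == "binary") "binary" else "ordinal",
                        min_class = min(y), max_class = max(y),
                        threshold = classify_threshold)
  } else NA_integer_

  metric_row <- function(d) {
    switch(kind,
      binary = {
        cc <- confusion_counts(d$classified, d$observed)
        tibble::tibble(mcc = mcc(cc$tp, cc$fp, cc$tn, cc$fn),
                       auroc = auroc(d$predicted, d$observed))
      },
      ordinal = tibble::tibble(kendall_tau = kendall_tau(d$predicted, d$observed),
                               spearman_rho = spearman_rho(d$predicted, d$observed)),
      continuous = tibble::tibble(pearson_r = pearson_r(d$predicted, d$observed),
                                  nmse = nmse(d$predicted, d$observed))
    )
  }
  per_fold <- dplyr::bind_rows(lapply(sort(unique(preds$fold)), function(f) {
    dplyr::bind_cols(tibble::tibble(fold = f),
                     metric_row(preds[preds$fold == f, ]))
  }))
  pooled <- metric_row(preds)

  structure(list(trait = trait, kind = kind,
                 pseudo_h2 = vc_full$pseudo_h2, vc = vc_full,
                 pooled = pooled, per_fold = per_fold,
                 predictions = preds[, c("id", "fold", "observed",
                                         "gebv", "predicted", "classified")],
                 folds = folds),
            class = "trait_report")
}

#' @export
print.trait_report <- function(x, ...) {
  cat(sprintf("<trait_report> %s (%s), pseudo_h2=%.3f\n",
              x$trait, x$kind, x$pseudo_h2))
  print(x$pooled)
  invisible(x)
}

#' Tidy the per-fold metrics of a trait report
#'
#' @param x A `trait_report`.
#' @param ... Unused.
#' @return A long tibble: `trait`, `fold`, `metric`, `value`.
#' @method tidy trait_report
#' @export
tidy.trait_report <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::mutate(x$per_fold, trait = x$trait, .before = 1),
    cols = -c("trait", "fold"), names_to = "metric", values_to = "value")
}

#' One-row summary of a trait report (pooled metrics)
#'
#' Mirrors the per-trait report-table shape: unused metric columns stay
#' `NA` (blank) depending on the trait's type.
#'
#' @param x A `trait_report`.
#' @param ... Unused.
#' @return A tibble: `trait`, `pseudo_h2`, `mcc`, `auroc`, `kendall_tau`,
#'   `spearman_rho`, `pearson_r`, `nmse`.
#' @export
glance.trait_report <- function(x, ...) {
  row <- tibble::tibble(trait = x$trait, pseudo_h2 = x$pseudo_h2,
                        mcc = NA_real_, auroc = NA_real_,
                        kendall_tau = NA_real_, spearman_rho = NA_real_,
                        pearson_r = NA_real_, nmse = NA_real_)
  for (m in names(x$pooled)) row[[m]] <- x$pooled[[m]]
  row
}

#' Evaluate several traits into a report table
#'
#' Runs [evaluate_trait()] for each named trait and stacks the pooled
#' summaries into one table, with metric columns left blank (`NA`) where the
#' trait's type does not warrant them.
#'
#' @param pheno,grm,fixed_effects,pcs,k,seed See [evaluate_trait()].
#' @param traits Named character vector: trait column -> kind (`"binary"`,
#'   `"ordinal"`, `"continuous"`).
#' @return A list: `table` (stacked [glance.trait_report()] rows) and
#'   `reports` (the individual `trait_report`s).
#' @export
evaluate_traits <- function(pheno, grm, traits,
                            fixed_effects = c("birth_year", "pc1", "pc2", "pc3"),
                            pcs = NULL, k = 5, seed = 1) {
  reports <- lapply(names(traits), function(tr) {
    evaluate_trait(pheno, grm, tr, kind = traits[[tr]],
                   fixed_effects = fixed_effects, pcs = pcs,
                   k = k, seed = seed)
  })
  names(reports) <- names(traits)
  list(table = dplyr::bind_rows(lapply(reports, glance)),
       reports = reports)
}

#' Evaluate success with an index score as an extra fixed effect
#'
#' Cross-validates the binary success outcome with the named score column
#' (e.g. `"behavior_score"`, `"total_score"`, `"parent_total_score"`)
#' appended to the fixed-effect design; scores are observed phenotypic
#' values, so they are available for test individuals. When a parental score
#' is requested the analysis is restricted to the trio subset (individuals
#' with the score non-missing).
#'
#' @param pheno,grm,fixed_effects,pcs,folds,k,seed See [evaluate_trait()].
#' @param extra_fixed Character vector of score columns to add (may be
#'   empty, giving the genomic-only baseline).
#' @return A `trait_report` for success.
#' @export
evaluate_success <- function(pheno, grm, extra_fixed = character(),
                             fixed_effects = c("birth_year", "pc1", "pc2", "pc3"),
                             pcs = NULL, folds = NULL, k = 5, seed = 1) {
  if (length(extra_fixed) > 0) {
    ok <- stats::complete.cases(pheno[, extra_fixed, drop = FALSE])
    pheno <- pheno[ok, , drop = FALSE]
    if (!is.null(folds)) folds <- folds[folds$id %in% pheno$id, ]
  }
  evaluate_trait(pheno, grm, "success", kind = "binary",
                 fixed_effects = fixed_effects, extra_fixed = extra_fixed,
                 pcs = pcs, folds = folds, k = k, seed = seed)
}
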