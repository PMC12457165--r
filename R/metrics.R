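#' Balanced k-fold assignment
#'
#' Uniform random partition of ids into k folds whose sizes differ by at
#' most one; every individual lands in exactly one test fold. Deterministic
#' under `seed`.
#'
#' @param ids Character vector of individual ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param stratify_by Optional vector (same length as `ids`) of class labels
#'   to stratify the partition on.
#' @return A `fold_plan`: tibble `id`, `fold` plus attributes `k`, `seed`.
#' @export
make_folds <- function(ids, k = 5, seed = 1, stratify_by = NULL) {
  stopifnot(k >= 2, length(ids) >= k)
  set.seed(seed)
  n <- length(ids)
  fold <- integer(n)
  if (is.null(stratify_by)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    for (cls in unique(stratify_by)) {
      idx <- which(stratify_by == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  out <- tibble::tibble(id = ids, fold = fold)
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  class(out) <- c("fold_plan", class(out))
  out
}

#' Matthews correlation coefficient
#'
#' Standard MCC from confusion counts. When any factor of the denominator is
#' zero (e.g. a one-class prediction on a low-prevalence trait), the
#' statistic is reported as 0, the convention under which degenerate
#' constant predictions score no better than chance.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return MCC in \[-1, 1\].
#' @export
#' @examples
#' mcc(tp = 3, fp = 1, tn = 4, fn = 2)
mcc <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("confusion counts must be nonnegative")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)   # avoid integer overflow
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Confusion counts from binary predictions and labels
#'
#' @param pred_class,obs 0/1 vectors of equal length.
#' @return A tibble: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred_class, obs) {
  stopifnot(length(pred_class) == length(obs))
  tibble::tibble(
    tp = sum(pred_class == 1 & obs == 1),
    fp = sum(pred_class == 1 & obs == 0),
    tn = sum(pred_class == 0 & obs == 0),
    fn = sum(pred_class == 0 & obs == 1)
  )
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive outranks
#' a random negative under `scores`, with ties credited one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 class labels.
#' @return AUROC in \[0, 1\], or `NA` if either class is absent.
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kendall's tau-b
#'
#' Tie-corrected rank correlation between predictions and observations.
#'
#' @param pred,obs Numeric vectors of equal length.
#' @return Tau-b in \[-1, 1\].
#' @export
kendall_tau <- function(pred, obs) {
  suppressWarnings(stats::cor(pred, obs, method = "kendall"))
}

#' Spearman's rho (average-rank ties)
#'
#' @inheritParams kendall_tau
#' @return Rho in \[-1, 1\].
#' @export
spearman_rho <- function(pred, obs) {
  suppressWarnings(stats::cor(pred, obs, method = "spearman"))
}

#' Pearson correlation
#'
#' @inheritParams kendall_tau
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(pred, obs) {
  suppressWarnings(stats::cor(pred, obs))
}

#' Normalized mean squared error
#'
#' Mean squared prediction error divided by the population (divide-by-n)
#' variance of the observations, so a constant predictor at the observed
#' mean scores exactly 1 and smaller is better.
#'
#' @inheritParams kendall_tau
#' @return NMSE >= 0, or `NA` if the observations have zero variance.
#' @export
#' @examples
#' nmse(c(1, 1, 3), c(1, 2, 3))  # 0.5
nmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  v <- mean((obs - mean(obs))^2)
  if (v == 0) return(NA_real_)
  mean((pred - obs)^2) / v
}

#' Turn continuous predictions into classes
#'
#' Binary traits: class 1 iff prediction >= 0.5. Ordinal traits: round to
#' the nearest valid class and clip to \[min_class, max_class\]. This is the
#' simplest thresholding rule consistent with constant low predictions on
#' unbalanced traits classifying everything negative.
#'
#' @param pred Numeric predicted phenotypes.
#' @param kind `"binary"` or `"ordinal"`.
#' @param min_class,max_class Valid class range for ordinal traits.
#' @param threshold Binary classification threshold (default 0.5).
#' @return Integer class vector.
#' @export
classify_prediction <- function(pred, kind = c("binary", "ordinal"),
                                min_class = 0L, max_class = 2L,
                                threshold = 0.5) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    as.integer(pred >= threshold)
  } else {
    as.integer(pmin(pmax(floor(pred + 0.5), min_class), max_class))
  }
}
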