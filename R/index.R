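#' Standardize a raw behavior category label
#'
#' Maps a trainer-recorded category label to its condensed ordinal score
#' (see [standardization_map()]).
#'
#' @param raw_label Character vector of raw category labels.
#' @param trait The behavior trait the labels belong to.
#' @param map A standardization map tibble (`trait`, `raw_label`, `score`);
#'   default [standardization_map()].
#' @return Integer scores, same length as `raw_label`.
#' @export
#' @examples
#' standardize_trait("High average", "pace")  # 2
#' standardize_trait(c("3+", "5"), "rating")  # 3, 7
standardize_trait <- function(raw_label, trait, map = standardization_map()) {
  sub <- map[map$trait == trait, ]
  if (nrow(sub) == 0) stop("unknown trait: ", trait)
  idx <- match(raw_label, sub$raw_label)
  if (anyNA(idx)) {
    stop("unknown label(s) for ", trait, ": ",
         paste(unique(raw_label[is.na(idx)]), collapse = ", "),
         "; valid labels: ", paste(sub$raw_label, collapse = ", "))
  }
  sub$score[idx]
}

#' Normalize a negative-direction behavior score
#'
#' Traits negatively correlated with success (neck, distraction, rating) are
#' inverted so higher raw scores produce lower normalized values:
#' |x_max - x| / x_max.
#'
#' @param x Standardized score(s), 0 <= x <= x_max.
#' @param x_max Maximum attainable standardized score (> 0).
#' @return Normalized value(s) in \[0, 1\].
#' @export
normalize_negative <- function(x, x_max) {
  if (any(x_max == 0)) stop("x_max must be positive")
  if (any(x < 0 | x > x_max)) stop("x must lie in [0, x_max]")
  abs(x_max - x) / x_max
}

#' Normalize a positive-direction behavior score
#'
#' Traits positively correlated with success (soundness, trainability) keep
#' their directionality: x / x_max.
#'
#' @inheritParams normalize_negative
#' @return Normalized value(s) in \[0, 1\].
#' @export
normalize_positive <- function(x, x_max) {
  if (any(x_max == 0)) stop("x_max must be positive")
  x / x_max
}

#' Normalize a neutral (optimum-intermediate) behavior score
#'
#' Traits with an optimal intermediate value (pace, pull) on the condensed
#' 0/1/2 scale: 1 - |x - 1|, so the optimum scores 1 and both extremes 0.
#'
#' @param x Standardized score(s) on the condensed scale.
#' @return Normalized value(s) (<= 1).
#' @export
normalize_neutral <- function(x) {
  1 - abs(x - 1)
}

# normalized value for one trait row of trait_definitions()
normalize_by_direction <- function(x, direction, x_max) {
  switch(direction,
         negative = normalize_negative(x, x_max),
         positive = normalize_positive(x, x_max),
         neutral = normalize_neutral(x),
         stop("unknown direction: ", direction))
}

#' Behavior Score of one or more dogs
#'
#' Each of the seven behavior traits (neck, distraction, rating, soundness,
#' trainability, pace, pull) is normalized by its direction rule and
#' multiplied by its weight, then the products are summed. The default
#' weight is the absolute Pearson correlation of the trait with success:
#' negative-direction traits are already inverted by their normalization, so
#' re-multiplying by a negative correlation would penalize good dogs;
#' `raw_sign_weights = TRUE` reproduces the literal signed-weight reading.
#'
#' @param scores Data frame (or single named list/vector) of standardized
#'   behavior scores, one column per trait, one row per dog.
#' @param specs Trait definition table ([trait_definitions()]).
#' @param raw_sign_weights Use the signed correlations as weights.
#' @return Numeric Behavior Score(s).
#' @export
#' @examples
#' behavior_score(data.frame(neck = 1, distraction = 0, rating = 3,
#'                           soundness = 2, trainability = 8, pace = 1,
#'                           pull = 1))
behavior_score <- function(scores, specs = trait_definitions(),
                           raw_sign_weights = FALSE) {
  scores <- tibble::as_tibble(as.data.frame(scores))
  behav <- specs[specs$kind == "ordinal_behavior", ]
  missing <- setdiff(behav$trait, names(scores))
  if (length(missing) > 0) {
    stop("missing behavior trait(s): ", paste(missing, collapse = ", "))
  }
  total <- numeric(nrow(scores))
  for (i in seq_len(nrow(behav))) {
    tr <- behav$trait[i]
    norm <- normalize_by_direction(scores[[tr]], behav$direction[i],
                                   behav$x_max[i])
    w <- if (raw_sign_weights) behav$weight_r[i] else abs(behav$weight_r[i])
    total <- total + norm * w
  }
  total
}

#' Health Score of one or more dogs
#'
#' The sum over the twenty health conditions of binary diagnosis status
#' times the condition's correlation with success. All correlations are
#' negative, so the Health Score is <= 0, with 0 meaning no diagnoses.
#'
#' @param diagnoses Data frame (or single named list/vector) of 0/1
#'   diagnosis indicators, one column per condition. Conditions absent from
#'   the table are treated as errors; extra columns are ignored.
#' @param specs Trait definition table ([trait_definitions()]).
#' @return Numeric Health Score(s) (<= 0).
#' @export
#' @examples
#' d <- data.frame(matrix(0, 1, 20))
#' names(d) <- trait_definitions()$trait[
#'   trait_definitions()$kind == "binary_health"]
#' d$atopic_dermatitis <- 1
#' health_score(d)  # -0.1
health_score <- function(diagnoses, specs = trait_definitions()) {
  diagnoses <- tibble::as_tibble(as.data.frame(diagnoses))
  health <- specs[specs$kind == "binary_health", ]
  missing <- setdiff(health$trait, names(diagnoses))
  if (length(missing) > 0) {
    stop("missing health trait(s): ", paste(missing, collapse = ", "))
  }
  status <- as.matrix(diagnoses[, health$trait, drop = FALSE])
  if (any(!status %in% 0:1)) stop("diagnosis status must be 0 or 1")
  as.vector(status %*% health$weight_r)
}

#' Total Score
#'
#' Weighted combination of the Health and Behavior Scores:
#' w_health x health + w_behavior x behavior.
#'
#' @param health Health Score(s).
#' @param behavior Behavior Score(s).
#' @param weights List with `w_health`, `w_behavior`
#'   ([default_index_weights()]); not both zero.
#' @return Numeric Total Score(s).
#' @export
total_score <- function(health, behavior, weights = default_index_weights()) {
  if (weights$w_health == 0 && weights$w_behavior == 0) {
    stop("index weights must not both be zero")
  }
  weights$w_health * health + weights$w_behavior * behavior
}

#' Condition-category counts
#'
#' Tallies diagnosed conditions per category: Dental Count, Ocular Count,
#' Dermal Count, and the overall Health Count (every diagnosed condition in
#' any category, including neurological/musculoskeletal, congenital and
#' infectious conditions, contributes one point).
#'
#' @inheritParams health_score
#' @return A tibble: `dental_count`, `ocular_count`, `dermal_count`,
#'   `health_count`, one row per dog.
#' @export
#' @examples
#' d <- data.frame(matrix(0, 1, 20))
#' names(d) <- trait_definitions()$trait[
#'   trait_definitions()$kind == "binary_health"]
#' d$supernumerary_teeth <- 1; d$distichiasis <- 1
#' category_counts(d)  # dental 1, ocular 1, dermal 0, health 2
category_counts <- function(diagnoses, specs = trait_definitions()) {
  diagnoses <- tibble::as_tibble(as.data.frame(diagnoses))
  health <- specs[specs$kind == "binary_health", ]
  missing <- setdiff(health$trait, names(diagnoses))
  if (length(missing) > 0) {
    stop("missing health trait(s): ", paste(missing, collapse = ", "))
  }
  status <- as.matrix(diagnoses[, health$trait, drop = FALSE])
  if (any(!status %in% 0:1)) stop("diagnosis status must be 0 or 1")
  grp <- health$category_group
  tibble::tibble(
    dental_count = as.integer(status[, grp == "dental", drop = FALSE] %*%
                                rep(1, sum(grp == "dental"))),
    ocular_count = as.integer(status[, grp == "ocular", drop = FALSE] %*%
                                rep(1, sum(grp == "ocular"))),
    dermal_count = as.integer(status[, grp == "dermal", drop = FALSE] %*%
                                rep(1, sum(grp == "dermal"))),
    health_count = as.integer(rowSums(status))
  )
}

#' Append index scores and counts to a phenotype table
#'
#' Computes the Behavior Score, Health Score, Total Score and the
#' Dental/Ocular/Dermal/Health Counts for every row and appends them as
#' columns, so downstream models can use them as responses or fixed effects.
#'
#' @param pheno Tibble with one row per dog carrying the standardized
#'   behavior trait columns and 0/1 health condition columns.
#' @param specs Trait definition table ([trait_definitions()]).
#' @param weights Total Score weights ([default_index_weights()]).
#' @param raw_sign_weights Passed to [behavior_score()].
#' @return `pheno` with columns `behavior_score`, `health_score`,
#'   `total_score`, `dental_count`, `ocular_count`, `dermal_count`,
#'   `health_count` appended.
#' @export
score_dogs <- function(pheno, specs = trait_definitions(),
                       weights = default_index_weights(),
                       raw_sign_weights = FALSE) {
  pheno <- tibble::as_tibble(pheno)
  bs <- behavior_score(pheno, specs, raw_sign_weights)
  hs <- health_score(pheno, specs)
  counts <- category_counts(pheno, specs)
  dplyr::bind_cols(
    pheno,
    tibble::tibble(behavior_score = bs, health_score = hs,
                   total_score = total_score(hs, bs, weights)),
    counts
  )
}

#' Attach parental index scores to the trio subset
#'
#' For offspring whose sire and dam are both present (and scored) in the
#' table, averages the two parents' Behavior, Health and Total Scores into
#' `parent_behavior_score`, `parent_health_score`, `parent_total_score`
#' columns (NA outside the trio subset).
#'
#' @param scored A table from [score_dogs()] with `id`, `sire`, `dam`.
#' @return `scored` with the three parental-score columns appended.
#' @export
add_parent_scores <- function(scored) {
  stopifnot(all(c("id", "sire", "dam") %in% names(scored)))
  si <- match(scored$sire, scored$id)
  di <- match(scored$dam, scored$id)
  avg <- function(col) (scored[[col]][si] + scored[[col]][di]) / 2
  dplyr::mutate(scored,
    parent_behavior_score = avg("behavior_score"),
    parent_health_score = avg("health_score"),
    parent_total_score = avg("total_score"))
}
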