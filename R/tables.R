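#' Behavior-trait standardization map
#'
#' The raw behavior categories recorded by trainers and their condensed
#' ordinal scores. Pace, pull and neck are condensed toward a 0/1/2
#' low/average/high scale (selection acts toward the mean for these), rating
#' keeps its full eight-level ladder (scores 0--7), distraction is condensed
#' to binary and soundness to a 0/1/2 ordinal (unidirectional selection).
#'
#' @return A tibble with columns `trait`, `raw_label`, `score`.
#' @export
#' @examples
#' standardization_map()
standardization_map <- function() {
  tibble::tribble(
    ~trait,         ~raw_label,          ~score,
    "pace",         "Fast",              2L,
    "pace",         "Above average",     2L,
    "pace",         "High average",      2L,
    "pace",         "Average",           1L,
    "pace",         "Less than average", 0L,
    "distraction",  "High",              1L,
    "distraction",  "Above average",     1L,
    "distraction",  "Average",           0L,
    "distraction",  "Less than average", 0L,
    "pull",         "Hard",              2L,
    "pull",         "Above average",     2L,
    "pull",         "Average",           1L,
    "pull",         "Defined average",   1L,
    "pull",         "Less than average", 0L,
    "neck",         "Hard",              2L,
    "neck",         "Above average",     2L,
    "neck",         "Average",           1L,
    "neck",         "Less than average", 0L,
    "neck",         "Easy",              0L,
    "rating",       "5",                 7L,
    "rating",       "4+",                6L,
    "rating",       "4",                 5L,
    "rating",       "4-",                4L,
    "rating",       "3+",                3L,
    "rating",       "3",                 2L,
    "rating",       "3-",                1L,
    "rating",       "2+",                0L,
    "soundness",    "Sound",             2L,
    "soundness",    "Above average",     1L,
    "soundness",    "Average",           0L,
    "soundness",    "Less than average", 0L
  )
}

#' Observed raw-category counts for the behavior traits
#'
#' Per-category animal counts in the 844-dog reference population, used by the
#' `"table1"` fixture and to parameterize the ordinal trait simulators.
#'
#' @return A tibble with columns `trait`, `raw_label`, `n`.
#' @export
raw_category_counts <- function() {
  tibble::tribble(
    ~trait,        ~raw_label,          ~n,
    "pace",        "Fast",              2L,
    "pace",        "Above average",     42L,
    "pace",        "High average",      205L,
    "pace",        "Average",           551L,
    "pace",        "Less than average", 44L,
    "distraction", "High",              20L,
    "distraction", "Above average",     364L,
    "distraction", "Average",           412L,
    "distraction", "Less than average", 48L,
    "pull",        "Hard",              3L,
    "pull",        "Above average",     46L,
    "pull",        "Average",           511L,
    "pull",        "Defined average",   233L,
    "pull",        "Less than average", 51L,
    "neck",        "Hard",              9L,
    "neck",        "Above average",     264L,
    "neck",        "Average",           496L,
    "neck",        "Less than average", 69L,
    "neck",        "Easy",              6L,
    "rating",      "5",                 8L,
    "rating",      "4+",                10L,
    "rating",      "4",                 174L,
    "rating",      "4-",                11L,
    "rating",      "3+",                305L,
    "rating",      "3",                 282L,
    "rating",      "3-",                32L,
    "rating",      "2+",                22L,
    "soundness",   "Sound",             262L,
    "soundness",   "Above average",     484L,
    "soundness",   "Average",           92L,
    "soundness",   "Less than average", 6L
  )
}

#' Trait definitions: directions, scales, groups and success correlations
#'
#' One row per trait handled by the selection indices: the seven behavior
#' traits and the twenty binary health conditions, plus the two composite
#' scores whose correlations with success drive the Total Score weights.
#' `weight_r` is the phenotypic Pearson correlation of each trait with guide
#' dog success in the reference population; `direction` is how the trait
#' relates to success (negative traits are inverted before weighting, neutral
#' traits have an optimal intermediate value of 1 on the condensed scale);
#' `x_max` is the maximum attainable standardized score; `category_group`
#' assigns health conditions to the Dental/Ocular/Dermal count groups.
#' `pseudo_h2` is the marker-based heritability estimated for the trait in
#' the reference population, used as the simulator's default target.
#'
#' @param trainability_x_max Maximum of the trainability scale. The raw scale
#'   is program-internal and not fixed here; the default 10 treats observed
#'   scores as proportions of a 10-point ladder. Override to match your data.
#' @return A tibble with columns `trait`, `kind`, `direction`, `x_max`,
#'   `optimum`, `weight_r`, `category_group`, `pseudo_h2`, `prevalence`.
#' @export
#' @examples
#' trait_definitions()
trait_definitions <- function(trainability_x_max = 10) {
  behavior <- tibble::tribble(
    ~trait,         ~direction, ~x_max, ~weight_r, ~pseudo_h2,
    "distraction",  "negative", 1,      -0.107,    0.177,
    "neck",         "negative", 2,      -0.108,    0.209,
    "rating",       "negative", 7,      -0.144,    0.179,
    "soundness",    "positive", 2,       0.127,    0,
    "trainability", "positive", NA,      0.531,    0.147,
    "pace",         "neutral",  2,       0.02,     0.153,
    "pull",         "neutral",  2,       0.017,    0.066
  )
  behavior$x_max[behavior$trait == "trainability"] <- trainability_x_max
  behavior <- dplyr::mutate(behavior,
    kind = "ordinal_behavior",
    optimum = ifelse(.data$direction == "neutral", 1, NA_real_),
    category_group = "behavior",
    prevalence = NA_real_
  )

  health <- tibble::tribble(
    ~trait,                                    ~weight_r, ~category_group,         ~pseudo_h2,
    "base_narrow_mandibular_canines",          -0.026,    "dental",                0.146,
    "malocclusion_class_i",                    -0.035,    "dental",                0.148,
    "distichiasis",                            -0.032,    "ocular",                0.092,
    "ppm",                                     -0.025,    "ocular",                0.142,
    "loose_interphalangeal_collateral_ligaments", -0.003, "neuro_musculoskeletal", 0.109,
    "umbilical_hernia",                        -0.009,    "other",                 0.037,
    "histiocytoma",                            -0.036,    "dermal",                0.039,
    "atopic_dermatitis",                       -0.1,      "dermal",                0.044,
    "allergic_dermatitis",                     -0.009,    "dermal",                0.019,
    "alopecia_bridge_of_nose",                 -0.027,    "dermal",                0.022,
    "acral_lick_dermatitis",                   -0.029,    "dermal",                0.046,
    "muzzle_folliculitis",                     -0.009,    "dermal",                0.023,
    "panosteitis",                             -0.02,     "neuro_musculoskeletal", 0.163,
    "oral_papillomatosis",                     -0.02,     "other",                 0.089,
    "supernumerary_teeth",                     -0.024,    "dental",                0,
    "retained_deciduous_teeth",                -0.013,    "dental",                0.131,
    "anodontia",                               -0.014,    "dental",                0.247,
    "mandibular_distocclusion",                -0.105,    "dental",                0.269,
    "mandibular_prognathism",                  -0.031,    "dental",                0.080,
    "mandibular_mesiocclusion",                -0.047,    "dental",                0.139
  )
  health <- dplyr::mutate(health,
    kind = "binary_health",
    direction = "negative",
    x_max = 1,
    optimum = NA_real_,
    prevalence = 0.05
  )

  dplyr::bind_rows(behavior, health)[, c(
    "trait", "kind", "direction", "x_max", "optimum", "weight_r",
    "category_group", "pseudo_h2", "prevalence"
  )]
}

#' Default index weights for the Total Score
#'
#' The Total Score combines the Health and Behavior Scores with weights taken
#' from the (absolute) correlations of those two composite scores with guide
#' dog success in the reference population: |-0.02| for health, |0.324| for
#' behavior. The absolute value is used because the Health Score is already
#' signed (it is a sum of negative correlation-weighted diagnoses), so a
#' negative combining weight would reward diagnoses.
#'
#' @return A named list with elements `w_health` and `w_behavior`.
#' @export
default_index_weights <- function() {
  list(w_health = 0.02, w_behavior = 0.324)
}

# Cumulative category frequencies (ascending score order) for an ordinal
# behavior trait, derived from the observed raw-category counts.
ordinal_cum_freq <- function(trait) {
  counts <- raw_category_counts()
  map <- standardization_map()
  x <- dplyr::inner_join(counts[counts$trait == trait, ],
                         map[map$trait == trait, ],
                         by = c("trait", "raw_label"))
  if (nrow(x) == 0) stop("unknown ordinal trait: ", trait)
  tab <- stats::aggregate(n ~ score, data = x, FUN = sum)
  tab <- tab[order(tab$score), ]
  cumsum(tab$n) / sum(tab$n)
}
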