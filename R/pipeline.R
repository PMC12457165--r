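#' Validate a phenotype table's schema
#'
#' Checks required columns and, for character behavior-trait columns, that
#' every raw category label is known to the standardization map. Errors name
#' the offending row and column.
#'
#' @param pheno A phenotype tibble (e.g. read from CSV).
#' @param required Columns that must be present.
#' @return `pheno`, invisibly, if valid.
#' @export
validate_pheno <- function(pheno,
                           required = c("id", "sire", "dam", "birth_year",
                                        "success")) {
  miss <- setdiff(required, names(pheno))
  if (length(miss) > 0) {
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  }
  map <- standardization_map()
  for (tr in intersect(unique(map$trait), names(pheno))) {
    col <- pheno[[tr]]
    if (is.character(col) || is.factor(col)) {
      valid <- map$raw_label[map$trait == tr]
      bad <- which(!is.na(col) & !(as.character(col) %in% valid))
      if (length(bad) > 0) {
        stop("unknown category label in column '", tr, "', row ", bad[1],
             ": '", col[bad[1]], "'")
      }
    }
  }
  invisible(pheno)
}

stage_manifest <- function(dir, stage, params, inputs = character()) {
  manifest <- list(
    stage = stage, params = params,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)]))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> qc -> grm -> index -> evaluate from one
#' configuration, writing each stage's outputs and a JSON manifest (input
#' hashes, parameters, seed) into its own subdirectory of `out_dir`. A rerun
#' with the same configuration and seed is bit-identical except timestamps.
#'
#' @param config A named list, or path to a YAML file with the same shape:
#'   \describe{
#'     \item{out_dir}{Output directory (created).}
#'     \item{seed}{Integer seed governing simulation and fold assignment.}
#'     \item{simulate}{List of [sim_config()] overrides, or `NULL` to load
#'       `genotype_prefix` (PLINK) + `pheno_csv` instead.}
#'     \item{genotype_prefix, pheno_csv}{Inputs when not simulating.}
#'     \item{qc}{`list(enabled=, min_variant_call_rate=, ...)`; defaults on.}
#'     \item{grm}{`list(pcs = 3, method = "vanraden1")`.}
#'     \item{evaluate}{`list(k = 5, traits = c(name = kind, ...),
#'       success_fixed = list(character(), "behavior_score", ...))`.}
#'   }
#' @return A list with the stage results: `pop` (if simulated), `geno`,
#'   `qc_report`, `grm`, `pcs`, `scored` (phenotypes + index scores),
#'   `report` (evaluation table), `success_reports`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out <- config$out_dir
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # --- simulate or load -----------------------------------------------------
  sim_dir <- file.path(out, "simulate")
  pop <- NULL
  if (!is.null(config$simulate) || is.null(config$genotype_prefix)) {
    dir.create(sim_dir, showWarnings = FALSE)
    sim_args <- config$simulate
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    pop <- simulate_population(cfg)
    geno <- pop$geno
    pheno <- pop$pheno
    write_plink(geno, file.path(sim_dir, "genotypes"), format = "bed")
    utils::write.csv(pheno, file.path(sim_dir, "pheno.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n = nrow(pheno), n_snps = cfg$n_snps,
           heritabilities = lapply(cfg$trait_specs, function(s) s$heritability)),
      file.path(sim_dir, "true_parameters.json"),
      auto_unbox = TRUE, digits = NA)
    stage_manifest(sim_dir, "simulate",
                   list(seed = seed, n_founders = cfg$n_founders,
                        n_offspring = cfg$n_offspring, n_snps = cfg$n_snps))
  } else {
    geno <- read_plink(config$genotype_prefix)
    pheno <- tibble::as_tibble(utils::read.csv(config$pheno_csv))
    validate_pheno(pheno)
  }

  # --- qc -------------------------------------------------------------------
  qc_cfg <- config$qc
  qc_report <- NULL
  if (is.null(qc_cfg$enabled) || isTRUE(qc_cfg$enabled)) {
    qc_dir <- file.path(out, "qc")
    dir.create(qc_dir, showWarnings = FALSE)
    thr <- qc_thresholds(
      min_variant_call_rate = qc_cfg$min_variant_call_rate %||% 0.90,
      min_sample_call_rate = qc_cfg$min_sample_call_rate %||% 0.90,
      hwe_alpha = qc_cfg$hwe_alpha %||% 1e-5,
      min_maf = qc_cfg$min_maf %||% 0.01)
    qc_res <- run_qc(geno, thr, keep_snps = qc_cfg$keep_snps)
    geno <- qc_res$geno
    qc_report <- qc_res$report
    write_qc_report(qc_report, file.path(qc_dir, "qc_report.json"))
    pheno <- pheno[pheno$id %in% geno$samples$id, , drop = FALSE]
    stage_manifest(qc_dir, "qc", unclass(thr))
  }

  # --- grm ------------------------------------------------------------------
  grm_dir <- file.path(out, "grm")
  dir.create(grm_dir, showWarnings = FALSE)
  grm_cfg <- config$grm
  grm <- compute_grm(geno, method = grm_cfg$method %||% "vanraden1")
  n_pcs <- grm_cfg$pcs %||% 3
  pcs <- compute_pcs(grm, k = n_pcs)
  write_grm(grm, file.path(grm_dir, "grm"))
  utils::write.csv(pcs, file.path(grm_dir, "pcs.csv"), row.names = FALSE)
  stage_manifest(grm_dir, "grm",
                 list(method = grm$method, pcs = n_pcs,
                      n_snps_used = grm$n_snps_used))

  # --- index ----------------------------------------------------------------
  index_dir <- file.path(out, "index")
  dir.create(index_dir, showWarnings = FALSE)
  defs <- trait_definitions()
  scorable <- all(defs$trait %in% names(pheno))
  scored <- if (scorable) {
    add_parent_scores(score_dogs(pheno))
  } else pheno
  utils::write.csv(scored, file.path(index_dir, "scored.csv"),
                   row.names = FALSE)
  stage_manifest(index_dir, "index",
                 list(scored = scorable,
                      weights = default_index_weights()))

  # --- evaluate -------------------------------------------------------------
  eval_dir <- file.path(out, "evaluate")
  dir.create(eval_dir, showWarnings = FALSE)
  ev_cfg <- config$evaluate
  k <- ev_cfg$k %||% 5
  traits <- ev_cfg$traits
  if (is.null(traits)) {
    traits <- c(success = "binary")
    if (scorable) {
      traits <- c(traits, behavior_score = "continuous",
                  health_score = "continuous", total_score = "continuous")
    }
  }
  traits <- unlist(traits)
  fixed <- ev_cfg$fixed_effects %||%
    c("birth_year", paste0("pc", seq_len(min(n_pcs, 3))))
  res <- evaluate_traits(scored, grm, traits, fixed_effects = fixed,
                         pcs = pcs, k = k, seed = seed)
  utils::write.csv(res$table, file.path(eval_dir, "report.csv"),
                   row.names = FALSE)
  per_fold <- dplyr::bind_rows(lapply(res$reports, tidy))
  jsonlite::write_json(per_fold, file.path(eval_dir, "per_fold.json"),
                       auto_unbox = TRUE, digits = NA)

  success_reports <- list()
  for (ef in ev_cfg$success_fixed %||% list()) {
    rep <- evaluate_success(scored, grm, extra_fixed = ef,
                            fixed_effects = fixed, pcs = pcs,
                            k = k, seed = seed)
    success_reports[[paste(c("success", ef), collapse = "+")]] <- rep
  }
  if (length(success_reports) > 0) {
    utils::write.csv(
      dplyr::bind_rows(lapply(success_reports, glance), .id = "model"),
      file.path(eval_dir, "success_models.csv"), row.names = FALSE)
  }
  stage_manifest(eval_dir, "evaluate",
                 list(k = k, seed = seed, traits = as.list(traits)))

  list(pop = pop, geno = geno, qc_report = qc_report, grm = grm, pcs = pcs,
       scored = scored, report = res$table, reports = res$reports,
       success_reports = success_reports, out_dir = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a small deterministic test fixture
#'
#' Tiny populations with known truths for unit tests:
#' \describe{
#'   \item{"trio"}{10 trios (both parents fully phenotyped) from 20
#'     founders, 200 SNPs.}
#'   \item{"null"}{All trait heritabilities 0 (40 dogs, 200 SNPs).}
#'   \item{"table1"}{A tibble of 844 dogs whose raw behavior-category counts
#'     equal the reference population's printed counts exactly (labels
#'     shuffled deterministically).}
#' }
#'
#' @param name Fixture name.
#' @param seed Integer seed.
#' @return A `sim_population`, or a tibble for `"table1"`.
#' @export
make_fixture <- function(name = c("trio", "null", "table1"), seed = 1) {
  name <- match.arg(name)
  if (name == "table1") {
    set.seed(seed)
    counts <- raw_category_counts()
    cols <- lapply(split(counts, counts$trait), function(d) {
      sample(rep(d$raw_label, d$n))
    })
    return(tibble::as_tibble(c(list(id = sprintf("dog%04d", 1:844)),
                               cols[unique(counts$trait)])))
  }
  base_traits <- list(
    sim_trait_spec("sickly", "binary",
                   if (name == "null") 0 else 0.4, 0.3),
    sim_trait_spec("pace", "ordinal",
                   if (name == "null") 0 else 0.3, ordinal_cum_freq("pace")),
    sim_trait_spec("trainability", "continuous",
                   if (name == "null") 0 else 0.5))
  cfg <- sim_config(
    n_founders = 20, n_offspring = if (name == "trio") 10 else 20,
    n_trio_offspring = 10, n_snps = 200, n_causal_per_trait = 50,
    trait_specs = base_traits,
    success_weights = c(trainability = 0.53), missing_rate = 0,
    seed = seed)
  simulate_population(cfg)
}
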