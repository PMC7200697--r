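#' Read and validate a study configuration
#'
#' A single YAML file drives the full pipeline: a `seed`, per-stage
#' sections (`population`, `imaging`, `calling`, `inference`, `backcross`,
#' `variants`) and an output directory. Referenced input paths are checked
#' before any stage executes.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return A validated config list of class `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "ploidyscope_out"
  for (p in cfg$input_paths) {
    if (!file.exists(p)) abort(paste0("configured input path does not exist: ", p))
  }
  structure(cfg, class = "study_config")
}

# hash of the analysis configuration; the output location is not part of
# the analysis identity
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  rlang::hash(cfg)
}

pipeline_header <- function(cfg) {
  c(paste0("# ploidyscope ", as.character(utils::packageVersion("ploidyscope"))),
    paste0("# seed: ", cfg$seed),
    paste0("# config_hash: ", config_hash(cfg)))
}

write_with_header <- function(df, path, cfg) {
  writeLines(pipeline_header(cfg), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the configured analysis pipeline end to end
#'
#' Stages run in dependency order: `simulate` (populations per animal and a
#' variant panel), `compose` (normalize, call ploidy, summarise each
#' animal), `compare` (two-group Student t-test on a composition metric),
#' `infer` (mode-of-inheritance model enumeration, if an observation pattern
#' is configured), `backcross` (genome-composition simulation) and
#' `filter_variants`. Every output file carries a header with the tool
#' version, seed and config hash; rerunning with the same config and seed
#' reproduces the outputs. Existing stage outputs are reused unless
#' `force = TRUE`.
#'
#' @param config A `study_config` (or path to one).
#' @param stages Character subset of stages to run.
#' @param force Recompute stages whose outputs already exist?
#' @return Invisibly, a manifest tibble of produced files.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "compose", "compare",
                                    "infer", "backcross", "filter_variants"),
                         force = FALSE) {
  cfg <- if (inherits(config, "study_config")) config else read_study_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  done <- function(path) file.exists(path) && !force

  pop <- cfg$population %||% list()
  strains <- pop$strains %||% c("BALB/cJ", "BALB/cByJ")
  n_animals <- pop$n_animals %||% 3L
  n_cells <- pop$n_cells %||% 500L

  comp_path <- file.path(cfg$out_dir, "composition.csv")
  if (any(c("simulate", "compose") %in% stages) && !done(comp_path)) {
    comps <- purrr::map(strains, function(st) {
      purrr::map(seq_len(n_animals), function(a) {
        spec <- strain_population_spec(
          st, n_cells = n_cells,
          seed = derive_seed(cfg$seed, "pipeline") + a +
            1000L * match(st, strains))
        truth <- generate_population(spec)
        compose_from_truth(truth, animal_id = paste0(st, "_", a),
                           min_cells = cfg$calling$min_cells %||% NULL) |>
          dplyr::mutate(strain = st)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    write_with_header(comps, comp_path, cfg)
  }
  manifest$composition <- comp_path

  if ("compare" %in% stages) {
    comps <- readr::read_csv(comp_path, comment = "#", show_col_types = FALSE)
    cmp <- compare_groups(comps, .data$mononuclear_pct, .data$strain)
    cmp_path <- file.path(cfg$out_dir, "comparisons.csv")
    write_with_header(tidy(cmp), cmp_path, cfg)
    manifest$comparisons <- cmp_path
  }

  if ("infer" %in% stages && !is.null(cfg$inference)) {
    obs <- cross_observation(
      strains = strains,
      parental_A = unlist(cfg$inference$parental_A),
      parental_B = unlist(cfg$inference$parental_B),
      f1_mother_A = unlist(cfg$inference$f1_mother_A),
      f1_mother_B = unlist(cfg$inference$f1_mother_B))
    surv <- infer_consistent_models(obs)
    inf_path <- file.path(cfg$out_dir, "inference.json")
    jsonlite::write_json(list(seed = cfg$seed,
                              config_hash = config_hash(cfg),
                              n_consistent = nrow(surv),
                              models = surv),
                         inf_path, dataframe = "rows", auto_unbox = TRUE)
    manifest$inference <- inf_path
  }

  if ("backcross" %in% stages) {
    bc <- cfg$backcross %||% list()
    sim <- simulate_backcross(
      breeding_scheme(n_backcross = bc$n_backcross %||% 3L,
                      marker_pos_cm = bc$marker_pos_cm %||% 35),
      n_replicates = bc$n_replicates %||% 200L, seed = cfg$seed)
    bc_path <- file.path(cfg$out_dir, "backcross.csv")
    write_with_header(glance(sim), bc_path, cfg)
    manifest$backcross <- bc_path
  }

  if ("filter_variants" %in% stages) {
    vr <- cfg$variants %||% list()
    panel <- generate_variant_panel(n_strains = vr$n_strains %||% 8L,
                                    seed = cfg$seed)
    strains_map <- panel$strains
    focal <- panel$calls[panel$calls$strain == strains_map[["focal"]], ]
    comparator <- panel$calls[panel$calls$strain == strains_map[["comparator"]], ]
    panel_calls <- panel$calls[!panel$calls$strain %in%
                                 strains_map[c("focal", "comparator")], ]
    res <- filter_focal_strain(focal) |>
      subtract_shared(comparator, panel_calls)
    cand_path <- file.path(cfg$out_dir, "candidates.tsv")
    writeLines(pipeline_header(cfg), cand_path)
    readr::write_tsv(res$candidates, cand_path, append = TRUE, col_names = TRUE)
    pipeline_report(res, json_path = file.path(cfg$out_dir, "filter_report.json"))
    manifest$candidates <- cand_path
    manifest$filter_report <- file.path(cfg$out_dir, "filter_report.json")
  }

  invisible(tibble(output = names(manifest), path = unlist(manifest)))
}
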