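# Shared fixtures and independent oracles used across test files.

# Small deterministic population spec builders ------------------------------

mono_2n_spec <- function(n = 100L, cv = 0, seed = 1L, viability = 1) {
  population_spec(
    c(cardiomyocyte = n),
    nucleation_probs = list(cardiomyocyte = c(`1` = 1, `2` = 0)),
    ploidy_probs = list(cardiomyocyte = list(`1` = c(`2` = 1, `4` = 0, `8` = 0),
                                             `2` = c(`2` = 1, `4` = 0, `8` = 0))),
    intensity_cv = cv, viability_prob = viability, seed = seed)
}

# Independent oracle: filter the model space by re-running the phenotype
# prediction one model and one observation cell at a time (no cached
# prediction table, no joins).
brute_force_consistent <- function(obs, models) {
  obs <- obs[!is.na(obs$phenotype), ]
  ok <- vapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    all(vapply(seq_len(nrow(obs)), function(j) {
      predict_phenotype(m, obs$mother[j], obs$father[j], obs$sex[j]) ==
        obs$phenotype[j]
    }, logical(1)))
  }, logical(1))
  models[ok, ]
}

# Independent oracle: the six-term cell-class expansion written out long-hand.
expand_six_classes <- function(mono_dist, bi_dist, mono_fraction, bi_fraction) {
  c(`1x2n` = mono_fraction * mono_dist[["2n"]] / 100,
    `1x4n` = mono_fraction * mono_dist[["4n"]] / 100,
    `1x8n` = mono_fraction * mono_dist[["8n"]] / 100,
    `2x2n` = bi_fraction * bi_dist[["2n"]] / 100,
    `2x4n` = bi_fraction * bi_dist[["4n"]] / 100,
    `2x8n` = bi_fraction * bi_dist[["8n"]] / 100)
}

# Hand-built cell/call tables for the composition calculus ------------------

# n_mono cells with one nucleus each (mono_classes), n_bi cells with two
# nuclei sharing a class (bi_classes); returns list(cells, calls).
build_population_tables <- function(mono_classes, bi_classes) {
  n_mono <- length(mono_classes)
  n_bi <- length(bi_classes)
  cells <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n_mono + n_bi)),
    cell_type = "cardiomyocyte",
    viable = TRUE,
    n_nuclei = c(rep(1L, n_mono), rep(2L, n_bi)))
  calls <- tibble::tibble(
    cell_id = c(cells$cell_id[seq_len(n_mono)],
                rep(cells$cell_id[n_mono + seq_len(n_bi)], each = 2)),
    ploidy_class = c(mono_classes, rep(bi_classes, each = 2)))
  list(cells = cells, calls = calls)
}

# Run the whole candidate filter over a generated panel --------------------

run_full_filter <- function(panel, cfg = filter_config()) {
  focal <- panel$calls[panel$calls$strain == panel$strains[["focal"]], ]
  comparator <- panel$calls[panel$calls$strain == panel$strains[["comparator"]], ]
  pan <- panel$calls[!panel$calls$strain %in%
                       panel$strains[c("focal", "comparator")], ]
  subtract_shared(filter_focal_strain(focal, cfg), comparator, pan, cfg)
}

# The two observed F1 phenotype patterns ------------------------------------

study_strains <- c("BALB/cJ", "BALB/cByJ")

# mononuclear-CM percentage: cJ low, cByJ high; elevated only in F1 males
# from cByJ mothers
obs_mononuclear_cm <- function() {
  cross_observation(study_strains,
                    parental_A = c("low", "low"),
                    parental_B = c("high", "high"),
                    f1_mother_A = c("low", "low"),
                    f1_mother_B = c("high", "low"))
}

# mononuclear-nucleus diploid percentage: cJ high, cByJ low; all F1 at the
# cJ level regardless of direction and sex
obs_nuclear_ploidy <- function() {
  cross_observation(study_strains,
                    parental_A = c("high", "high"),
                    parental_B = c("low", "low"),
                    f1_mother_A = c("high", "high"),
                    f1_mother_B = c("high", "high"))
}
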