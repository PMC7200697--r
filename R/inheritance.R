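#' Enumerate the single-locus trait model space
#'
#' A trait model fixes the chromosome of the causal locus (X-linked or
#' autosomal), which strain carries the high allele, whether that allele is
#' dominant, whether the trait acts cell-autonomously (relevant only for
#' X-linked heterozygous females, where X-inactivation mosaicism predicts an
#' intermediate phenotype for autonomous traits), an optional maternal
#' effect, and an optional imprinted (silenced) parental allele. The full
#' space is 2 x 2 x 2 x 2 x 2 x 3 = 96 models.
#'
#' @param strains Character vector of the two strain labels, low/high roles
#'   assigned by `high_allele_origin`.
#' @return A tibble of 96 models with a `model_id` column.
#' @export
trait_models <- function(strains = c("BALB/cJ", "BALB/cByJ")) {
  stopifnot(length(strains) == 2)
  m <- tidyr::expand_grid(
    linkage = c("X-linked", "autosomal"),
    high_allele_origin = strains,
    high_allele_dominant = c(TRUE, FALSE),
    autonomy = c("cell-autonomous", "nonautonomous"),
    maternal_effect = c(FALSE, TRUE),
    imprinted_parent = c("none", "maternal", "paternal")
  )
  dplyr::mutate(m, model_id = dplyr::row_number(), .before = 1)
}

predict_one <- function(linkage, high_allele_origin, high_allele_dominant,
                        autonomy, maternal_effect, imprinted_parent,
                        mother, father, sex) {
  level_of <- function(allele) {
    if (allele == high_allele_origin) "high" else "low"
  }
  # a maternal effect makes the offspring phenotype that of its (purebred)
  # mother, regardless of the offspring's own genotype
  if (maternal_effect) return(level_of(mother))
  inherited <- if (linkage == "X-linked") {
    if (sex == "male") c(maternal = mother) else c(maternal = mother, paternal = father)
  } else c(maternal = mother, paternal = father)
  silenced <- switch(imprinted_parent, none = character(),
                     maternal = "maternal", paternal = "paternal")
  effective <- inherited[setdiff(names(inherited), silenced)]
  if (length(effective) == 0) effective <- inherited  # imprinting vacuous
  alleles <- unique(unname(effective))
  if (length(alleles) == 1) return(level_of(alleles))
  # heterozygous at the effective locus
  if (linkage == "X-linked" && sex == "female" && autonomy == "cell-autonomous") {
    return("intermediate")
  }
  if (high_allele_dominant) "high" else "low"
}

#' Predict the phenotype category for cross contexts under trait models
#'
#' Deterministic categorical prediction (`low`, `high`, `intermediate`) for
#' each model row, given a genotype context of purebred mother strain,
#' father strain and offspring sex. X-linked heterozygous females are
#' intermediate under cell-autonomous models (X-inactivation mosaicism) and
#' show the dominant allele's level under nonautonomous models.
#'
#' @param models Tibble of models (rows of [trait_models()]).
#' @param mother,father Strain labels of the parents.
#' @param sex `"male"` or `"female"`.
#' @return Character vector of predictions, one per model row.
#' @export
predict_phenotype <- function(models, mother, father, sex) {
  purrr::pmap_chr(
    models[c("linkage", "high_allele_origin", "high_allele_dominant",
             "autonomy", "maternal_effect", "imprinted_parent")],
    predict_one, mother = mother, father = father, sex = sex)
}

#' Assemble an observed cross phenotype pattern
#'
#' Eight context cells: the two parental strains and the two reciprocal F1
#' directions, each by sex. Phenotypes are categorical (`low`, `high`,
#' `intermediate`); use `NA` for cells not observed — inference never
#' guesses on missing cells.
#'
#' @param strains The two strain labels `c(A, B)`.
#' @param parental_A,parental_B Named or length-2 vectors `c(male, female)`
#'   of parental phenotypes.
#' @param f1_mother_A,f1_mother_B Length-2 vectors `c(male, female)` of F1
#'   phenotypes by maternal strain.
#' @return A tibble with columns `mother`, `father`, `sex`, `phenotype`.
#' @export
cross_observation <- function(strains,
                              parental_A, parental_B,
                              f1_mother_A, f1_mother_B) {
  ok <- function(v) length(v) == 2 &&
    all(v %in% c("low", "high", "intermediate") | is.na(v))
  if (!all(vapply(list(parental_A, parental_B, f1_mother_A, f1_mother_B),
                  ok, logical(1)))) {
    abort("phenotypes must be length-2 (male, female) in {low, high, intermediate, NA}")
  }
  A <- strains[1]; B <- strains[2]
  tibble(
    mother = c(A, A, B, B, A, A, B, B),
    father = c(A, A, B, B, B, B, A, A),
    sex = rep(c("male", "female"), 4),
    phenotype = c(parental_A, parental_B, f1_mother_A, f1_mother_B)
  )
}

#' Enumerate the trait models consistent with an observed cross pattern
#'
#' Exhaustively evaluates every model in the space against every observed
#' (non-missing) context cell and returns exactly the models that match all
#' of them. An empty result is a valid outcome. The implementation builds a
#' cached prediction table over the distinct contexts and joins; it is
#' exactly equivalent to re-running [predict_phenotype()] per model.
#'
#' @param obs A [cross_observation()] tibble.
#' @param models Model space; defaults to [trait_models()] over the strains
#'   appearing in `obs`.
#' @return The subset of `models` consistent with `obs`.
#' @export
infer_consistent_models <- function(obs, models = NULL) {
  strains <- unique(c(obs$mother, obs$father))
  if (length(strains) != 2) abort("`obs` must involve exactly two strains")
  models <- models %||% trait_models(strains)
  obs <- dplyr::filter(obs, !is.na(.data$phenotype))
  if (nrow(obs) == 0) return(models)
  contexts <- dplyr::distinct(obs, .data$mother, .data$father, .data$sex)
  pred <- purrr::pmap(contexts, function(mother, father, sex) {
    p <- predict_phenotype(models, mother, father, sex)
    tibble(model_id = models$model_id, mother = mother, father = father,
           sex = sex, predicted = p)
  }) |> dplyr::bind_rows()
  mismatches <- pred |>
    dplyr::inner_join(obs, by = c("mother", "father", "sex")) |>
    dplyr::filter(.data$predicted != .data$phenotype)
  dplyr::filter(models, !.data$model_id %in% mismatches$model_id)
}
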