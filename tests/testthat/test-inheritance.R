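# phenotype prediction and mode-of-inheritance inference

xl_recessive_nonauto <- function() {
  m <- trait_models(study_strains)
  dplyr::filter(m, linkage == "X-linked", high_allele_origin == "BALB/cByJ",
                !high_allele_dominant, autonomy == "nonautonomous",
                !maternal_effect, imprinted_parent == "none")
}

test_that("the X-linked recessive nonautonomous model matches the F1 pattern", {
  m <- xl_recessive_nonauto()
  expect_equal(nrow(m), 1)
  # F1 male from a cByJ mother carries only the cByJ X: high
  expect_equal(predict_phenotype(m, "BALB/cByJ", "BALB/cJ", "male"), "high")
  # F1 male from a cJ mother: low
  expect_equal(predict_phenotype(m, "BALB/cJ", "BALB/cByJ", "male"), "low")
  # heterozygous F1 females, either direction: the dominant (cJ) level
  expect_equal(predict_phenotype(m, "BALB/cByJ", "BALB/cJ", "female"), "low")
  expect_equal(predict_phenotype(m, "BALB/cJ", "BALB/cByJ", "female"), "low")
})

test_that("cell-autonomous X-linked heterozygous females are intermediate", {
  m <- dplyr::mutate(xl_recessive_nonauto(), autonomy = "cell-autonomous")
  expect_equal(predict_phenotype(m, "BALB/cJ", "BALB/cByJ", "female"),
               "intermediate")
  # males are unaffected by the autonomy field
  expect_equal(predict_phenotype(m, "BALB/cByJ", "BALB/cJ", "male"), "high")
})

test_that("the mononuclear-CM pattern pins the X-linked recessive model", {
  surv <- infer_consistent_models(obs_mononuclear_cm())
  expect_gt(nrow(surv), 0)
  expect_true(all(surv$linkage == "X-linked"))
  expect_true(all(surv$high_allele_origin == "BALB/cByJ"))
  expect_true(all(!surv$high_allele_dominant))
  expect_true(all(surv$autonomy == "nonautonomous"))
  # agrees with brute-force filtering of the full 96-model space
  models <- trait_models(study_strains)
  expect_equal(nrow(models), 96)
  expect_identical(surv, brute_force_consistent(obs_mononuclear_cm(), models))
})

test_that("the nuclear-ploidy pattern keeps only autosomal cJ-dominant models", {
  surv <- infer_consistent_models(obs_nuclear_ploidy())
  expect_gt(nrow(surv), 0)
  expect_true(all(surv$linkage == "autosomal"))
  expect_true(all(surv$high_allele_origin == "BALB/cJ"))
  expect_true(all(surv$high_allele_dominant))
  # in particular no X-linked model with a recessive cByJ allele survives
  expect_false(any(surv$linkage == "X-linked"))
  expect_identical(surv,
                   brute_force_consistent(obs_nuclear_ploidy(),
                                          trait_models(study_strains)))
})

test_that("a constant observation keeps exactly the constant-predicting models", {
  obs <- cross_observation(study_strains, c("low", "low"), c("low", "low"),
                           c("low", "low"), c("low", "low"))
  surv <- infer_consistent_models(obs)
  models <- trait_models(study_strains)
  expect_identical(surv, brute_force_consistent(obs, models))
  # every model shows "high" in the parental strain carrying the high
  # allele, so no single-locus model predicts a constant pattern: the
  # surviving set is empty, and that is reported rather than raised
  expect_equal(nrow(surv), 0)
  # with only the high-allele parental cells unobserved, survivors exist
  obs2 <- cross_observation(study_strains, c("low", "low"), c(NA, NA),
                            c("low", "low"), c("low", "low"))
  surv2 <- infer_consistent_models(obs2)
  expect_gt(nrow(surv2), 0)
  expect_identical(surv2, brute_force_consistent(obs2, models))
})

test_that("missing cells are never guessed and can empty the result", {
  # observe only the parental cells; many models survive
  obs <- cross_observation(study_strains, c("low", "low"), c("high", "high"),
                           c(NA, NA), c(NA, NA))
  surv_partial <- infer_consistent_models(obs)
  surv_full <- infer_consistent_models(obs_mononuclear_cm())
  expect_gt(nrow(surv_partial), nrow(surv_full))
  # an impossible pattern yields an empty, non-error result
  impossible <- cross_observation(study_strains, c("low", "high"), c("low", "low"),
                                  c("high", "low"), c("low", "high"))
  expect_equal(nrow(infer_consistent_models(impossible)), 0)
})

test_that("inference equals brute force on random observation patterns", {
  models <- trait_models(study_strains)
  phenos <- c("low", "high", "intermediate")
  withr::with_seed(99, {
    for (k in 1:8) {
      obs <- cross_observation(study_strains,
                               sample(phenos, 2, replace = TRUE),
                               sample(phenos, 2, replace = TRUE),
                               sample(phenos, 2, replace = TRUE),
                               sample(phenos, 2, replace = TRUE))
      expect_identical(infer_consistent_models(obs, models),
                       brute_force_consistent(obs, models))
    }
  })
})
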