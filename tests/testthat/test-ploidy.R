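# normalization, windows, and the composition calculus

test_that("normalization divides by the reference median", {
  nuclei <- tibble::tibble(integrated_intensity = c(10.5, 21, 5.25))
  ref <- c(9, 10, 11, 100, 8, 12, 10.5, 10.5, 9.5, 11.5)
  # oracle: direct median computation
  expect_equal(median(c(9, 10, 11, 100)), 10.5)
  out <- normalize_intensities(nuclei, reference = c(9, 10, 11, 100),
                               min_reference = 4)
  expect_equal(out$normalized_intensity, c(1, 2, 0.5))
  out2 <- normalize_intensities(nuclei, reference = ref)
  expect_equal(out2$normalized_intensity[2], 21 / median(ref))
})

test_that("too few reference nuclei is a refusal, not a fallback", {
  nuclei <- tibble::tibble(integrated_intensity = 1:5,
                           cd31_positive = c(TRUE, TRUE, rep(FALSE, 3)))
  expect_error(normalize_intensities(nuclei), "reference nuclei")
})

test_that("ploidy windows follow the documented boundary convention", {
  vals <- c(1.0, 2.0, 3.5, 2.7, 0.4, 1.5, 2.5)
  expect_equal(classify_ploidy(vals),
               c("2n", "4n", "8n", "unassigned", "unassigned", "4n", "unassigned"))
  # remaining boundaries: 0.5 enters the diploid window, 3.0 is still the gap
  expect_equal(classify_ploidy(c(0.5, 3.0, 3.0 + 1e-9)),
               c("2n", "unassigned", "8n"))
  expect_error(classify_ploidy(c(1, -0.1)), "negative")
})

test_that("normalization and calls are invariant to global rescaling", {
  withr::with_seed(1, {
    raw <- c(runif(40, 3000, 45000))
    ref <- runif(15, 4500, 5500)
  })
  nuclei <- tibble::tibble(integrated_intensity = raw)
  base <- call_nuclear_ploidy(normalize_intensities(nuclei, ref))
  for (c_scale in c(0.01, 7, 1234)) {
    scaled <- call_nuclear_ploidy(
      normalize_intensities(tibble::tibble(integrated_intensity = raw * c_scale),
                            ref * c_scale))
    expect_equal(scaled$normalized_intensity, base$normalized_intensity)
    expect_identical(scaled$ploidy_class, base$ploidy_class)
  }
})

test_that("the composition calculus reproduces the worked strain example", {
  # 1000 cardiomyocytes, 66 mononuclear of which 44 diploid
  pop <- build_population_tables(
    mono_classes = c(rep("2n", 44), rep("4n", 20), rep("8n", 2)),
    bi_classes = c(rep("2n", 850), rep("4n", 80), rep("8n", 4)))
  comp <- summarize_sample(pop$cells, pop$calls, "cardiomyocyte",
                           animal_id = "cJ")
  expect_equal(comp$n_cells_counted, 1000)
  expect_equal(comp$mononuclear_pct, 6.6)
  expect_equal(comp$binuclear_pct, 93.4)
  expect_equal(round(comp$mono_pct_2n, 1), 66.7)
  expect_equal(round(comp$diploid_cell_pct, 1), 4.4)
  # cell classes: both nuclei share the class by construction
  expect_equal(comp$cc_1x2n, 4.4)
  expect_equal(comp$cc_2x2n, 85.0)
})

test_that("an all-binuclear population has zero diploid-cell fraction", {
  pop <- build_population_tables(mono_classes = character(0),
                                 bi_classes = rep("2n", 200))
  comp <- suppressWarnings(
    summarize_sample(pop$cells, pop$calls, "cardiomyocyte", min_cells = 100))
  expect_equal(comp$mononuclear_pct, 0)
  expect_equal(comp$diploid_cell_pct, 0)
})

test_that("subgroup class percentages conserve mass", {
  withr::with_seed(7, {
    for (k in 1:5) {
      classes <- c("2n", "4n", "8n", "unassigned")
      pop <- build_population_tables(
        mono_classes = sample(classes, 150, replace = TRUE),
        bi_classes = sample(classes, 350, replace = TRUE))
      comp <- summarize_sample(pop$cells, pop$calls, "cardiomyocyte")
      expect_equal(comp$mono_pct_2n + comp$mono_pct_4n + comp$mono_pct_8n +
                     comp$mono_pct_un, 100, tolerance = 1e-9)
      expect_equal(comp$bi_pct_2n + comp$bi_pct_4n + comp$bi_pct_8n +
                     comp$bi_pct_un, 100, tolerance = 1e-9)
      expect_equal(comp$mononuclear_pct + comp$binuclear_pct, 100,
                   tolerance = 1e-9)
    }
  })
})

test_that("under-counted samples are flagged with a warning", {
  pop <- build_population_tables(mono_classes = rep("2n", 10),
                                 bi_classes = rep("2n", 40))
  expect_warning(comp <- summarize_sample(pop$cells, pop$calls, "cardiomyocyte"),
                 "flagged")
  expect_true(comp$flagged)
  expect_equal(comp$n_cells_counted, 50)
})

test_that("cells with three or more nuclei are excluded from the calculus", {
  pop <- build_population_tables(mono_classes = rep("2n", 50),
                                 bi_classes = rep("2n", 50))
  pop$cells$n_nuclei[1] <- 3L
  comp <- suppressWarnings(
    summarize_sample(pop$cells, pop$calls, "cardiomyocyte", min_cells = 10))
  expect_equal(comp$n_cells_counted, 99)
  expect_equal(comp$n_multi_excluded, 1)
})

test_that("subgroup combination equals the direct six-term expansion", {
  expect_equal(
    combine_subgroups(c(`2n` = 100, `4n` = 0, `8n` = 0),
                      c(`2n` = 100, `4n` = 0, `8n` = 0), 10, 90)$pct,
    c(10, 0, 0, 90, 0, 0, 0))
  expect_equal(
    combine_subgroups(c(`2n` = 66.7, `4n` = 29.3, `8n` = 4),
                      c(`2n` = 88, `4n` = 11, `8n` = 1), 6.6, 93.4)$pct[1],
    4.4, tolerance = 0.05)
  withr::with_seed(11, {
    for (k in 1:10) {
      m <- rexp(3); m <- 100 * m / sum(m)
      b <- rexp(3); b <- 100 * b / sum(b)
      f <- runif(1, 0, 100)
      names(m) <- names(b) <- c("2n", "4n", "8n")
      got <- combine_subgroups(m, b, f, 100 - f)
      want <- expand_six_classes(m, b, f, 100 - f)
      expect_equal(setNames(got$pct[1:6], got$cell_class[1:6]), want)
      expect_equal(sum(got$pct), 100, tolerance = 1e-9)
    }
  })
  expect_error(combine_subgroups(c(`2n` = -5, `4n` = 105, `8n` = 0),
                                 c(`2n` = 100, `4n` = 0, `8n` = 0), 50, 50),
               "negative")
})
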