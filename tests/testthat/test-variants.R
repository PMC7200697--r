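# synthetic variant panels and the substrain-private candidate filter

test_that("with no decoys the planted variants are the only calls", {
  panel <- generate_variant_panel(decoy_mix = c(rsid = 0), seed = 2)
  expect_equal(nrow(panel$calls), 2)
  res <- run_full_filter(panel)
  expect_equal(res$candidates$pos, c(74309969L, 141723152L))
})

test_that("the study variants are planted at their genomic coordinates", {
  panel <- generate_variant_panel(seed = 5)
  focal <- panel$calls[panel$calls$strain == "BALB_cByJ", ]
  gdi1 <- focal[focal$pos == 74309969, ]
  irs4 <- focal[focal$pos == 141723152, ]
  expect_equal(gdi1$chrom, "X"); expect_equal(gdi1$ref, "C"); expect_equal(gdi1$alt, "T")
  expect_equal(irs4$chrom, "X"); expect_equal(irs4$ref, "G"); expect_equal(irs4$alt, "A")
  expect_true(all(c(gdi1$genotype, irs4$genotype) == "hom_alt"))
  # absent from every other strain
  others <- panel$calls[panel$calls$strain != "BALB_cByJ", ]
  expect_false(any(others$pos %in% c(74309969, 141723152)))
})

test_that("panel generation is deterministic given the seed", {
  expect_identical(generate_variant_panel(seed = 31),
                   generate_variant_panel(seed = 31))
})

test_that("the QUAL boundary keeps calls at exactly 70", {
  base <- tibble::tibble(chrom = "X", pos = 100L, ref = "A", alt = "G",
                         qual = 70, genotype = "hom_alt",
                         rsid = NA_character_, consequence = "nonsynonymous")
  expect_equal(nrow(filter_focal_strain(base)$candidates), 1)
  low <- dplyr::mutate(base, qual = 69)
  res <- filter_focal_strain(low)
  expect_equal(nrow(res$candidates), 0)
  expect_equal(res$tally$removed[res$tally$rule == "quality"], 1L)
})

test_that("each removal rule fires on its own class", {
  mk <- function(...) {
    dplyr::mutate(tibble::tibble(chrom = "X", pos = 1L, ref = "A", alt = "G",
                                 qual = 99, genotype = "hom_alt",
                                 rsid = NA_character_,
                                 consequence = "nonsynonymous"), ...)
  }
  cases <- list(rsID = mk(rsid = "rs123"),
                zygosity = mk(genotype = "het"),
                chromosome = mk(chrom = "7"),
                consequence = mk(consequence = "synonymous"))
  for (rule in names(cases)) {
    res <- filter_focal_strain(cases[[rule]])
    expect_equal(nrow(res$candidates), 0)
    expect_equal(res$tally$removed[res$tally$rule == rule], 1L,
                 label = paste("rule", rule))
  }
  malformed <- mk(genotype = NA_character_)
  res <- filter_focal_strain(malformed)
  expect_equal(res$tally$removed[res$tally$rule == "malformed"], 1L)
})

test_that("survivors are identical under any rule ordering", {
  panel <- generate_variant_panel(seed = 13)
  focal <- panel$calls[panel$calls$strain == "BALB_cByJ", ]
  cfg <- filter_config()
  got <- filter_focal_strain(focal, cfg)$candidates
  # oracle: one conjunctive predicate, no sequencing at all
  keep <- (is.na(focal$rsid) | focal$rsid == ".") &
    focal$qual >= cfg$min_qual &
    !is.na(focal$genotype) & focal$genotype == "hom_alt" &
    focal$chrom %in% cfg$chrom_whitelist &
    focal$consequence %in% cfg$allowed_consequences
  expect_equal(dplyr::arrange(got, pos),
               dplyr::arrange(focal[keep, ], pos))
})

test_that("the filter is idempotent on its own output", {
  panel <- generate_variant_panel(seed = 21)
  res <- run_full_filter(panel)
  again <- subtract_shared(
    filter_focal_strain(res$candidates),
    panel$calls[panel$calls$strain == "BALB_cJ", ],
    panel$calls[!panel$calls$strain %in% c("BALB_cJ", "BALB_cByJ"), ])
  expect_equal(again$candidates, res$candidates)
})

test_that("survivors equal the planted truth over random panels", {
  withr::with_seed(1234, {
    for (k in 1:25) {
      mix <- c(rsid = sample(0:60, 1), low_qual = sample(0:60, 1),
               het = sample(0:60, 1), autosomal = sample(0:60, 1),
               shared_pair = sample(0:60, 1), shared_panel = sample(0:60, 1),
               synonymous = sample(0:20, 1))
      panel <- generate_variant_panel(n_strains = sample(3:10, 1),
                                      decoy_mix = mix, seed = 5000 + k)
      res <- run_full_filter(panel)
      want <- panel$truth[panel$truth$planted, c("chrom", "pos", "ref", "alt")]
      got <- res$candidates[, c("chrom", "pos", "ref", "alt")]
      expect_equal(as.data.frame(dplyr::arrange(got, pos)),
                   as.data.frame(dplyr::arrange(want, pos)))
    }
  })
})

test_that("VCF files round-trip the call table dialect", {
  skip_if_not_installed("vcfR")
  panel <- generate_variant_panel(seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_variant_vcf(panel$calls, dir)
  rt <- read_variant_vcf(paths[["BALB_cByJ"]], strain = "BALB_cByJ")
  orig <- dplyr::arrange(panel$calls[panel$calls$strain == "BALB_cByJ", ],
                         chrom, pos)
  expect_equal(as.data.frame(dplyr::arrange(rt, chrom, pos)[, names(orig)]),
               as.data.frame(orig))
})

test_that("hemizygous and phased genotypes parse correctly", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS",
    "X\t100\t.\tA\tG\t99\t.\tCSQ=nonsynonymous\tGT\t1",
    "X\t200\t.\tA\tG\t99\t.\tCSQ=nonsynonymous\tGT\t0|1",
    "X\t300\t.\tA\tG\t99\t.\tCSQ=nonsynonymous\tGT\t1|1",
    "X\t400\t.\tA\tG,T\t99\t.\tCSQ=nonsynonymous\tGT\t0/1"), path)
  calls <- read_variant_vcf(path)
  expect_equal(calls$genotype[calls$pos == 100], "hom_alt")
  expect_equal(calls$genotype[calls$pos == 200], "het")
  expect_equal(calls$genotype[calls$pos == 300], "hom_alt")
  # multi-allelic record split into one call per alt
  expect_equal(calls$alt[calls$pos == 400], c("G", "T"))
})

test_that("reports are complete for empty candidate sets and reproducible", {
  panel <- generate_variant_panel(planted_private = study_private_variants()[0, ],
                                  decoy_mix = c(rsid = 5, het = 5), seed = 6)
  res <- run_full_filter(panel)
  rep1 <- pipeline_report(res)
  expect_equal(rep1$n_candidates, 0)
  expect_true(any(grepl("none", rep1$text)))
  expect_equal(nrow(rep1$waterfall), 8)
  expect_identical(rep1, pipeline_report(run_full_filter(panel)))
})
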