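# segmentation and nucleus-to-cell assignment

make_two_blob_frame <- function() {
  f <- matrix(10, 128, 128)
  add <- function(f, r0, c0, I) {
    for (r in (r0 - 6):(r0 + 6)) for (cc in (c0 - 6):(c0 + 6)) {
      f[r, cc] <- f[r, cc] + I * exp(-((r - r0)^2 + (cc - c0)^2) / 8) / (2 * pi * 4)
    }
    f
  }
  f <- add(f, 30, 30, 4000)
  add(f, 90, 90, 8000)
}

test_that("disjoint supra-threshold blobs give one record each", {
  f <- make_two_blob_frame()
  nuc <- segment_nuclei(f, threshold = 50)
  expect_equal(nrow(nuc), 2)
  expect_false(any(nuc$flagged))
})

test_that("a blank frame yields zero records, not an error", {
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64), threshold = 10)), 0)
  expect_equal(nrow(segment_nuclei(matrix(5, 64, 64), threshold = 10)), 0)
})

test_that("saturated frames trigger a warning", {
  f <- matrix(0.2, 64, 64)
  f[1:10, 1:30] <- 1
  expect_warning(segment_nuclei(f, threshold = 0.5, saturation_level = 1),
                 "saturated")
})

test_that("zero-noise synthetic frames are recovered exactly", {
  spec <- strain_population_spec("BALB/cJ", n_cells = 60, n_endothelial = 20,
                                 seed = 5, intensity_cv = 0, viability_prob = 1)
  truth <- generate_population(spec)
  rnd <- render_images(truth, imaging_spec(additive_noise_sd = 0), seed = 5)
  q <- quantify_frames(rnd)
  # recall 1.0 against the placement map
  expect_equal(nrow(q$nuclei), nrow(rnd$placement))
  # per-nucleus intensity within 2% of ground truth (matched by position)
  pl <- rnd$placement
  for (i in seq_len(nrow(q$nuclei))) {
    d <- (pl$row - q$nuclei$row[i])^2 + (pl$col - q$nuclei$col[i])^2 +
      1e9 * (pl$frame != q$nuclei$frame[i])
    j <- which.min(d)
    expect_lt(abs(q$nuclei$integrated_intensity[i] - pl$true_intensity[j]) /
                pl$true_intensity[j], 0.02)
  }
  # nucleation matches the ground truth cell for cell
  got <- q$cells |> dplyr::count(cell_type, n_nuclei)
  want <- cells_from_truth(truth) |> dplyr::count(cell_type, n_nuclei)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("integrated intensities are equivariant to global rescaling", {
  f <- make_two_blob_frame()
  base <- segment_nuclei(f, threshold = 50)
  for (c_scale in c(0.5, 3, 17.2)) {
    scaled <- segment_nuclei(f * c_scale, threshold = 50 * c_scale)
    expect_equal(scaled$integrated_intensity,
                 base$integrated_intensity * c_scale, tolerance = 1e-10)
    expect_equal(scaled$row, base$row)
    expect_equal(scaled$area, base$area)
  }
})

test_that("per-nucleus intensities never exceed the frame total", {
  f <- make_two_blob_frame()
  nuc <- segment_nuclei(f, threshold = 50)
  bg <- median(f[f <= 50])
  expect_lte(sum(nuc$integrated_intensity), sum(f - bg))
})

test_that("nuclei outside all marker masks are typed unknown", {
  f <- matrix(10, 128, 128)
  f[28:32, 28:32] <- 1000
  nuc <- segment_nuclei(f, threshold = 100, min_area = 4)
  asn <- assign_nuclei_to_cells(nuc, matrix(0, 128, 128), matrix(0, 128, 128))
  expect_equal(asn$cells$cell_type, "unknown")
  expect_equal(nrow(asn$cells), 1)
})

test_that("two nuclei in one lineage component form one binuclear cell", {
  f <- matrix(10, 128, 128)
  f[28:32, 28:32] <- 1000
  f[28:32, 44:48] <- 1000
  lineage <- matrix(0, 128, 128)
  lineage[20:56, 20:56] <- 1
  nuc <- segment_nuclei(f, threshold = 100, min_area = 4)
  asn <- assign_nuclei_to_cells(nuc, lineage, matrix(0, 128, 128))
  expect_equal(nrow(asn$cells), 1)
  expect_equal(asn$cells$n_nuclei, 2L)
  expect_equal(asn$cells$cell_type, "cardiomyocyte")
})

test_that("marker collisions are resolved by the stronger marker", {
  f <- matrix(10, 64, 64)
  f[30:34, 30:34] <- 1000
  lineage <- matrix(0, 64, 64); lineage[25:40, 25:40] <- 0.6
  cd31 <- matrix(0, 64, 64); cd31[25:40, 25:40] <- 0.9
  nuc <- segment_nuclei(f, threshold = 100, min_area = 4)
  expect_message(asn <- assign_nuclei_to_cells(nuc, lineage, cd31),
                 "both marker masks")
  expect_equal(asn$cells$cell_type, "endothelial")
})
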