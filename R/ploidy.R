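#' Ploidy class windows on the normalized intensity axis
#'
#' With the endothelial diploid standard at 1, nuclei are diploid (2n) in
#' \[0.5, 1.5), tetraploid (4n) in \[1.5, 2.5), and octoploid (8n) above 3.
#' Values below 0.5 (debris/apoptotic) and in the undefined (2.5, 3\] gap are
#' `unassigned`: they are counted and reported, never imputed. Windows are
#' taken closed-left/open-right so every value has exactly one class.
#'
#' @param diploid,tetraploid Two-element numeric `[lo, hi)` windows.
#' @param octoploid_min Lower edge of the octoploid window (exclusive).
#' @return An object of class `ploidy_bins`.
#' @export
ploidy_bins <- function(diploid = c(0.5, 1.5), tetraploid = c(1.5, 2.5),
                        octoploid_min = 3) {
  if (diploid[2] > tetraploid[1]) abort("diploid and tetraploid windows overlap")
  if (tetraploid[2] > octoploid_min) abort("tetraploid and octoploid windows overlap")
  structure(list(diploid = diploid, tetraploid = tetraploid,
                 octoploid_min = octoploid_min),
            class = "ploidy_bins")
}

#' Classify normalized intensities into nuclear ploidy classes
#'
#' @param x Numeric vector of normalized intensities (diploid standard = 1).
#' @param bins A [ploidy_bins()] object.
#' @return Character vector in `{"2n", "4n", "8n", "unassigned"}`.
#' @export
classify_ploidy <- function(x, bins = ploidy_bins()) {
  if (any(is.na(x)) || any(x < 0)) {
    bad <- which(is.na(x) | x < 0)
    abort(paste0("negative or missing normalized intensity at position(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  dplyr::case_when(
    x >= bins$diploid[1] & x < bins$diploid[2] ~ "2n",
    x >= bins$tetraploid[1] & x < bins$tetraploid[2] ~ "4n",
    x > bins$octoploid_min ~ "8n",
    TRUE ~ "unassigned"
  )
}

#' Normalize nuclear intensities to the endothelial diploid standard
#'
#' The median integrated DAPI intensity of CD31-positive endothelial nuclei
#' defines the diploid standard and is given the value 1; every nuclear
#' intensity is expressed relative to it. The result is invariant under a
#' global rescaling of all raw intensities. With fewer than `min_reference`
#' reference nuclei the function refuses: there is no fallback standard.
#'
#' @param nuclei Tibble with an `integrated_intensity` column and, unless
#'   `reference` is given, a logical `cd31_positive` column.
#' @param reference Optional tibble (or numeric vector) of reference
#'   intensities; defaults to the CD31-positive rows of `nuclei`.
#' @param min_reference Minimum number of reference nuclei (default 10).
#' @return `nuclei` with a `normalized_intensity` column added.
#' @export
normalize_intensities <- function(nuclei, reference = NULL, min_reference = 10L) {
  ref <- if (is.null(reference)) {
    if (!"cd31_positive" %in% names(nuclei)) {
      abort("no `reference` given and `nuclei` has no `cd31_positive` column")
    }
    nuclei$integrated_intensity[nuclei$cd31_positive]
  } else if (is.data.frame(reference)) {
    reference$integrated_intensity
  } else as.numeric(reference)
  ref <- ref[!is.na(ref)]
  if (length(ref) < min_reference) {
    abort(paste0("only ", length(ref), " CD31-positive reference nuclei; ",
                 "at least ", min_reference,
                 " are required for the diploid standard"))
  }
  standard <- stats::median(ref)
  if (standard <= 0) abort("diploid standard median is not positive")
  dplyr::mutate(nuclei, normalized_intensity = .data$integrated_intensity / standard)
}

#' Call nuclear ploidy for a nucleus table
#'
#' @param nuclei Tibble with a `normalized_intensity` column (see
#'   [normalize_intensities()]).
#' @param bins A [ploidy_bins()] object.
#' @return `nuclei` with a `ploidy_class` column added.
#' @export
call_nuclear_ploidy <- function(nuclei, bins = ploidy_bins()) {
  dplyr::mutate(nuclei, ploidy_class = classify_ploidy(.data$normalized_intensity, bins))
}

#' Mononuclear-diploid cell fraction from its two defining percentages
#'
#' The fraction of cells that are mononuclear diploid equals the mononuclear
#' cell percentage times the diploid percentage of mononuclear nuclei, e.g.
#' 6.6% x 66.7% = 4.4%. Reported to one decimal.
#'
#' @param mononuclear_pct Mononuclear cell percentage (0..100).
#' @param mono_2n_pct Percentage of mononuclear-cell nuclei called 2n.
#' @param digits Rounding digits (default 1).
#' @return The diploid-cell percentage.
#' @export
diploid_cell_fraction <- function(mononuclear_pct, mono_2n_pct, digits = 1) {
  if (any(mononuclear_pct < 0) || any(mono_2n_pct < 0)) {
    abort("percentages must be nonnegative")
  }
  round(mononuclear_pct * mono_2n_pct / 100, digits)
}

#' Combine subgroup ploidy spectra into a cell-class distribution
#'
#' Weights the per-subgroup nuclear class spectra by the mononuclear and
#' binuclear cell percentages: class `1xk` gets `mono_fraction * mono %k /
#' 100` and class `2xk` gets `bi_fraction * bi %k / 100` for k in
#' {2n, 4n, 8n}. The output sums to 100 minus the unassigned mass.
#'
#' @param mono_dist,bi_dist Named numeric vectors (names `2n`, `4n`, `8n`,
#'   optionally `unassigned`) summing to 100.
#' @param mono_fraction,bi_fraction Cell percentages summing to 100.
#' @return Tibble with `cell_class` (`1x2n`, `1x4n`, `1x8n`, `2x2n`, `2x4n`,
#'   `2x8n`, `unassigned`) and `pct`.
#' @export
combine_subgroups <- function(mono_dist, bi_dist, mono_fraction, bi_fraction) {
  if (any(c(mono_dist, bi_dist, mono_fraction, bi_fraction) < 0)) {
    abort("negative inputs to the subgroup combination")
  }
  if (abs(mono_fraction + bi_fraction - 100) > 1e-6) {
    abort("mono_fraction + bi_fraction must equal 100")
  }
  for (d in list(mono_dist, bi_dist)) {
    if (abs(sum(d) - 100) > 1e-6) abort("subgroup distributions must sum to 100")
  }
  k <- c("2n", "4n", "8n")
  get0n <- function(d, kk) if (kk %in% names(d)) d[[kk]] else 0
  pct <- c(
    purrr::map_dbl(k, ~ mono_fraction * get0n(mono_dist, .x) / 100),
    purrr::map_dbl(k, ~ bi_fraction * get0n(bi_dist, .x) / 100)
  )
  unassigned <- mono_fraction * get0n(mono_dist, "unassigned") / 100 +
    bi_fraction * get0n(bi_dist, "unassigned") / 100
  tibble(cell_class = c(paste0("1x", k), paste0("2x", k), "unassigned"),
         pct = c(pct, unassigned))
}

# minimum cells to count per sample before a composition is trusted
.min_cells_default <- c(cardiomyocyte = 300L, hepatocyte = 200L,
                        marrow = 400L, endothelial = 100L, unknown = 0L)

#' Summarise a sample into its nucleation-by-ploidy composition
#'
#' Computes, over viable QC-passing cells of one type, the mononuclear and
#' binuclear percentages, the nuclear ploidy spectrum within each nucleation
#' subgroup, the combined cell-class distribution (1x2n ... 2x8n), and the
#' mononuclear-diploid cell fraction (mononuclear % x mono %2n / 100). Cells
#' with three or more detected nuclei are excluded from the mono/binuclear
#' calculus and counted separately. Compositions from fewer than `min_cells`
#' cells are computed but flagged.
#'
#' @param cells Tibble with `cell_id`, `cell_type`, `viable`, `n_nuclei`
#'   (e.g. from [quantify_frames()] or [cells_from_truth()]).
#' @param calls Tibble with `cell_id` and `ploidy_class` per nucleus (from
#'   [call_nuclear_ploidy()]).
#' @param cell_type Which cell type to summarise.
#' @param animal_id Sample label carried into the output.
#' @param viability_filter Keep viable cells only? Default `TRUE`.
#' @param min_cells Minimum cell count; defaults to 300 for cardiomyocytes,
#'   200 for hepatocytes, 400 for marrow.
#' @return A one-row tibble: counts, subgroup percentages (`mono_pct_2n`,
#'   ..., including `*_unassigned` so each subgroup sums to 100), cell-class
#'   percentages (`cc_1x2n`, ...), `diploid_cell_pct`, and a `flagged`
#'   column marking under-counted samples.
#' @export
summarize_sample <- function(cells, calls, cell_type = "cardiomyocyte",
                             animal_id = "sample", viability_filter = TRUE,
                             min_cells = NULL) {
  min_cells <- min_cells %||% .min_cells_default[[cell_type]] %||% 0L
  cc <- dplyr::filter(cells, .data$cell_type == !!cell_type)
  if (viability_filter) cc <- dplyr::filter(cc, .data$viable)
  if (!"qc_multi" %in% names(cc)) cc$qc_multi <- cc$n_nuclei >= 3L
  n_multi <- sum(cc$qc_multi)
  cc <- dplyr::filter(cc, !.data$qc_multi)
  n_counted <- nrow(cc)
  flagged <- n_counted < min_cells
  if (flagged) {
    warn(paste0(animal_id, ": only ", n_counted, " ", cell_type,
                " cells counted (minimum ", min_cells, "); composition flagged"))
  }
  if (n_counted == 0) {
    abort(paste0("no QC-passing ", cell_type, " cells to summarise"))
  }
  mono_cells <- cc$cell_id[cc$n_nuclei == 1L]
  bi_cells <- cc$cell_id[cc$n_nuclei == 2L]
  mono_pct <- 100 * length(mono_cells) / n_counted
  bi_pct <- 100 * length(bi_cells) / n_counted

  lv <- c("2n", "4n", "8n", "unassigned")
  sub_dist <- function(ids) {
    sub <- calls[calls$cell_id %in% ids, ]
    if (nrow(sub) == 0) return(setNames(rep(NA_real_, 4), lv))
    100 * as.numeric(table(factor(sub$ploidy_class, levels = lv))) / nrow(sub)
  }
  mono_dist <- setNames(sub_dist(mono_cells), lv)
  bi_dist <- setNames(sub_dist(bi_cells), lv)

  # cell classes: both nuclei of a binuclear cell must share the class
  cell_class <- calls[calls$cell_id %in% cc$cell_id, ] |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      k = dplyr::n(),
      cls = if (dplyr::n_distinct(.data$ploidy_class) == 1L)
        .data$ploidy_class[1] else "unassigned",
      .groups = "drop") |>
    dplyr::mutate(cell_class = dplyr::if_else(
      .data$cls == "unassigned", "unassigned",
      paste0(.data$k, "x", .data$cls)))
  classes <- c("1x2n", "1x4n", "1x8n", "2x2n", "2x4n", "2x8n", "unassigned")
  cc_pct <- 100 * as.numeric(table(factor(cell_class$cell_class, levels = classes))) /
    n_counted

  out <- tibble(
    animal_id = animal_id, cell_type = cell_type,
    n_cells_counted = n_counted, n_multi_excluded = n_multi,
    mononuclear_pct = mono_pct, binuclear_pct = bi_pct,
    diploid_cell_pct = if (mono_pct == 0) 0 else mono_pct * mono_dist[["2n"]] / 100,
    flagged = flagged
  )
  for (i in seq_along(lv)) {
    out[[paste0("mono_pct_", sub("unassigned", "un", lv[i]))]] <- mono_dist[[i]]
    out[[paste0("bi_pct_", sub("unassigned", "un", lv[i]))]] <- bi_dist[[i]]
  }
  for (i in seq_along(classes)) {
    out[[paste0("cc_", sub("unassigned", "other", classes[i]))]] <- cc_pct[i]
  }
  out
}

#' One-stop composition from a ground-truth cell table
#'
#' Table-level entry point that bypasses imaging: treats `true_intensity` as
#' the measured integrated intensity, normalizes to the endothelial median,
#' calls ploidy and summarises. Useful for spec'd populations and for CSV
#' input produced elsewhere.
#'
#' @param truth Nucleus-level tibble (see [generate_population()]).
#' @param cell_type Cell type to summarise.
#' @param animal_id Sample label.
#' @param bins,min_reference,min_cells Passed through.
#' @return A one-row composition tibble (see [summarize_sample()]).
#' @export
compose_from_truth <- function(truth, cell_type = "cardiomyocyte",
                               animal_id = "sample", bins = ploidy_bins(),
                               min_reference = 10L, min_cells = NULL) {
  nuclei <- truth |>
    dplyr::mutate(integrated_intensity = .data$true_intensity,
                  cd31_positive = .data$cell_type == "endothelial")
  calls <- nuclei |>
    normalize_intensities(min_reference = min_reference) |>
    call_nuclear_ploidy(bins)
  cells <- cells_from_truth(truth)
  summarize_sample(cells, calls, cell_type = cell_type, animal_id = animal_id,
                   min_cells = min_cells)
}
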