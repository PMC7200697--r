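#' Describe a synthetic cell population
#'
#' A population spec fixes, per cell type, how many cells to draw, the
#' probability of a cell being mono- vs binucleated, and the nuclear ploidy
#' distribution (genome copies per nucleus, 2/4/8) within each nucleation
#' subgroup. Binucleated cells carry one ploidy class shared by both nuclei,
#' reflecting their origin in a single interrupted mitosis. The integrated
#' DAPI intensity of a nucleus is proportional to its genome copy number with
#' multiplicative lognormal noise of coefficient of variation `intensity_cv`.
#'
#' Endothelial cells are constrained to be mononucleated and diploid: they are
#' the diploid reference standard downstream, and suspensions show them
#' uniformly mononucleated with narrowly clustered DAPI intensity.
#'
#' @param n_cells Named integer vector of cell counts, names among
#'   `"cardiomyocyte"`, `"hepatocyte"`, `"endothelial"`, `"marrow"`.
#' @param nucleation_probs Named list: per cell type, a probability vector
#'   over nucleus counts, names `"1"` and `"2"`.
#' @param ploidy_probs Named list: per cell type, a list with entries `"1"`
#'   and `"2"` (nucleation), each a probability vector over genome copies per
#'   nucleus with names `"2"`, `"4"`, `"8"`.
#' @param intensity_cv Coefficient of variation of the multiplicative
#'   lognormal intensity noise (unitless, >= 0).
#' @param reference_intensity Mean integrated intensity of one diploid
#'   nucleus, in arbitrary units.
#' @param viability_prob Fraction of live cells (0..1).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return An object of class `population_spec`.
#' @seealso [strain_population_spec()] for presets at the measured substrain
#'   parameters, [generate_population()] to draw cells.
#' @export
population_spec <- function(n_cells,
                            nucleation_probs = NULL,
                            ploidy_probs = NULL,
                            intensity_cv = 0.08,
                            reference_intensity = 5000,
                            viability_prob = 0.9,
                            seed = 1L) {
  types <- names(n_cells)
  if (is.null(types) || any(!nzchar(types))) {
    abort("`n_cells` must be a named vector of cell counts")
  }
  bad <- setdiff(types, c("cardiomyocyte", "hepatocyte", "endothelial", "marrow"))
  if (length(bad)) abort(paste0("unknown cell type(s): ", paste(bad, collapse = ", ")))
  if (any(n_cells < 0)) abort("all cell counts must be >= 0")
  if (intensity_cv < 0) abort("`intensity_cv` must be >= 0")
  if (reference_intensity <= 0) abort("`reference_intensity` must be > 0")
  if (viability_prob < 0 || viability_prob > 1) abort("`viability_prob` must be in [0, 1]")

  nucleation_probs <- nucleation_probs %||% list()
  ploidy_probs <- ploidy_probs %||% list()
  for (ty in types) {
    nucleation_probs[[ty]] <- nucleation_probs[[ty]] %||% .default_nucleation[[ty]]
    ploidy_probs[[ty]] <- ploidy_probs[[ty]] %||% .default_ploidy[[ty]]
  }
  # endothelial cells are the diploid standard: force 1 x 2n
  if ("endothelial" %in% types) {
    nucleation_probs$endothelial <- c(`1` = 1, `2` = 0)
    ploidy_probs$endothelial <- list(`1` = c(`2` = 1, `4` = 0, `8` = 0),
                                     `2` = c(`2` = 1, `4` = 0, `8` = 0))
  }
  for (ty in types) {
    check_prob_vector(nucleation_probs[[ty]][c("1", "2")],
                      paste0("nucleation_probs$", ty))
    for (k in c("1", "2")) {
      check_prob_vector(ploidy_probs[[ty]][[k]][c("2", "4", "8")],
                        paste0("ploidy_probs$", ty, "$", k))
    }
  }
  structure(
    list(n_cells = n_cells, nucleation_probs = nucleation_probs,
         ploidy_probs = ploidy_probs, intensity_cv = intensity_cv,
         reference_intensity = reference_intensity,
         viability_prob = viability_prob, seed = as.integer(seed)),
    class = "population_spec"
  )
}

# Fallback composition for types without explicit parameters. Marrow cells
# are uniformly mononucleated with a modest polyploid minority (mitotic cells
# and megakaryocytes).
.default_nucleation <- list(
  cardiomyocyte = c(`1` = 0.10, `2` = 0.90),
  hepatocyte    = c(`1` = 0.43, `2` = 0.57),
  endothelial   = c(`1` = 1.00, `2` = 0.00),
  marrow        = c(`1` = 1.00, `2` = 0.00)
)

.default_ploidy <- list(
  cardiomyocyte = list(`1` = c(`2` = 0.55, `4` = 0.40, `8` = 0.05),
                       `2` = c(`2` = 0.90, `4` = 0.09, `8` = 0.01)),
  hepatocyte    = list(`1` = c(`2` = 0.30, `4` = 0.55, `8` = 0.15),
                       `2` = c(`2` = 0.65, `4` = 0.30, `8` = 0.05)),
  endothelial   = list(`1` = c(`2` = 1, `4` = 0, `8` = 0),
                       `2` = c(`2` = 1, `4` = 0, `8` = 0)),
  marrow        = list(`1` = c(`2` = 0.95, `4` = 0.04, `8` = 0.01),
                       `2` = c(`2` = 1, `4` = 0, `8` = 0))
)

# Measured parameters for the two BALB substrains: mononuclear fraction and
# the diploid share of mononuclear nuclei are known per strain;
# binuclear spectra are set so that 2 x 2n remains the most common polyploid
# cardiomyocyte class in both strains, with the cByJ spectrum shifted towards
# octoploidy.
.strain_params <- list(
  `BALB/cJ` = list(
    cardiomyocyte = list(mono = 0.066, mono_ploidy = c(`2` = 0.667, `4` = 0.293, `8` = 0.040),
                         bi_ploidy = c(`2` = 0.88, `4` = 0.11, `8` = 0.01)),
    hepatocyte = list(mono = 0.437, mono_ploidy = c(`2` = 0.319, `4` = 0.546, `8` = 0.135),
                      bi_ploidy = c(`2` = 0.70, `4` = 0.26, `8` = 0.04))
  ),
  `BALB/cByJ` = list(
    cardiomyocyte = list(mono = 0.143, mono_ploidy = c(`2` = 0.376, `4` = 0.474, `8` = 0.150),
                         bi_ploidy = c(`2` = 0.75, `4` = 0.22, `8` = 0.03)),
    hepatocyte = list(mono = 0.426, mono_ploidy = c(`2` = 0.268, `4` = 0.532, `8` = 0.200),
                      bi_ploidy = c(`2` = 0.60, `4` = 0.33, `8` = 0.07))
  )
)

#' Population spec preset at the measured substrain parameters
#'
#' Builds a [population_spec()] whose cardiomyocyte (or hepatocyte)
#' mononuclear fraction and mononuclear nuclear-ploidy spectrum equal the
#' values reported for the BALB/cJ and BALB/cByJ substrains (e.g. 6.6% vs
#' 14.3% mononuclear cardiomyocytes; 66.7% vs 37.6% diploid mononuclear
#' nuclei). A complement of endothelial reference cells is always included.
#'
#' @param strain `"BALB/cJ"` or `"BALB/cByJ"`.
#' @param cell_type `"cardiomyocyte"` or `"hepatocyte"`.
#' @param n_cells Number of cells of `cell_type` to draw.
#' @param n_endothelial Number of endothelial reference cells.
#' @param ... Passed on to [population_spec()] (noise, seed, ...).
#' @return A `population_spec`.
#' @export
strain_population_spec <- function(strain = c("BALB/cJ", "BALB/cByJ"),
                                   cell_type = c("cardiomyocyte", "hepatocyte"),
                                   n_cells = 1000L, n_endothelial = 100L, ...) {
  strain <- match.arg(strain)
  cell_type <- match.arg(cell_type)
  par <- .strain_params[[strain]][[cell_type]]
  n <- setNames(c(n_cells, n_endothelial), c(cell_type, "endothelial"))
  nuc <- list(c(`1` = par$mono, `2` = 1 - par$mono))
  pl <- list(list(`1` = par$mono_ploidy, `2` = par$bi_ploidy))
  names(nuc) <- cell_type
  names(pl) <- cell_type
  population_spec(n, nucleation_probs = nuc, ploidy_probs = pl, ...)
}

#' Draw a ground-truth cell table from a population spec
#'
#' Samples cells per the spec: counts per type are exact, nucleation and
#' per-cell nuclear ploidy are drawn from the spec distributions, and each
#' nucleus receives `true_intensity = reference_intensity * (copies / 2) *
#' lognormal(mean 1, cv)`. With `intensity_cv = 0` intensities are exactly
#' proportional to genome copy number. Deterministic given `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @return A tibble with one row per nucleus: `cell_id`, `cell_type`,
#'   `viable`, `nucleus_index`, `true_copies`, `true_intensity`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(derive_seed(spec$seed, "population"), {
    cells <- purrr::imap(spec$n_cells, function(n, ty) {
      if (n == 0) return(NULL)
      n_nuclei <- sample(c(1L, 2L), n, replace = TRUE,
                         prob = spec$nucleation_probs[[ty]][c("1", "2")])
      copies <- integer(n)
      for (k in c(1L, 2L)) {
        idx <- which(n_nuclei == k)
        if (length(idx)) {
          copies[idx] <- sample(c(2L, 4L, 8L), length(idx), replace = TRUE,
                                prob = spec$ploidy_probs[[ty]][[as.character(k)]][c("2", "4", "8")])
        }
      }
      tibble(cell_type = ty, n_nuclei = n_nuclei, true_copies = copies,
             viable = runif(n) < spec$viability_prob)
    })
    cells <- dplyr::bind_rows(cells)
    cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))
    nuclei <- tidyr::uncount(cells, weights = .data$n_nuclei, .id = "nucleus_index")
    cv <- spec$intensity_cv
    noise <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(nrow(nuclei), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(nuclei))
    nuclei$true_intensity <-
      spec$reference_intensity * (nuclei$true_copies / 2) * noise
    dplyr::select(nuclei, "cell_id", "cell_type", "viable",
                  "nucleus_index", "true_copies", "true_intensity")
  })
}

#' Collapse a ground-truth nucleus table to one row per cell
#'
#' @param truth Tibble from [generate_population()].
#' @return Tibble with `cell_id`, `cell_type`, `viable`, `n_nuclei`.
#' @export
cells_from_truth <- function(truth) {
  truth |>
    dplyr::group_by(.data$cell_id, .data$cell_type, .data$viable) |>
    dplyr::summarise(n_nuclei = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$cell_id)
}

#' Read/write the ground-truth cell table CSV dialect
#'
#' One row per nucleus: `cell_id, cell_type, viable, nucleus_index,
#' true_copies, true_intensity`.
#'
#' @param truth Tibble as returned by [generate_population()].
#' @param path File path.
#' @return `read_cell_table()` returns the tibble; `write_cell_table()`
#'   returns `path` invisibly.
#' @export
write_cell_table <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    cell_id = readr::col_character(),
                    cell_type = readr::col_character(),
                    viable = readr::col_logical(),
                    nucleus_index = readr::col_integer(),
                    true_copies = readr::col_integer(),
                    true_intensity = readr::col_double()))
}
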