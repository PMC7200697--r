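#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram geom_vline
#'   labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Stacked cell-class composition per animal
#'
#' Bar chart of the combined nucleation-by-ploidy cell classes (1x2n ...
#' 2x8n) for a stack of per-animal compositions, optionally faceted by a
#' grouping column such as strain.
#'
#' @param comps Composition tibble (rows from [summarize_sample()], possibly
#'   with extra grouping columns).
#' @param facet_by Optional column name (string) to facet on.
#' @return A ggplot object.
#' @export
plot_composition <- function(comps, facet_by = NULL) {
  long <- comps |>
    tidyr::pivot_longer(dplyr::starts_with("cc_"), names_to = "cell_class",
                        values_to = "pct") |>
    dplyr::mutate(cell_class = sub("^cc_", "", .data$cell_class))
  p <- ggplot(long, aes(x = .data$animal_id, y = .data$pct,
                        fill = .data$cell_class)) +
    geom_col() +
    labs(x = NULL, y = "% of cells", fill = "cell class") +
    theme_minimal()
  if (!is.null(facet_by)) {
    p <- p + facet_wrap(stats::as.formula(paste("~", facet_by)), scales = "free_x")
  }
  p
}

#' Normalized DNA-content histogram with the ploidy windows
#'
#' The classic DNA-content view: a histogram of normalized nuclear
#' intensities (diploid standard = 1) with the 2n/4n window edges and the
#' octoploid lower bound marked.
#'
#' @param calls Nucleus tibble with a `normalized_intensity` column.
#' @param bins A [ploidy_bins()] object (drawn as vertical lines).
#' @param binwidth Histogram bin width on the normalized axis.
#' @return A ggplot object.
#' @export
plot_dna_content <- function(calls, bins = ploidy_bins(), binwidth = 0.05) {
  edges <- c(bins$diploid, bins$tetraploid[2], bins$octoploid_min)
  ggplot(calls, aes(x = .data$normalized_intensity)) +
    geom_histogram(binwidth = binwidth, fill = "grey40") +
    geom_vline(xintercept = edges, linetype = "dashed", colour = "firebrick") +
    labs(x = "normalized DAPI intensity (diploid standard = 1)",
         y = "nuclei") +
    theme_minimal()
}

#' @describeIn simulate_backcross Histogram of the per-replicate
#'   homozygous-recurrent genome fraction.
#' @param object A `backcross_sim`.
#' @param ... Unused.
#' @method autoplot backcross_sim
#' @export
autoplot.backcross_sim <- function(object, ...) {
  ggplot(object$replicates, aes(x = 100 * .data$hom_recurrent_frac)) +
    geom_histogram(bins = 40, fill = "grey40") +
    labs(x = "% genome homozygous for the recurrent parent",
         y = "replicates") +
    theme_minimal()
}
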