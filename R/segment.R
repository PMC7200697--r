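#' Otsu threshold of a pooled intensity histogram
#'
#' The same threshold must be applied to every frame of a study ("a standard
#' threshold requirement for all samples"), so the histogram is pooled over
#' all frames before Otsu's between-class variance criterion is maximised.
#'
#' @param frames A list of numeric matrices (DAPI frames).
#' @param n_breaks Number of histogram bins.
#' @return The threshold, in frame intensity units.
#' @export
pooled_otsu <- function(frames, n_breaks = 512L) {
  rng <- range(purrr::map_dbl(frames, min), purrr::map_dbl(frames, max))
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_breaks + 1)
  counts <- Reduce(`+`, purrr::map(frames, function(f) {
    tabulate(findInterval(f, breaks, rightmost.closed = TRUE), n_breaks)
  }))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- counts / sum(counts)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Segment nuclei in a DAPI frame and measure integrated intensity
#'
#' Supra-threshold connected components of at least `min_area` pixels are
#' nuclei. The background estimate is the median of sub-threshold pixels; the
#' integrated intensity of a nucleus is the background-subtracted pixel sum
#' over its component grown by `dilate_radius` pixels (a measurement aperture
#' that recovers the blurred tail of the nuclear signal lost to
#' thresholding). Records whose background subtraction overshoots to a
#' non-positive total are flagged, never dropped.
#'
#' @param frame Single-channel nonnegative numeric matrix.
#' @param threshold Absolute intensity threshold (e.g. from [pooled_otsu()]).
#' @param min_area Minimum component area in pixels.
#' @param dilate_radius Measurement-aperture growth in pixels.
#' @param saturation_level Optional dtype maximum; if >= 1% of pixels sit at
#'   it a saturation warning is raised.
#' @return Tibble with one row per nucleus: `nucleus_id`, `row`, `col`
#'   (0-based centroid), `area` (px^2 of the thresholded component),
#'   `integrated_intensity` (a.u.), `flagged`.
#' @export
segment_nuclei <- function(frame, threshold, min_area = 9L,
                           dilate_radius = 6L, saturation_level = NULL) {
  if (any(frame < 0)) abort("frame must be nonnegative")
  if (!is.null(saturation_level) && mean(frame >= saturation_level) >= 0.01) {
    warn("saturated frame: >= 1% of pixels at the dtype maximum")
  }
  mask <- frame > threshold
  if (!any(mask)) {
    return(tibble(nucleus_id = integer(), row = double(), col = double(),
                  area = integer(), integrated_intensity = double(),
                  flagged = logical()))
  }
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (!length(keep)) {
    return(tibble(nucleus_id = integer(), row = double(), col = double(),
                  area = integer(), integrated_intensity = double(),
                  flagged = logical()))
  }
  lab[!(lab %in% keep)] <- 0L
  background <- stats::median(frame[!mask])
  # measurement aperture: grow the union mask, then split the grown region
  # between components by proximity so no nucleus annexes a neighbour's tail
  brush <- EBImage::makeBrush(2L * dilate_radius + 1L, shape = "disc")
  dmask <- EBImage::dilate(lab > 0, brush)
  dlab <- EBImage::propagate(frame, seeds = lab, mask = dmask, lambda = 1e8)
  out <- purrr::map(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    didx <- dlab == l
    intensity <- sum(frame[didx] - background)
    tibble(nucleus_id = l, row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1,
           area = nrow(idx), integrated_intensity = intensity,
           flagged = intensity <= 0)
  })
  dplyr::bind_rows(out)
}

#' Group segmented nuclei into typed cells via the marker channels
#'
#' Nuclei whose centroids fall inside one lineage-marker component form one
#' cell of `lineage_type`; nuclei inside a CD31 component are endothelial;
#' nuclei in neither mask are typed `unknown`, one cell per nucleus. A
#' nucleus inside both masks is assigned to the marker with the larger local
#' intensity, and the collision is counted in the `collisions` attribute.
#'
#' @param nuclei Tibble from [segment_nuclei()].
#' @param lineage_frame,cd31_frame Marker channel matrices, co-registered
#'   with the DAPI frame.
#' @param marker_threshold Threshold applied to both marker channels.
#' @param lineage_type Cell type of lineage-positive cells.
#' @return A list with `nuclei` (input plus `cell_id`, `lineage_positive`,
#'   `cd31_positive`) and `cells` (one row per cell: `cell_id`, `cell_type`,
#'   `n_nuclei`, `viable`, `qc_multi`).
#' @export
assign_nuclei_to_cells <- function(nuclei, lineage_frame, cd31_frame,
                                   marker_threshold = 0.5,
                                   lineage_type = "cardiomyocyte") {
  lab_lin <- EBImage::bwlabel(lineage_frame > marker_threshold)
  lab_cd <- EBImage::bwlabel(cd31_frame > marker_threshold)
  n <- nrow(nuclei)
  lin_lab <- integer(n); cd_lab <- integer(n)
  collisions <- 0L
  for (i in seq_len(n)) {
    r <- round(nuclei$row[i]) + 1L
    cc <- round(nuclei$col[i]) + 1L
    ll <- lab_lin[r, cc]
    lc <- lab_cd[r, cc]
    if (ll > 0 && lc > 0) {
      collisions <- collisions + 1L
      rows <- max(1, r - 1):min(nrow(lineage_frame), r + 1)
      cols <- max(1, cc - 1):min(ncol(lineage_frame), cc + 1)
      if (mean(lineage_frame[rows, cols]) >= mean(cd31_frame[rows, cols])) {
        lc <- 0L
      } else ll <- 0L
    }
    lin_lab[i] <- ll; cd_lab[i] <- lc
  }
  cell_id <- dplyr::case_when(
    lin_lab > 0 ~ sprintf("L%04d", lin_lab),
    cd_lab > 0 ~ sprintf("E%04d", cd_lab),
    TRUE ~ sprintf("U%04d", seq_len(n))
  )
  nuclei$cell_id <- cell_id
  nuclei$lineage_positive <- lin_lab > 0
  nuclei$cd31_positive <- cd_lab > 0
  cells <- nuclei |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_nuclei = dplyr::n(),
      cell_type = dplyr::case_when(
        any(.data$lineage_positive) ~ lineage_type,
        any(.data$cd31_positive) ~ "endothelial",
        TRUE ~ "unknown"),
      .groups = "drop") |>
    dplyr::mutate(viable = TRUE, qc_multi = .data$n_nuclei >= 3L) |>
    dplyr::select("cell_id", "cell_type", "n_nuclei", "viable", "qc_multi")
  if (collisions > 0) {
    inform(paste0(collisions, " nucleus/nuclei fell in both marker masks; ",
                  "typed by the larger marker intensity"))
  }
  structure(list(nuclei = nuclei, cells = cells), collisions = collisions)
}

#' Quantify a full set of rendered (or loaded) frames
#'
#' Applies one study-wide threshold (pooled Otsu by default, or a fixed
#' absolute value), segments every DAPI frame, and groups nuclei into typed
#' cells via the marker channels. The computational analogue of the
#' photograph-by-photograph ImageJ quantification step.
#'
#' @param rendered A `rendered_frames` object from [render_images()].
#' @param threshold_policy `"otsu"` or a single numeric absolute threshold.
#' @param min_area,dilate_radius Passed to [segment_nuclei()].
#' @param lineage_type Cell type assigned to lineage-positive cells.
#' @return A list with `nuclei` and `cells` tibbles (ids unique across
#'   frames), plus the `threshold` used.
#' @export
quantify_frames <- function(rendered, threshold_policy = "otsu",
                            min_area = 9L, dilate_radius = 6L,
                            lineage_type = NULL) {
  stopifnot(inherits(rendered, "rendered_frames"))
  dapi <- purrr::map(rendered$frames, "dapi")
  threshold <- if (identical(threshold_policy, "otsu")) {
    pooled_otsu(dapi)
  } else if (is.numeric(threshold_policy) && length(threshold_policy) == 1) {
    threshold_policy
  } else abort("`threshold_policy` must be \"otsu\" or a single number")
  lineage_type <- lineage_type %||%
    setdiff(unique(rendered$placement$cell_type), "endothelial")[1] %||%
    "unknown"
  nuclei <- list(); cells <- list()
  for (f in seq_along(rendered$frames)) {
    fr <- rendered$frames[[f]]
    nuc <- segment_nuclei(fr$dapi, threshold, min_area, dilate_radius)
    if (nrow(nuc) == 0) next
    asn <- assign_nuclei_to_cells(nuc, fr$lineage, fr$cd31,
                                  lineage_type = lineage_type)
    asn$nuclei$nucleus_id <- sprintf("f%03d_n%04d", f, asn$nuclei$nucleus_id)
    asn$nuclei$cell_id <- sprintf("f%03d_%s", f, asn$nuclei$cell_id)
    asn$cells$cell_id <- sprintf("f%03d_%s", f, asn$cells$cell_id)
    asn$nuclei$frame <- f
    nuclei[[f]] <- asn$nuclei
    cells[[f]] <- asn$cells
  }
  list(nuclei = dplyr::bind_rows(nuclei), cells = dplyr::bind_rows(cells),
       threshold = threshold)
}
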