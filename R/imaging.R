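#' Describe the synthetic imaging setup
#'
#' Parameters of the rendered multi-channel frames: square frame size, the
#' nuclear blob size, an isotropic Gaussian point-spread, a flat background
#' offset and additive Gaussian pixel noise. Cells are laid out on a jittered
#' grid so that no two cells' marker masks overlap; the grid capacity bounds
#' `cells_per_frame`.
#'
#' @param frame_size Side length of the square frame, pixels.
#' @param nucleus_radius_px Mean nuclear radius in pixels.
#' @param nucleus_radius_sd SD of the nuclear radius, pixels.
#' @param psf_sigma Gaussian point-spread sigma, pixels.
#' @param background_level Flat background offset, arbitrary units.
#' @param additive_noise_sd SD of additive Gaussian pixel noise, a.u.
#' @param cells_per_frame Cells placed per frame.
#' @return An object of class `imaging_spec`.
#' @export
imaging_spec <- function(frame_size = 256L,
                         nucleus_radius_px = 4,
                         nucleus_radius_sd = 0.4,
                         psf_sigma = 1.5,
                         background_level = 100,
                         additive_noise_sd = 2,
                         cells_per_frame = 40L) {
  if (frame_size <= 4 * nucleus_radius_px) {
    abort("`frame_size` must exceed 4 x nucleus radius")
  }
  if (any(c(nucleus_radius_sd, psf_sigma, background_level, additive_noise_sd) < 0)) {
    abort("noise and blur parameters must all be >= 0")
  }
  structure(
    list(frame_size = as.integer(frame_size),
         nucleus_radius_px = nucleus_radius_px,
         nucleus_radius_sd = nucleus_radius_sd,
         psf_sigma = psf_sigma,
         background_level = background_level,
         additive_noise_sd = additive_noise_sd,
         cells_per_frame = as.integer(cells_per_frame),
         channels = c("DAPI", "lineage", "CD31")),
    class = "imaging_spec"
  )
}

# Add a normalised Gaussian blob of total mass `intensity` at (r0, c0).
# The discrete kernel is renormalised so the integrated (summed) signal
# equals `intensity` exactly, keeping DNA-content linearity testable.
add_blob <- function(frame, r0, c0, sigma, intensity) {
  n <- nrow(frame)
  w <- ceiling(4 * sigma)
  rows <- max(1, round(r0) - w):min(n, round(r0) + w)
  cols <- max(1, round(c0) - w):min(ncol(frame), round(c0) + w)
  k <- exp(-outer((rows - r0)^2, (cols - c0)^2, "+") / (2 * sigma^2))
  frame[rows, cols] <- frame[rows, cols] + intensity * k / sum(k)
  frame
}

add_disk <- function(frame, r0, c0, radius, level = 1) {
  n <- nrow(frame)
  w <- ceiling(radius)
  rows <- max(1, round(r0) - w):min(n, round(r0) + w)
  cols <- max(1, round(c0) - w):min(ncol(frame), round(c0) + w)
  d2 <- outer((rows - r0)^2, (cols - c0)^2, "+")
  sub <- frame[rows, cols]
  sub[d2 <= radius^2] <- pmax(sub[d2 <= radius^2], level)
  frame[rows, cols] <- sub
  frame
}

#' Render a cell table into multi-channel frames
#'
#' Each nucleus becomes a Gaussian blob in the DAPI channel whose integrated
#' (background-subtracted) signal equals its `true_intensity`; the nuclei of
#' one cell sit inside that cell's lineage-marker disk (cardiomyocyte,
#' hepatocyte and marrow cells) or CD31 disk (endothelial cells). Cells are
#' placed on a jittered grid, one cell per slot, so marker masks never
#' overlap. A placement map links every rendered nucleus back to its
#' ground-truth record.
#'
#' Only viable cells are rendered by default, mirroring the acquisition rule
#' that only live cells are photographed and counted.
#'
#' @param truth Ground-truth nucleus table from [generate_population()].
#' @param img An [imaging_spec()].
#' @param seed Integer seed for placement and pixel noise.
#' @param include_nonviable Render dead cells too? Default `FALSE`.
#' @return An object of class `rendered_frames`: a list with `frames` (each a
#'   list of `dapi`, `lineage`, `cd31` matrices), `placement` (tibble linking
#'   nuclei to frames and positions) and the generating `img` spec.
#' @export
render_images <- function(truth, img = imaging_spec(), seed = 1L,
                          include_nonviable = FALSE) {
  stopifnot(inherits(img, "imaging_spec"))
  if (nrow(truth) == 0) abort("`truth` must contain at least one nucleus")
  if (!include_nonviable) truth <- dplyr::filter(truth, .data$viable)

  cell_radius <- 3.5 * img$nucleus_radius_px
  pitch <- ceiling(2 * cell_radius + 4)
  per_side <- img$frame_size %/% pitch
  if (per_side^2 < img$cells_per_frame) {
    abort(paste0("packing error: ", img$cells_per_frame,
                 " cells per frame exceed the ", per_side^2,
                 "-slot capacity of a ", img$frame_size, "px frame"))
  }

  cells <- truth |>
    dplyr::group_by(.data$cell_id, .data$cell_type) |>
    dplyr::summarise(n_nuclei = dplyr::n(), .groups = "drop")
  n_frames <- ceiling(nrow(cells) / img$cells_per_frame)
  cells$frame <- rep(seq_len(n_frames), each = img$cells_per_frame)[seq_len(nrow(cells))]

  with_seed(derive_seed(seed, "images"), {
    frames <- vector("list", n_frames)
    placement <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      fc <- cells[cells$frame == f, ]
      dapi <- matrix(img$background_level, img$frame_size, img$frame_size)
      lineage <- matrix(0, img$frame_size, img$frame_size)
      cd31 <- matrix(0, img$frame_size, img$frame_size)
      slots <- sample(per_side^2, nrow(fc))
      rows <- ((slots - 1) %/% per_side) * pitch + pitch / 2
      cols <- ((slots - 1) %% per_side) * pitch + pitch / 2
      jit <- 1.5
      rows <- rows + runif(nrow(fc), -jit, jit)
      cols <- cols + runif(nrow(fc), -jit, jit)
      pl <- vector("list", nrow(fc))
      for (i in seq_len(nrow(fc))) {
        nuc <- truth[truth$cell_id == fc$cell_id[i], ]
        if (fc$n_nuclei[i] == 1L) {
          nr <- rows[i]; nc <- cols[i]
        } else {
          theta <- runif(1, 0, pi)
          d <- 0.7 * cell_radius
          nr <- rows[i] + c(-1, 1) * d * sin(theta)
          nc <- cols[i] + c(-1, 1) * d * cos(theta)
        }
        marker <- if (fc$cell_type[i] == "endothelial") "cd31" else "lineage"
        if (marker == "cd31") {
          cd31 <- add_disk(cd31, rows[i], cols[i], cell_radius)
        } else {
          lineage <- add_disk(lineage, rows[i], cols[i], cell_radius)
        }
        sig <- numeric(nrow(nuc))
        for (j in seq_len(nrow(nuc))) {
          radius <- max(1, rnorm(1, img$nucleus_radius_px, img$nucleus_radius_sd))
          sigma <- sqrt((radius / 2)^2 + img$psf_sigma^2)
          sig[j] <- sigma
          dapi <- add_blob(dapi, nr[j], nc[j], sigma, nuc$true_intensity[j])
        }
        pl[[i]] <- tibble(
          frame = f, cell_id = fc$cell_id[i], cell_type = fc$cell_type[i],
          nucleus_index = nuc$nucleus_index, row = nr - 1, col = nc - 1,
          blob_sigma = sig, true_copies = nuc$true_copies,
          true_intensity = nuc$true_intensity
        )
      }
      if (img$additive_noise_sd > 0) {
        dapi <- dapi + matrix(rnorm(length(dapi), 0, img$additive_noise_sd),
                              nrow(dapi))
        dapi[dapi < 0] <- 0
      }
      frames[[f]] <- list(dapi = dapi, lineage = lineage, cd31 = cd31)
      placement[[f]] <- dplyr::bind_rows(pl)
    }
    structure(list(frames = frames, placement = dplyr::bind_rows(placement),
                   img = img),
              class = "rendered_frames")
  })
}

#' @export
print.rendered_frames <- function(x, ...) {
  cat("<rendered_frames> ", length(x$frames), " frame(s) of ",
      x$img$frame_size, "x", x$img$frame_size, " px, ",
      nrow(x$placement), " nuclei\n", sep = "")
  invisible(x)
}

#' Write rendered frames to disk as per-channel TIFF files
#'
#' Emits `frame<k>_<channel>.tif` (32-bit float) for each frame plus
#' `placement.csv` with the ground-truth placement map.
#'
#' @param rendered A `rendered_frames` object.
#' @param dir Output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_frames <- function(rendered, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("writing TIFF frames requires the 'tiff' package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(purrr::map_dbl(rendered$frames, ~ max(.x$dapi)))
  for (f in seq_along(rendered$frames)) {
    fr <- rendered$frames[[f]]
    for (ch in names(fr)) {
      tiff::writeTIFF(fr[[ch]] / scale,
                      file.path(dir, sprintf("frame%03d_%s.tif", f, ch)),
                      bits.per.sample = 32L)
    }
  }
  readr::write_csv(rendered$placement, file.path(dir, "placement.csv"))
  readr::write_csv(tibble(key = "intensity_scale", value = scale),
                   file.path(dir, "scale.csv"))
  invisible(dir)
}
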