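# Digital pathology: nucleus segmentation on the haematoxylin channel,
# tumour/stroma compartment assignment from nuclear shape and size, and
# DAB-positive CD8 counting per compartment.
#
# The original implementation ran in discontinued commercial software; this
# module reconstructs the described rules with every threshold exposed:
# nuclei are segmented by thresholding + watershed splitting; a nucleus is
# tumour-class when it is large and round (area >= area_cutoff AND
# eccentricity <= eccentricity_cutoff); the tumour compartment is the union
# of disks of a configurable radius around tumour-nucleus centroids (the
# "immediate region surrounding" the tumour cells); remaining tissue is
# stroma; pixels outside the tissue envelope (morphological closing of the
# nuclei + DAB support) are background and excluded from area denominators.
# Reported coordinates are 0-based pixel indices; areas are mm^2.

region_props <- function(lab, pixel_size) {
  idx <- which(lab > 0)
  if (!length(idx)) {
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      area = numeric(0), eccentricity = numeric(0)))
  }
  nr <- nrow(lab)
  l <- lab[idx]
  r <- (idx - 1) %% nr + 1
  c <- (idx - 1) %/% nr + 1
  s <- rowsum(cbind(n = 1, r = r, c = c, rr = r * r, cc = c * c, rc = r * c),
              l)
  n <- s[, "n"]
  mr <- s[, "r"] / n
  mc <- s[, "c"] / n
  mu20 <- s[, "rr"] / n - mr^2
  mu02 <- s[, "cc"] / n - mc^2
  mu11 <- s[, "rc"] / n - mr * mc
  tr2 <- (mu20 + mu02) / 2
  det_root <- sqrt(pmax(((mu20 - mu02) / 2)^2 + mu11^2, 0))
  l1 <- tr2 + det_root
  l2 <- pmax(tr2 - det_root, 0)
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  data.frame(label = as.integer(rownames(s)),
             row = mr - 1, col = mc - 1,           # 0-based centroids
             area = n * pixel_size^2, eccentricity = ecc)
}

#' Segment nuclei on the haematoxylin channel
#'
#' Thresholds the channel, splits touching objects by watershed on the
#' Euclidean distance transform (markers = distance-transform plateaus of
#' local maxima), and measures each nucleus.
#'
#' @param hema haematoxylin intensity matrix.
#' @param pixel_size microns per pixel.
#' @param intensity_threshold binarization threshold (default 0.45).
#' @param min_area minimum nucleus area in micron^2 (default 8).
#' @param marker_sep_um half-width of the local-maximum window used for
#'   watershed markers (default 4; roughly a nucleus radius).
#' @return data frame of nucleus records: `row`, `col` (0-based centroid),
#'   `area` (micron^2), `eccentricity`, `class` (tumour/stroma is assigned
#'   later by [classify_compartments()]; here `NA`). An empty image yields
#'   zero rows.
#' @export
segment_nuclei <- function(hema, pixel_size, intensity_threshold = 0.45,
                           min_area = 8, marker_sep_um = 4) {
  mask <- hema > intensity_threshold
  if (!any(mask)) {
    return(data.frame(row = numeric(0), col = numeric(0), area = numeric(0),
                      eccentricity = numeric(0)))
  }
  dt <- edt_cpp(!mask)   # distance to background
  r_nms <- max(1L, as.integer(round(marker_sep_um / pixel_size)))
  # markers from a smoothed distance transform: smoothing leaves one
  # maximum per convex nucleus (the ridge of an elongated nucleus is a
  # near-flat plateau otherwise) while the saddle between touching nuclei
  # survives; the half-pixel tolerance keeps each plateau connected
  sdt <- mean_filter_cpp(dt, max(1L, r_nms %/% 2L))
  peaks <- mask & sdt >= max_filter_cpp(sdt, r_nms) - 0.5 & dt > 0.5
  markers <- label_components_cpp(peaks)
  lab <- watershed_cpp(mask, dt, markers)
  props <- region_props(lab, pixel_size)
  props <- props[props$area >= min_area, , drop = FALSE]
  rownames(props) <- NULL
  props[, c("row", "col", "area", "eccentricity")]
}

#' Assign tumour/stroma compartments from nucleus shape and size
#'
#' Nuclei with `area >= area_cutoff` and
#' `eccentricity <= eccentricity_cutoff` are tumour-class; the tumour
#' compartment is the union of disks of radius `dilation_radius_um` around
#' their centroids, clipped to the tissue envelope; remaining tissue is
#' stroma; the rest is background.
#'
#' @param nuclei data frame from [segment_nuclei()].
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param pixel_size microns per pixel.
#' @param area_cutoff tumour-class minimum area (micron^2, default 45).
#' @param eccentricity_cutoff tumour-class maximum eccentricity
#'   (default 0.7).
#' @param dilation_radius_um disk radius defining the "immediate region"
#'   around tumour cells (default 12).
#' @param support optional logical matrix of tissue support (typically
#'   nuclei-or-DAB positive pixels); when supplied, the tissue envelope is
#'   its morphological closing with `closing_radius_um`; when `NULL` the
#'   whole frame is tissue.
#' @param closing_radius_um closing radius for the tissue envelope
#'   (default 25).
#' @return list of class `immunophen_mask`: `labels` (integer matrix, 0 =
#'   background, 1 = stroma, 2 = tumour), `pixel_size`, `areas` (mm^2 per
#'   compartment), `nuclei` (input with a `class` column).
#' @export
classify_compartments <- function(nuclei, dim, pixel_size, area_cutoff = 45,
                                  eccentricity_cutoff = 0.7,
                                  dilation_radius_um = 12, support = NULL,
                                  closing_radius_um = 25) {
  tissue <- if (is.null(support)) {
    matrix(TRUE, dim[1], dim[2])
  } else {
    morph_closing(support, closing_radius_um / pixel_size)
  }
  labels <- matrix(0L, dim[1], dim[2])
  labels[tissue] <- 1L
  if (nrow(nuclei) == 0) {
    warning("no nuclei: returning an all-tissue stroma mask")
    nuclei$class <- character(0)
  } else {
    nuclei$class <- ifelse(nuclei$area >= area_cutoff &
                           nuclei$eccentricity <= eccentricity_cutoff,
                           "tumour", "stroma")
    tum <- nuclei[nuclei$class == "tumour", , drop = FALSE]
    if (nrow(tum) > 0) {
      seeds <- matrix(FALSE, dim[1], dim[2])
      seeds[cbind(pmin(pmax(round(tum$row) + 1, 1), dim[1]),
                  pmin(pmax(round(tum$col) + 1, 1), dim[2]))] <- TRUE
      tumour_mask <- edt_cpp(seeds) <= dilation_radius_um / pixel_size
      labels[tumour_mask & tissue] <- 2L
    }
  }
  px_mm2 <- (pixel_size / 1000)^2
  structure(list(
    labels = labels, pixel_size = pixel_size,
    areas = c(tumour = sum(labels == 2L) * px_mm2,
              stroma = sum(labels == 1L) * px_mm2),
    nuclei = nuclei
  ), class = "immunophen_mask")
}

morph_closing <- function(mask, radius_px) {
  dilated <- edt_cpp(mask) <= radius_px
  edt_cpp(!dilated) > radius_px
}

#' Count DAB-positive CD8 cells per compartment
#'
#' Each connected DAB-positive component at least `min_blob_area` large is
#' counted once and assigned to the compartment of its centroid pixel.
#'
#' @param dab DAB intensity matrix (same geometry as the mask).
#' @param mask an `immunophen_mask` from [classify_compartments()].
#' @param dab_threshold binarization threshold (default 0.5).
#' @param min_blob_area minimum blob area in micron^2 (default 3).
#' @param sample_id identifier carried into the output row.
#' @return one-row data frame (`CompartmentDensities` schema):
#'   `sample_id`, `cd8_tumour_count`, `cd8_stroma_count`, `tumour_area`,
#'   `stroma_area` (mm^2), `cd8_tumour_density`, `cd8_stroma_density`
#'   (cells/mm^2; `NA` when the compartment has zero area).
#' @export
count_cd8 <- function(dab, mask, dab_threshold = 0.5, min_blob_area = 3,
                      sample_id = "sample") {
  stopifnot(inherits(mask, "immunophen_mask"))
  if (!all(base::dim(dab) == base::dim(mask$labels))) {
    stop_input("DAB channel and mask geometry differ")
  }
  px <- mask$pixel_size
  lab <- label_components_cpp(dab > dab_threshold)
  props <- region_props(lab, px)
  props <- props[props$area >= min_blob_area, , drop = FALSE]
  compartment <- if (nrow(props)) {
    mask$labels[cbind(pmin(pmax(round(props$row) + 1, 1), nrow(dab)),
                      pmin(pmax(round(props$col) + 1, 1), ncol(dab)))]
  } else integer(0)
  n_tum <- sum(compartment == 2L)
  n_str <- sum(compartment == 1L)
  data.frame(
    sample_id = sample_id,
    cd8_tumour_count = n_tum, cd8_stroma_count = n_str,
    tumour_area = mask$areas[["tumour"]], stroma_area = mask$areas[["stroma"]],
    cd8_tumour_density = if (mask$areas[["tumour"]] > 0)
      n_tum / mask$areas[["tumour"]] else NA_real_,
    cd8_stroma_density = if (mask$areas[["stroma"]] > 0)
      n_str / mask$areas[["stroma"]] else NA_real_
  )
}

#' Quantify a two-channel IHC image end to end
#'
#' Segmentation, compartment assignment (tissue envelope from the closing
#' of the nuclei + DAB support) and CD8 counting with one call.
#'
#' @param hema,dab channel matrices.
#' @param pixel_size microns per pixel.
#' @param sample_id identifier for the output row.
#' @param use_support if `TRUE` (default `FALSE`) the tissue envelope is
#'   the closing of the positive-signal support instead of the full frame
#'   (the synthetic cartoons fill the frame with tissue).
#' @param ... passed through to the stage functions
#'   (`intensity_threshold`, `min_area`, `area_cutoff`,
#'   `eccentricity_cutoff`, `dilation_radius_um`, `dab_threshold`,
#'   `min_blob_area`).
#' @return list: `densities` (one-row table), `mask`, `nuclei`.
#' @export
quantify_image <- function(hema, dab, pixel_size, sample_id = "sample",
                           use_support = FALSE, ...) {
  dots <- list(...)
  nuclei <- do.call(segment_nuclei, c(
    list(hema = hema, pixel_size = pixel_size),
    dots[intersect(names(dots),
                   c("intensity_threshold", "min_area", "marker_sep_um"))]))
  support <- if (use_support) {
    thr <- dots$intensity_threshold %||% 0.45
    dthr <- dots$dab_threshold %||% 0.5
    (hema > thr) | (dab > dthr)
  } else NULL
  mask <- do.call(classify_compartments, c(
    list(nuclei = nuclei, dim = base::dim(hema), pixel_size = pixel_size,
         support = support),
    dots[intersect(names(dots),
                   c("area_cutoff", "eccentricity_cutoff",
                     "dilation_radius_um", "closing_radius_um"))]))
  dens <- do.call(count_cd8, c(
    list(dab = dab, mask = mask, sample_id = sample_id),
    dots[intersect(names(dots), c("dab_threshold", "min_blob_area"))]))
  list(densities = dens, mask = mask, nuclei = mask$nuclei)
}
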