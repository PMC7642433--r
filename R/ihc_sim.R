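# Synthetic brightfield-like IHC images: flattened cartoon histology with a
# haematoxylin channel (elliptical nuclei) and a DAB channel (disk-shaped
# CD8 cells), plus a per-pixel compartment truth mask and planted counts.
#
# Tumour nests are disks; tumour nuclei (large, round) sit on a jittered
# grid inside the nests, stroma nuclei (small, elongated) are scattered
# outside with a minimum separation. CD8 cells are placed uniformly inside
# their designated compartment with a margin, so every planted position
# falls strictly inside its compartment. No stain spectra or colour
# deconvolution are simulated: the two channels are the algorithm's inputs.

#' Configuration for a synthetic IHC image
#'
#' @param image_size image side length in pixels (square).
#' @param pixel_size microns per pixel.
#' @param n_tumour_nests number of disk-shaped tumour nests.
#' @param nest_radius_um nest radius (microns).
#' @param tumour_nucleus_area,stroma_nucleus_area mean nucleus area
#'   (micron^2); tumour nuclei must be strictly larger on average.
#' @param tumour_nucleus_ecc,stroma_nucleus_ecc mean nucleus eccentricity;
#'   tumour nuclei must be strictly rounder (lower) on average.
#' @param nucleus_area_sd,nucleus_ecc_sd draw spread.
#' @param tumour_spacing_um grid spacing of tumour nuclei inside nests.
#' @param n_stroma_nuclei stroma nuclei to scatter outside the nests.
#' @param cd8_tumour_count,cd8_stroma_count planted CD8 cells per
#'   compartment.
#' @param cd8_radius_um CD8 cell radius.
#' @param cd8_margin_um minimum distance of planted CD8 centroids from the
#'   nest boundary (both sides). Keeps planted cells out of the thin strip
#'   where any reconstruction of the "immediate region" around tumour
#'   cells legitimately disagrees with the geometric nest truth.
#' @param noise_sd Gaussian intensity noise added to both channels.
#' @param seed RNG seed.
#' @return validated list of class `immunophen_ihcspec`.
#' @export
ihc_image_spec <- function(image_size = 512L, pixel_size = 0.5,
                           n_tumour_nests = 3L, nest_radius_um = 50,
                           tumour_nucleus_area = 60, tumour_nucleus_ecc = 0.3,
                           stroma_nucleus_area = 25, stroma_nucleus_ecc = 0.85,
                           nucleus_area_sd = 5, nucleus_ecc_sd = 0.05,
                           tumour_spacing_um = 10, n_stroma_nuclei = 120L,
                           cd8_tumour_count = 10L, cd8_stroma_count = 20L,
                           cd8_radius_um = 3, cd8_margin_um = 15,
                           noise_sd = 0, seed = 1L) {
  if (tumour_nucleus_area <= stroma_nucleus_area) {
    stop_input("tumour nuclei must be larger than stroma nuclei on average")
  }
  if (tumour_nucleus_ecc >= stroma_nucleus_ecc) {
    stop_input("tumour nuclei must be rounder than stroma nuclei on average")
  }
  if (cd8_tumour_count < 0 || cd8_stroma_count < 0) {
    stop_input("CD8 counts must be non-negative")
  }
  structure(as.list(environment()), class = "immunophen_ihcspec")
}

# render filled ellipse (centre in pixel units, axes in pixels) into img
render_ellipse <- function(img, cr, cc, a, b, phi, value) {
  nr <- nrow(img)
  ext <- ceiling(max(a, b)) + 1
  rs <- max(1, floor(cr - ext)):min(nr, ceiling(cr + ext))
  cs <- max(1, floor(cc - ext)):min(ncol(img), ceiling(cc + ext))
  dr <- outer(rs - cr, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - cc)
  u <- dr * cos(phi) + dc * sin(phi)
  v <- -dr * sin(phi) + dc * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  block <- img[rs, cs, drop = FALSE]
  block[inside] <- value
  img[rs, cs] <- block
  img
}

# rejection-sample `n` points with pairwise min distance, inside/outside
# the nest mask as requested; error when the compartment cannot hold them
sample_points <- function(n, allowed_idx, nr, min_dist_px, existing = NULL,
                          what = "points") {
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("r", "c"))))
  }
  if (length(allowed_idx) < n) {
    stop_input("requested %s count exceeds available compartment area", what)
  }
  pts <- existing
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("r", "c")))
  got <- 0
  tries <- 0
  while (got < n) {
    tries <- tries + 1
    if (tries > 200 * n) {
      stop_input("requested %s count exceeds available compartment area", what)
    }
    p <- allowed_idx[sample.int(length(allowed_idx), 1)]
    r <- ((p - 1) %% nr) + 1
    c <- ((p - 1) %/% nr) + 1
    if (!is.null(pts) && nrow(pts) > 0 &&
        min((pts[, 1] - r)^2 + (pts[, 2] - c)^2) < min_dist_px^2) next
    got <- got + 1
    out[got, ] <- c(r, c)
    pts <- rbind(pts, c(r, c))
  }
  out
}

#' Generate a synthetic two-channel IHC image with ground truth
#'
#' @param spec an [ihc_image_spec()].
#' @return list: `hema` and `dab` (numeric matrices in \[0, ~1\]),
#'   `truth_mask` (integer matrix, 0 = background, 1 = stroma, 2 = tumour;
#'   the synthetic tissue fills the frame, so background is empty here),
#'   and `truth` (planted counts, nucleus table, CD8 position table).
#' @export
generate_ihc_image <- function(spec = ihc_image_spec()) {
  stopifnot(inherits(spec, "immunophen_ihcspec"))
  set.seed(spec$seed)
  n <- spec$image_size
  px <- spec$pixel_size
  hema <- matrix(0.05, n, n)
  dab <- matrix(0.02, n, n)

  # tumour nests: disk centres kept away from the border and each other
  nest_r_px <- spec$nest_radius_um / px
  centers <- matrix(NA_real_, spec$n_tumour_nests, 2)
  for (i in seq_len(spec$n_tumour_nests)) {
    sep <- 2.1 * nest_r_px
    tries <- 0
    repeat {
      cand <- runif(2, nest_r_px + 2, n - nest_r_px - 2)
      if (i == 1 || min(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) -
                                 cand)^2)) > sep^2) break
      tries <- tries + 1
      if (tries %% 100 == 0) sep <- sep * 0.95  # relax when crowded
      if (tries > 5000) stop_input("cannot place tumour nests; too many/large")
    }
    centers[i, ] <- cand
  }
  rowg <- matrix(seq_len(n), n, n)
  colg <- t(rowg)
  tumour_truth <- matrix(FALSE, n, n)
  for (i in seq_len(spec$n_tumour_nests)) {
    tumour_truth <- tumour_truth |
      ((rowg - centers[i, 1])^2 + (colg - centers[i, 2])^2 <= nest_r_px^2)
  }
  truth_mask <- matrix(1L, n, n)
  truth_mask[tumour_truth] <- 2L

  # tumour nuclei: jittered grid inside nests, kept off the nest edge
  margin_px <- 8 / px
  nuclei <- NULL
  spacing <- spec$tumour_spacing_um / px
  for (i in seq_len(spec$n_tumour_nests)) {
    gr <- seq(-nest_r_px, nest_r_px, by = spacing)
    grid <- expand.grid(r = centers[i, 1] + gr, c = centers[i, 2] + gr)
    keep <- (grid$r - centers[i, 1])^2 + (grid$c - centers[i, 2])^2 <=
      (nest_r_px - margin_px)^2
    grid <- grid[keep, , drop = FALSE]
    jit <- matrix(runif(2 * nrow(grid), -0.5, 0.5) / px * 0.25, ncol = 2)
    nuclei <- rbind(nuclei, data.frame(
      r = grid$r + jit[, 1], c = grid$c + jit[, 2], class = "tumour"))
  }
  # stroma nuclei: scattered outside nests with a buffer and min spacing
  stroma_ok <- which(!(edt_cpp(tumour_truth) <= (6 / px)) &
                     rowg > 8 & rowg < n - 8 & colg > 8 & colg < n - 8)
  spts <- sample_points(spec$n_stroma_nuclei, stroma_ok, n,
                        min_dist_px = 9 / px,
                        existing = as.matrix(nuclei[, c("r", "c")]),
                        what = "stroma nucleus")
  nuclei <- rbind(nuclei, data.frame(r = spts[, 1], c = spts[, 2],
                                     class = "stroma"))

  # render nuclei
  nuclei$area <- NA_real_
  nuclei$ecc <- NA_real_
  for (i in seq_len(nrow(nuclei))) {
    tum <- nuclei$class[i] == "tumour"
    area <- rtruncnorm(1,
      if (tum) spec$tumour_nucleus_area else spec$stroma_nucleus_area,
      spec$nucleus_area_sd, lower = 8)
    ecc <- rtruncnorm(1,
      if (tum) spec$tumour_nucleus_ecc else spec$stroma_nucleus_ecc,
      spec$nucleus_ecc_sd, lower = 0, upper = 0.95)
    ratio <- sqrt(1 - ecc^2)              # b / a
    a <- sqrt(area / (pi * ratio)) / px   # semi-axes in pixels
    b <- a * ratio
    phi <- runif(1, 0, pi)
    hema <- render_ellipse(hema, nuclei$r[i], nuclei$c[i], a, b, phi, 0.85)
    nuclei$area[i] <- area
    nuclei$ecc[i] <- ecc
  }

  # CD8 cells: non-overlapping disks strictly inside their compartment
  cd8_r_px <- spec$cd8_radius_um / px
  safety <- max(ceiling(cd8_r_px) + 2, ceiling(spec$cd8_margin_um / px))
  tum_ok <- which(edt_cpp(!tumour_truth) > safety)
  str_ok <- which(edt_cpp(tumour_truth) > safety &
                  rowg > safety & rowg < n - safety &
                  colg > safety & colg < n - safety)
  tpts <- sample_points(spec$cd8_tumour_count, tum_ok, n,
                        min_dist_px = 2 * cd8_r_px + 3, what = "tumour CD8")
  spts2 <- sample_points(spec$cd8_stroma_count, str_ok, n,
                         min_dist_px = 2 * cd8_r_px + 3,
                         existing = tpts, what = "stroma CD8")
  cd8 <- rbind(
    if (nrow(tpts)) data.frame(r = tpts[, 1], c = tpts[, 2],
                               compartment = "tumour"),
    if (nrow(spts2)) data.frame(r = spts2[, 1], c = spts2[, 2],
                                compartment = "stroma"))
  if (is.null(cd8)) cd8 <- data.frame(r = numeric(0), c = numeric(0),
                                      compartment = character(0))
  for (i in seq_len(nrow(cd8))) {
    dab <- render_ellipse(dab, cd8$r[i], cd8$c[i], cd8_r_px, cd8_r_px, 0, 0.9)
  }

  if (spec$noise_sd > 0) {
    hema <- hema + matrix(rnorm(n * n, 0, spec$noise_sd), n, n)
    dab <- dab + matrix(rnorm(n * n, 0, spec$noise_sd), n, n)
  }

  list(
    hema = hema, dab = dab, truth_mask = truth_mask,
    truth = list(
      cd8_tumour_count = as.integer(spec$cd8_tumour_count),
      cd8_stroma_count = as.integer(spec$cd8_stroma_count),
      n_nuclei = nrow(nuclei),
      nuclei = nuclei,
      cd8 = cd8,
      pixel_size = px
    )
  )
}
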