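blank <- function(n = 80, value = 0.02) matrix(value, n, n)

test_that("ihc_image_spec enforces the recoverability invariants", {
  expect_error(ihc_image_spec(tumour_nucleus_area = 20), "larger")
  expect_error(ihc_image_spec(tumour_nucleus_ecc = 0.9), "rounder")
  expect_error(ihc_image_spec(cd8_tumour_count = -1), "non-negative")
})

test_that("generated images honour planted counts and truth masks", {
  img <- generate_ihc_image(ihc_image_spec(seed = 3))
  expect_identical(img$truth$cd8_tumour_count, 10L)
  expect_identical(img$truth$cd8_stroma_count, 20L)
  expect_true(all(img$truth_mask %in% c(0L, 1L, 2L)))
  # planted CD8 positions sit inside their designated compartment
  pos <- img$truth$cd8
  at <- img$truth_mask[cbind(round(pos$r), round(pos$c))]
  expect_true(all(at[pos$compartment == "tumour"] == 2L))
  expect_true(all(at[pos$compartment == "stroma"] == 1L))

  # zero tumour CD8 leaves the tumour truth region DAB-negative
  img0 <- generate_ihc_image(ihc_image_spec(cd8_tumour_count = 0, seed = 4))
  expect_true(all(img0$dab[img0$truth_mask == 2L] <= 0.02))

  # two seeds: different placements, same planted counts
  a <- generate_ihc_image(ihc_image_spec(seed = 5))
  b <- generate_ihc_image(ihc_image_spec(seed = 6))
  expect_false(identical(a$truth$nuclei, b$truth$nuclei))
  expect_identical(a$truth$cd8_tumour_count, b$truth$cd8_tumour_count)
  # same seed: identical everything
  expect_identical(generate_ihc_image(ihc_image_spec(seed = 5)), a)

  expect_error(generate_ihc_image(ihc_image_spec(cd8_tumour_count = 10000L)),
               "exceeds available compartment area")
})

test_that("segment_nuclei recovers planted nuclei and applies min_area", {
  img <- generate_ihc_image(ihc_image_spec(seed = 7))
  nuc <- segment_nuclei(img$hema, 0.5)
  expect_identical(nrow(nuc), img$truth$n_nuclei)

  expect_identical(nrow(segment_nuclei(blank(), 0.5)), 0L)

  # one nucleus below min_area is excluded
  hema <- blank(60)
  hema <- immunophen:::render_ellipse(hema, 20, 20, 6, 6, 0, 0.9)  # ~113 px
  hema <- immunophen:::render_ellipse(hema, 45, 45, 1.2, 1.2, 0, 0.9)  # ~4 px
  nuc2 <- segment_nuclei(hema, 1, min_area = 20)
  expect_identical(nrow(nuc2), 1L)

  # touching objects are split by the watershed
  hh <- blank(60)
  hh <- immunophen:::render_ellipse(hh, 25, 25, 8, 8, 0, 0.9)
  hh <- immunophen:::render_ellipse(hh, 25, 38, 8, 8, 0, 0.9)
  expect_identical(nrow(segment_nuclei(hh, 1, min_area = 5)), 2L)
})

test_that("compartment masks follow the shape/size rule and dilation", {
  # single tumour nucleus: tumour area ~ disk area pi r^2
  nuc <- data.frame(row = 99, col = 99, area = 60, eccentricity = 0.3)
  mask <- classify_compartments(nuc, c(200, 200), pixel_size = 1,
                                dilation_radius_um = 20)
  expect_identical(mask$nuclei$class, "tumour")
  disk_px <- pi * 20^2
  expect_lt(abs(sum(mask$labels == 2L) - disk_px), 2 * (2 * pi * 20))
  expect_equal(mask$areas[["tumour"]], sum(mask$labels == 2L) * 1e-6)

  # all stroma-like nuclei: tumour area 0
  nuc2 <- data.frame(row = c(30, 60), col = c(30, 60),
                     area = c(25, 24), eccentricity = c(0.85, 0.9))
  mask2 <- classify_compartments(nuc2, c(100, 100), 1)
  expect_identical(sum(mask2$labels == 2L), 0L)
  expect_identical(unname(mask2$areas[["stroma"]]), 100 * 100 * 1e-6)

  # idempotence on the same nuclei
  mask3 <- classify_compartments(nuc, c(200, 200), 1,
                                 dilation_radius_um = 20)
  expect_identical(mask3$labels, mask$labels)

  expect_warning(
    classify_compartments(data.frame(row = numeric(0), col = numeric(0),
                                     area = numeric(0),
                                     eccentricity = numeric(0)),
                          c(50, 50), 1), "no nuclei")
})

test_that("mask agreement with planted truth is at least 95%", {
  img <- generate_ihc_image(ihc_image_spec(seed = 11))
  q <- quantify_image(img$hema, img$dab, 0.5)
  agreement <- mean(q$mask$labels == img$truth_mask)
  expect_gte(agreement, 0.95)
})

test_that("count_cd8 applies blob filtering and the centroid rule", {
  img <- generate_ihc_image(ihc_image_spec(seed = 13))
  q <- quantify_image(img$hema, img$dab, 0.5, sample_id = "fx")
  expect_identical(q$densities$cd8_tumour_count, 10L)
  expect_identical(q$densities$cd8_stroma_count, 20L)
  expect_equal(q$densities$cd8_tumour_density,
               10 / q$densities$tumour_area)

  # empty DAB channel: zero counts
  mask <- q$mask
  z <- count_cd8(blank(nrow(mask$labels)), mask)
  expect_identical(c(z$cd8_tumour_count, z$cd8_stroma_count), c(0L, 0L))

  # blob straddling the boundary counts for its centroid's compartment
  lab <- matrix(1L, 50, 50)
  lab[, 1:10] <- 2L  # tumour strip on the left
  m <- structure(list(labels = lab, pixel_size = 1,
                      areas = c(tumour = 500e-6, stroma = 2000e-6),
                      nuclei = NULL), class = "immunophen_mask")
  dab <- matrix(0, 50, 50)
  dab[23:27, 8:14] <- 1  # centroid at col 11 -> stroma
  one <- count_cd8(dab, m)
  expect_identical(c(one$cd8_tumour_count, one$cd8_stroma_count), c(0L, 1L))

  # zero-area compartment: density missing, count retained
  lab0 <- matrix(1L, 20, 20)
  m0 <- structure(list(labels = lab0, pixel_size = 1,
                       areas = c(tumour = 0, stroma = 400e-6),
                       nuclei = NULL), class = "immunophen_mask")
  d0 <- count_cd8(matrix(0, 20, 20), m0)
  expect_true(is.na(d0$cd8_tumour_density))

  expect_error(count_cd8(matrix(0, 10, 10), m), "geometry")
})

test_that("count conservation: every tissue blob lands in one compartment", {
  for (seed in c(17, 19)) {
    img <- generate_ihc_image(ihc_image_spec(seed = seed, noise_sd = 0.05))
    q <- quantify_image(img$hema, img$dab, 0.5)
    lab <- immunophen:::label_components_cpp(img$dab > 0.5)
    props <- immunophen:::region_props(lab, 0.5)
    props <- props[props$area >= 3, ]
    in_tissue <- q$mask$labels[cbind(round(props$row) + 1,
                                     round(props$col) + 1)] > 0
    expect_identical(q$densities$cd8_tumour_count +
                       q$densities$cd8_stroma_count,
                     as.integer(sum(in_tissue)))
  }
})

test_that("counts survive intensity noise within 5%", {
  img <- generate_ihc_image(ihc_image_spec(seed = 21, noise_sd = 0.08,
                                           cd8_tumour_count = 20L,
                                           cd8_stroma_count = 40L))
  q <- quantify_image(img$hema, img$dab, 0.5)
  expect_lte(abs(q$densities$cd8_tumour_count - 20) / 20, 0.05)
  expect_lte(abs(q$densities$cd8_stroma_count - 40) / 40, 0.05)
})
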