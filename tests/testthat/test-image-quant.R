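# Nuclear segmentation, foci detection and per-well measurement.

test_that("segmentation recovers well-separated nuclei with close centroids", {
  f <- render_field(well_separated_centres())
  mask <- segment_nuclei(f$nuclei)
  expect_equal(mask$n, 5)
  cen <- nucleus_centroids(mask)
  for (i in seq_len(5)) {
    d <- sqrt((cen$x - f$truth$x[i])^2 + (cen$y - f$truth$y[i])^2)
    expect_lt(min(d), 2)
  }
  # labels are consecutive from 1
  expect_setequal(setdiff(unique(as.vector(mask$label_map)), 0L), 1:5)
})

test_that("blank images yield zero nuclei and border nuclei are dropped", {
  noise <- withr::with_seed(1, matrix(abs(rnorm(256^2, 0, 10)), 256, 256))
  expect_equal(segment_nuclei(noise)$n, 0)
  # nucleus centred on the border is excluded
  f <- render_field(rbind(c(2, 128), c(128, 128)))
  expect_equal(segment_nuclei(f$nuclei)$n, 1)
  expect_error(segment_nuclei(matrix(numeric(0), 0, 0)),
               class = "igem_input_error")
})

test_that("touching nuclei are split by the watershed", {
  # 30% overlap: centres 1.4 radii apart
  f <- render_field(rbind(c(100, 100), c(100, 145), c(190, 60)))
  expect_equal(segment_nuclei(f$nuclei)$n, 3)
})

test_that("foci detection finds the planted spots and nothing in blank nuclei", {
  f <- render_field(well_separated_centres(), n_foci = 3)
  mask <- segment_nuclei(f$nuclei)
  foci <- detect_foci(f$mbd, mask)
  counts <- table(factor(foci$nucleus_label, levels = 1:5))
  expect_true(all(counts == 3))
  expect_true(all(foci$area_px >= 1))
  f0 <- render_field(well_separated_centres(), n_foci = 0)
  mask0 <- segment_nuclei(f0$nuclei)
  expect_equal(nrow(detect_foci(f0$mbd, mask0)), 0)
  expect_error(detect_foci(f$mbd[1:10, 1:10], mask),
               class = "igem_input_error")
})

test_that("foci intensity is exactly equivariant to channel rescaling", {
  f <- render_field(well_separated_centres(), n_foci = 2)
  mask <- segment_nuclei(f$nuclei)
  a <- detect_foci(f$mbd, mask)
  b <- detect_foci(f$mbd * 3, mask)
  expect_equal(nrow(a), nrow(b))
  expect_equal(b$integrated_intensity, 3 * a$integrated_intensity,
               tolerance = 1e-12)
  expect_equal(b$area_px, a$area_px)
})

test_that("well measurement is the per-nucleus mean over all fields", {
  # synthetic records: 2 fields, 10 nuclei each, every nucleus 2 foci of 4 px
  mk_mask <- function(n) structure(
    list(label_map = matrix(0L, 2, 2),
         areas = stats::setNames(rep(100L, n), seq_len(n)),
         n = as.integer(n)), class = "igem_nucleus_mask")
  foci <- tibble::tibble(nucleus_label = rep(1:10, each = 2),
                         area_px = 4L, mean_intensity = 50,
                         integrated_intensity = 200)
  fields <- list(list(mask = mk_mask(10), foci = foci),
                 list(mask = mk_mask(10), foci = foci))
  m <- measure_well(fields, "w")
  expect_equal(m$nuclei_count, 20L)
  expect_equal(m$foci_count_per_nucleus, 2)
  expect_equal(m$foci_area_per_nucleus, 8)
  expect_equal(m$foci_intensity_per_nucleus, 400)
  # zero nuclei: flagged undefined
  m0 <- measure_well(list(list(mask = mk_mask(0),
                               foci = foci[0, ])), "empty")
  expect_false(m0$defined)
  expect_true(is.na(m0$foci_count_per_nucleus))
  expect_error(measure_well(list()), class = "igem_input_error")
})

test_that("label permutation does not change the well measure", {
  f <- render_field(well_separated_centres(), n_foci = 3)
  mask <- segment_nuclei(f$nuclei)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  lab2 <- mask$label_map
  lab2[lab2 > 0] <- perm[lab2[lab2 > 0]]
  mask2 <- igemscreen:::new_nucleus_mask(lab2)
  m1 <- measure_well(list(list(mask = mask,
                               foci = detect_foci(f$mbd, mask))), "w")
  m2 <- measure_well(list(list(mask = mask2,
                               foci = detect_foci(f$mbd, mask2))), "w")
  expect_equal(m1[-1], m2[-1])
})

test_that("every focus lies inside a nucleus and counts are consistent", {
  cfg <- small_cfg(seed = 6)
  w <- sim_plate_images(cfg, "control")
  for (fld in w$fields) {
    mask <- segment_nuclei(fld$nuclei)
    foci <- detect_foci(fld$mbd, mask)
    expect_true(all(foci$nucleus_label %in% seq_len(mask$n)))
    per_nuc <- table(foci$nucleus_label)
    expect_equal(sum(per_nuc), nrow(foci))
  }
})

test_that("count recovery on the easy stratum is within 5%", {
  cfg <- sim_config(seed = 13, n_fields_per_well = 4L)
  tot_meas <- 0; tot_true <- 0; tot_nuc <- 0
  for (w in 1:4) {
    sim <- sim_plate_images(cfg, "control", well = w)
    easy_by_field <- split(sim$truth, sim$truth$field)
    for (f in seq_along(sim$fields)) {
      tr <- easy_by_field[[f]]
      if (any(tr$crowded)) next  # stratify on fields free of crowded nuclei
      mask <- segment_nuclei(sim$fields[[f]]$nuclei)
      foci <- detect_foci(sim$fields[[f]]$mbd, mask)
      tot_meas <- tot_meas + nrow(foci)
      tot_true <- tot_true + sum(tr$n_foci)
      tot_nuc <- tot_nuc + mask$n
    }
  }
  expect_gt(tot_nuc, 50)
  expect_lt(abs(tot_meas / tot_true - 1), 0.05)
})

test_that("field TIFF round-trip preserves both channels", {
  skip_if_not_installed("tiff")
  f <- render_field(well_separated_centres()[1:2, , drop = FALSE])
  path <- withr::local_tempfile(fileext = ".tif")
  write_field_tiff(f, path)
  back <- read_field_tiff(path)
  expect_equal(back$nuclei, f$nuclei, tolerance = 1e-4)
  expect_equal(back$mbd, f$mbd, tolerance = 1e-4)
})
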