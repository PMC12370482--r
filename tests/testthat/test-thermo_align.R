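# Registration, ring extraction, mask selection and threshold-temperature
# histories against generator ground truth.

test_that("hotspot detection finds the beam centre and breaks ties lexicographically", {
  sim <- simulate_thermal_video(pt_beam(), pt_thermal(), fps = 40, seed = 1)
  expect_lte(max(abs(find_hotspot(sim$video) - sim$truth$beam_center_px)), 1)
  # moved beam centre
  b2 <- beam_profile(416, 12.22, 2000, 3, center = c(100, 50))
  sim2 <- simulate_thermal_video(b2, pt_thermal(), fps = 40, seed = 2,
                                 shape = c(160, 160))
  expect_lte(max(abs(find_hotspot(sim2$video) - c(100, 50))), 1)
  # uniform frames: smallest (row, col)
  vid <- thermal_video(array(35, c(20, 8, 8)), 100, 6, 35, c(0, 20))
  expect_equal(find_hotspot(vid), c(1L, 1L))
})

test_that("mask registration applies scale, orientation and translation correctly", {
  sim <- simulate_thermal_video(pt_beam(), pt_thermal(), fps = 40, seed = 3)
  d <- dim(sim$video$frames)[2:3]
  # identity scale: pure translation, area preserved
  dm <- finalize_mask(disk_mask(60, center = c(20, 20), radius = 12),
                      pixel_pitch = sim$video$pixel_pitch)
  rm1 <- register_mask(dm, sim$video)
  expect_equal(sum(rm1$mask), sum(dm$mask))
  idx <- which(rm1$mask, arr.ind = TRUE)
  expect_lte(max(abs(colMeans(idx) - find_hotspot(sim$video))), 1)
  # fluorescence pitch 3, thermal 6: linear dimensions halve, area ratio ~ 0.25
  dm3 <- finalize_mask(disk_mask(120, radius = 40), pixel_pitch = 3)
  rm3 <- register_mask(dm3, sim$video)
  expect_equal(sum(rm3$mask) / sum(dm3$mask), 0.25, tolerance = 0.05)
  # horizontal flip is an involution (up to the centroid re-translation);
  # the shape must be connected and asymmetric to survive finalisation
  asym <- disk_mask(60, center = c(30, 22), radius = 10)
  asym[28:32, 22:52] <- TRUE
  dma <- finalize_mask(asym, pixel_pitch = 6)
  f1 <- register_mask(dma, sim$video, list(flip_h = TRUE, flip_v = FALSE, rotations = 0L))
  f0 <- register_mask(dma, sim$video)
  expect_false(identical(f1$mask, f0$mask))
  # flipping the flipped mask reproduces the unflipped registration
  dmb <- dma; dmb$mask <- dma$mask[, rev(seq_len(ncol(dma$mask)))]
  f2 <- register_mask(dmb, sim$video, list(flip_h = TRUE, flip_v = FALSE, rotations = 0L))
  expect_identical(f2$mask, f0$mask)
  # out-of-frame error
  huge <- finalize_mask(disk_mask(400, radius = 150), pixel_pitch = 6)
  expect_error(register_mask(huge, sim$video), class = "laserlesion_out_of_frame_error")
})

test_that("boundary rings have the expected geometry", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE   # 10x10 solid square
  ring <- boundary_ring(list(mask = sq))
  expect_equal(nrow(ring$pixels), 36L)
  # a digital circle's 8-connected ring carries extra stair-step pixels on the
  # diagonals (approaching the L1 perimeter 8r, i.e. ~(4/pi) * 2*pi*r)
  dk <- disk_mask(120, radius = 50)
  rr <- boundary_ring(list(mask = dk))
  ratio <- nrow(rr$pixels) / (2 * pi * 50)
  expect_gte(ratio, 1.0); expect_lte(ratio, 4 / pi)
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_error(boundary_ring(list(mask = one)), class = "laserlesion_degenerate_mask_error")
})

test_that("mask selection minimises boundary-temperature SD", {
  sim <- simulate_thermal_video(pt_beam(), pt_thermal(), fps = 40, seed = 4)
  ctr <- sim$truth$beam_center_px
  # isotherm radius for 46 C, in thermal px
  r_um <- uniroot(function(r) sim$truth$temp_at(r) - 46, c(1, 500))$root
  iso <- disk_registered_mask(sim$video, ctr, r_um / 6, stringency = 1L)
  off <- disk_registered_mask(sim$video, ctr + c(10, 0), r_um / 6, stringency = 0L)
  sel <- select_mask(list(off, iso), sim$video)
  expect_equal(sel$chosen$stringency_index, 1L)
  expect_equal(nrow(sel$report), 2L)
  expect_true(all(sel$report$ring_sd >= min(sel$report$ring_sd)))
  # single candidate returned; identical candidates tie-break to index 0
  expect_equal(select_mask(list(iso), sim$video)$chosen$stringency_index, 1L)
  iso0 <- iso; iso0$stringency_index <- 0L
  expect_equal(select_mask(list(iso0, iso), sim$video)$chosen$stringency_index, 0L)
})

test_that("threshold history recovers the isotherm temperature and dT identities", {
  sim <- simulate_thermal_video(pt_beam(), pt_thermal(), fps = 40, seed = 5)
  ctr <- sim$truth$beam_center_px
  r_um <- uniroot(function(r) sim$truth$temp_at(r) - 46, c(1, 500))$root
  # +0.5 px so the ring pixel centres (just inside the disk edge) average the
  # isotherm radius
  iso <- disk_registered_mask(sim$video, ctr, r_um / 6 + 0.5)
  res <- extract_threshold_history(sim$video, boundary_ring(iso))
  expect_lt(abs(res$threshold_peak_temperature - 46), 0.1)
  # centre peak: ambient 34.5 and dT_ss 15.5 give 50.0 / 15.5
  expect_equal(res$center_peak_temperature, 50.0, tolerance = 0.01)
  expect_equal(res$center_peak_dT, 15.5, tolerance = 0.03 / 15.5)
  expect_equal(res$threshold_peak_dT + res$ambient, res$threshold_peak_temperature)
  expect_lte(res$threshold_peak_temperature, res$center_peak_temperature)
  # zero-irradiance video: boundary at ambient, dT ~ 0
  sim0 <- simulate_thermal_video(beam_profile(416, 0, 2000, 3), pt_thermal(),
                                 fps = 40, seed = 6)
  res0 <- extract_threshold_history(sim0$video, boundary_ring(
    disk_registered_mask(sim0$video, sim0$truth$beam_center_px, 20)))
  expect_equal(res0$threshold_peak_dT, 0, tolerance = 0.05)
  # short exposure window rejected
  vid <- thermal_video(array(35, c(12, 16, 16)), 100, 6, 35, c(0, 5))
  expect_error(extract_threshold_history(vid, boundary_ring(
    disk_registered_mask(vid, c(8, 8), 4))), class = "laserlesion_window_error")
})

test_that("the irradiance-temperature standard curve fits and inverts", {
  E <- c(2, 5, 7.3, 10, 12.22)
  temp <- 35.5 + 1.2 * E
  fit <- fit_thermal_curve(E, temp)
  expect_equal(fit$slope, 1.2, tolerance = 1e-12)
  expect_equal(fit$intercept, 35.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # line through the two printed anchors, evaluated at 10.1 W cm^-2
  anchors <- fit_thermal_curve(c(7.3, 12.22), c(44.5, 50.0))
  expect_equal(anchors$predict_temperature(10.1), 47.3, tolerance = 0.5 / 47.3)
  # inverse identity
  expect_equal(anchors$predict_irradiance(anchors$predict_temperature(9)), 9)
  expect_error(fit_thermal_curve(c(5, 5), c(40, 41)), class = "laserlesion_rank_error")
})

test_that("end-to-end: the fused pipeline recovers the death-boundary isotherm", {
  # shared ground truth; reduced to 6 seeds here (20 in the acceptance suite)
  errs <- numeric(0)
  for (s in 1:6) {
    si <- simulate_viability_image(pt_beam(), pt_thermal(), pt_phenotype(), seed = s)
    sv <- simulate_thermal_video(pt_beam(), pt_thermal(), fps = 40, seed = 100 + s)
    rmasks <- lapply(mask_pipeline(si$image), register_mask, video = sv$video)
    sel <- select_mask(rmasks, sv$video)
    res <- extract_threshold_history(sv$video, boundary_ring(sel$chosen))
    errs <- c(errs, res$threshold_peak_temperature - si$truth$boundary_temperature)
  }
  expect_lt(median(abs(errs)), 0.5)
})
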