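# Mask construction: channel arithmetic, contrast, RATS vs brute force,
# morphological cleaning, finalisation, and the four-stringency schedule.

test_that("bleed-through correction produces the expected damage signal", {
  g <- matrix(100, 32, 32); r <- matrix(0, 32, 32)
  img <- two_channel_image(g, r, 3)
  # red == 0: L = green, D = max(green) - green
  out <- correct_bleedthrough(img)
  expect_equal(out$live, g)
  expect_equal(out$damage, max(g) - g)
  # uniform green carpet with a green-free disk: D maximal exactly on the disk
  hole <- disk_mask(32, radius = 6)
  g2 <- g; g2[hole] <- 0
  out2 <- correct_bleedthrough(two_channel_image(g2, r, 3))
  expect_true(all(out2$damage[hole] == max(out2$damage)))
  expect_true(all(out2$damage[!hole] == 0))
  # all-zero corrected signal -> degenerate error
  expect_error(correct_bleedthrough(two_channel_image(r, g, 3)),
               class = "laserlesion_degenerate_error")
})

test_that("contrast enhancement is an order-preserving rescale with tail clipping", {
  set.seed(4)
  m <- matrix(runif(900, 10, 20), 30, 30)
  out <- enhance_contrast(m, 0)
  expect_equal(min(out), 0); expect_equal(max(out), 1)
  expect_equal(order(m), order(out))  # monotone bijection
  # already full-range: fraction 0 leaves ordering and range
  m01 <- (m - min(m)) / (max(m) - min(m))
  expect_equal(enhance_contrast(m01, 0), m01, tolerance = 1e-12)
  # 1% hot outliers with 0.35% clipping: the outlier block maps to the top of
  # the range while the bulk stays compressed near the bottom
  m2 <- matrix(runif(10000), 100, 100)
  m2[1:100] <- 50
  out2 <- enhance_contrast(m2, 0.0035)
  expect_equal(unname(quantile(out2, 0.995)), 1)
  expect_lt(quantile(out2, 0.985), 0.1)
  expect_warning(enhance_contrast(matrix(1, 20, 20)), "constant")
  expect_error(enhance_contrast(m, 0.6), class = "laserlesion_parameter_error")
})

test_that("RATS equals the brute-force weighted mean on single-leaf instances", {
  for (s in 1:5) {
    set.seed(s)
    n <- 16
    img <- matrix(runif(n * n), n, n)
    img[disk_mask(n, radius = 4)] <- img[disk_mask(n, radius = 4)] + 2
    p <- rats_params(noise_sd = 0.05, lambda_factor = 3, min_leaf = 16L)
    # min_leaf = image size: a single leaf, so one global weighted threshold
    mask <- rats_threshold(img, p)
    brute <- brute_rats_single_leaf(img, 3, 0.05)
    surf <- attr(mask, "threshold_surface")
    expect_lt(max(abs(surf - brute)), 1e-9)
    expect_identical(unclass(mask)[, ], img >= brute)
  }
})

test_that("RATS recovers a two-level step and rejects flat images", {
  a <- 0.2; b <- 0.8
  img <- cbind(matrix(a, 64, 32), matrix(b, 64, 32))
  # single-leaf: the only weighted pixels straddle the edge symmetrically, so
  # the global threshold is (a + b) / 2 and the mask is exactly the b-region
  mask <- rats_threshold(img, rats_params(noise_sd = 1e-6, min_leaf = 64L))
  expect_true(all(mask[, 33:64]))
  expect_false(any(mask[, 1:32]))
  surf <- attr(mask, "threshold_surface")
  expect_equal(mean(surf), (a + b) / 2, tolerance = 1e-9)
  expect_error(rats_threshold(matrix(1, 64, 64), rats_params(noise_sd = 0.1)),
               class = "laserlesion_no_edges_error")
})

test_that("RATS segments a synthetic disk lesion accurately", {
  sim <- simulate_viability_image(pt_beam(), pt_thermal(), pt_phenotype(), seed = 4)
  sig <- correct_bleedthrough(sim$image)
  d <- enhance_contrast(sig$damage)
  mask <- rats_threshold(d, rats_params(min_leaf = 16L))
  mask <- clean_mask(mask)
  fm <- finalize_mask(mask)
  expect_gte(jaccard(fm$mask, sim$truth$death_region), 0.9)
})

test_that("mask cleaning removes thin structure but preserves large convex regions", {
  sq <- matrix(FALSE, 220, 220); sq[11:210, 11:210] <- TRUE
  expect_equal(sum(clean_mask(sq)), sum(sq))  # opening identity on a big square
  # scattered single pixels all removed
  set.seed(9)
  sp <- matrix(FALSE, 64, 64)
  sp[sample(64 * 64, 12)] <- TRUE
  expect_error(clean_mask(sp), class = "laserlesion_empty_mask_error")
  # disk with a 5-px spur on a 64x64 instance: clean_mask equals a
  # brute-force opening oracle (union of all 21x21 squares inside the mask)
  # and the spur is removed
  dk <- disk_mask(64, center = c(32, 32), radius = 22)
  spur <- dk; spur[30:34, 54:64] <- TRUE
  cleaned <- clean_mask(spur, 10)
  brute <- matrix(FALSE, 64, 64)
  for (r in 11:54) for (cc in 11:54)
    if (all(spur[(r - 10):(r + 10), (cc - 10):(cc + 10)]))
      brute[(r - 10):(r + 10), (cc - 10):(cc + 10)] <- TRUE
  expect_identical(unclass(cleaned), brute)
  expect_false(any(cleaned[, 55:64]))            # spur gone
  # a disk much larger than the structuring element keeps its area within 5%
  big <- disk_mask(160, radius = 70)
  expect_lt(abs(sum(clean_mask(big)) - sum(big)) / sum(big), 0.05)
  # idempotence up to boundary effects (area within 1%)
  once <- clean_mask(spur); twice <- clean_mask(once)
  expect_lt(abs(sum(twice) - sum(once)) / sum(once), 0.01)
})

test_that("finalisation yields one contiguous hole-free region and flags ambiguity", {
  dk <- disk_mask(96, center = c(40, 40), radius = 20)
  dk[60:62, 60:62] <- NA  # placeholder, replaced below
  dk <- disk_mask(96, center = c(40, 40), radius = 20)
  dk[38:42, 38:42] <- FALSE           # interior hole
  blob <- dk; blob[90:92, 90:92] <- TRUE  # far small blob
  fm <- finalize_mask(blob)
  expect_false(any(fm$mask[90:92, 90:92]))
  expect_true(all(fm$mask[38:42, 38:42]))  # hole filled
  expect_false(fm$needs_review)
  lab <- laserlesion:::label_components(fm$mask)
  expect_equal(attr(lab, "n"), 1L)
  # annulus -> filled disk
  ann <- disk_mask(64, radius = 25) & !disk_mask(64, radius = 15)
  fa <- finalize_mask(ann)
  expect_equal(sum(fa$mask), sum(disk_mask(64, radius = 25)))
  # two equal-area components -> needs_review
  two <- matrix(FALSE, 80, 80)
  two[10:30, 10:30] <- TRUE; two[50:70, 50:70] <- TRUE
  expect_true(finalize_mask(two)$needs_review)
  expect_error(finalize_mask(matrix(FALSE, 10, 10)), class = "laserlesion_empty_mask_error")
})

test_that("the four-stringency schedule behaves and degrades gracefully", {
  expect_error(build_mask_set(matrix(0, 64, 64), default_rats_schedule()[1:3]),
               class = "laserlesion_parameter_error")
  bad <- default_rats_schedule(c(8L, 8L, 16L, 32L))
  expect_error(build_mask_set(matrix(0, 64, 64), bad),
               class = "laserlesion_parameter_error")
  # blank image: all four stringencies fail
  set.seed(3)
  blank <- matrix(rnorm(256 * 256, 0, 0.01), 256, 256)
  expect_error(build_mask_set(blank), class = "laserlesion_all_masks_failed_error")
  # synthetic lesion: all masks contain the beam centre; boundary roughness
  # (perimeter^2 / area) does not increase with coarser leaves
  sim <- simulate_viability_image(pt_beam(), pt_thermal(), pt_phenotype(), seed = 6)
  masks <- mask_pipeline(sim$image)
  ctr <- round(sim$truth$beam_center_px)
  rough <- vapply(masks, function(m) {
    expect_true(m$mask[ctr[1], ctr[2]])
    ring <- m$mask & !laserlesion:::binary_erode(m$mask, 1)
    sum(ring)^2 / sum(m$mask)
  }, numeric(1))
  expect_lte(rough[length(rough)], rough[1] * 1.05)
  # determinism: same image, same schedule -> identical masks
  masks2 <- mask_pipeline(sim$image)
  expect_identical(lapply(masks, `[[`, "mask"), lapply(masks2, `[[`, "mask"))
})
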