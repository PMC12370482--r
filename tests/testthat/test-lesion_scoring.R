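# Scoring criteria against generator ground truth and constructed edge cases.

# paint a minimal image: uniform live carpet plus red nuclei at given centres
scored_image <- function(n = 200, nuclei = NULL, pitch = 3, carpet = 15000,
                         erase = NULL, blob = NULL) {
  g <- matrix(carpet, n, n); r <- matrix(0, n, n)
  if (!is.null(nuclei) && nrow(nuclei)) {
    r <- r + laserlesion:::paint_disks(n, n, nuclei[, 1], nuclei[, 2],
                                       5 / pitch, 30000, op = "max")
    g[r > 0] <- 0
  }
  if (!is.null(erase)) g[erase] <- 0
  if (!is.null(blob)) g <- g + blob
  set.seed(99)
  g <- pmax(round(g + matrix(rnorm(n * n, 400, 100), n, n)), 0)
  r <- pmax(round(r + matrix(rnorm(n * n, 400, 100), n, n)), 0)
  two_channel_image(g, r, pitch)
}

small_beam <- function() beam_profile(416, 10, 447, 200)

test_that("dead-cell detection finds nuclei and matches generator truth", {
  expect_equal(nrow(detect_dead_cells(scored_image())), 0L)
  # constructed non-touching nuclei are all recovered near their centres
  set.seed(5)
  pts <- cbind(sample(seq(20, 180, 12)), sample(seq(20, 180, 12)))
  img <- scored_image(nuclei = pts)
  found <- detect_dead_cells(img)
  expect_equal(nrow(found), nrow(pts))
  d <- sapply(seq_len(nrow(pts)), function(i)
    min(sqrt((found[, 1] - pts[i, 1])^2 + (found[, 2] - pts[i, 2])^2)))
  expect_lt(max(d) * img$pixel_pitch, 10)  # within 2 nucleus radii
  # generator image: merged nuclei reduce the centroid count, but the
  # area-based estimate over all components stays near the truth
  sim <- simulate_viability_image(pc_beam(), pc_thermal(), pc_phenotype(p = 0.3),
                                  seed = 7)
  truth_n <- nrow(sim$truth$dead_cell_centroids)
  cc <- detect_dead_cells(sim$image)
  est_n <- sum(attr(cc, "components")$est_n)
  expect_lte(nrow(cc), truth_n)
  expect_gt(est_n, 0.75 * truth_n)
  expect_lt(est_n, 1.25 * truth_n)
  # saturated red frame -> QC error
  sat <- two_channel_image(matrix(100, 50, 50), matrix(30000, 50, 50), 3)
  expect_error(detect_dead_cells(sat), class = "laserlesion_qc_error")
})

test_that("photochemical scoring applies the five-cell, circularity and footprint rules", {
  beam <- small_beam()
  ctr <- 100.5
  # 4 dead cells centrally: negative for want of a fifth
  th <- seq(0, 2 * pi, length.out = 5)[1:4]
  pts4 <- cbind(ctr + 15 * cos(th), ctr + 15 * sin(th))
  rep4 <- score_photochemical(scored_image(nuclei = pts4), beam)
  expect_equal(rep4$outcome, "negative")
  expect_true("min dead cells" %in% rep4$reasons)
  # a 12-cell circular cluster well inside the footprint: positive
  th <- seq(0, 2 * pi, length.out = 13)[1:12]
  pts12 <- rbind(cbind(ctr + 25 * cos(th), ctr + 25 * sin(th)), c(ctr, ctr))
  rep12 <- score_photochemical(scored_image(nuclei = pts12), beam)
  expect_equal(rep12$outcome, "positive")
  expect_gte(rep12$circularity, 0.6)
  # 30 dead cells spread over 2x the beam diameter: exceeds footprint
  set.seed(8)
  pts30 <- cbind(runif(30, 40, 160), runif(30, 40, 160)) # 120 px = 360 um > 1.05 * footprint... keep inside image
  big <- scored_image(n = 300, nuclei = cbind(runif(30, 10, 290), runif(30, 10, 290)))
  repb <- score_photochemical(big, beam_profile(416, 10, 447, 200,
                                                center = c(150, 150)))
  expect_equal(repb$outcome, "negative")
  expect_true("exceeds footprint" %in% repb$reasons)
  # generator photochemical lesion at p = 0.5: positive
  sim <- simulate_viability_image(pc_beam(), pc_thermal(), pc_phenotype(p = 0.5),
                                  seed = 9)
  expect_equal(score_photochemical(sim$image, pc_beam())$outcome, "positive")
})

test_that("photothermal scoring requires a central contiguous dead core", {
  # generator lesion with the isotherm exceeded centrally: positive
  sim <- simulate_viability_image(pt_beam(), pt_thermal(), pt_phenotype(), seed = 10)
  expect_equal(score_photothermal(sim$image, pt_beam())$outcome, "positive")
  # halo-only world: T_crit above the centre temperature, halo band reached
  halo_only <- lesion_phenotype_params("photothermal", T_crit = 52, halo_width = 4)
  sim2 <- simulate_viability_image(pt_beam(), pt_thermal(), halo_only, seed = 11)
  expect_equal(sum(sim2$truth$death_region), 0)
  expect_equal(score_photothermal(sim2$image, pt_beam())$outcome, "negative")
  # blank image: negative
  expect_equal(score_photothermal(scored_image(), small_beam())$outcome, "negative")
})

test_that("QC heuristics flag disrupted monolayers and foreign material", {
  beam <- small_beam()
  expect_null(qc_exclusion(scored_image(), beam))
  sim <- simulate_viability_image(pt_beam(), pt_thermal(), pt_phenotype(), seed = 12)
  expect_null(qc_exclusion(sim$image, pt_beam()))
  # a contiguous scrape removing ~45% of the carpet outside the footprint
  n <- 200
  erase <- matrix(FALSE, n, n)
  erase[1:90, ] <- TRUE
  erase[disk_mask(n, radius = 70)] <- FALSE
  expect_equal(qc_exclusion(scored_image(erase = erase), beam), "monolayer disruption")
  # a ~5000 um^2 bright blob outside the footprint
  blob <- laserlesion:::paint_disks(n, n, 30, 30, 13, 60000)
  expect_equal(qc_exclusion(scored_image(blob = blob), beam), "foreign material")
})

test_that("scorers discriminate sub- from supra-threshold lesions across seeds", {
  # reduced-n version of the sensitivity/specificity >= 0.9 invariant
  pc_pos <- pc_neg <- pt_pos <- pt_neg <- 0
  n_per <- 8
  for (s in seq_len(n_per)) {
    supra <- simulate_viability_image(pc_beam(), pc_thermal(), pc_phenotype(p = 0.5),
                                      seed = 20 + s)
    sub <- simulate_viability_image(pc_beam(), pc_thermal(),
                                    pc_phenotype(p = 0.005), seed = 40 + s)
    pc_pos <- pc_pos + (score_photochemical(supra$image, pc_beam())$outcome == "positive")
    pc_neg <- pc_neg + (score_photochemical(sub$image, pc_beam())$outcome == "negative")
    supra_t <- simulate_viability_image(pt_beam(), pt_thermal(), pt_phenotype(),
                                        seed = 60 + s)
    sub_t <- simulate_viability_image(pt_beam(), pt_thermal(),
                                      lesion_phenotype_params("photothermal", T_crit = 52),
                                      seed = 80 + s)
    pt_pos <- pt_pos + (score_photothermal(supra_t$image, pt_beam())$outcome == "positive")
    pt_neg <- pt_neg + (score_photothermal(sub_t$image, pt_beam())$outcome == "negative")
  }
  expect_gte(pc_pos / n_per, 0.9)
  expect_gte(pc_neg / n_per, 0.9)
  expect_gte(pt_pos / n_per, 0.9)
  expect_gte(pt_neg / n_per, 0.9)
})

test_that("photochemical positive rate is monotone in p_death_max", {
  rate <- sapply(c(0.05, 0.3, 0.8), function(p) {
    mean(sapply(1:6, function(s) {
      sim <- simulate_viability_image(pc_beam(), pc_thermal(), pc_phenotype(p = p),
                                      seed = 200 + s)
      score_photochemical(sim$image, pc_beam())$outcome == "positive"
    }))
  })
  expect_true(all(diff(rate) >= 0))
})
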