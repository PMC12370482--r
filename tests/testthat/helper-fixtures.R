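# Shared fixtures: small worlds for the photothermal / photochemical
# phenotypes (3-s exposures keep thermal stacks small; the model reaches
# steady state by ~1.5 s with the default 0.4-s rise constant).

pt_beam <- function(irradiance = 12.22, duration = 3)
  beam_profile(416, irradiance, 2000, duration_s = duration)

pt_thermal <- function(ambient = 34.5)
  thermal_model_params(ambient = ambient, k_slope = 15.5 / 12.22, intercept = 0)

pt_phenotype <- function(...) lesion_phenotype_params("photothermal", T_crit = 46, ...)

pc_beam <- function(irradiance = 15, duration = 3)
  beam_profile(416, irradiance, 447, duration_s = duration)

pc_thermal <- function() thermal_model_params(ambient = 34.5, k_slope = 0.2, intercept = 0)

pc_phenotype <- function(p = 1, ...)
  lesion_phenotype_params("photochemical", p_death_max = p, ...)

# a filled disk mask
disk_mask <- function(n, center = c((n + 1) / 2, (n + 1) / 2), radius) {
  outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, "+") <= radius^2
}

# brute-force RATS oracle for a single quadtree leaf spanning the image:
# weighted-mean threshold over gradient-gated pixels
brute_rats_single_leaf <- function(img, lambda_factor, noise_sd) {
  g <- laserlesion:::sobel_magnitude(img)
  w <- ifelse(g > lambda_factor * noise_sd, g^2, 0)
  sum(w * img) / sum(w)
}

# registered mask built directly from a disk in thermal coordinates (bypasses
# the fluorescence pipeline; used for mask-selection tests)
disk_registered_mask <- function(video, center, radius_px, stringency = 0L) {
  d <- dim(video$frames)[2:3]
  m <- outer((seq_len(d[1]) - center[1])^2, (seq_len(d[2]) - center[2])^2, "+") <= radius_px^2
  structure(list(mask = m, transform = list(), stringency_index = stringency),
            class = "registered_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
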