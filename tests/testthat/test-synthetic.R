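test_that("single-sphere mask matches the analytic sphere volume", {
  cfg <- lesion_sim_config(grid_shape = c(64, 64, 64), spacing_mm = 1,
                           n_components = 1, radius_range_mm = c(5, 5),
                           dispersion_mm = 0, seed = 1)
  sim <- make_lesion_mask(cfg)
  expect_equal(sim$ground_truth$n_components, 1)
  vol <- sum(sim$mask$data)  # 1 mm^3 voxels
  expect_lt(abs(vol - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.15)
  expect_equal(sum(sim$ground_truth$component_volumes_mm3), vol)
})

test_that("generated blobs are disjoint and ground truth matches labeling", {
  for (seed in 1:5) {
    cfg <- lesion_sim_config(n_components = 4, dispersion_mm = 20,
                             seed = seed)
    sim <- make_lesion_mask(cfg)
    expect_equal(sim$ground_truth$n_components, 4)
    # even under the most permissive adjacency the guard keeps blobs apart
    expect_equal(label_components(sim$mask, 26)$n_components, 4)
    expect_equal(label_components(sim$mask, 6)$n_components, 4)
  }
})

test_that("lesion generation is bit-reproducible under a fixed seed", {
  cfg <- lesion_sim_config(n_components = 3, dispersion_mm = 15, seed = 99)
  a <- make_lesion_mask(cfg)
  b <- make_lesion_mask(cfg)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("impossible placement fails loudly, not silently", {
  cfg <- lesion_sim_config(grid_shape = c(16, 16, 16), spacing_mm = 1,
                           n_components = 30, radius_range_mm = c(5, 6),
                           dispersion_mm = 2, seed = 1, max_tries = 200)
  expect_error(make_lesion_mask(cfg), "could not place")
})

test_that("config invariants are enforced", {
  expect_error(lesion_sim_config(grid_shape = c(8, 64, 64)), "16")
  expect_error(lesion_sim_config(n_components = 0), "n_components")
  expect_error(lesion_sim_config(radius_range_mm = c(6, 3)), "radius")
  expect_error(lesion_sim_config(dispersion_mm = -1), "dispersion")
})

test_that("ADC volumes have the right contrast, spacing and determinism", {
  cfg <- lesion_sim_config(n_components = 2, seed = 5)
  sim <- make_lesion_mask(cfg)
  adc <- make_adc_volume(sim$mask, 400e-6, 800e-6, noise_sd = 0)
  expect_identical(adc$spacing_mm, sim$mask$spacing_mm)
  expect_true(all(adc$data[sim$mask$data == 1L] == 400e-6))
  expect_true(all(adc$data[sim$mask$data == 0L] == 800e-6))

  noisy1 <- make_adc_volume(sim$mask, noise_sd = 50e-6, seed = 3)
  noisy2 <- make_adc_volume(sim$mask, noise_sd = 50e-6, seed = 3)
  expect_identical(noisy1$data, noisy2$data)

  expect_error(make_adc_volume(sim$mask, 800e-6, 400e-6), "below")

  empty <- lesion_mask(array(0L, c(16, 16, 16)), 1)
  flat <- make_adc_volume(empty, noise_sd = 0)
  expect_true(all(flat$data == 800e-6))
})

test_that("toy atlas partitions the grid with consistent geometry", {
  atl <- make_toy_atlas(c(32, 32, 32), 1, shell_voxels = 2)
  expect_true(all(atl$labels >= 1 & atl$labels <= 8))

  tab <- atl$label_table
  hemi <- tab$hemisphere[match(as.vector(atl$labels), tab$label)]
  i <- as.vector(slice.index(atl$labels, 1))
  expect_true(all(hemi[i <= 16] == "left"))
  expect_true(all(hemi[i > 16] == "right"))

  # cortical labels lie within 2 voxels of the outer boundary
  cort <- array(tab$cortical[match(as.vector(atl$labels), tab$label)],
                dim(atl$labels))
  idx <- which(cort, arr.ind = TRUE)
  d_edge <- pmin(idx - 1, sweep(-idx, 2, dim(atl$labels), `+`))
  expect_true(all(apply(d_edge, 1, min) < 2))
})

test_that("cohort simulation hits the target prevalence under the null", {
  cfg <- cohort_sim_config(5000, beta = numeric(0) ,
                           intercept = qlogis(0.12), seed = 21)
  coh <- simulate_cohort(cfg)
  se <- sqrt(0.12 * 0.88 / 5000)
  expect_lt(abs(mean(coh$af) - 0.12), 2 * se)
  expect_identical(coh, simulate_cohort(cfg))
})

test_that("cohort config validates beta names and sizes", {
  expect_error(cohort_sim_config(0), "n_subjects")
  expect_error(cohort_sim_config(10, beta = c(nonexistent = 1)),
               "no generated feature")
  expect_error(cohort_sim_config(10, beta = c(age = Inf)), "finite")
})

test_that("univariate fit recovers a planted OBB-volume odds ratio", {
  hits <- 0L
  n_seeds <- 100
  for (seed in seq_len(n_seeds)) {
    cfg <- cohort_sim_config(2000, beta = c(obb_volume_ml = log(1.72)),
                             seed = seed)
    prep <- prepare_features(simulate_cohort(cfg))
    or <- fit_univariate(prep, "obb_volume_ml")$or
    if (or >= 1.4 && or <= 2.1) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_seeds)
})
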