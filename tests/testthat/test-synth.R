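test_that("zero target density yields a poreless specimen with zero porosity", {
  g <- generate_specimen(synthetic_spec(seed = 5, target_pore_density = 0,
                                        noise_sigma = 0, debris_count = 0))
  expect_equal(n_pores(g$truth$pore_mask), 0L)
  expect_equal(g$truth$porosity_pct, 0)
  expect_equal(g$truth$pd, 0)
})

test_that("pore areas are exact pixel counts and identical when CV = 0", {
  g <- generate_specimen(synthetic_spec(seed = 11, pixel_size = 0.5,
                                        image_shape = c(1456L, 544L),
                                        pore_area_mean = 16,
                                        pore_area_cv = 0,
                                        noise_sigma = 0, debris_count = 0))
  tr <- g$truth$true_params$pores
  # every declared area equals its rendered pixel count times pixel area
  px_counts <- tabulate(g$truth$pore_mask$labels[g$truth$pore_mask$labels > 0])
  expect_equal(tr$area_um2[!tr$occluded], px_counts * 0.25)
  # CV 0 at pixel_size 0.5: every pore is exactly 64 pixels = 16 um^2
  expect_true(all(tr$area_um2 == 16))
  expect_equal(g$truth$mps, 16)
  expect_equal(g$truth$porosity_pct, 100 * g$truth$pd * 16)
})

test_that("identical seed and spec regenerate bit-identical outputs", {
  sp <- synthetic_spec(seed = 42)
  g1 <- generate_specimen(sp)
  g2 <- generate_specimen(sp)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$truth$pore_mask$labels, g2$truth$pore_mask$labels)
  expect_identical(g1$truth$chamber_map$labels, g2$truth$chamber_map$labels)
  expect_identical(g1$truth$debris_mask, g2$truth$debris_mask)
})

test_that("per-specimen porosity identity and density targeting hold", {
  for (g in list(clean_specimen(), noisy_specimen())) {
    expect_lt(abs(g$truth$porosity_pct - 100 * g$truth$pd * g$truth$mps),
              1e-9)
    # achieved whole-test density within 10% of the requested target
    expect_lt(abs(g$truth$pd - g$spec$target_pore_density) /
                g$spec$target_pore_density, 0.10)
  }
})

test_that("debris occludes whole pores and masks stay disjoint", {
  g <- noisy_specimen()
  expect_true(any(g$truth$debris_mask))
  pore_px <- g$truth$pore_mask$labels > 0
  expect_equal(sum(pore_px & g$truth$debris_mask), 0L)
  off_test <- g$truth$chamber_map$labels == 0L
  expect_equal(sum(pore_px & off_test), 0L)
  expect_equal(sum(g$truth$debris_mask & off_test), 0L)
  # totals in the per-chamber table equal the visible mask totals
  vis <- visible_truth(g)
  expect_equal(sum(g$truth$true_params$per_chamber$n_pores), nrow(vis))
  expect_equal(n_pores(g$truth$pore_mask), nrow(vis))
})

test_that("geometrically impossible densities fail naming the chamber", {
  expect_error(
    generate_specimen(synthetic_spec(seed = 1, target_pore_density = 0.03,
                                     pore_area_mean = 40)),
    "density unattainable.*chamber")
})

test_that("cohort generation is deterministic and validates its inputs", {
  c1 <- generate_cohort(1, "guayaquil", seed = 3)
  expect_length(c1, 1L)
  t1 <- draw_cohort_targets(40, "okhotsk", seed = 8)
  t2 <- draw_cohort_targets(40, "okhotsk", seed = 8)
  expect_identical(t1, t2)
  expect_error(generate_cohort(3, "atlantis", seed = 1), "unknown preset")
  expect_error(generate_cohort(0, "default", seed = 1), "n must be >= 1")
})

test_that("cohort targets converge to the preset parameters", {
  for (preset in c("guayaquil", "okhotsk", "default")) {
    p <- cohort_presets()[[preset]]
    tg <- draw_cohort_targets(500, preset, seed = 13)
    expect_lt(abs(mean(tg$pd) - p$pd_mean), 3 * p$pd_sd / sqrt(500))
    expect_lt(abs(mean(tg$mps) - p$mps_mean), 3 * p$mps_sd / sqrt(500))
  }
})

test_that("rendered guayaquil cohort reproduces the preset mean pore density", {
  cohort <- generate_cohort(100, "guayaquil", seed = 21)
  pd <- vapply(cohort, function(s) s$truth$pd, 0)
  sem <- cohort_presets()$guayaquil$pd_sd / sqrt(length(pd))
  expect_lt(abs(mean(pd) - 0.0043), 2 * sem)
})
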