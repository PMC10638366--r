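test_that("test-mask detection recovers the silhouette and handles degenerate frames", {
  g <- clean_specimen()
  mask <- detect_test_mask(g$image)
  sil <- g$truth$chamber_map$labels > 0
  iou <- sum(mask & sil) / sum(mask | sil)
  expect_gte(iou, 0.95)

  blank <- sem_image(matrix(0, 64, 64), pixel_size = 1)
  expect_error(detect_test_mask(blank), "no specimen found")

  bright <- sem_image(matrix(1, 64, 64), pixel_size = 1)
  expect_true(all(detect_test_mask(bright)))
})

test_that("classical segmentation recovers exact counts on noise-free images", {
  g <- clean_specimen()
  lm <- segment_pores_classical(g$image)
  expect_identical(n_pores(lm), n_pores(g$truth$pore_mask))

  poreless <- generate_specimen(synthetic_spec(seed = 9,
                                               target_pore_density = 0,
                                               noise_sigma = 0,
                                               debris_count = 0))
  expect_identical(n_pores(segment_pores_classical(poreless$image)), 0L)
})

test_that("classical segmentation stays accurate at default noise", {
  g <- noisy_specimen()
  lm <- segment_pores_classical(g$image)
  nt <- n_pores(g$truth$pore_mask)
  expect_lt(abs(n_pores(lm) - nt) / nt, 0.05)
  # per-pore area accuracy: match segmented pores to truth by centroid
  roi <- whole_test_roi(g)
  recs <- measure_pores(lm, roi, g$image$pixel_size)
  tr <- visible_truth(g)
  nn <- vapply(seq_len(nrow(recs)), function(i) {
    d2 <- (tr$row - 1 - recs$centroid_row[i])^2 +
      (tr$col - 1 - recs$centroid_col[i])^2
    which.min(d2)
  }, 0L)
  rel_err <- abs(recs$area_um2 - tr$area_um2[nn]) / tr$area_um2[nn]
  expect_lte(median(rel_err), 0.10)
})

test_that("label maps satisfy the configured filters", {
  g <- noisy_specimen()
  cfg <- seg_config(min_pore_area = 2, max_pore_area = 100)
  lm <- segment_pores_classical(g$image, cfg)
  areas <- tabulate(lm$labels[lm$labels > 0]) * g$image$pixel_size^2
  expect_true(all(areas >= cfg$min_pore_area))
  expect_true(all(areas <= cfg$max_pore_area))
  # labels are consecutive 1..k
  expect_identical(sort(unique(as.vector(lm$labels[lm$labels > 0]))),
                   seq_len(n_pores(lm)))
  expect_error(seg_config(min_pore_area = 5, max_pore_area = 2),
               "min_pore_area")
})

test_that("classical labels are invariant to positive intensity rescaling", {
  g <- clean_specimen()
  lm1 <- segment_pores_classical(g$image)
  scaled <- sem_image(g$image$pixels * 0.7, g$image$pixel_size,
                      id = g$image$id)
  lm2 <- segment_pores_classical(scaled)
  expect_identical(lm1$labels, lm2$labels)
})

test_that("watershed splitting separates touching pores without over-splitting", {
  px <- matrix(0.8, 96, 96)
  # two overlapping discs forming a dumbbell of dark pixels
  for (ctr in list(c(48, 40), c(48, 57))) {
    d <- outer((1:96 - ctr[1])^2, (1:96 - ctr[2])^2, "+")
    px[d <= 100] <- 0.2
  }
  img <- sem_image(px, pixel_size = 1)
  mask <- matrix(TRUE, 96, 96)
  no_split <- segment_pores_classical(img, seg_config(split_touching = FALSE,
                                                      max_pore_area = 2000),
                                      test_mask = mask)
  split <- segment_pores_classical(img, seg_config(split_touching = TRUE,
                                                   max_pore_area = 2000),
                                   test_mask = mask)
  expect_identical(n_pores(no_split), 1L)
  expect_identical(n_pores(split), 2L)
  # a single elliptical pore is not split
  px2 <- matrix(0.8, 96, 96)
  d <- outer((1:96 - 48)^2 / 18^2, (1:96 - 48)^2 / 9^2, "+")
  px2[d <= 1] <- 0.2
  one <- segment_pores_classical(sem_image(px2, 1),
                                 seg_config(split_touching = TRUE,
                                            max_pore_area = 2000),
                                 test_mask = mask)
  expect_identical(n_pores(one), 1L)
})

test_that("artifact removal never increases the pore count", {
  g <- noisy_specimen()
  lm <- segment_pores_classical(g$image)
  # empty artifact mask leaves the segmentation unchanged
  empty <- matrix(FALSE, nrow(lm$labels), ncol(lm$labels))
  same <- remove_artifacts(lm, empty, g$image$pixel_size)
  expect_identical(same$labels, lm$labels)
  expect_identical(same$provenance, "corrected")
  # mask covering everything removes all pores
  all_mask <- matrix(TRUE, nrow(lm$labels), ncol(lm$labels))
  none <- remove_artifacts(lm, all_mask, g$image$pixel_size)
  expect_identical(n_pores(none), 0L)
  # true debris mask: count can only stay equal or drop
  corrected <- remove_artifacts(lm, g$truth$debris_mask, g$image$pixel_size)
  expect_lte(n_pores(corrected), n_pores(lm))
  expect_error(remove_artifacts(lm, matrix(FALSE, 10, 10), 0.6),
               "shape")
})

test_that("manual artifact correction does not change cohort pore density", {
  # automated measurements with and without removing the (known) debris
  # pixels agree: the two cohort mean PDs are statistically
  # indistinguishable
  cohort <- cohort_noisy50()
  pd_raw <- pd_cor <- numeric(length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    lm <- segment_pores_classical(s$image)
    lmc <- remove_artifacts(lm, s$truth$debris_mask, s$image$pixel_size)
    roi <- whole_test_roi(s)
    pd_raw[i] <- nrow(measure_pores(lm, roi, s$image$pixel_size)) / roi$area
    pd_cor[i] <- nrow(measure_pores(lmc, roi, s$image$pixel_size)) / roi$area
  }
  res <- t_test(pd_cor, pd_raw, "student")
  expect_gt(res$p, 0.05)
})
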