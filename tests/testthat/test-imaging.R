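test_that("band extraction takes the nearest centers within half a spacing", {
  fix <- zero_noise_imaging()
  cube <- fix$cubes[[1]]
  sub <- extract_bands(cube, 1450)
  expect_equal(dim(sub$data)[3], 1L)
  expect_lte(abs(sub$band_centers - 1450), 5.876 / 2)

  exact <- cube$band_centers[40]
  expect_equal(extract_bands(cube, exact)$band_centers, exact)

  six <- extract_bands(cube, six_bands)
  expect_equal(dim(six$data)[3], 6L)
  expect_error(extract_bands(cube, 800), class = "nirfm_imaging_error")
})

test_that("background removal separates objects from the belt", {
  fix <- noisy_imaging()
  cube <- extract_bands(fix$cubes[[1]], six_bands)
  mask <- remove_background(cube, 1731)
  expect_equal(dim(mask), dim(cube$data)[1:2])
  in_mask <- sum(vapply(cube$truth$pixels, function(px) {
    sum(mask[cbind(px[, 1], px[, 2])])
  }, numeric(1)))
  total <- sum(vapply(cube$truth$pixels, nrow, integer(1)))
  expect_gt(in_mask / total, 0.95)

  low <- remove_background(cube, 1731, method = "fixed",
                           level = min(cube$data) - 1)
  expect_true(all(low))
  flat <- new_hypercube(array(1, dim = c(4, 4, 2)), c(1000, 1100))
  expect_error(remove_background(flat, 1000), class = "nirfm_imaging_error")
})

test_that("zero-noise pixel classification labels every FM pixel as FM", {
  fix <- zero_noise_imaging()
  w <- spectra_wavelengths(fix$training)
  idx <- sort(unique(sapply(six_bands, function(b) which.min(abs(w - b)))))
  model <- fit_plsda(fix$training[, c("sample_id", "label",
                                      names(fix$training)[-(1:2)][idx])],
                     n_lv = 5L)
  for (cube in fix$cubes) {
    sub <- extract_bands(cube, w[idx])
    mask <- remove_background(sub, 1731)
    map <- classify_pixels(sub, model, mask, median_filter = FALSE)
    for (i in which(cube$truth$class == "fm")) {
      px <- cube$truth$pixels[[i]]
      in_mask <- mask[cbind(px[, 1], px[, 2])]
      labels <- map[cbind(px[, 1], px[, 2])][in_mask]
      expect_true(all(labels == 2L))
    }
  }
})

test_that("empty masks give all-background maps and filters behave as stated", {
  fix <- zero_noise_imaging()
  cube <- extract_bands(fix$cubes[[1]], six_bands)
  w <- spectra_wavelengths(fix$training)
  idx <- sort(unique(sapply(six_bands, function(b) which.min(abs(w - b)))))
  model <- fit_plsda(fix$training[, c("sample_id", "label",
                                      names(fix$training)[-(1:2)][idx])],
                     n_lv = 5L)
  none <- classify_pixels(cube, model, matrix(FALSE, 48, 48))
  expect_true(all(none == 0L))

  # a single isolated mislabeled pixel survives without the median filter
  # and is removed by it
  mask <- matrix(FALSE, 48, 48)
  mask[24, 24] <- TRUE
  raw_map <- classify_pixels(cube, model, mask, median_filter = FALSE)
  expect_equal(sum(raw_map != 0L), 1L)
  smooth_map <- classify_pixels(cube, model, mask, median_filter = TRUE)
  expect_equal(sum(smooth_map != 0L), 0L)
})

test_that("detection scoring matches a brute-force overlap oracle", {
  truth <- tibble::tibble(
    object_id = 1:3,
    class = c("vegetable", "fm", "fm"),
    pixels = list(
      as.matrix(expand.grid(2:10, 2:10)),
      as.matrix(expand.grid(15:20, 4:9)),
      as.matrix(expand.grid(30:34, 25:29))
    )
  )
  map <- matrix(0L, 40, 40)
  map[2:10, 2:10] <- 1L
  map[15:20, 4:9] <- 2L          # detected FM
  map[36:38, 36:38] <- 2L        # spurious blob (false positive)
  map[12, 30] <- 2L              # single-pixel noise, below min_blob
  row <- score_detections(map, truth, min_blob = 5L, scene_id = "oracle")
  expect_equal(row$total_fms, 2L)
  expect_equal(row$detected_fms, 1L)
  expect_equal(row$false_positives, 1L)

  # brute-force oracle: intersect every truth FM with every surviving blob
  blobs <- nirfm:::label_components(map == 2L)
  sizes <- table(blobs[blobs > 0])
  keep <- as.integer(names(sizes)[sizes >= 5])
  oracle_detected <- 0L
  for (i in which(truth$class == "fm")) {
    px <- truth$pixels[[i]]
    ids <- setdiff(unique(blobs[px]), 0L)
    if (length(intersect(ids, keep)) > 0) oracle_detected <- oracle_detected + 1L
  }
  expect_equal(row$detected_fms, oracle_detected)
})

test_that("8-connected labeling joins diagonals and min_blob filters noise", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- m[2, 2] <- m[3, 3] <- TRUE
  lab <- nirfm:::label_components(m)
  expect_equal(max(lab), 1L)

  truth <- tibble::tibble(object_id = 1L, class = "fm",
                          pixels = list(cbind(1:3, 1:3)))
  map <- matrix(0L, 5, 5)
  map[cbind(1:3, 1:3)] <- 2L
  row <- score_detections(map, truth, min_blob = 5L)
  expect_equal(row$detected_fms, 0L)   # 3-pixel blob filtered out
  expect_equal(row$false_positives, 0L)
  row2 <- score_detections(map, truth, min_blob = 3L)
  expect_equal(row2$detected_fms, 1L)
})

test_that("detection is monotone in correctly placed FM pixels", {
  truth <- tibble::tibble(object_id = 1:2, class = c("vegetable", "fm"),
                          pixels = list(as.matrix(expand.grid(1:5, 1:5)),
                                        as.matrix(expand.grid(10:15, 10:15))))
  map <- matrix(0L, 20, 20)
  map[10:11, 10:15] <- 2L
  base <- score_detections(map, truth, min_blob = 5L)
  map2 <- map
  map2[12:15, 10:15] <- 2L
  more <- score_detections(map2, truth, min_blob = 5L)
  expect_gte(more$detected_fms, base$detected_fms)
})

test_that("aggregation reproduces pooled detection-rate arithmetic", {
  rows <- tibble::tibble(
    scene_id = paste0("v", 1:7),
    total_fms = c(13L, 18L, 13L, 16L, 12L, 16L, 19L),
    detected_fms = c(13L, 17L, 13L, 14L, 11L, 13L, 18L),
    false_positives = c(3L, 0L, 0L, 0L, 0L, 0L, 0L)
  )
  rep <- aggregate_report(rows)
  expect_equal(round(attr(rep, "overall_accuracy"), 1), 92.5)
  expect_equal(glance(rep)$detected_fms, 99L)
  expect_equal(glance(rep)$total_fms, 107L)

  all_found <- aggregate_report(dplyr::mutate(rows, detected_fms = total_fms))
  expect_equal(attr(all_found, "overall_accuracy"), 100)
  expect_error(aggregate_report(rows[0, ]), class = "nirfm_imaging_error")
  expect_error(aggregate_report(dplyr::mutate(rows, total_fms = 0L)),
               class = "nirfm_imaging_error")
})

test_that("end-to-end zero-noise detection is perfect with the six bands", {
  fix <- zero_noise_imaging()
  rep <- detect_fms(fix$cubes, fix$training, six_bands)
  expect_equal(attr(rep, "overall_accuracy"), 100)
  expect_equal(sum(rep$false_positives), 0L)
})

test_that("adding the 1450 nm water band strictly improves noisy detection", {
  fix <- noisy_imaging()
  ranked <- evaluate_band_combinations(fix$cubes, fix$training,
                                       list(five_bands, six_bands))
  expect_equal(ranked$n_bands[1], 6L)
  acc6 <- ranked$overall_accuracy[ranked$n_bands == 6]
  acc5 <- ranked$overall_accuracy[ranked$n_bands == 5]
  expect_gt(acc6, acc5)
  # ranking is invariant under input order
  flipped <- evaluate_band_combinations(fix$cubes, fix$training,
                                        list(six_bands, five_bands))
  expect_equal(ranked$bands, flipped$bands)
  expect_equal(ranked$overall_accuracy, flipped$overall_accuracy)
})
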