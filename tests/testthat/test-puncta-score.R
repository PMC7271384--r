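test_that("the dim-pixel cutoff follows the order-statistic rule", {
  expect_equal(baseline_cutoff(1:10, 0.4), 4)            # m = ceil(4) = 4
  expect_equal(baseline_cutoff(c(5, 5, 5), 0.4), 5)
  expect_equal(baseline_cutoff(1:3, 1), 3)               # f = 1 gives the max
  expect_equal(baseline_cutoff(c(2, 8, 10), 0.4, mode = "max_fraction"), 6)
  expect_error(baseline_cutoff(numeric(0), 0.4), "non-empty")
  expect_error(baseline_cutoff(1:5, 0), "f must be")
  expect_error(baseline_cutoff(1:5, 1.2), "f must be")
})

test_that("the baseline averages the dim pixels, with uniform fallback", {
  expect_equal(baseline_mean(1:10, 0.4), 2)              # mean(1:3)
  expect_equal(baseline_mean(rep(5, 3), 0.4), 5)         # fallback
  expect_equal(baseline_mean(c(1, 1, 1, 1, 100), 0.4), 1)  # fallback at ties
})

test_that("the 5x5 worked micro-example is reproduced exactly", {
  img <- matrix(1, 5, 5)
  img[3, 3] <- 100
  reg <- rect_region(1:5, 1:5)
  res <- nucleus_score(img, reg)
  expect_equal(res$baseline, 1)
  expect_equal(res$threshold, 1.5)
  block <- as.matrix(expand.grid(row = 2:4, col = 2:4))
  expect_equal(coord_set(res$positive_mask), coord_set(block))
  expect_equal(res$positive_sum, 108)
  expect_equal(res$nucleus_mean, 4.96)
  expect_equal(res$score, 108 / 4.96)
  oracle <- oracle_score_region(img, reg)
  expect_equal(res$score, oracle$score)
  expect_equal(coord_set(res$positive_mask), coord_set(oracle$positive))
})

test_that("uniform nuclei score zero and scaling leaves scores unchanged", {
  reg <- rect_region(1:5, 1:5)
  uniform <- matrix(7, 5, 5)
  expect_equal(nucleus_score(uniform, reg)$score, 0)
  expect_equal(nrow(positive_pixels(uniform, reg)), 0L)
  img <- matrix(1, 5, 5)
  img[3, 3] <- 100
  s1 <- nucleus_score(img, reg)$score
  for (c in c(0.5, 2, 255)) {
    sc <- nucleus_score(img * c, reg)
    expect_equal(sc$score, s1, tolerance = 1e-9)
    expect_equal(coord_set(sc$positive_mask),
                 coord_set(nucleus_score(img, reg)$positive_mask))
  }
})

test_that("neighborhood means never include pixels outside the region", {
  # bright pixel just outside the region must not pull its neighbors up
  img <- matrix(1, 5, 5)
  img[3, 4] <- 1000            # outside the 5x3 region below
  reg <- rect_region(1:5, 1:3)
  expect_equal(nrow(positive_pixels(img, reg)), 0L)
})

test_that("an all-zero nucleus scores 0 with a warning flag", {
  reg <- rect_region(1:4, 1:4)
  expect_warning(res <- nucleus_score(matrix(0, 4, 4), reg), "zero mean")
  expect_equal(res$score, 0)
  expect_true(res$zero_mean)
})

test_that("production scorer matches the brute-force oracle on random fields", {
  for (seed in 1:6) {
    f <- generate_nucleus_field(small_field_spec(seed = seed))
    seg <- segment_nuclei(f$dapi, segmentation_params(smoothing_sigma = 0))
    expect_gt(length(seg$regions), 0L)
    for (reg in seg$regions) {
      res <- nucleus_score(f$marker, reg)
      oracle <- oracle_score_region(f$marker, reg)
      expect_equal(coord_set(res$positive_mask), coord_set(oracle$positive))
      expect_equal(res$baseline, oracle$baseline)
      expect_equal(res$score, oracle$score, tolerance = 1e-9)
    }
  }
})

test_that("oracle agreement also holds in max_fraction mode and radius 0", {
  f <- generate_nucleus_field(small_field_spec(seed = 17))
  seg <- segment_nuclei(f$dapi, segmentation_params(smoothing_sigma = 0))
  reg <- seg$regions[[1]]
  pm <- puncta_params(baseline_mode = "max_fraction")
  res <- nucleus_score(f$marker, reg, pm)
  oracle <- oracle_score_region(f$marker, reg, mode = "max_fraction")
  expect_equal(res$score, oracle$score, tolerance = 1e-9)
  p0 <- puncta_params(neighborhood_radius = 0)
  res0 <- nucleus_score(f$marker, reg, p0)
  oracle0 <- oracle_score_region(f$marker, reg, radius = 0L)
  expect_equal(coord_set(res0$positive_mask), coord_set(oracle0$positive))
})

test_that("the response to brightening is monotone where it can be", {
  # Two sound monotonicity laws (the normalized score itself can drop
  # when a sub-threshold pixel is brightened without crossing the
  # threshold, because only the nuclear mean grows):
  #  (a) brightening a pixel strictly above the cutoff never decreases
  #      the positive-pixel sum (baseline and threshold are unchanged,
  #      window means only grow);
  #  (b) brightening an already-positive pixel never decreases the
  #      normalized score (the numerator gains at least the bump, and
  #      positive_sum <= area * nucleus_mean bounds the mean's growth).
  set.seed(99)
  f <- generate_nucleus_field(small_field_spec(seed = 23, puncta = 3L))
  seg <- segment_nuclei(f$dapi, segmentation_params(smoothing_sigma = 0))
  n_checked <- 0L
  for (reg in seg$regions) {
    ints <- f$marker[reg$pixel_coords]
    cutoff <- baseline_cutoff(ints, 0.4)
    above <- which(ints > cutoff)
    base <- nucleus_score(f$marker, reg)
    pos_keys <- coord_set(base$positive_mask)
    all_keys <- paste(reg$pixel_coords[, 1], reg$pixel_coords[, 2],
                      sep = ",")
    positive_idx <- which(all_keys %in% pos_keys)
    for (rep in seq_len(200)) {
      i <- above[sample.int(length(above), 1)]
      bump <- stats::runif(1, 0, 200)
      perturbed <- f$marker
      perturbed[reg$pixel_coords[i, 1], reg$pixel_coords[i, 2]] <-
        ints[i] + bump
      res <- nucleus_score(perturbed, reg)
      expect_gte(res$positive_sum, base$positive_sum - 1e-9)
      n_checked <- n_checked + 1L
    }
    if (length(positive_idx) == 0) next   # a punctum-free noisy nucleus
    for (rep in seq_len(140)) {
      i <- positive_idx[sample.int(length(positive_idx), 1)]
      bump <- stats::runif(1, 0, 200)
      perturbed <- f$marker
      perturbed[reg$pixel_coords[i, 1], reg$pixel_coords[i, 2]] <-
        ints[i] + bump
      res <- nucleus_score(perturbed, reg)
      expect_gte(res$score, base$score * (1 - 1e-9))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 1000L)
})

test_that("score_field composes segmentation and per-nucleus scoring", {
  f <- generate_nucleus_field(small_field_spec(seed = 3))
  sp <- segmentation_params(smoothing_sigma = 0)
  tab <- score_field(f$dapi, f$marker, sp)
  seg <- segment_nuclei(f$dapi, sp)
  expect_equal(nrow(tab), length(seg$regions))
  for (i in seq_along(seg$regions)) {
    res <- nucleus_score(f$marker, seg$regions[[i]])
    expect_equal(tab$score[i], res$score)
    expect_equal(tab$positive_count[i], res$positive_count)
    expect_equal(tab$baseline[i], res$baseline)
  }
  expect_identical(tab, score_field(f$dapi, f$marker, sp))  # deterministic
  expect_equal(nrow(score_field(matrix(0, 16, 16), matrix(0, 16, 16))), 0L)
  expect_error(score_field(matrix(0, 4, 4), matrix(0, 5, 5)), "same shape")
})
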