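test_that("identity and constant resampling are fixed points", {
  set.seed(21)
  vol <- make_vol(runif(32, 0, 50))
  same <- resample_to_reference(vol, vol, mode = "linear")
  expect_equal(same$data, vol$data, tolerance = 1e-6)

  # constant image onto a strictly finer interior grid stays constant
  const <- make_vol(7, dim = c(6, 6, 4), spacing = c(2, 2, 2))
  fine <- make_vol(0, dim = c(8, 8, 5), spacing = c(1, 1, 1), origin = c(1, 1, 1))
  res <- resample_to_reference(const, fine, mode = "linear")
  expect_true(all(abs(res$data - 7) < 1e-9))
})

test_that("nearest-neighbour resampling keeps masks binary", {
  set.seed(22)
  msk <- make_mask(rbinom(32, 1, 0.5))
  fine <- make_vol(0, dim = c(8, 8, 4), spacing = c(0.5, 0.5, 1.5),
                   origin = c(-0.25, -0.25, -0.75))
  up <- resample_to_reference(msk, fine, mode = "nearest")
  expect_true(all(up$data %in% c(0, 1)))
  expect_error(resample_to_reference(msk, fine, mode = "linear"), "nearest")
})

test_that("pooled histograms conserve and add voxel counts", {
  set.seed(23)
  vol <- make_vol(runif(32, 10, 90))
  msk <- make_mask(c(rep(1, 10), rep(0, 22)))
  h <- pooled_histogram(list(vol), list(msk), bins = 8)
  expect_equal(sum(h$counts), 10)
  h2 <- pooled_histogram(list(vol, vol), list(msk, msk), bins = 8)
  expect_equal(h2$counts, 2 * h$counts)

  ph <- generate_phantom(phantom_spec(seed = 23))
  n_in <- sum(ph$mask$data)
  h3 <- pooled_histogram(list(ph$water), list(ph$mask), bins = 256)
  expect_equal(sum(h3$counts), n_in)

  expect_error(pooled_histogram(list(), list()), "empty")
  expect_error(pooled_histogram(list(make_vol(7)), list(make_mask(1))), "zero-width")
})

test_that("Otsu separates a two-spike histogram exactly", {
  edges <- 0:101
  counts <- numeric(101)
  counts[1] <- 50    # intensity bin [0,1)
  counts[101] <- 50  # intensity bin [100,101]
  t <- otsu_threshold(intensity_histogram(edges, counts))
  expect_gt(t, 0)
  expect_lte(t, 100)
  vals <- c(rep(0.5, 50), rep(100.5, 50))
  expect_equal(sum(vals > t), 50)
})

test_that("Otsu equals the exhaustive between-class-variance scan", {
  h <- intensity_histogram(0:6, c(4, 2, 0, 0, 6, 3))
  expect_equal(otsu_threshold(h), oracle_otsu(h$bin_edges, h$counts))
  # maximizing between-class variance = minimizing within-class variance
  wv <- oracle_within_variance(h$bin_edges, h$counts)
  sigma <- eomhabitat:::otsu_between_class_variance(h)
  expect_equal(which.max(sigma), which.min(wv))

  set.seed(24)
  for (i in 1:200) {
    h <- random_histogram(64)
    expect_equal(otsu_threshold(h), oracle_otsu(h$bin_edges, h$counts))
  }
})

test_that("Otsu is invariant to count scaling and errors on a single spike", {
  set.seed(25)
  h <- random_histogram(32)
  h5 <- intensity_histogram(h$bin_edges, 5 * h$counts)
  expect_equal(otsu_threshold(h), otsu_threshold(h5))
  spike <- intensity_histogram(0:4, c(0, 7, 0, 0))
  expect_error(otsu_threshold(spike), "one bin")
})

test_that("exact ties resolve to the smallest threshold", {
  # symmetric two-spike histogram: cuts 1 and 2 tie exactly
  h <- intensity_histogram(0:3, c(5, 0, 5))
  sigma <- eomhabitat:::otsu_between_class_variance(h)
  expect_equal(sigma[1], sigma[2], tolerance = 1e-12)
  expect_equal(otsu_threshold(h), 1)
})

test_that("binarize applies a strict greater-than rule inside the mask", {
  vol <- make_vol(7)
  msk <- make_mask(1)
  expect_equal(sum(binarize(vol, msk, 7)$data), 0)   # boundary goes low
  expect_equal(sum(binarize(vol, msk, 6.5)$data), 32)
  set.seed(26)
  rv <- make_vol(runif(32, 0, 10))
  rm_ <- make_mask(rbinom(32, 1, 0.7))
  b <- binarize(rv, rm_, 5)
  expect_equal(b$data, array(as.numeric(rv$data > 5 & rm_$data == 1), dim = dim(rv$data)))
  expect_error(binarize(rv, make_mask(1, dim = c(4, 4, 3)), 5), "aligned")
})

test_that("habitat combination matches the 2x2 contingency of the channels", {
  msk <- make_mask(1)
  all_hl <- combine_habitats(binarize(make_vol(9), msk, 5), binarize(make_vol(1), msk, 5), msk)
  expect_true(all(all_hl$data == habitat_levels["HL"]))
  all_lh <- combine_habitats(binarize(make_vol(1), msk, 5), binarize(make_vol(9), msk, 5), msk)
  expect_true(all(all_lh$data == habitat_levels["LH"]))

  set.seed(27)
  w <- make_mask(rbinom(32, 1, 0.5))
  f <- make_mask(rbinom(32, 1, 0.5))
  lab <- combine_habitats(w, f, msk)
  counts <- habitat_counts(lab)
  tab <- table(factor(w$data, levels = 0:1), factor(f$data, levels = 0:1))
  expect_equal(unname(counts["LL"]), unname(tab["0", "0"]))
  expect_equal(unname(counts["HL"]), unname(tab["1", "0"]))
  expect_equal(unname(counts["LH"]), unname(tab["0", "1"]))
  expect_equal(unname(counts["HH"]), unname(tab["1", "1"]))
  expect_equal(sum(counts), sum(msk$data))
})

test_that("raising the water threshold only moves voxels out of the water-high classes", {
  ph <- generate_phantom(phantom_spec(seed = 28, noise_sd = 15))
  msk <- ph$mask
  tf <- 55
  lab1 <- combine_habitats(binarize(ph$water, msk, 40), binarize(ph$fat, msk, tf), msk)
  lab2 <- combine_habitats(binarize(ph$water, msk, 70), binarize(ph$fat, msk, tf), msk)
  moved <- which(lab1$data != lab2$data)
  expect_gt(length(moved), 0)
  # allowed transitions: HL -> LL, HH -> LH, nothing else
  expect_true(all(lab1$data[moved] %in% habitat_levels[c("HL", "HH")]))
  from_hl <- moved[lab1$data[moved] == habitat_levels["HL"]]
  from_hh <- moved[lab1$data[moved] == habitat_levels["HH"]]
  expect_true(all(lab2$data[from_hl] == habitat_levels["LL"]))
  expect_true(all(lab2$data[from_hh] == habitat_levels["LH"]))
})

test_that("cohort thresholds are symmetric in identical channels and stable under duplication", {
  td <- tempfile()
  mp <- generate_cohort(2, 2, td, seed = 29)
  m <- read_manifest(mp)
  # identical water and fat channels give identical thresholds
  m2 <- m
  m2$pre_fat <- m2$pre_water
  m2$post_fat <- m2$post_water
  thr <- compute_cohort_thresholds(m2, bins = 64)
  expect_identical(thr$t_water, thr$t_fat)
  # duplicating every subject leaves the pooled histogram shape unchanged
  m3 <- rbind(m, transform(m, patient_id = paste0(patient_id, "b")))
  class(m3) <- class(m)
  thr1 <- compute_cohort_thresholds(m, bins = 64)
  thr3 <- compute_cohort_thresholds(m3, bins = 64)
  expect_equal(thr1$t_water, thr3$t_water)
  expect_equal(thr1$t_fat, thr3$t_fat)
})

test_that("well-separated cohort modes put the water threshold between them", {
  td <- tempfile()
  means <- default_class_means()  # low 30 / high 80, sd 5 per channel
  mp <- generate_cohort(3, 3, td, seed = 30,
                        base_spec = phantom_spec(class_means = means, noise_sd = 3))
  thr <- compute_cohort_thresholds(read_manifest(mp))
  expect_gt(thr$t_water, 35); expect_lt(thr$t_water, 65)
  expect_gt(thr$t_fat, 35); expect_lt(thr$t_fat, 65)
})

test_that("phantom voxels recover their planted class almost everywhere", {
  ph <- generate_phantom(phantom_spec(seed = 31, noise_sd = 7))  # 7-SD separation
  thr_w <- otsu_threshold(pooled_histogram(list(ph$water), list(ph$mask)))
  thr_f <- otsu_threshold(pooled_histogram(list(ph$fat), list(ph$mask)))
  lab <- combine_habitats(binarize(ph$water, ph$mask, thr_w),
                          binarize(ph$fat, ph$mask, thr_f), ph$mask)
  in_mask <- ph$mask$data == 1
  agree <- mean(lab$data[in_mask] == ph$truth$data[in_mask])
  expect_gte(agree, 0.99)
})

test_that("label maps round-trip with their sidecar thresholds", {
  ph <- generate_phantom(phantom_spec(seed = 32))
  thr <- threshold_pair(55, 52, "test")
  lab <- combine_habitats(binarize(ph$water, ph$mask, thr$t_water),
                          binarize(ph$fat, ph$mask, thr$t_fat), ph$mask, thr)
  f <- tempfile(fileext = ".nii.gz")
  write_labelmap(lab, f)
  expect_true(file.exists(sub("\\.nii\\.gz$", ".json", f)))
  back <- read_labelmap(f)
  expect_equal(back$data, lab$data)
  expect_equal(back$thresholds$t_water, 55)
})
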