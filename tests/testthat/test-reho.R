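test_that("Kendall's W matches hand-computed cases", {
  # perfect concordance
  expect_equal(kendalls_w(rbind(1:4, 1:4, 1:4)), 1)
  # perfect discordance of two series: rank sums all equal
  expect_equal(kendalls_w(rbind(c(1, 2, 3), c(3, 2, 1))), 0)
  # K=3, T=3 with one reversed series: S = 2, W = 24/216 = 1/9
  expect_equal(kendalls_w(rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))), 1 / 9)
  # all series fully tied: undefined
  expect_true(is.nan(kendalls_w(rbind(c(1, 1, 1), c(2, 2, 2)))))
})

test_that("Kendall's W rejects degenerate input", {
  expect_error(kendalls_w(matrix(1:4, 1)), "at least 2 series")
  expect_error(kendalls_w(matrix(1:4, 2)), "at least 3 time points")
  expect_error(kendalls_w(rbind(c(1, NA, 3), 1:3)), "finite")
})

test_that("Kendall's W agrees with a brute-force oracle, with and without ties", {
  set.seed(42)
  for (i in 1:30) {
    x <- random_kcc_instance(sample(2:27, 1), sample(3:20, 1),
                             ties = i %% 2 == 0)
    expect_equal(kendalls_w(x), oracle_kendalls_w(x), tolerance = 1e-12)
  }
})

test_that("Kendall's W is invariant to the order of the series", {
  set.seed(7)
  for (i in 1:10) {
    x <- random_kcc_instance(sample(3:10, 1), sample(4:12, 1), ties = TRUE)
    expect_equal(kendalls_w(x), kendalls_w(x[sample(nrow(x)), ]))
  }
})

test_that("ReHo map is 1 when every voxel shares one non-constant series", {
  s <- sin(seq_len(20))
  dat <- array(rep(s, each = 5 * 5 * 5), c(5, 5, 5, 20))
  rm_ <- reho_map(volume_time_series(dat))
  expect_true(all(rm_$values == 1))
  expect_equal(rm_$neighbor_counts[3, 3, 3], 27L)
})

test_that("ReHo neighborhoods shrink at mask edges but stay defined", {
  set.seed(5)
  dat <- array(rnorm(6^3 * 30), c(6, 6, 6, 30))
  rm_ <- reho_map(volume_time_series(dat))
  expect_equal(rm_$neighbor_counts[1, 1, 1], 8L)   # corner: self + 7
  expect_equal(rm_$neighbor_counts[1, 3, 3], 18L)  # face
  expect_true(is.finite(rm_$values[1, 1, 1]))
  expect_true(all(rm_$values[is.finite(rm_$values)] >= 0 &
                    rm_$values[is.finite(rm_$values)] <= 1))
})

test_that("ReHo values stay in [0, 1] on heavily tied data", {
  set.seed(6)
  dat <- array(sample(0:2, 5^3 * 12, replace = TRUE), c(5, 5, 5, 12))
  rm_ <- reho_map(volume_time_series(dat * 1.0))
  v <- rm_$values[is.finite(rm_$values)]
  expect_gt(length(v), 0)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("constant series are excluded from the neighborhood count", {
  set.seed(8)
  dat <- array(rnorm(5^3 * 15), c(5, 5, 5, 15))
  dat[2, 2, 2, ] <- 3.14                 # flat series carries no ranks
  rm_ <- reho_map(volume_time_series(dat))
  expect_equal(rm_$neighbor_counts[3, 3, 3], 26L)
  full <- reho_map(volume_time_series(array(rnorm(5^3 * 15), c(5, 5, 5, 15))))
  expect_equal(full$neighbor_counts[3, 3, 3], 27L)
})

test_that("out-of-mask voxels are NaN and a min_neighbors floor applies", {
  set.seed(9)
  dat <- array(rnorm(5^3 * 10), c(5, 5, 5, 10))
  mask <- array(FALSE, c(5, 5, 5))
  mask[1, 1, 1] <- TRUE                  # isolated voxel: K = 1 < 2
  mask[4:5, 4:5, 4:5] <- TRUE
  rm_ <- reho_map(volume_time_series(dat, mask = mask))
  expect_true(is.nan(rm_$values[1, 1, 1]))
  expect_true(is.nan(rm_$values[3, 3, 3]))
  expect_true(is.finite(rm_$values[4, 4, 4]))
  rm9 <- reho_map(volume_time_series(dat, mask = mask), min_neighbors = 9)
  expect_true(all(is.nan(rm9$values)))   # all K = 8 < 9
})

test_that("regional means average defined voxels only", {
  a <- make_toy_atlas(c(10, 10, 10), 1, seed = 1)
  m <- array(NaN, dim(a$labels))
  vox <- which(a$labels == 1L)
  m[vox[1:2]] <- c(0.2, 0.4)
  m[a$labels == 2L] <- 0.5
  m[a$labels == 0L] <- 99                # background must never contribute
  means <- extract_regional_means(m, a)
  expect_equal(unname(means["region_01_L"]), 0.3)
  expect_equal(unname(means["region_01_R"]), 0.5)
  m[a$labels == 2L] <- NaN
  expect_warning(means2 <- extract_regional_means(m, a), "region_01_R")
  expect_true(is.nan(means2["region_01_R"]))
  expect_error(extract_regional_means(array(0, c(3, 3, 3)), a), "shape")
})

test_that("hemisphere averaging follows the (L+R)/2 and NaN contracts", {
  subj <- data.frame(subject_id = c("a", "b", "c"), age = c(30, 40, 50),
                     sex = c(0, 1, 0), dx = c(1, 0, 1))
  m <- cbind(front_L = c(0.2, NaN, -0.1), front_R = c(0.4, 0.4, -0.3),
             temp_L = c(1, 2, 3), temp_R = c(3, 2, 1))
  tab <- regional_table(subj, m)
  bi <- average_hemispheres(tab)
  expect_identical(bi$region_ids, c("front", "temp"))
  expect_equal(bi$measures[, "front"], c(0.3, NaN, -0.2))
  expect_equal(bi$measures[, "temp"], c(2, 2, 2))
  orphan <- regional_table(subj, cbind(front_L = c(1, 2, 3), temp_R = c(1, 2, 3)))
  expect_error(average_hemispheres(orphan), "front")
})
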