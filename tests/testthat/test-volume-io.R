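test_that("NIfTI write/read round-trips shape, affine and intensities", {
  dir <- withr::local_tempdir()
  arr <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  aff <- diag(c(2, 2, 2, 1))
  aff[1:3, 4] <- c(-10, 5, 3)
  v <- new_volume(arr, voxel_size_mm = c(2, 2, 2), space = "MNI152",
                  affine = aff)
  path <- file.path(dir, "vol.nii.gz")
  write_volume(v, path)
  back <- read_volume(path)
  expect_identical(dim(back$data), dim(arr))
  expect_equal(back$affine, aff, ignore_attr = TRUE, tolerance = 1e-5)
  expect_equal(back$voxel_size_mm, c(2, 2, 2), tolerance = 1e-5)
  expect_lt(max(abs(back$data - arr)), 1e-6)   # storage precision
})

test_that("4D images and missing files are rejected", {
  dir <- withr::local_tempdir()
  p4 <- file.path(dir, "ts.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), p4)
  expect_error(read_volume(p4), "3D")
  expect_error(read_volume(file.path(dir, "nope.nii")), "not found")
  expect_error(write_volume(new_volume(array(0, c(2, 2, 2))),
                            file.path(dir, "no/such/dir/x.nii")),
               "directory")
})

test_that("volume invariants are enforced", {
  expect_error(new_volume(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(new_volume(array(0, c(2, 2, 2)), voxel_size_mm = c(1, 0, 1)),
               "positive")
  expect_error(new_volume(matrix(0, 2, 2)), "3D")
})

test_that("resampling follows the round(n * factor) shape rule", {
  v <- new_volume(array(0, c(182L, 218L, 182L)))
  out <- resample_volume(v, 0.5)
  expect_identical(dim(out$data), c(91L, 109L, 91L))
  expect_equal(out$voxel_size_mm, c(2, 2, 2))
  v2 <- new_volume(array(rnorm(10 * 12 * 14), c(10, 12, 14)))
  expect_identical(dim(resample_volume(v2, 1)$data), c(10L, 12L, 14L))
  expect_equal(resample_volume(v2, 1)$data, v2$data)
  expect_error(resample_volume(v2, 0), "positive")
  expect_error(resample_volume(v2, 0.5, spline_order = 7), "0..5")
})

test_that("resampling a constant volume stays constant", {
  v <- new_volume(array(3.5, c(12, 12, 12)))
  for (ord in c(0L, 1L, 3L, 5L)) {
    out <- resample_volume(v, 0.5, spline_order = ord)
    expect_lt(max(abs(out$data - 3.5)), 1e-6)
    up <- resample_volume(v, 2, spline_order = ord)
    expect_lt(max(abs(up$data - 3.5)), 1e-6)
  }
})

test_that("downsample of even dims then matching upsample restores shape", {
  v <- new_volume(array(rnorm(16 * 20 * 24), c(16, 20, 24)))
  down <- resample_volume(v, 0.5)
  up <- resample_volume(down, 2)
  expect_identical(dim(up$data), dim(v$data))
})

test_that("compute_bmi is weight/height^2 and homogeneous in weight", {
  expect_equal(compute_bmi(1, 1), 1)
  expect_equal(compute_bmi(70, 1.75), 70 / 1.75^2)
  expect_equal(compute_bmi(80, 2), 20)
  for (c in c(0.5, 2, 3.7))
    expect_equal(compute_bmi(c * 70, 1.75), c * compute_bmi(70, 1.75))
  expect_error(compute_bmi(-1, 1.7), "positive")
  expect_error(compute_bmi(70, 0), "positive")
})

test_that("cohort CSV parsing validates ids, sex codes and numbers", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cohort.csv")
  ok <- data.frame(subject_id = c("a", "b", "c"),
                   volume_path = c("a.nii", "b.nii", "c.nii"),
                   age_years = c(50, 60.5, 70), sex = c(0, 1, 0),
                   bmi = c(22.5, NA, 31))
  utils::write.csv(ok, path, row.names = FALSE, na = "")
  tab <- read_cohort(path)
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 3L)
  expect_true(is.na(tab$bmi[2]))

  bad_sex <- ok; bad_sex$sex[2] <- 2
  utils::write.csv(bad_sex, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "sex")

  dup <- ok; dup$subject_id[3] <- "a"
  utils::write.csv(dup, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "a")

  bad_age <- ok; bad_age$age_years <- as.character(bad_age$age_years)
  bad_age$age_years[2] <- "sixty"
  utils::write.csv(bad_age, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "row.* 2")
})

test_that("split_cohort sizes, disjointness, exhaustiveness, determinism", {
  recs <- data.frame(subject_id = sprintf("s%02d", 1:10),
                     volume_path = NA_character_, age_years = 50,
                     sex = rep(c(0, 1), 5), bmi = runif(10, 20, 30))
  tab <- cohort_table(recs)
  sp <- split_cohort(tab, c(0.8, 0.1, 0.1), seed = 7L)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 8L, validation = 1L, test = 1L))
  ids <- lapply(sp, `[[`, "subject_id")
  expect_length(intersect(ids$train, ids$validation), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_setequal(unlist(ids), recs$subject_id)
  sp2 <- split_cohort(tab, c(0.8, 0.1, 0.1), seed = 7L)
  expect_identical(lapply(sp, as.data.frame), lapply(sp2, as.data.frame))
  expect_error(split_cohort(tab, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("the published cohort split sizes are reproduced", {
  n <- 17938L
  recs <- data.frame(subject_id = sprintf("s%05d", seq_len(n)),
                     volume_path = NA_character_, age_years = 60,
                     sex = 0, bmi = 25)
  sp <- split_cohort(cohort_table(recs),
                     c(13938, 2000, 2000) / n, seed = 1L)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 13938L, validation = 2000L, test = 2000L))
})
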