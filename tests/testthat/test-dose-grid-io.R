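test_that("hadron-ascii reader maps records to voxels and defaults the rest to zero", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# shape: 1 1 1", "# spacing: 1 1 1", "0 0 0 1.5"), f)
  g <- read_dose_grid(f)
  expect_equal(dim(g$values), c(1L, 1L, 1L))
  expect_equal(g$values[1, 1, 1], 1.5)

  writeLines(c("# shape: 3 3 3", "# spacing: 2 2 2",
               "0 0 0 1", "1 1 1 2", "2 2 2 3", "0 2 1 4"), f)
  g <- read_dose_grid(f)
  expect_equal(sum(g$values == 0), 23L)
  expect_equal(g$values[2, 2, 2], 2)
  expect_equal(g$values[1, 3, 2], 4)
  expect_equal(g$spacing, c(2, 2, 2))
})

test_that("grid write/read round trip is bit-exact", {
  set.seed(42)
  vals <- array(round(rexp(3 * 4 * 5), 8) * runif(60), dim = c(3, 4, 5))
  vals[sample(60, 20)] <- 0
  g <- dose_grid(vals, spacing = c(0.5, 1, 2.5), beam_axis = 1L,
                 name = "fixture")
  f <- withr::local_tempfile(fileext = ".txt")
  write_dose_grid(g, f)
  g2 <- read_dose_grid(f)
  expect_identical(g2$values, g$values)
  expect_identical(g2$spacing, g$spacing)
  expect_identical(g2$beam_axis, g$beam_axis)
})

test_that("reader rejects malformed, negative and duplicate records with informative errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# shape: 2 2 2", "0 0 0 1", "0 1 oops 2"), f)
  expect_error(read_dose_grid(f), "line 3")
  writeLines(c("# shape: 2 2 2", "0 0 0 -1"), f)
  expect_error(read_dose_grid(f), "negative")
  writeLines(c("# shape: 2 2 2", "0 0 0 1", "0 0 0 2"), f)
  expect_error(read_dose_grid(f), "duplicate")
  writeLines(c("# shape: 2 2 2", "5 0 0 1"), f)
  expect_error(read_dose_grid(f), "outside")
  expect_error(read_dose_grid(file.path(tempdir(), "nope.txt")), "not found")
})

test_that("csv3d dialect reads long-format CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("i,j,k,dose", "0,0,0,1.25", "2,1,0,3"), f)
  g <- read_dose_grid(f, dialect = "csv3d", shape = c(3, 2, 1),
                      spacing = c(1, 1, 1))
  expect_equal(g$values[1, 1, 1], 1.25)
  expect_equal(g$values[3, 2, 1], 3)
  expect_equal(sum(g$values > 0), 2L)
  # shape inferred from the largest listed index when not declared
  g2 <- read_dose_grid(f, dialect = "csv3d")
  expect_equal(dim(g2$values), c(3L, 2L, 1L))
})

test_that("extract_slice takes the perpendicular plane, keeps sums, flags anisotropy", {
  g <- dose_grid(array(seq_len(75) / 10, dim = c(5, 5, 3)),
                 spacing = c(1, 1, 2), beam_axis = 3L)
  sl <- extract_slice(g, 2)
  expect_s3_class(sl, "lateral_slice")
  expect_equal(dim(sl$values), c(5L, 5L))
  expect_equal(sl$center, c(3L, 3L))  # geometric center of an odd plane
  expect_equal(sum(sl$values), sum(g$values[, , 2]))
  expect_equal(sl$depth_label, 2)  # (index - 1) * dz
  expect_false(attr(sl, "anisotropic"))
  expect_error(extract_slice(g, 99), "out of range")

  ones <- dose_grid(array(1, dim = c(4, 6, 2)), spacing = c(1, 2, 1))
  sl2 <- extract_slice(ones, 1)
  expect_equal(sum(sl2$values), 4 * 6)
  expect_true(attr(sl2, "anisotropic"))
})

test_that("profile CSV writes header plus one row per entry and round-trips exactly", {
  ent <- data.frame(radius_mm = c(0, 1, sqrt(2)),
                    dose = c(1, 1 / 3, 1e-7),
                    n_voxels = c(1L, 4L, 4L),
                    rse_percent = c(NA, 2.5, 17.3),
                    region = c("point", "point", "interval"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile(ent, f)
  expect_length(readLines(f), 4L)
  back <- read_profile(f)
  expect_identical(back$radius_mm, ent$radius_mm)
  expect_identical(back$dose, ent$dose)
  expect_identical(back$n_voxels, ent$n_voxels)
  expect_identical(back$rse_percent, ent$rse_percent)
  expect_error(write_profile(ent[0, ], f), "empty")
})

test_that("constructors enforce the container invariants", {
  expect_error(dose_grid(array(-1, dim = c(2, 2, 2))), "non-negative")
  expect_error(dose_grid(array(1, dim = c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(lateral_slice(matrix(1, 3, 3), center = c(9, 1)), "inside")
})
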