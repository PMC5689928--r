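test_that("exact grouping reproduces the lattice worked examples", {
  sl <- lateral_slice(matrix(1, 15, 15))
  groups <- group_by_radius(sl)

  origin <- group_with_key(groups, 0)
  expect_equal(nrow(origin$offsets), 1L)

  g2 <- group_with_key(groups, 2)
  expect_equal(g2$radius_mm, sqrt(2))
  got <- apply(g2$offsets, 1, paste, collapse = ",")
  expect_setequal(got, c("1,1", "-1,1", "-1,-1", "1,-1"))

  g25 <- group_with_key(groups, 25)
  expect_equal(g25$radius_mm, 5)
  want <- list(c(5, 0), c(4, 3), c(3, 4), c(0, 5), c(-3, 4), c(-4, 3),
               c(-5, 0), c(-4, -3), c(-3, -4), c(0, -5), c(3, -4), c(4, -3))
  expect_setequal(apply(g25$offsets, 1, paste, collapse = ","),
                  vapply(want, paste, "", collapse = ","))

  # every member's integer offsets reproduce its key exactly
  for (g in groups$groups)
    expect_true(all(rowSums(g$offsets^2) == g$r2_key))
})

test_that("groups partition the slice and match the brute-force multiplicity oracle", {
  sl <- random_slice(n = 63, seed = 3)
  groups <- group_by_radius(sl)
  mult <- vapply(groups$groups, function(g) nrow(g$offsets), 1L)
  keys <- vapply(groups$groups, `[[`, 1, "r2_key")
  expect_equal(sum(mult), 63L * 63L)

  # all representations of r^2 <= 961 fit inside a 63 x 63 plane, so the
  # slice multiplicities there must equal the free-lattice counts
  small <- keys <= 961
  expect_true(all(vapply(keys[small], brute_multiplicity, 1L) == mult[small]))
  # lattice four-fold symmetry away from the origin
  expect_true(all(mult[small & keys > 0] %% 4L == 0L))
})

test_that("annulus counts match the printed lattice arithmetic and the circle asymptotic", {
  expect_identical(count_voxels_in_annulus(1.0, 2.0), 4L)
  expect_identical(count_voxels_in_annulus(5.0, 6.0), 28L)
  for (r in c(10, 20, 40)) {
    n <- count_voxels_in_annulus(0, r, open_interval = FALSE)
    expect_lt(abs(n - pi * r^2), 4 * r)
  }
  expect_error(count_voxels_in_annulus(2, 1), "r_lo < r_hi")
})

test_that("point averages are plain means and reproduce the noise-free dose exactly", {
  g <- list(r2_key = 2, radius_mm = sqrt(2), offsets = cbind(1:3, 0),
            scores = c(2, 4, 6))
  pa <- point_average(g)
  expect_equal(pa[["dose"]], 4)
  expect_equal(pa[["n"]], 3)
  single <- list(r2_key = 0, radius_mm = 0, offsets = cbind(0, 0),
                 scores = 7.5)
  expect_equal(point_average(single)[["dose"]], 7.5)

  m <- default_beam_model()
  sl <- noise_free_slice(m, n = 41)
  pp <- point_profile(sl)
  expect_equal(pp$dose, expected_dose(m, pp$radius_mm), tolerance = 1e-14)
  expect_true(!is.unsorted(pp$radius_mm, strictly = TRUE))
  expect_equal(pp$n[pp$radius_mm == 0], 1L)
})

test_that("boundary is the first radius at or below threshold, with equality included", {
  pp <- point_profile(0:4, dose = c(1.0, 0.5, 0.009, 0.02, 0.001))
  # first crossing wins even though the profile rebounds above T afterwards
  expect_equal(find_boundary(pp, 0.01), 2)
  # threshold below the profile minimum: no boundary, all point region
  expect_identical(find_boundary(pp, 0.0005), Inf)
  # "equal to" branch on a monotone profile
  mono <- point_profile(0:3, dose = c(1, 0.5, 0.01, 0.005))
  expect_equal(find_boundary(mono, 0.01), 2)
  # persistence = 2 ignores the isolated dip at radius 2
  expect_identical(find_boundary(pp, 0.01, persistence = 2), Inf)
  pp2 <- point_profile(0:5, dose = c(1.0, 0.5, 0.009, 0.02, 0.001, 0.002))
  expect_equal(find_boundary(pp2, 0.01, persistence = 2), 4)
  expect_error(find_boundary(pp, 1.5), "\\(0, 1\\)")
})

test_that("interval bins accumulate until the running sum reaches the threshold", {
  pp <- point_profile(c(0, 10, 11, 12, 13), dose = c(1, 0.004, 0.003, 0.002, 0.006),
                      n = c(1, 4, 4, 8, 8))
  bins <- build_intervals(pp, boundary = 10, threshold = 0.01)
  expect_equal(nrow(bins), 1L)
  expect_equal(bins$n_points, 4L)       # 0.004+0.003+0.002 < T, +0.006 closes
  expect_equal(bins$sum_norm, 0.015)
  expect_false(bins$partial)

  # every tail point at or above T: bins degenerate to single points
  pp2 <- point_profile(c(0, 5, 6), dose = c(1, 0.02, 0.03))
  bins2 <- build_intervals(pp2, boundary = 5, threshold = 0.01)
  expect_equal(nrow(bins2), 2L)
  expect_true(all(bins2$n_points == 1L))

  # voxel-count-weighted representative score and radius
  pp3 <- point_profile(c(0, 3, 3.162), dose = c(1, 0.004, 0.003), n = c(1, 4, 8))
  bins3 <- build_intervals(pp3, boundary = 3, threshold = 0.01)
  expect_equal(bins3$s_bar, (4 * 0.004 + 8 * 0.003) / 12)
  expect_equal(bins3$r_bar, (4 * 3 + 8 * 3.162) / 12)
  expect_equal(bins3$n_total, 12L)
  expect_true(bins3$partial)            # running sum 0.007 < T at profile end

  # unweighted-over-points variant
  bins3p <- build_intervals(pp3, boundary = 3, threshold = 0.01,
                            weighting = "point")
  expect_equal(bins3p$s_bar, (0.004 + 0.003) / 2)
  expect_equal(bins3p$r_bar, (3 + 3.162) / 2)
})

test_that("full profile conserves dose and is exact in the noise-free limit", {
  m <- default_beam_model()
  sl <- simulate_slice(m, small_config(seed = 21, n = 81))
  rp <- radial_profile(sl, threshold = 0.01)
  expect_equal(sum(rp$entries$dose * rp$entries$n_voxels), sum(sl$values),
               tolerance = 1e-12)
  expect_true(all(rp$entries$radius_mm[rp$entries$region == "point"] <
                    rp$boundary))
  expect_true(all(rp$intervals$r_min >= rp$boundary))
  expect_true(all(rp$intervals$r_bar >= rp$intervals$r_min &
                    rp$intervals$r_bar <= rp$intervals$r_max))

  nf <- noise_free_slice(m, n = 41)
  rpn <- radial_profile(nf, threshold = 0.01)
  pt <- rpn$entries[rpn$entries$region == "point", ]
  expect_equal(pt$dose, expected_dose(m, pt$radius_mm), tolerance = 1e-14)
})

test_that("degenerate all-zero slice yields a pure point profile with no boundary", {
  rp <- radial_profile(lateral_slice(matrix(0, 11, 11)), threshold = 0.5)
  expect_identical(rp$boundary, Inf)
  expect_true(all(rp$entries$region == "point"))
  expect_true(all(rp$entries$dose == 0))
  expect_true(all(is.na(rp$entries$rse_percent)))
})

test_that("raising the threshold pulls the boundary inward and widens bins", {
  m <- default_beam_model()
  nf <- noise_free_slice(m, n = 121)
  ts <- c(0.002, 0.005, 0.01, 0.02)
  profs <- lapply(ts, function(t) radial_profile(nf, threshold = t))
  r0 <- vapply(profs, `[[`, 1, "boundary")
  expect_true(all(diff(r0) <= 0))
  width <- vapply(profs, function(p) mean(p$intervals$n_points), 1)
  expect_true(all(diff(width) >= 0))
})

test_that("point region agrees with the cylindrical-like sweep-and-fill oracle", {
  for (seed in 1:3) {
    sl <- random_slice(n = 31, seed = seed)
    ora <- cylindrical_oracle(sl)
    pp <- point_profile(sl)
    expect_equal(pp$radius_mm, ora$radius_mm, tolerance = 1e-14)
    expect_equal(pp$dose, ora$dose, tolerance = 1e-12)
    expect_equal(pp$n, ora$n)
  }
  # and through the full pipeline: point-region entries are the oracle's rows
  sl <- simulate_slice(default_beam_model(), small_config(seed = 4, n = 41))
  rp <- radial_profile(sl, threshold = 0.01)
  ora <- cylindrical_oracle(sl)
  pt <- rp$entries[rp$entries$region == "point", ]
  keep <- ora$radius_mm < rp$boundary
  expect_equal(pt$dose, ora$dose[keep], tolerance = 1e-12)
})

test_that("conventional rays read single voxels out from the center", {
  m <- default_beam_model()
  nf <- noise_free_slice(m, n = 41)
  ax <- conventional_profile(nf, "+x")
  expect_equal(ax$radius_mm, 0:20)
  expect_equal(ax$dose, expected_dose(m, 0:20))
  di <- conventional_profile(nf, "-x-y")
  expect_equal(di$radius_mm, (0:20) * sqrt(2))
  # on a symmetric noise-free slice the ray equals the point average at
  # every shared radius
  pp <- point_profile(nf)
  shared <- match(ax$radius_mm, pp$radius_mm)
  expect_equal(pp$dose[shared], ax$dose, tolerance = 1e-14)
  # truncated at the edge from an off-center start, no error
  off <- lateral_slice(matrix(1, 9, 9), center = c(7, 5))
  expect_equal(nrow(conventional_profile(off, "+x")), 3L)
  expect_error(conventional_profile(nf, "north"), "direction")
})

test_that("anisotropic spacing is refused exactly and grouped under tolerance mode", {
  sl <- lateral_slice(matrix(1, 11, 21), spacing = c(1, 0.5))
  expect_error(group_by_radius(sl), "tolerance")
  groups <- group_by_radius(sl, tolerance = TRUE)
  mult <- vapply(groups$groups, function(g) nrow(g$offsets), 1L)
  expect_equal(sum(mult), 11L * 21L)
  # physical radii: voxels at (±1, 0) offsets (1 mm) merge with (0, ±2) (1 mm)
  r1 <- group_with_key(groups, signif(1, 9))
  expect_equal(nrow(r1$offsets), 4L)
})
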