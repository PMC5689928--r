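# Core radial-projection machinery: exact integer-r^2 grouping of lattice
# voxels, per-radius point averages, threshold-driven boundary detection and
# variable-width interval averaging in the low-dose tail.

# Per-radius sufficient statistics of a slice: for every exact radial group,
# its key, physical radius, multiplicity n, mean score, and centered sum of
# squares ss = sum((x - mean)^2). Keys are integer di^2 + dj^2 in the exact
# (isotropic) mode, or physical r^2 quantized to 9 significant digits in
# tolerance mode. Returned sorted by ascending radius.
.radial_stats <- function(slice, tolerance = FALSE) {
  stopifnot(inherits(slice, "lateral_slice"))
  sp <- slice$spacing
  n1 <- nrow(slice$values); n2 <- ncol(slice$values)
  di <- rep(seq_len(n1) - slice$center[1], times = n2)
  dj <- rep(seq_len(n2) - slice$center[2], each = n1)
  if (sp[1] == sp[2] && !tolerance) {
    r2 <- di * di + dj * dj
    radius_of <- function(k) sqrt(k) * sp[1]
  } else {
    if (!tolerance)
      stop("anisotropic in-plane spacing: exact grouping is ambiguous; ",
           "call with tolerance = TRUE to group on quantized physical r^2")
    r2 <- signif((di * sp[1])^2 + (dj * sp[2])^2, 9)
    radius_of <- function(k) sqrt(k)
  }
  keys <- sort(unique(r2))
  g <- match(r2, keys)
  n <- tabulate(g, length(keys))
  x <- as.vector(slice$values)
  s <- rowsum(x, g, reorder = TRUE)[, 1]
  mu <- s / n
  dev <- x - mu[g]
  ss <- rowsum(dev * dev, g, reorder = TRUE)[, 1]
  list(key = keys, radius_mm = radius_of(keys), n = n, mean = mu, ss = ss,
       group = g, di = di, dj = dj)
}

#' Group slice voxels by exact radial distance
#'
#' Projects every voxel of a lateral slice onto the radius axis. Grouping is
#' exact: voxels share a group if and only if their integer squared offsets
#' from the beam center, `di^2 + dj^2`, are equal, so equal radii are never
#' split by floating-point ties. On a unit lattice the group at radius
#' `sqrt(2)` has exactly 4 members and the group at radius 5 has exactly 12 —
#' the number of lattice representations of the key as a sum of two squares.
#'
#' Exact grouping requires isotropic in-plane spacing; with
#' `tolerance = TRUE` the physical squared radius quantized to 9 significant
#' digits is used instead (for anisotropic planes or off-lattice use).
#'
#' @param slice a [lateral_slice()].
#' @param tolerance use quantized physical r^2 keys instead of exact integer
#'   keys.
#' @return An object of class `radial_groups`: a list of groups sorted by
#'   ascending radius, each with `r2_key`, `radius_mm`, `offsets` (an n x 2
#'   matrix of voxel offsets from the beam center, in voxels) and `scores`.
#' @export
group_by_radius <- function(slice, tolerance = FALSE) {
  st <- .radial_stats(slice, tolerance)
  idx <- split(seq_along(st$group), st$group)
  x <- as.vector(slice$values)
  groups <- lapply(seq_along(st$key), function(k) {
    ii <- idx[[as.character(k)]]
    list(r2_key = st$key[k],
         radius_mm = st$radius_mm[k],
         offsets = cbind(di = st$di[ii], dj = st$dj[ii]),
         scores = x[ii])
  })
  structure(list(groups = groups, spacing = slice$spacing,
                 exact = !tolerance && slice$spacing[1] == slice$spacing[2]),
            class = "radial_groups")
}

#' @export
print.radial_groups <- function(x, ...) {
  cat(sprintf("<radial_groups> %d radii, %d voxels (%s keys)\n",
              length(x$groups),
              sum(vapply(x$groups, function(g) length(g$scores), 1L)),
              if (x$exact) "exact integer r^2" else "quantized r^2"))
  invisible(x)
}

#' Point average of one radial group
#'
#' The arithmetic mean of the voxel scores sharing one exact radial distance
#' is the representative score for that radius.
#'
#' @param group one element of [group_by_radius()]'s `groups` list.
#' @return Named numeric vector `(radius_mm, dose, n)`.
#' @export
point_average <- function(group) {
  if (length(group$scores) == 0L) stop("empty radial group")
  c(radius_mm = group$radius_mm, dose = mean(group$scores),
    n = length(group$scores))
}

#' Point-average profile
#'
#' The ascending sequence of per-radius point averages. Can be computed from
#' a slice or assembled from vectors (e.g. hand-built fixtures).
#'
#' @param x a [lateral_slice()], or a numeric vector of radii.
#' @param ... passed on to methods.
#' @return A data frame of class `point_profile` with columns `radius_mm`,
#'   `dose`, `n` and attribute `peak_dose` (the maximum point average).
#' @export
point_profile <- function(x, ...) UseMethod("point_profile")

#' @rdname point_profile
#' @param tolerance see [group_by_radius()].
#' @export
point_profile.lateral_slice <- function(x, tolerance = FALSE, ...) {
  st <- .radial_stats(x, tolerance)
  new_point_profile(st$radius_mm, st$mean, st$n)
}

#' @rdname point_profile
#' @param dose point-average doses at `x` (radii).
#' @param n voxel multiplicities (default 1).
#' @export
point_profile.numeric <- function(x, dose, n = 1L, ...) {
  new_point_profile(x, dose, rep(as.integer(n), length.out = length(x)))
}

new_point_profile <- function(radius_mm, dose, n) {
  if (length(radius_mm) == 0L) stop("empty point profile")
  if (is.unsorted(radius_mm, strictly = TRUE))
    stop("radii must be strictly increasing")
  if (any(n < 1L)) stop("multiplicities must be >= 1")
  structure(
    data.frame(radius_mm = radius_mm, dose = dose, n = as.integer(n)),
    peak_dose = max(dose),
    class = c("point_profile", "data.frame")
  )
}

#' Locate the point/interval boundary from a threshold
#'
#' Scanning the point-average profile in ascending radius, the boundary `R0`
#' is the first radius whose point-average dose, normalized to the profile
#' peak, is less than or equal to the threshold `T`. Radii below `R0` form
#' the high-dose (point-average) region; radii at or beyond `R0` form the
#' low-dose (interval-average) region. If no point falls to the threshold
#' the boundary is `+Inf` and the whole profile is point region.
#'
#' The optional `persistence` parameter requires `k` consecutive
#' sub-threshold points before accepting the crossing, guarding against a
#' single noise-driven dip; the default `k = 1` is the literal
#' first-crossing rule.
#'
#' @param profile a [point_profile()].
#' @param threshold fraction of the peak point-average dose, in (0, 1).
#' @param persistence number of consecutive sub-threshold points required.
#' @return The boundary radius `R0` in mm, or `Inf`.
#' @export
find_boundary <- function(profile, threshold, persistence = 1L) {
  stopifnot(inherits(profile, "point_profile"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a single fraction in (0, 1)")
  k <- as.integer(persistence)
  if (k < 1L) stop("`persistence` must be >= 1")
  peak <- max(profile$dose)
  if (peak <= 0) return(Inf)
  below <- profile$dose / peak <= threshold
  if (k > 1L) {
    runs <- stats::filter(as.integer(below), rep(1L, k), sides = 1)
    hit <- which(!is.na(runs) & runs == k)
    if (!length(hit)) return(Inf)
    profile$radius_mm[hit[1] - k + 1L]
  } else {
    hit <- which(below)
    if (!length(hit)) return(Inf)
    profile$radius_mm[hit[1]]
  }
}

#' Build variable-width interval bins in the low-dose tail
#'
#' Consecutive radius points at or beyond the boundary are accumulated into
#' bins; a bin closes at the first point where the running sum of normalized
#' point averages reaches the threshold `T`, so bins widen as the dose
#' falls. Each bin carries the representative score `S_bar` and radius
#' `R_bar`. Under the default `weighting = "voxel"` both are voxel-count
#' weighted means over all member voxels, which makes the profile's
#' voxel-weighted dose sum exactly equal to the slice's; `"point"` averages
#' the member radius points unweighted.
#'
#' The final bin may end before its running sum reaches `T`; it is kept and
#' flagged `partial` rather than dropped, so the tail is never truncated.
#'
#' @param profile a [point_profile()].
#' @param boundary the boundary radius `R0` (finite, from
#'   [find_boundary()]).
#' @param threshold the same threshold `T` used for the boundary.
#' @param weighting `"voxel"` (default) or `"point"`.
#' @return A data frame of class `interval_bins` with columns `r_bar`,
#'   `s_bar`, `n_total`, `n_points`, `r_min`, `r_max`, `sum_norm`,
#'   `partial`, and attribute `assignment` mapping each tail point of
#'   `profile` to its bin.
#' @export
build_intervals <- function(profile, boundary, threshold,
                            weighting = c("voxel", "point")) {
  stopifnot(inherits(profile, "point_profile"))
  weighting <- match.arg(weighting)
  if (!is.finite(boundary)) stop("`boundary` must be finite")
  tail_idx <- which(profile$radius_mm >= boundary)
  if (!length(tail_idx)) stop("no radius points at or beyond the boundary")
  peak <- max(profile$dose)
  norm <- profile$dose[tail_idx] / peak
  bin <- integer(length(tail_idx))
  b <- 1L; acc <- 0
  for (m in seq_along(tail_idx)) {
    bin[m] <- b
    acc <- acc + norm[m]
    if (acc >= threshold) { b <- b + 1L; acc <- 0 }
  }
  nb <- max(bin)
  r <- profile$radius_mm[tail_idx]
  d <- profile$dose[tail_idx]
  n <- profile$n[tail_idx]
  agg <- function(v) rowsum(v, bin, reorder = TRUE)[, 1]
  n_total <- agg(n)
  sum_norm <- agg(norm)
  out <- data.frame(
    r_bar = if (weighting == "voxel") agg(n * r) / n_total else
      agg(r) / agg(rep(1, length(r))),
    s_bar = if (weighting == "voxel") agg(n * d) / n_total else
      agg(d) / agg(rep(1, length(d))),
    n_total = as.integer(n_total),
    n_points = as.integer(agg(rep(1L, length(r)))),
    r_min = vapply(seq_len(nb), function(k) min(r[bin == k]), 1),
    r_max = vapply(seq_len(nb), function(k) max(r[bin == k]), 1),
    sum_norm = sum_norm,
    partial = FALSE
  )
  out$partial[nb] <- sum_norm[nb] < threshold
  attr(out, "assignment") <- data.frame(point = tail_idx, bin = bin)
  class(out) <- c("interval_bins", "data.frame")
  out
}

#' Radial-projection profile of a lateral slice
#'
#' The full radial-projection pipeline: group voxels by exact radius, take
#' per-radius point averages, locate the boundary `R0` where the normalized
#' point average first falls to the threshold `T`, and merge the points at
#' and beyond `R0` into variable-width interval bins. The high-dose region
#' (`r < R0`) keeps one entry per exact radius; the low-dose region is
#' represented by each bin's `(R_bar, S_bar)`. Every entry also carries the
#' relative standard error of its member voxel scores (undefined — `NA` —
#' for single-voxel entries or zero means).
#'
#' Under the default voxel weighting the profile conserves dose exactly:
#' the sum of `dose * n_voxels` over all entries equals the sum of all voxel
#' scores in the slice (up to floating-point associativity).
#'
#' @param slice a [lateral_slice()].
#' @param threshold fraction of the peak point-average dose in (0, 1);
#'   typical values for pencil-beam tails are 0.001 to 0.01.
#' @param weighting interval-average convention, see [build_intervals()].
#' @param persistence boundary persistence, see [find_boundary()].
#' @param tolerance grouping mode, see [group_by_radius()].
#' @return An object of class `radial_profile`: a list with `entries` (data
#'   frame: `radius_mm`, `dose`, `n_voxels`, `rse_percent`, `region`),
#'   `intervals` (the [build_intervals()] table plus `rse_percent`),
#'   `threshold`, `boundary`, `peak_dose`, `weighting`, `total_dose`.
#' @examples
#' sl <- simulate_slice(default_beam_model(), default_sim_config(seed = 7))
#' rp <- radial_profile(sl, threshold = 0.01)
#' rp
#' @export
radial_profile <- function(slice, threshold = 0.01,
                           weighting = c("voxel", "point"),
                           persistence = 1L, tolerance = FALSE) {
  weighting <- match.arg(weighting)
  st <- .radial_stats(slice, tolerance)
  rse_pt <- ifelse(st$n >= 2L & st$mean > 0,
                   100 * sqrt(st$ss / (st$n * (st$n - 1))) / st$mean,
                   NA_real_)
  pp <- new_point_profile(st$radius_mm, st$mean, st$n)
  peak <- attr(pp, "peak_dose")
  r0 <- find_boundary(pp, threshold, persistence)

  if (is.finite(r0)) {
    bins <- build_intervals(pp, r0, threshold, weighting)
    asg <- attr(bins, "assignment")
    # Eq.-3 RSE of each bin over all member voxel scores: pool the member
    # groups' centered sums of squares around the bin's voxel-weighted mean.
    n_tot <- bins$n_total
    mu_vox <- rowsum(st$n[asg$point] * st$mean[asg$point], asg$bin)[, 1] / n_tot
    ss_bin <- rowsum(st$ss[asg$point] +
                       st$n[asg$point] * (st$mean[asg$point] - mu_vox[asg$bin])^2,
                     asg$bin)[, 1]
    bins$rse_percent <- ifelse(n_tot >= 2L & mu_vox > 0,
                               100 * sqrt(ss_bin / (n_tot * (n_tot - 1))) / mu_vox,
                               NA_real_)
    pt <- which(st$radius_mm < r0)
    entries <- rbind(
      data.frame(radius_mm = st$radius_mm[pt], dose = st$mean[pt],
                 n_voxels = st$n[pt], rse_percent = rse_pt[pt],
                 region = "point"),
      data.frame(radius_mm = bins$r_bar, dose = bins$s_bar,
                 n_voxels = bins$n_total, rse_percent = bins$rse_percent,
                 region = "interval")
    )
  } else {
    bins <- NULL
    entries <- data.frame(radius_mm = st$radius_mm, dose = st$mean,
                          n_voxels = st$n, rse_percent = rse_pt,
                          region = "point")
  }
  rownames(entries) <- NULL
  structure(
    list(entries = entries, intervals = bins, threshold = threshold,
         boundary = r0, peak_dose = peak, weighting = weighting,
         normalization = "raw", total_dose = sum(slice$values),
         spacing = slice$spacing, center = slice$center),
    class = "radial_profile"
  )
}

#' @export
print.radial_profile <- function(x, ...) {
  npt <- sum(x$entries$region == "point")
  nint <- sum(x$entries$region == "interval")
  cat(sprintf("<radial_profile> threshold %g of peak %.4g\n",
              x$threshold, x$peak_dose))
  if (is.finite(x$boundary)) {
    cat(sprintf("  boundary R0 = %.4g mm; %d point radii (r < R0), %d interval bins (r >= R0)\n",
                x$boundary, npt, nint))
    if (any(x$intervals$partial))
      cat("  (final bin is partial: running sum below threshold at profile end)\n")
  } else {
    cat(sprintf("  no boundary (no point average <= threshold); %d point radii\n",
                npt))
  }
  cat(sprintf("  %s-weighted interval averages; voxel-weighted dose total %.6g\n",
              x$weighting, x$total_dose))
  invisible(x)
}

#' Count lattice voxel centers in an annulus
#'
#' Brute-force count of unit-lattice points (voxel centers, spacing in mm)
#' whose radial distance from the center lies between `r_lo` and `r_hi` —
#' strictly between by default, or inclusive of both bounds. Comparison is
#' done on exact squared radii, so voxels sitting exactly on a bound are
#' never misclassified by rounding.
#'
#' @param r_lo,r_hi annulus bounds in mm, `0 <= r_lo < r_hi`.
#' @param open_interval if `TRUE` (default) count radii strictly between the
#'   bounds; otherwise include both.
#' @param spacing lattice spacing in mm.
#' @return Integer voxel count.
#' @examples
#' count_voxels_in_annulus(1, 2)  # 4: the four voxels at radius sqrt(2)
#' count_voxels_in_annulus(5, 6)  # 28
#' @export
count_voxels_in_annulus <- function(r_lo, r_hi, open_interval = TRUE,
                                    spacing = 1) {
  if (!is.numeric(r_lo) || !is.numeric(r_hi) || r_lo < 0 || r_lo >= r_hi)
    stop("need 0 <= r_lo < r_hi")
  m <- ceiling(r_hi / spacing)
  i <- rep(-m:m, times = 2 * m + 1)
  j <- rep(-m:m, each = 2 * m + 1)
  r2 <- (i * i + j * j) * spacing^2
  lo2 <- r_lo^2; hi2 <- r_hi^2
  if (open_interval) sum(r2 > lo2 & r2 < hi2) else sum(r2 >= lo2 & r2 <= hi2)
}

#' Conventional single-ray profile
#'
#' The conventional way to read a lateral profile off a scored plane: take
#' the individual voxel scores along one ray out from the beam center, one
#' voxel per radius. Rays along the two lattice axes and the two diagonals
#' (both senses each) are supported; the ray is truncated at the grid edge.
#'
#' @param slice a [lateral_slice()].
#' @param direction one of `"+x"`, `"-x"`, `"+y"`, `"-y"`, `"+x+y"`,
#'   `"+x-y"`, `"-x+y"`, `"-x-y"` (x = first array index, y = second).
#' @return Data frame with columns `radius_mm` and `dose`, ascending radius
#'   starting at the center voxel.
#' @export
conventional_profile <- function(slice, direction = "+x") {
  stopifnot(inherits(slice, "lateral_slice"))
  steps <- list(
    "+x" = c(1, 0), "-x" = c(-1, 0), "+y" = c(0, 1), "-y" = c(0, -1),
    "+x+y" = c(1, 1), "+x-y" = c(1, -1), "-x+y" = c(-1, 1), "-x-y" = c(-1, -1)
  )
  if (!direction %in% names(steps))
    stop("`direction` must be one of: ", paste(names(steps), collapse = ", "))
  dstep <- steps[[direction]]
  step_mm <- sqrt(sum((dstep * slice$spacing)^2))
  i0 <- slice$center[1]; j0 <- slice$center[2]
  n1 <- nrow(slice$values); n2 <- ncol(slice$values)
  kmax_i <- if (dstep[1] > 0) n1 - i0 else if (dstep[1] < 0) i0 - 1L else Inf
  kmax_j <- if (dstep[2] > 0) n2 - j0 else if (dstep[2] < 0) j0 - 1L else Inf
  kmax <- min(kmax_i, kmax_j)
  k <- 0:kmax
  data.frame(
    radius_mm = k * step_mm,
    dose = slice$values[cbind(i0 + k * dstep[1], j0 + k * dstep[2])]
  )
}
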