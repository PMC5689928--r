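# Relative-standard-error analysis of radial-projection profiles and the
# RP-vs-conventional comparison machinery.

#' Relative standard error of a sample of voxel scores
#'
#' The statistical uncertainty of a mean score, relative to the mean and in
#' percent:
#' \deqn{RSE = 100 \sqrt{\sum_i (x_i - \bar x)^2 / (n (n-1))} / \bar x}
#' Undefined (returns `NA`) for fewer than two scores or a zero mean — a
#' single voxel score carries no internal uncertainty estimate.
#'
#' @param scores numeric vector of voxel scores at one radius (or in one
#'   interval bin).
#' @return RSE in percent, or `NA_real_` when undefined.
#' @examples
#' rse(c(1, 2, 3))  # 100 * sqrt(2/6) / 2
#' @export
rse <- function(scores) {
  n <- length(scores)
  if (n < 2L) return(NA_real_)
  xbar <- mean(scores)
  if (xbar == 0) return(NA_real_)
  100 * sqrt(sum((scores - xbar)^2) / (n * (n - 1))) / xbar
}

#' Expected residual uncertainty of an n-score mean
#'
#' Averaging `n` independent scores reduces statistical uncertainty by about
#' the square root of `n`: the mean retains `100 / sqrt(n)` percent of a
#' single score's uncertainty. At multiplicity 4 the uncertainty is halved;
#' at 12 it drops to 28.87%.
#'
#' @param n voxel multiplicity, `>= 1`; vectorized.
#' @return Percent of single-score uncertainty remaining.
#' @export
reduction_factor <- function(n) {
  if (any(n < 1)) stop("`n` must be >= 1")
  100 / sqrt(n)
}

#' RSE versus radius for a radial profile
#'
#' Extracts the per-entry relative standard error computed by
#' [radial_profile()]: for point-region radii, Eq.-3 RSE over the member
#' voxel scores of that exact radius; for interval bins, over all member
#' voxel scores of the bin. Undefined entries (single-voxel radii such as
#' the origin, or zero means) are present with `rse_percent = NA`.
#'
#' @param profile a [radial_profile()].
#' @return Data frame with columns `radius_mm`, `n`, `rse_percent`,
#'   `region`.
#' @export
rse_curve <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  data.frame(radius_mm = profile$entries$radius_mm,
             n = profile$entries$n_voxels,
             rse_percent = profile$entries$rse_percent,
             region = profile$entries$region)
}

#' Voxel multiplicity versus radius
#'
#' The number of voxels backing each profile entry: the lattice multiplicity
#' of the exact radius in the point region, the total member count of each
#' bin in the interval region. Multiplicity grows with radius (on average
#' linearly — the circumference effect), which is what makes the projection
#' increasingly effective off-axis.
#'
#' @param profile a [radial_profile()].
#' @return Data frame with columns `radius_mm`, `n`, `region`.
#' @export
voxel_count_curve <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  data.frame(radius_mm = profile$entries$radius_mm,
             n = profile$entries$n_voxels,
             region = profile$entries$region)
}

# Mean of the defined RSE entries of a profile whose radius lies in
# [region[1], region[2]]; unweighted over entries, NA entries excluded.
.region_mean_rse <- function(curve, region) {
  sel <- curve$radius_mm >= region[1] & curve$radius_mm <= region[2]
  vals <- curve$rse_percent[sel]
  list(mean = mean(vals, na.rm = TRUE),
       n_entries = sum(sel),
       n_undefined = sum(is.na(vals)))
}

#' Compare RP and conventional profile uncertainty
#'
#' Simulates replicate synthetic slices and contrasts the statistical
#' quality of the radial-projection profile at `n_rp` emulated histories
#' with that of the conventional single-ray profile at `n_conventional`
#' histories, over a radial region (by default the low-dose tail beyond the
#' threshold boundary of the noise-free beam).
#'
#' The RP profile's uncertainty is the Eq.-3 RSE computed within each slice
#' and averaged over region entries, then over replicates. The conventional
#' estimator at a radius is a *single* voxel score, so Eq. 3 is undefined
#' within one slice; its uncertainty is instead estimated as the
#' across-replicate relative standard deviation of that single score at
#' each ray radius, averaged over region radii. Radii whose replicate mean
#' is zero (deep-tail voxels that never score) are excluded and counted.
#'
#' @param model a [beam_model()].
#' @param n_conventional,n_rp emulated history counts for the two methods.
#' @param threshold boundary threshold `T` passed to [radial_profile()].
#' @param region length-2 radial range in mm, or `NULL` to use
#'   `[R0, r_edge]` where `R0` is the noise-free boundary at `threshold`
#'   and `r_edge` is the largest radius on the conventional ray.
#' @param replicates number of replicate slices per method.
#' @param seed base RNG seed; replicate seeds are derived from it.
#' @param config a [sim_config()] supplying geometry and the `peak_counts`
#'   calibration (its `n_histories` and `seed` are overridden).
#' @param direction conventional ray, see [conventional_profile()].
#' @return An object of class `rp_comparison`: region, per-method mean RSE
#'   (percent), `reduction_factor` (conventional / RP), history counts,
#'   replicate count and per-method counts of excluded undefined entries.
#' @export
compare_methods <- function(model, n_conventional, n_rp, threshold = 0.01,
                            region = NULL, replicates = 50, seed = 1L,
                            config = default_sim_config(),
                            direction = "+x") {
  stopifnot(inherits(model, "beam_model"), inherits(config, "sim_config"))
  if (n_conventional <= 0 || n_rp <= 0) stop("history counts must be positive")
  cfg_of <- function(N, s) {
    cfg <- config; cfg$n_histories <- N; cfg$seed <- as.integer(s); cfg
  }
  seeds <- .replicate_seeds(seed, 2L * replicates)

  noise_free <- config; noise_free$noise <- FALSE
  ideal <- simulate_slice(model, noise_free)
  if (is.null(region)) {
    r0 <- find_boundary(point_profile(ideal), threshold)
    if (!is.finite(r0))
      stop("noise-free profile never reaches the threshold; give `region`")
    edge <- max(conventional_profile(ideal, direction)$radius_mm)
    region <- c(r0, edge)
  }
  region <- as.numeric(region)

  if (!config$noise) {
    # degenerate noise-free mode: both methods are exact
    return(structure(
      list(region = region, rse_rp = 0, rse_conventional = 0,
           reduction_factor = 1, n_rp = n_rp,
           n_conventional = n_conventional, replicates = replicates,
           n_undefined_rp = 0L, n_undefined_conventional = 0L,
           threshold = threshold),
      class = "rp_comparison"))
  }

  # conventional: across-replicate relative SD of the single-voxel score
  ray0 <- conventional_profile(simulate_slice(model, cfg_of(n_conventional,
                                                            seeds[1])),
                               direction)
  ray_scores <- matrix(NA_real_, nrow = nrow(ray0), ncol = replicates)
  ray_scores[, 1] <- ray0$dose
  for (m in seq_len(replicates - 1L)) {
    sl <- simulate_slice(model, cfg_of(n_conventional, seeds[m + 1L]))
    ray_scores[, m + 1L] <- conventional_profile(sl, direction)$dose
  }
  mu <- rowMeans(ray_scores)
  sdv <- apply(ray_scores, 1, stats::sd)
  conv_curve <- data.frame(
    radius_mm = ray0$radius_mm,
    rse_percent = ifelse(mu > 0, 100 * sdv / mu, NA_real_)
  )
  conv <- .region_mean_rse(conv_curve, region)

  # RP: within-slice Eq.-3 RSE of the profile entries, averaged per slice
  rp_means <- numeric(replicates)
  rp_undef <- 0L
  for (m in seq_len(replicates)) {
    sl <- simulate_slice(model, cfg_of(n_rp, seeds[replicates + m]))
    prof <- radial_profile(sl, threshold = threshold)
    rm_ <- .region_mean_rse(rse_curve(prof), region)
    rp_means[m] <- rm_$mean
    rp_undef <- rp_undef + rm_$n_undefined
  }
  rp_mean <- mean(rp_means, na.rm = TRUE)

  structure(
    list(region = region, rse_rp = rp_mean, rse_conventional = conv$mean,
         reduction_factor = if (rp_mean == 0 && conv$mean == 0) 1 else
           conv$mean / rp_mean,
         n_rp = n_rp, n_conventional = n_conventional,
         replicates = replicates, n_undefined_rp = rp_undef,
         n_undefined_conventional = conv$n_undefined,
         threshold = threshold),
    class = "rp_comparison"
  )
}

#' @export
print.rp_comparison <- function(x, ...) {
  cat(sprintf("<rp_comparison> region %.4g..%.4g mm, threshold %g, %d replicates\n",
              x$region[1], x$region[2], x$threshold, x$replicates))
  cat(sprintf("  RP:           mean RSE %.3f%% at N = %.3g histories\n",
              x$rse_rp, x$n_rp))
  cat(sprintf("  conventional: mean RSE %.3f%% at N = %.3g histories (%d zero-mean radii excluded)\n",
              x$rse_conventional, x$n_conventional,
              x$n_undefined_conventional))
  cat(sprintf("  uncertainty reduction factor (conventional / RP): %.3f\n",
              x$reduction_factor))
  invisible(x)
}

# Derive `n` well-separated 31-bit replicate seeds from one base seed.
.replicate_seeds <- function(seed, n) {
  .with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

#' Fit a double Gaussian to a radial profile
#'
#' Least-squares fit of the beam-model form
#' `A ((1-w) exp(-r^2/2 s_c^2) + w exp(-r^2/2 s_t^2))` to a profile's
#' entries (point averages and interval representatives alike), via
#' Levenberg–Marquardt. Used to check that the projection preserves the
#' beam shape well enough for parameter recovery.
#'
#' @param profile a [radial_profile()] or a data frame with `radius_mm` and
#'   `dose` columns.
#' @param start optional named list of starting values (`amplitude`,
#'   `sigma_core`, `sigma_tail`, `tail_weight`); defaults are derived from
#'   the profile (peak dose, half-maximum radius).
#' @return A [beam_model()] with the fitted parameters, with the `nls` fit
#'   object attached as attribute `fit`.
#' @export
fit_double_gaussian <- function(profile, start = NULL) {
  ent <- if (inherits(profile, "radial_profile")) profile$entries else
    as.data.frame(profile)
  df <- data.frame(r = ent$radius_mm, d = ent$dose)
  df <- df[is.finite(df$d) & df$d >= 0, ]
  if (nrow(df) < 5L) stop("too few profile points to fit")
  if (is.null(start)) {
    peak <- max(df$d)
    r_half <- df$r[which(df$d <= peak / 2)[1]]
    if (is.na(r_half) || r_half <= 0) r_half <- max(df$r) / 4
    start <- list(amplitude = peak, sigma_core = r_half / sqrt(2 * log(2)),
                  sigma_tail = 4 * r_half / sqrt(2 * log(2)),
                  tail_weight = 0.05)
  }
  fit <- minpack.lm::nlsLM(
    d ~ A * ((1 - w) * exp(-r^2 / (2 * sc^2)) + w * exp(-r^2 / (2 * st^2))),
    data = df,
    start = list(A = start$amplitude, sc = start$sigma_core,
                 st = start$sigma_tail, w = start$tail_weight),
    lower = c(A = 0, sc = 1e-6, st = 1e-6, w = 0),
    upper = c(A = Inf, sc = Inf, st = Inf, w = 0.999),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  out <- beam_model(sigma_core = cf[["sc"]], sigma_tail = cf[["st"]],
                    tail_weight = cf[["w"]], amplitude = cf[["A"]])
  attr(out, "fit") <- fit
  out
}
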