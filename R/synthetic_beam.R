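#' Double-Gaussian pencil-beam model
#'
#' Analytic stand-in for the lateral dose distribution of a scanned proton
#' pencil beam: a narrow Gaussian core carrying most of the dose plus a broad
#' low-amplitude Gaussian tail, the shape such beams show down to the 1e-4
#' level of the central dose. The expected dose at radius `r` is
#'
#' \deqn{D(r) = A [(1 - w) e^{-r^2 / 2\sigma_c^2} + w e^{-r^2 / 2\sigma_t^2}]}
#'
#' which is strictly positive and strictly decreasing in `r`. With
#' `ellipticity > 1` the iso-dose contours are ellipses with major/minor axis
#' ratio `rho`; the circular radius is replaced by the elliptical radius
#' `sqrt((u / sqrt(rho))^2 + (v * sqrt(rho))^2)`, which keeps the product of
#' the two axis sigmas (hence the iso-dose contour areas) equal to the
#' circular model's.
#'
#' @param sigma_core core Gaussian sigma, mm (`> 0`).
#' @param sigma_tail tail Gaussian sigma, mm (`> sigma_core`).
#' @param tail_weight fraction `w` of the central amplitude carried by the
#'   tail term, in `[0, 1)`.
#' @param amplitude central dose `A` (dose units, `> 0`).
#' @param ellipticity major/minor axis ratio `rho >= 1`; 1 = circular.
#' @return An object of class `beam_model`.
#' @examples
#' m <- beam_model(sigma_core = 5, sigma_tail = 20, tail_weight = 0)
#' expected_dose(m, c(0, 5))  # 1 and exp(-1/2)
#' @export
beam_model <- function(sigma_core = 6, sigma_tail = 25, tail_weight = 0.05,
                       amplitude = 1, ellipticity = 1) {
  if (!is.numeric(sigma_core) || sigma_core <= 0)
    stop("`sigma_core` must be > 0")
  if (!is.numeric(sigma_tail) || sigma_tail <= sigma_core)
    stop("`sigma_tail` must exceed `sigma_core`")
  if (tail_weight < 0 || tail_weight >= 1)
    stop("`tail_weight` must be in [0, 1)")
  if (amplitude <= 0) stop("`amplitude` must be > 0")
  if (ellipticity < 1) stop("`ellipticity` must be >= 1")
  structure(
    list(sigma_core = sigma_core, sigma_tail = sigma_tail,
         tail_weight = tail_weight, amplitude = amplitude,
         ellipticity = ellipticity),
    class = "beam_model"
  )
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> core sigma %g mm, tail sigma %g mm (weight %g), amplitude %g",
              x$sigma_core, x$sigma_tail, x$tail_weight, x$amplitude))
  if (x$ellipticity > 1)
    cat(sprintf(", ellipticity %g", x$ellipticity))
  cat("\n")
  invisible(x)
}

#' Expected (noise-free) dose of a beam model
#'
#' `expected_dose()` evaluates the circular radial form `D(r)`;
#' `expected_dose_xy()` evaluates the (possibly elliptical) model at in-plane
#' offsets `(u, v)` from the beam center.
#'
#' @param model a [beam_model()].
#' @param r radial distance from the beam axis, mm (`>= 0`); vectorized.
#' @return Expected dose, same length as `r`.
#' @export
expected_dose <- function(model, r) {
  stopifnot(inherits(model, "beam_model"))
  if (any(r < 0)) stop("radius must be non-negative")
  w <- model$tail_weight
  model$amplitude * ((1 - w) * exp(-r^2 / (2 * model$sigma_core^2)) +
                       w * exp(-r^2 / (2 * model$sigma_tail^2)))
}

#' @rdname expected_dose
#' @param u,v in-plane offsets from the beam center, mm; vectorized
#'   (recycled against each other).
#' @export
expected_dose_xy <- function(model, u, v) {
  stopifnot(inherits(model, "beam_model"))
  s <- sqrt(model$ellipticity)
  expected_dose(model, sqrt((u / s)^2 + (v * s)^2))
}

#' Give a beam model an elliptical cross section
#'
#' Sets the major/minor iso-dose axis ratio to `rho` while preserving the
#' product of the two axis sigmas, so the area enclosed by each iso-dose
#' contour is unchanged. Scanned proton beams typically show ratios between
#' 1.05 and 1.15 at the isocenter.
#'
#' @param model a [beam_model()].
#' @param rho major/minor axis ratio, `>= 1`.
#' @return The modified `beam_model`.
#' @export
make_elliptical <- function(model, rho) {
  stopifnot(inherits(model, "beam_model"))
  if (!is.numeric(rho) || length(rho) != 1L || rho < 1)
    stop("`rho` must be a single number >= 1")
  model$ellipticity <- rho
  model
}

#' Simulation configuration for the synthetic beam
#'
#' Defines the emulated Monte-Carlo run: the particle-history count `N`, a
#' calibration constant `peak_counts` (expected particle count scored at the
#' beam-center voxel *per history*), the scoring-plane geometry, and the RNG
#' seed. The expected count at a voxel with expected dose `D` is
#' `peak_counts * n_histories * D / A`, so the per-voxel relative standard
#' deviation of the simulated score is `(peak_counts * n_histories * D/A)^-1/2`
#' — the 1/sqrt(N) counting behavior of real MC voxel scoring.
#'
#' @param n_histories emulated particle-history count `N` (positive).
#' @param peak_counts expected beam-center count per history (`> 0`). The
#'   default pairs with the default `n_histories` of 2e7 to give 1e4 expected
#'   counts at the peak voxel.
#' @param seed integer RNG seed; simulation is deterministic given the seed
#'   and does not touch the global RNG stream.
#' @param shape integer length-2 scoring-plane shape in voxels.
#' @param spacing in-plane voxel spacing, mm (isotropic scalar or length-2).
#' @param noise if `FALSE`, [simulate_slice()] returns the noise-free
#'   expected dose at every voxel center.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_histories = 2e7, peak_counts = 5e-4, seed = 1L,
                       shape = c(201L, 201L), spacing = 1, noise = TRUE) {
  if (!is.numeric(n_histories) || n_histories < 1)
    stop("`n_histories` must be a positive count")
  if (!is.numeric(peak_counts) || peak_counts <= 0)
    stop("`peak_counts` must be > 0")
  shape <- as.integer(rep(shape, length.out = 2L))
  if (any(shape < 1L)) stop("plane shape must be positive")
  spacing <- as.numeric(rep(spacing, length.out = 2L))
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(
    list(n_histories = as.numeric(n_histories), peak_counts = peak_counts,
         seed = as.integer(seed), shape = shape, spacing = spacing,
         noise = isTRUE(noise)),
    class = "sim_config"
  )
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one noisy lateral dose slice
#'
#' Emulates MC voxel scoring of the beam model on a lateral plane. Each voxel
#' score is an independent scaled Poisson draw:
#' `score = (A / (c N)) * Poisson(c N D(r) / A)` with `c = peak_counts` and
#' `N = n_histories`, so every voxel's expectation equals the model dose at
#' its center and its relative SD follows counting statistics. Where the
#' expected count exceeds 2^30 the Poisson draw is replaced by a Gaussian of
#' matching mean and variance (truncated at zero) to stay inside the integer
#' counting range.
#'
#' @param model a [beam_model()].
#' @param config a [sim_config()].
#' @return A [lateral_slice()] with the beam center at the plane's geometric
#'   center voxel.
#' @export
simulate_slice <- function(model, config) {
  stopifnot(inherits(model, "beam_model"), inherits(config, "sim_config"))
  shape <- config$shape
  sp <- config$spacing
  center <- (shape + 1L) %/% 2L
  u <- (seq_len(shape[1]) - center[1]) * sp[1]
  v <- (seq_len(shape[2]) - center[2]) * sp[2]
  dose <- outer(u, v, function(uu, vv) expected_dose_xy(model, uu, vv))
  if (!config$noise) {
    sl <- lateral_slice(dose, spacing = sp, center = center)
    return(sl)
  }
  cn <- config$peak_counts * config$n_histories
  lambda <- cn * dose / model$amplitude
  counts <- .with_seed(config$seed, {
    out <- numeric(length(lambda))
    big <- lambda > 2^30
    if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
    if (any(big))
      out[big] <- pmax(0, stats::rnorm(sum(big), mean = lambda[big],
                                       sd = sqrt(lambda[big])))
    out
  })
  scores <- matrix((model$amplitude / cn) * counts, nrow = shape[1])
  lateral_slice(scores, spacing = sp, center = center)
}

#' Default desk-scale study fixture
#'
#' The beam and run configuration used throughout the package's examples and
#' tests: a 201 x 201 plane at 1 mm spacing with core sigma 6 mm, tail sigma
#' 25 mm and tail weight 0.05 — a tail that spans the 1e-4 dynamic range a
#' clinical beam model must cover — scored with 2e7 emulated histories
#' yielding 1e4 expected counts at the peak voxel.
#'
#' @param seed RNG seed stored in the returned configuration.
#' @return `default_beam_model()` a [beam_model()];
#'   `default_sim_config()` a [sim_config()].
#' @export
default_beam_model <- function() {
  beam_model(sigma_core = 6, sigma_tail = 25, tail_weight = 0.05,
             amplitude = 1, ellipticity = 1)
}

#' @rdname default_beam_model
#' @export
default_sim_config <- function(seed = 1L) {
  sim_config(n_histories = 2e7, peak_counts = 5e-4, seed = seed,
             shape = c(201L, 201L), spacing = 1, noise = TRUE)
}
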