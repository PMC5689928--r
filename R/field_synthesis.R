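# Square-field synthesis: central doses and output factors obtained by
# superposing spot profiles on a scan grid.

#' Square scan-field specification
#'
#' @param field_size square field side length, mm.
#' @param spot_spacing spot grid pitch, mm (`> 0`, `<= field_size`).
#' @param reference_field_size side of the reference field for output-factor
#'   normalization, mm (default 100).
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(field_size, spot_spacing,
                       reference_field_size = 100) {
  if (spot_spacing <= 0) stop("`spot_spacing` must be > 0")
  if (field_size < spot_spacing)
    stop("`field_size` must be at least one spot spacing")
  structure(list(field_size = field_size, spot_spacing = spot_spacing,
                 reference_field_size = reference_field_size),
            class = "field_spec")
}

#' Turn a radial profile into a dose-vs-radius function
#'
#' Builds an interpolating function over the profile entries: linear in
#' dose through the high-dose (point) region, linear in log-dose through
#' the low-dose tail where doses span orders of magnitude (falling back to
#' linear across any zero-dose tail entries), and zero beyond the last
#' profile radius.
#'
#' @param profile a [radial_profile()], or a data frame with `radius_mm`
#'   and `dose` columns (all of it then treated as tail if a `region`
#'   column says so, point region otherwise).
#' @return A function `f(r)` mapping radius (mm, vectorized) to dose.
#' @export
radial_to_function <- function(profile) {
  if (inherits(profile, "radial_profile")) {
    ent <- profile$entries
    boundary <- profile$boundary
  } else {
    ent <- as.data.frame(profile)
    boundary <- if ("region" %in% names(ent) &&
                    any(ent$region == "interval"))
      min(ent$radius_mm[ent$region == "interval"]) else Inf
  }
  if (nrow(ent) == 0L) stop("empty profile")
  ent <- ent[order(ent$radius_mm), ]
  r <- ent$radius_mm
  d <- ent$dose
  r_max <- max(r)
  use_log <- is.finite(boundary) && all(d[r >= boundary] > 0)
  lin <- stats::approxfun(r, d, rule = 2)
  logf <- if (use_log && sum(r >= boundary) >= 2L) {
    ri <- r[r >= boundary]
    stats::approxfun(ri, log(d[r >= boundary]), rule = 2)
  } else NULL
  function(rq) {
    out <- numeric(length(rq))
    inside <- rq <= r_max
    if (any(inside)) {
      ri <- rq[inside]
      val <- lin(ri)
      if (!is.null(logf)) {
        tailq <- ri >= boundary
        if (any(tailq)) val[tailq] <- exp(logf(ri[tailq]))
      }
      out[inside] <- val
    }
    out
  }
}

#' Central dose of a square field composed of spots
#'
#' Superposes identical spots on a square grid centered on the field: spot
#' positions are integer multiples of the spacing in both directions, and a
#' spot is included when its center lies within the field boundary
#' (inclusive). The central dose is the sum of the radial profile evaluated
#' at each spot's distance from the field center.
#'
#' @param profile_fn a dose-vs-radius function, e.g. from
#'   [radial_to_function()] or a closed-form model.
#' @param field a [field_spec()].
#' @return Central dose of the composed field.
#' @export
square_field_central_dose <- function(profile_fn, field) {
  stopifnot(inherits(field, "field_spec"))
  s <- field$spot_spacing
  half <- field$field_size / 2
  m <- floor(half / s + 1e-9)
  pos <- (-m:m) * s
  xx <- rep(pos, times = length(pos))
  yy <- rep(pos, each = length(pos))
  sum(profile_fn(sqrt(xx^2 + yy^2)))
}

#' Output factors over a set of field sizes
#'
#' Central dose of each square field relative to the reference field's,
#' all composed from the same spot profile at the same spacing.
#'
#' @param profile_fn a dose-vs-radius function.
#' @param field_sizes square side lengths, mm.
#' @param spot_spacing spot grid pitch, mm.
#' @param reference reference field side, mm (default 100).
#' @return Data frame with columns `field_size`, `central_dose`,
#'   `output_factor`.
#' @export
output_factor_curve <- function(profile_fn, field_sizes, spot_spacing,
                                reference = 100) {
  dose_of <- function(fs)
    square_field_central_dose(profile_fn, field_spec(fs, spot_spacing,
                                                     reference))
  ref_dose <- dose_of(reference)
  if (ref_dose <= 0) stop("reference field has zero central dose")
  cd <- vapply(field_sizes, dose_of, 1)
  data.frame(field_size = field_sizes, central_dose = cd,
             output_factor = cd / ref_dose)
}
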