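#' Voxelized 3D dose grid
#'
#' Container for a Monte-Carlo-scored cuboid sensitive volume: a 3D array of
#' non-negative voxel dose scores with physical voxel spacing and a designated
#' beam axis. Voxel `(i, j, k)` (1-based in R) sits at physical position
#' `((i-1) dx, (j-1) dy, (k-1) dz)` relative to the grid origin voxel; all
#' radii are measured between voxel centers.
#'
#' @param values 3D numeric array of dose scores (arbitrary dose units,
#'   all `>= 0`).
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm,
#'   all `> 0`.
#' @param beam_axis integer in 1..3: the grid axis parallel to the beam.
#' @param name free-text label stored with the grid.
#' @return An object of class `dose_grid`.
#' @examples
#' g <- dose_grid(array(1, dim = c(5, 5, 3)))
#' dim(g$values)
#' @export
dose_grid <- function(values, spacing = c(1, 1, 1), beam_axis = 3L,
                      name = "") {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (anyNA(values) || any(values < 0))
    stop("dose values must be non-negative and non-missing")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  beam_axis <- as.integer(beam_axis)
  if (!beam_axis %in% 1:3)
    stop("`beam_axis` must be 1, 2 or 3")
  structure(
    list(values = values, spacing = spacing, beam_axis = beam_axis,
         name = as.character(name)[1]),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %g x %g x %g mm, beam axis %d\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$beam_axis))
  cat(sprintf("  total dose %g, %d non-zero voxels",
              sum(x$values), sum(x$values > 0)))
  if (nzchar(x$name)) cat(sprintf("  (%s)", x$name))
  cat("\n")
  invisible(x)
}

#' One lateral scoring plane perpendicular to the beam axis
#'
#' @param values 2D numeric matrix of dose scores, all `>= 0`.
#' @param spacing numeric length-2 in-plane voxel spacing `(du, dv)` in mm.
#' @param center integer length-2 `(i0, j0)` voxel index (1-based) of the beam
#'   center; defaults to the geometric center voxel of the plane.
#' @param depth_label position of the plane along the beam axis, in mm.
#' @return An object of class `lateral_slice`.
#' @export
lateral_slice <- function(values, spacing = c(1, 1), center = NULL,
                          depth_label = NA_real_) {
  values <- as.matrix(values)
  if (anyNA(values) || any(values < 0))
    stop("dose values must be non-negative and non-missing")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("`spacing` must be two positive numbers (mm)")
  if (is.null(center)) center <- (dim(values) + 1L) %/% 2L
  center <- as.integer(center)
  if (length(center) != 2L ||
      center[1] < 1L || center[1] > nrow(values) ||
      center[2] < 1L || center[2] > ncol(values))
    stop("`center` must index a voxel inside the plane")
  structure(
    list(values = values, spacing = spacing, center = center,
         depth_label = as.numeric(depth_label)[1]),
    class = "lateral_slice"
  )
}

#' @export
print.lateral_slice <- function(x, ...) {
  cat(sprintf("<lateral_slice> %d x %d voxels, spacing %g x %g mm, center (%d, %d)\n",
              nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
              x$center[1], x$center[2]))
  if (!is.na(x$depth_label))
    cat(sprintf("  depth %g mm\n", x$depth_label))
  invisible(x)
}

#' Extract a lateral slice from a dose grid
#'
#' Takes the 2D plane perpendicular to the grid's beam axis at the given
#' index. In-plane spacings are taken from the grid; if they differ
#' (anisotropic plane), the slice is returned with an `anisotropic` attribute
#' set so that downstream exact radial grouping can refuse or switch to
#' tolerance mode.
#'
#' @param grid a [dose_grid()].
#' @param index 1-based voxel index along the beam axis.
#' @param center optional `(i0, j0)` beam-center voxel index in the plane;
#'   defaults to the plane's geometric center voxel.
#' @return A [lateral_slice()].
#' @export
extract_slice <- function(grid, index, center = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  index <- as.integer(index)
  n_depth <- dim(grid$values)[grid$beam_axis]
  if (length(index) != 1L || is.na(index) || index < 1L || index > n_depth)
    stop(sprintf("slice index %s out of range 1..%d along beam axis",
                 as.character(index), n_depth))
  plane_axes <- setdiff(1:3, grid$beam_axis)
  idx <- list(TRUE, TRUE, TRUE)
  idx[[grid$beam_axis]] <- index
  vals <- do.call(`[`, c(list(grid$values), idx, list(drop = FALSE)))
  vals <- array(vals, dim = dim(grid$values)[plane_axes])
  sp <- grid$spacing[plane_axes]
  sl <- lateral_slice(vals, spacing = sp, center = center,
                      depth_label = (index - 1) * grid$spacing[grid$beam_axis])
  attr(sl, "anisotropic") <- sp[1] != sp[2]
  sl
}

# Parse "# key: v1 v2 ..." header lines of the hadron-ascii dialect.
.parse_ascii_header <- function(lines) {
  hdr <- list()
  for (ln in lines) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (!grepl(":", body, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", body))
    val <- trimws(sub("^[^:]*:", "", body))
    hdr[[key]] <- val
  }
  hdr
}

#' Read a 3D dose grid from a text file
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"hadron-ascii"`}{Whitespace-separated `i j k dose` records with
#'     0-based voxel indices, preceded by `#`-prefixed header lines carrying
#'     `shape`, `spacing`, and optionally `beam_axis` and `name`. This mirrors
#'     the sparse ASCII output of Geant4-example-style cuboid scoring; voxels
#'     absent from the file read as 0 dose.}
#'   \item{`"csv3d"`}{Long-format CSV with header `i,j,k,dose` (0-based
#'     indices). Grid `shape` and `spacing` must be supplied as arguments
#'     (shape defaults to the smallest grid holding every listed voxel).}
#' }
#'
#' @param path file to read.
#' @param dialect `"hadron-ascii"` (default) or `"csv3d"`.
#' @param shape,spacing,beam_axis grid declaration for `"csv3d"` (ignored for
#'   `"hadron-ascii"`, whose header is authoritative).
#' @return A [dose_grid()].
#' @export
read_dose_grid <- function(path, dialect = c("hadron-ascii", "csv3d"),
                           shape = NULL, spacing = c(1, 1, 1),
                           beam_axis = 3L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))

  if (dialect == "hadron-ascii") {
    lines <- readLines(path)
    is_hdr <- grepl("^\\s*#", lines)
    hdr <- .parse_ascii_header(lines[is_hdr])
    if (is.null(hdr$shape))
      stop("hadron-ascii header must declare '# shape: nx ny nz'")
    shape <- as.integer(strsplit(trimws(hdr$shape), "\\s+")[[1]])
    if (!is.null(hdr$spacing))
      spacing <- as.numeric(strsplit(trimws(hdr$spacing), "\\s+")[[1]])
    if (!is.null(hdr$beam_axis)) beam_axis <- as.integer(hdr$beam_axis)
    name <- if (is.null(hdr$name)) "" else hdr$name
    data_idx <- which(!is_hdr & nzchar(trimws(lines)))
    recs <- matrix(NA_real_, nrow = length(data_idx), ncol = 4L)
    for (m in seq_along(data_idx)) {
      ln <- data_idx[m]
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      val <- suppressWarnings(as.numeric(tok))
      if (length(tok) != 4L || anyNA(val))
        stop(sprintf("parse error at line %d: expected 'i j k dose', got '%s'",
                     ln, lines[ln]))
      recs[m, ] <- val
    }
  } else {
    df <- utils::read.csv(path)
    need <- c("i", "j", "k", "dose")
    if (!all(need %in% names(df)))
      stop("csv3d file must have header columns i,j,k,dose")
    recs <- as.matrix(df[, need])
    name <- ""
    if (is.null(shape)) {
      shape <- if (nrow(recs)) as.integer(apply(recs[, 1:3, drop = FALSE],
                                                2, max) + 1) else c(1L, 1L, 1L)
    }
  }

  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("grid shape must be three positive integers")
  if (nrow(recs)) {
    ijk <- recs[, 1:3, drop = FALSE]
    if (any(ijk != floor(ijk)))
      stop("voxel indices must be integers")
    if (any(ijk < 0) || any(t(ijk) >= shape))
      stop("voxel index outside the declared grid shape")
    if (any(recs[, 4] < 0))
      stop("negative dose value in file")
    lin <- 1 + ijk[, 1] + shape[1] * (ijk[, 2] + shape[2] * ijk[, 3])
    if (anyDuplicated(lin))
      stop("duplicate (i, j, k) voxel record in file")
  }
  values <- array(0, dim = shape)
  if (nrow(recs)) values[lin] <- recs[, 4]
  dose_grid(values, spacing = spacing, beam_axis = beam_axis, name = name)
}

#' Write a dose grid in the sparse hadron-ascii dialect
#'
#' Only non-zero voxels are written (0-based `i j k dose` records); the
#' header carries shape, spacing and beam axis so the file is
#' self-describing. Doses are written with 17 significant digits so the
#' write/read round trip is bit-exact.
#'
#' @param grid a [dose_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  d <- dim(grid$values)
  nz <- which(grid$values != 0)
  ijk <- arrayInd(nz, d) - 1L
  hdr <- c(
    "# radproj dose grid",
    sprintf("# shape: %d %d %d", d[1], d[2], d[3]),
    sprintf("# spacing: %.17g %.17g %.17g",
            grid$spacing[1], grid$spacing[2], grid$spacing[3]),
    sprintf("# beam_axis: %d", grid$beam_axis)
  )
  if (nzchar(grid$name)) hdr <- c(hdr, sprintf("# name: %s", grid$name))
  body <- sprintf("%d %d %d %.17g", ijk[, 1], ijk[, 2], ijk[, 3],
                  grid$values[nz])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a radial profile to CSV
#'
#' Columns are `radius_mm`, `dose`, `n_voxels`, `rse_percent` (empty where
#' undefined) and `region` (`point` or `interval`), one row per profile
#' entry in ascending radius. Numeric fields are written with 17 significant
#' digits, so reading the file back reproduces them exactly.
#'
#' @param profile a [radial_profile()] object, or a data frame with the
#'   columns above.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  ent <- if (inherits(profile, "radial_profile")) profile$entries else
    as.data.frame(profile)
  if (is.null(ent) || nrow(ent) == 0L)
    stop("cannot write an empty profile")
  if (!"rse_percent" %in% names(ent)) ent$rse_percent <- NA_real_
  if (!"region" %in% names(ent)) ent$region <- "point"
  ent <- ent[order(ent$radius_mm), ]
  num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(
    radius_mm = num(ent$radius_mm),
    dose = num(ent$dose),
    n_voxels = as.integer(ent$n_voxels),
    rse_percent = num(ent$rse_percent),
    region = ent$region,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a profile CSV written by [write_profile()]
#'
#' @param path file to read.
#' @return A data frame with columns `radius_mm`, `dose`, `n_voxels`,
#'   `rse_percent`, `region`.
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("radius_mm", "dose", "n_voxels", "rse_percent", "region")
  if (!all(need %in% names(df)))
    stop("not a radproj profile CSV (missing columns)")
  for (cl in c("radius_mm", "dose", "rse_percent"))
    df[[cl]] <- as.numeric(df[[cl]])
  df$n_voxels <- as.integer(df$n_voxels)
  df
}
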