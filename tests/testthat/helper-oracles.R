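# Independent oracles and small fixture builders shared across the suite.

# Brute-force lattice multiplicity: number of integer pairs (i, j) with
# i^2 + j^2 == r2, counted by an explicit double loop.
brute_multiplicity <- function(r2) {
  m <- ceiling(sqrt(r2))
  cnt <- 0L
  for (i in -m:m)
    for (j in -m:m)
      if (i * i + j * j == r2) cnt <- cnt + 1L
  cnt
}

# Cylindrical-like scoring oracle: sweep the slice voxel by voxel, find each
# voxel's histogram bin by its exact squared radius, and fill running sum and
# count histograms; the filled histogram divided by the bin count gives the
# mean dose per radius. Independent of the package's grouped implementation.
cylindrical_oracle <- function(slice) {
  sums <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  i0 <- slice$center[1]; j0 <- slice$center[2]
  for (i in seq_len(nrow(slice$values))) {
    for (j in seq_len(ncol(slice$values))) {
      key <- as.character((i - i0)^2 + (j - j0)^2)
      sums[[key]] <- (if (is.null(sums[[key]])) 0 else sums[[key]]) +
        slice$values[i, j]
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  r2 <- sort(as.numeric(ls(sums)))
  data.frame(
    radius_mm = sqrt(r2) * slice$spacing[1],
    dose = vapply(as.character(r2), function(k) sums[[k]] / counts[[k]], 1),
    n = vapply(as.character(r2), function(k) counts[[k]], 1L),
    row.names = NULL
  )
}

# Uniform random slice on an odd square lattice, seeded.
random_slice <- function(n = 31L, seed = 1L, spacing = 1) {
  set.seed(seed)
  lateral_slice(matrix(runif(n * n), n, n), spacing = c(spacing, spacing))
}

# Noise-free slice of a model on an odd square lattice.
noise_free_slice <- function(model, n = 61L, spacing = 1) {
  simulate_slice(model, sim_config(shape = c(n, n), spacing = spacing,
                                   noise = FALSE))
}

# Small-plane noisy config helper.
small_config <- function(seed, n = 41L, peak = 1e4) {
  sim_config(n_histories = 2e7, peak_counts = peak / 2e7, seed = seed,
             shape = c(n, n), spacing = 1)
}

# Extract the group with a given exact r^2 key from group_by_radius() output.
group_with_key <- function(groups, r2) {
  keys <- vapply(groups$groups, `[[`, 1, "r2_key")
  hit <- which(keys == r2)
  if (!length(hit)) return(NULL)
  groups$groups[[hit]]
}
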