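# Shared fixtures and independent oracles for the test suite.
# Expected values marked "frozen" below were computed with these oracles.

# Compact phantom used throughout unit tests (fast, same structure as the
# default geometry).
small_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(24L, 24L, 8L), body_radius = 7,
         skin_rim_thickness = 2, noise_box = 6L,
         lesion_center = c(19, 13, 4), lesion_radius = 2.2),
    list(...))
  do.call(phantom_spec, args)
}

# Build a dwi_study directly from a voxel-wise diffusivity field (bypasses
# the phantom generator; used as an independent route in map tests).
study_from_field <- function(D, b_values = c(50, 800), S0 = 1000) {
  g <- dim(D)
  vols <- array(0, dim = c(g, length(b_values)))
  for (i in seq_along(b_values)) vols[, , , i] <- S0 * exp(-b_values[i] * D)
  dwi_study(vols, b_values, case_id = "field")
}

# Brute-force 6-connected erosion oracle (triple loop, border = background).
erode_oracle <- function(mask) {
  m <- mask > 0
  d <- dim(m)
  out <- array(FALSE, dim = d)
  at <- function(x, y, z) {
    if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) FALSE
    else m[x, y, z]
  }
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    out[x, y, z] <- m[x, y, z] &&
      at(x - 1, y, z) && at(x + 1, y, z) &&
      at(x, y - 1, z) && at(x, y + 1, z) &&
      at(x, y, z - 1) && at(x, y, z + 1)
  }
  out
}

# Mann-Whitney U for x (midrank ties convention).
u_stat_oracle <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) group assignments (tie-free samples only).
ranksum_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i)
    u_stat_oracle(pooled[i], pooled[-i]))
  u_obs <- u_stat_oracle(x, y)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}
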