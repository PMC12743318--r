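# Small programmatic fixtures shared across the suite.

# Minimal topology: n unnamed carbon atoms, one residue each.
toy_topology <- function(n, name = "C1", resname = "UNK", segid = "TOY") {
  pet_topology(data.frame(
    serial = seq_len(n), name = name, resname = resname,
    resid = seq_len(n), segid = segid, chain = "",
    stringsAsFactors = FALSE))
}

# One-frame trajectory around a coordinate matrix.
toy_trajectory <- function(coords, box = NULL, topology = NULL) {
  if (is.null(topology)) topology <- toy_topology(nrow(coords))
  pet_trajectory(topology, matrix(as.vector(t(coords)), 1), box = box)
}

# Marker-style protein topology matching the PETaseSM14 preset roles.
sm14_marker_frame <- function(d = c(d1 = 6.5, d2 = 8.5, d3 = 3.0, d4 = 5.0)) {
  sim <- simulate_site(site_dynamics_params(
    d1 = distance_dynamics(d[["d1"]], 0),
    d2 = distance_dynamics(d[["d2"]], 0),
    d3 = distance_dynamics(d[["d3"]], 0),
    d4 = distance_dynamics(d[["d4"]], 0)), n_frames = 2, seed = 1)
  sim
}

# Random rigid motion applied to the rows of a coordinate matrix.
rigid_motion <- function(coords) {
  R <- pettraj:::.random_rotation()
  t0 <- stats::runif(3, -20, 20)
  sweep(coords %*% R, 2, t0, "+")
}

# Brute-force minimum-image distance via explicit 27-image enumeration.
brute_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- sqrt(sum((a - b + c(i, j, k) * box)^2))
    best <- min(best, d)
  }
  best
}
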