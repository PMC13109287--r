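# Shared fixtures: small deterministic clouds and generator configs.

# planar grid cloud: n x n points spaced `step` apart at height z,
# normals +z (or -z), residues tiled in `res_cols` columns
plane_cloud <- function(n = 10, step = 1, z = 0, chain = "A", up = TRUE,
                        resname = "LEU", potential = 0) {
  g <- expand.grid(x = seq_len(n) * step, y = seq_len(n) * step)
  as_surface_cloud(data.frame(
    x = g$x, y = g$y, z = z,
    nx = 0, ny = 0, nz = if (up) 1 else -1,
    potential = potential, chain = chain,
    resnum = ceiling(seq_len(n^2) / n), # one residue per row block
    resname = resname
  ))
}

# cloud from explicit point table rows
cloud_from_points <- function(df, chain = "A") {
  defaults <- list(nx = 0, ny = 0, nz = 1, potential = 0, resname = "LEU")
  if (!"resnum" %in% names(df)) df$resnum <- seq_len(nrow(df))
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  }
  df$chain <- chain
  as_surface_cloud(df)
}

# small, fast generator config for unit tests
tiny_config <- function(...) {
  generator_config(
    n_complexes = 2, density = 3, surface_radius = 12, residue_radius = 5,
    far_offset = 36, pairs_per_complex = 4, ...
  )
}

# random cloud for brute-force oracles
random_cloud <- function(n, chain = "A", seed = 1, spread = 10) {
  set.seed(seed)
  as_surface_cloud(data.frame(
    x = runif(n, 0, spread), y = runif(n, 0, spread), z = runif(n, 0, spread),
    nx = 0, ny = 0, nz = 1,
    potential = rnorm(n), chain = chain,
    resnum = sample(1:max(2, n %/% 10), n, replace = TRUE),
    resname = sample(c("LEU", "SER", "ARG"), n, replace = TRUE)
  ))
}

# smooth random heightfield patch as an oriented point set (for projection
# and moment tests that do not need a full cloud)
synthetic_oriented_patch <- function(n = 600, seed = 1, amp = 1) {
  set.seed(seed)
  r <- 9 * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  x <- r * cos(th)
  y <- r * sin(th)
  z <- amp * (sin(x / 3) + cos(y / 4)) / 2
  structure(
    list(
      coords = cbind(x, y, z - mean(z)),
      potential = rnorm(n),
      invert = FALSE, frame = diag(3), centroid = c(0, 0, 0)
    ),
    class = "oriented_patch"
  )
}
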