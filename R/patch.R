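# Surface patches: extraction within a 9 A sphere, least-squares plane
# re-orientation, and 45-degree cone projection onto a 25 x 25 disk image.

#' Extract a surface patch
#'
#' All cloud points within `R` (inclusive) of the point at `center_index`.
#'
#' @param cloud A `surface_cloud`.
#' @param center_index Row index of the patch center point.
#' @param R Patch sphere radius in Angstrom (default 9).
#' @param min_points Patches with fewer points cannot support a reliable
#'   plane fit and raise a too-sparse error (default 10).
#' @return A `patch` object: list with `points` (tibble), `center`
#'   (length-3), `radius`.
#' @export
extract_patch <- function(cloud, center_index, R = 9, min_points = 10) {
  if (center_index < 1 || center_index > nrow(cloud)) {
    abort("center index out of range")
  }
  xyz <- cloud_xyz(cloud)
  ctr <- xyz[center_index, ]
  d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
  member <- which(d2 <= R^2)
  if (length(member) < min_points) {
    abort(paste0(
      "patch too sparse: ", length(member), " point(s) within ", R, " A"
    ), class = "surfcomp_sparse_patch_error")
  }
  out <- list(
    points = tibble::as_tibble(as.data.frame(cloud)[member, ]),
    center = ctr, radius = R, indices = member
  )
  class(out) <- "patch"
  out
}

#' @export
print.patch <- function(x, ...) {
  cat("<patch>", nrow(x$points), "points, R =", x$radius, "A\n")
  invisible(x)
}

#' Re-orient a patch onto the x-y plane
#'
#' Fits a least-squares plane through the patch points (smallest principal
#' axis of the centered coordinates) and rotates the patch so the plane
#' normal is the z-axis and the patch centroid is the origin. With
#' `invert = FALSE` the solvent-exposed side (mean of the member outward
#' normals) faces +z; with `invert = TRUE` it faces -z, which is the
#' arrangement used for the second patch of a complementarity comparison
#' ("solvent-exposed sides face opposite verses"). The in-plane axes are the
#' remaining principal directions with signs fixed by the third moment of
#' the point distribution, so the frame is deterministic; descriptors are in
#' any case invariant to the residual in-plane rotation.
#'
#' @param patch A `patch` from [extract_patch()].
#' @param invert Logical; orient the solvent side toward -z.
#' @return An `oriented_patch`: list with `coords` (n x 3 matrix),
#'   `potential`, `invert` and the rotation `frame`.
#' @export
orient_patch <- function(patch, invert = FALSE) {
  pts <- patch$points
  P <- cbind(pts$x, pts$y, pts$z)
  mu <- colMeans(P)
  Q <- sweep(P, 2, mu)
  C <- crossprod(Q) / nrow(Q)
  eig <- eigen(C, symmetric = TRUE)
  if (eig$values[2] < 1e-10 * max(eig$values[1], 1e-300)) {
    abort("degenerate patch: points are (nearly) collinear",
      class = "surfcomp_orientation_error"
    )
  }
  e3 <- eig$vectors[, 3] # smallest variance = plane normal
  mean_normal <- colMeans(cbind(pts$nx, pts$ny, pts$nz))
  if (sum(e3 * mean_normal) < 0) e3 <- -e3
  if (invert) e3 <- -e3
  e1 <- eig$vectors[, 1]
  s1 <- sum((Q %*% e1)^3)
  if (s1 < 0) e1 <- -e1
  e2 <- c(
    e3[2] * e1[3] - e3[3] * e1[2],
    e3[3] * e1[1] - e3[1] * e1[3],
    e3[1] * e1[2] - e3[2] * e1[1]
  )
  frame <- cbind(e1, e2, e3)
  out <- list(
    coords = Q %*% frame,
    potential = pts$potential,
    invert = invert,
    frame = frame,
    centroid = mu
  )
  class(out) <- "oriented_patch"
  out
}

#' Project an oriented patch onto the unit disk
#'
#' Places the cone apex `C` on the z-axis at the minimal height such that
#' every secant from `C` to a patch point makes an angle of at most
#' `theta_max` with the axis (closed form: `max(z + rho / tan(theta_max))`).
#' Each point is labelled with its distance `r` to `C`, points are projected
#' onto the x-y plane, scaled by the maximum planar radius so the patch rim
#' touches the unit circle, and binned on a `grid` x `grid` image. A pixel
#' carries the mean `r` (shape) or mean electrostatic potential
#' (electrostatic) of the points projected into it; empty pixels are masked.
#'
#' With `infill = TRUE` (the default) disk pixels left empty by the finite
#' surface sampling are filled with the value of the nearest occupied pixel
#' before expansion, so the descriptor reflects the surface rather than the
#' sampling holes; `mask` still records the genuinely occupied pixels.
#'
#' @param oriented An `oriented_patch` from [orient_patch()].
#' @param kind `"shape"` or `"electrostatic"`.
#' @param theta_max Cone half-angle in degrees (default 45).
#' @param grid Image size (default 25).
#' @param infill Nearest-neighbor infill of empty disk pixels (default
#'   TRUE).
#' @return A `projection`: list with `grid` (matrix, `NA` at empty pixels
#'   unless infilled), `mask` (occupied pixels), `kind`, `apex` height,
#'   `scale`, `n_points`.
#' @export
build_projection <- function(oriented, kind = c("shape", "electrostatic"),
                             theta_max = 45, grid = 25, infill = TRUE) {
  kind <- match.arg(kind)
  X <- oriented$coords
  rho <- sqrt(X[, 1]^2 + X[, 2]^2)
  tan_t <- tan(theta_max * pi / 180)
  apex <- max(X[, 3] + rho / tan_t)
  r <- sqrt(rho^2 + (apex - X[, 3])^2)
  scale <- max(rho)
  if (scale < 1e-9) {
    abort("degenerate projection: all points on the z-axis",
      class = "surfcomp_projection_error"
    )
  }
  u <- X[, 1] / scale
  v <- X[, 2] / scale
  ix <- pmin(pmax(floor((u + 1) / 2 * grid) + 1L, 1L), grid)
  iy <- pmin(pmax(floor((v + 1) / 2 * grid) + 1L, 1L), grid)
  pix <- (iy - 1L) * grid + ix # column-major: x fastest, matches grid_geometry
  vals <- if (kind == "shape") r else oriented$potential
  sums <- rowsum(vals, pix)
  cnts <- rowsum(rep(1, length(pix)), pix)
  img <- rep(NA_real_, grid * grid)
  img[as.integer(rownames(sums))] <- sums / cnts
  occupied <- sum(!is.na(img))
  if (occupied < 2 && nrow(X) > 1) {
    abort("degenerate projection: all points fall into one pixel",
      class = "surfcomp_projection_error"
    )
  }
  mask <- !is.na(img)
  if (infill) {
    geom <- grid_geometry(grid)
    fill <- which(!mask & geom$inside)
    if (length(fill) > 0) {
      occ <- which(mask)
      d2 <- outer(geom$x[fill], geom$x[occ], "-")^2 +
        outer(geom$y[fill], geom$y[occ], "-")^2
      k <- min(3L, length(occ))
      img[fill] <- vapply(seq_along(fill), function(i) {
        mean(img[occ[order(d2[i, ])[seq_len(k)]]])
      }, numeric(1))
    }
  }
  out <- list(
    grid = matrix(img, grid, grid),
    mask = matrix(mask, grid, grid),
    kind = kind, apex = apex, scale = scale,
    n_points = nrow(X)
  )
  class(out) <- "projection"
  out
}

#' @export
print.projection <- function(x, ...) {
  cat(
    "<projection>", x$kind, paste0(nrow(x$grid), "x", ncol(x$grid)),
    "grid,", sum(x$mask), "occupied pixels\n"
  )
  invisible(x)
}

#' Export a projection grid as CSV
#'
#' @param projection A `projection`.
#' @param path Output CSV path (25 x 25 matrix; empty pixels empty cells).
#' @return `path`, invisibly.
#' @export
write_projection_csv <- function(projection, path) {
  utils::write.table(projection$grid, path,
    sep = ",", na = "",
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Zernike descriptor of a patch around one surface point
#'
#' Convenience pipeline: extract, orient, project, expand. Both the shape
#' and the electrostatic descriptor reuse one extraction and orientation.
#'
#' Patch images carry point-sampling noise, and the Gram-corrected moment
#' engine - exact for band-limited full-grid images - overfits that noise
#' (121 complex coefficients against ~450 noisy pixels). Descriptors for
#' patch comparison therefore default to the plain quadrature engine,
#' whose bounded operator norm damps pixel noise; pass
#' `moments_method = "gram"` to override.
#'
#' @param cloud A `surface_cloud`.
#' @param center_index Patch center point index.
#' @param kind `"shape"`, `"electrostatic"`, or `"both"`.
#' @param invert Orient the solvent side toward -z (use for the second
#'   patch of a comparison).
#' @param R,N,theta_max,grid Pipeline parameters (defaults 9 A, order 20,
#'   45 degrees, 25 px).
#' @param moments_method Moment engine (default `"quadrature"`).
#' @return For `"both"` a list with elements `shape` and `electrostatic`
#'   (descriptor vectors); otherwise a single descriptor vector.
#' @export
patch_descriptor <- function(cloud, center_index, kind = "both",
                             invert = FALSE, R = 9, N = 20,
                             theta_max = 45, grid = 25,
                             moments_method = "quadrature") {
  oriented <- orient_patch(extract_patch(cloud, center_index, R = R), invert = invert)
  one <- function(k) {
    zernike_descriptor(zernike_moments(
      build_projection(oriented, kind = k, theta_max = theta_max, grid = grid),
      N = N, method = moments_method
    ))
  }
  if (kind == "both") {
    list(shape = one("shape"), electrostatic = one("electrostatic"))
  } else {
    one(match.arg(kind, c("shape", "electrostatic")))
  }
}
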