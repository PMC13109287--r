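# 2D Zernike expansion on the unit disk.
#
# Disk images (shape or electrostatic projections of surface patches) are
# expanded as f(r,psi) = sum c_nm Z_nm(r,psi), Z_nm = R_nm(r) e^{i m psi},
# with coefficients c_nm = (n+1)/pi * int Z*_nm f over the disk. The vector
# of norms |c_nm| is rotation-invariant and is the patch descriptor.
#
# Two moment engines are provided. "gram" (default) evaluates the
# quadrature sums over pixels and then solves against the Gram matrix of
# the discretely sampled basis - a least-squares projection that restores
# orthogonality exactly on the pixel grid (a constant image yields only
# c00, band-limited images are recovered exactly, and reconstruction error
# is non-increasing in the expansion order). "quadrature" is the plain
# midpoint rule; at coarse grids it aliases high radial orders and is kept
# for comparison.

#' Valid Zernike index pairs up to order N
#'
#' All `(n, m)` with `0 <= m <= n <= N` and `n - m` even; 121 pairs at the
#' default working order N = 20.
#'
#' @param N Maximum radial order.
#' @return Tibble with columns `n`, `m`.
#' @export
zernike_indices <- function(N) {
  stopifnot(N >= 0)
  n <- unlist(lapply(0:N, function(nn) rep(nn, floor(nn / 2) + 1L)))
  m <- unlist(lapply(0:N, function(nn) seq(nn %% 2, nn, by = 2)))
  tibble::tibble(n = as.integer(n), m = as.integer(m))
}

#' Radial Zernike polynomial
#'
#' The standard radial part
#' `R_nm(r) = sum_k (-1)^k (n-k)! / (k! ((n+m)/2-k)! ((n-m)/2-k)!) r^(n-2k)`.
#' Satisfies `R_nm(1) = 1` for all valid index pairs.
#'
#' @param n,m Integer indices with `0 <= m <= n` and `n - m` even.
#' @param r Radii in `[0, 1]` (vectorised).
#' @return Numeric vector of polynomial values.
#' @export
zernike_radial <- function(n, m, r) {
  if (length(n) != 1 || length(m) != 1) abort("n and m must be scalars")
  if (m < 0 || m > n) abort("need 0 <= m <= n")
  if ((n - m) %% 2 != 0) abort("n - m must be even", class = "surfcomp_domain_error")
  out <- numeric(length(r))
  for (k in 0:((n - m) / 2)) {
    lc <- lgamma(n - k + 1) - lgamma(k + 1) -
      lgamma((n + m) / 2 - k + 1) - lgamma((n - m) / 2 - k + 1)
    out <- out + (-1)^k * exp(lc) * r^(n - 2 * k)
  }
  out
}

# --- cached grid basis --------------------------------------------------

# pixel-center geometry of a g x g grid covering [-1,1]^2
grid_geometry <- function(g) {
  key <- paste0("geom_", g)
  if (!is.null(the[[key]])) {
    return(the[[key]])
  }
  cen <- ((seq_len(g)) - 0.5) / g * 2 - 1
  px <- expand.grid(x = cen, y = cen) # x varies fastest (column-major grid)
  r <- sqrt(px$x^2 + px$y^2)
  geom <- list(
    g = g, x = px$x, y = px$y, r = r, psi = atan2(px$y, px$x),
    inside = r <= 1, dA = (2 / g)^2
  )
  the[[key]] <- geom
  geom
}

# real design matrix (columns R_n0, R_nm cos, R_nm sin), complex basis,
# Gram Cholesky; cached per (grid size, N)
grid_basis <- function(g, N) {
  key <- paste0("basis_", g, "_", N)
  if (!is.null(the[[key]])) {
    return(the[[key]])
  }
  geom <- grid_geometry(g)
  idx <- zernike_indices(N)
  K <- nrow(idx)
  rr <- pmin(geom$r, 1)
  npix <- length(rr)
  n_real <- sum(ifelse(idx$m == 0, 1L, 2L))
  D <- matrix(0, npix, n_real)
  B <- matrix(0 + 0i, npix, K)
  real_col <- integer(K) # first real column of each (n,m)
  col <- 1L
  for (j in seq_len(K)) {
    R <- zernike_radial(idx$n[j], idx$m[j], rr)
    B[, j] <- R * exp(1i * idx$m[j] * geom$psi)
    real_col[j] <- col
    if (idx$m[j] == 0) {
      D[, col] <- R
      col <- col + 1L
    } else {
      D[, col] <- R * cos(idx$m[j] * geom$psi)
      D[, col + 1L] <- R * sin(idx$m[j] * geom$psi)
      col <- col + 2L
    }
  }
  D[!geom$inside, ] <- 0
  B[!geom$inside, ] <- 0
  A <- crossprod(D) * geom$dA
  cholA <- chol(A)
  basis <- list(
    idx = idx, D = D, B = B, real_col = real_col,
    cholA = cholA, tcholA = t(cholA),
    i_m0 = which(idx$m == 0), i_mp = which(idx$m > 0),
    geom = geom
  )
  the[[key]] <- basis
  basis
}

# convert real-basis coefficients (cos/sin pairs) to complex c_nm
real_to_complex <- function(coef, basis) {
  cc <- complex(length.out = nrow(basis$idx))
  cc[basis$i_m0] <- complex(real = coef[basis$real_col[basis$i_m0]])
  p <- basis$real_col[basis$i_mp]
  cc[basis$i_mp] <- complex(real = coef[p] / 2, imaginary = -coef[p + 1L] / 2)
  cc
}

new_zernike_moments <- function(coef, idx, N, grid, method) {
  out <- list(coef = coef, n = idx$n, m = idx$m, N = N, grid = grid, method = method)
  class(out) <- "zernike_moments"
  out
}

#' 2D Zernike moments of a disk projection
#'
#' Expands a projected patch image in the Zernike basis up to order `N`.
#' Masked (empty) pixels and pixels outside the inscribed unit circle
#' contribute the fill value 0; occupied pixel values are mean-centered
#' first so that the arbitrary cone-apex offset of shape images (and any
#' constant potential offset) does not dominate the leading coefficient.
#'
#' @param projection A `projection` from [build_projection()], or a plain
#'   square numeric matrix in which `NA` marks empty pixels.
#' @param N Maximum expansion order (default 20, giving 121 descriptors).
#' @param method `"gram"` (Gram-corrected least-squares quadrature, default)
#'   or `"quadrature"` (plain midpoint rule).
#' @param center Mean-center occupied pixels before expansion (default TRUE).
#' @return A `zernike_moments` object holding the complex coefficients
#'   `coef` and indices `n`, `m`; see [zernike_descriptor()].
#' @export
zernike_moments <- function(projection, N = 20, method = c("gram", "quadrature"),
                            center = TRUE) {
  method <- match.arg(method)
  if (inherits(projection, "projection")) {
    grid <- projection$grid
    mask <- !is.na(grid) # infilled pixels count as support
  } else {
    grid <- as.matrix(projection)
    if (nrow(grid) != ncol(grid)) abort("projection grid must be square")
    mask <- !is.na(grid)
  }
  g <- nrow(grid)
  basis <- grid_basis(g, N)
  occ <- as.vector(mask) & basis$geom$inside
  if (!any(occ)) abort("empty projection: no occupied pixels on the disk")
  w <- numeric(length(occ))
  vals <- as.vector(grid)[occ]
  if (center) vals <- vals - mean(vals)
  w[occ] <- vals
  if (method == "quadrature") {
    pref <- (basis$idx$n + 1) / pi
    cc <- pref * as.vector(crossprod(Conj(basis$B), w)) * basis$geom$dA
  } else {
    q <- as.vector(crossprod(basis$D, w)) * basis$geom$dA
    coef <- backsolve(basis$cholA, forwardsolve(basis$tcholA, q))
    cc <- real_to_complex(coef, basis)
  }
  new_zernike_moments(cc, basis$idx, N, g, method)
}

#' Zernike moments of an analytic disk function
#'
#' Computes the expansion coefficients of a function `f(r, psi)` by midpoint
#' quadrature on a fine polar grid. Used to validate orthogonality,
#' rotational invariance and reconstruction against closed forms,
#' independently of the pixel pipeline.
#'
#' @param f Vectorised function of `(r, psi)`.
#' @param N Maximum order.
#' @param n_r,n_psi Number of radial / angular quadrature nodes.
#' @return A `zernike_moments` object.
#' @export
zernike_moments_fn <- function(f, N = 20, n_r = 501, n_psi = 501) {
  idx <- zernike_indices(N)
  rr <- (seq_len(n_r) - 0.5) / n_r
  pp <- (seq_len(n_psi) - 0.5) / n_psi * 2 * pi
  fv <- outer(rr, pp, f) # n_r x n_psi
  wr <- rr / n_r # r dr
  dpsi <- 2 * pi / n_psi
  ms <- sort(unique(idx$m))
  # angular transforms per distinct m, then radial integrals
  ang <- vapply(
    ms, function(m) as.vector(fv %*% exp(-1i * m * pp)) * dpsi,
    complex(n_r)
  )
  cc <- complex(length.out = nrow(idx))
  for (j in seq_len(nrow(idx))) {
    R <- zernike_radial(idx$n[j], idx$m[j], rr)
    cc[j] <- (idx$n[j] + 1) / pi * sum(wr * R * ang[, match(idx$m[j], ms)])
  }
  new_zernike_moments(cc, idx, N, NA_integer_, "polar")
}

#' Rotation-invariant Zernike descriptor
#'
#' The vector of coefficient norms `|c_nm|`, invariant under in-plane
#' rotation of the underlying image. Length 121 at N = 20.
#'
#' @param x A `zernike_moments` object.
#' @return Named numeric vector (`"n.m"` names).
#' @export
zernike_descriptor <- function(x) {
  stopifnot(inherits(x, "zernike_moments"))
  setNames(Mod(x$coef), paste0(x$n, ".", x$m))
}

#' @export
print.zernike_moments <- function(x, ...) {
  cat(
    "<zernike_moments> N =", x$N, "(", length(x$coef), "coefficients ),",
    "method =", x$method, "\n"
  )
  invisible(x)
}

#' Reconstruct a disk image from Zernike moments
#'
#' Evaluates the partial sum `f(r,psi) = Re[ sum_m eps_m c_nm Z_nm ]` with
#' `eps_m = 1` for m = 0 and 2 otherwise (the m >= 0 half of the expansion
#' of a real image). Used for convergence checks.
#'
#' @param moments A `zernike_moments` object.
#' @param grid Output grid size (default 25); pixels outside the unit disk
#'   are `NA`.
#' @param N Optionally truncate to a lower order.
#' @return A `grid` x `grid` numeric matrix.
#' @export
zernike_reconstruct <- function(moments, grid = 25, N = NULL) {
  stopifnot(inherits(moments, "zernike_moments"))
  keep <- rep(TRUE, length(moments$coef))
  if (!is.null(N)) {
    if (N < 0 || N > moments$N) abort("invalid truncation order")
    keep <- moments$n <= N
  }
  geom <- grid_geometry(grid)
  rr <- pmin(geom$r, 1)
  acc <- numeric(length(rr))
  for (j in which(keep)) {
    Z <- zernike_radial(moments$n[j], moments$m[j], rr) *
      exp(1i * moments$m[j] * geom$psi)
    eps <- if (moments$m[j] == 0) 1 else 2
    acc <- acc + Re(eps * moments$coef[j] * Z)
  }
  acc[!geom$inside] <- NA_real_
  matrix(acc, grid, grid)
}

#' Complementarity distance between two descriptors
#'
#' Euclidean distance between the Zernike descriptor vectors of two patches
#' processed with opposite z-orientations. Lower values indicate higher
#' complementarity.
#'
#' @param a,b `zernike_moments` objects or plain descriptor vectors of equal
#'   order.
#' @return Non-negative scalar.
#' @export
complementarity_distance <- function(a, b) {
  va <- if (inherits(a, "zernike_moments")) zernike_descriptor(a) else as.numeric(a)
  vb <- if (inherits(b, "zernike_moments")) zernike_descriptor(b) else as.numeric(b)
  if (length(va) != length(vb)) {
    abort("descriptors have different orders", class = "surfcomp_domain_error")
  }
  sqrt(sum((va - vb)^2))
}

#' Numerical orthogonality error of the Zernike basis
#'
#' Evaluates all pairwise inner products `int Z*_nm Z_n'm'` over the unit
#' disk on an `n_r` x `n_psi` polar midpoint grid and returns the maximum
#' absolute deviation from the analytic value `pi/(n+1) delta_nn' delta_mm'`.
#'
#' @param max_n Largest order included (default 8).
#' @param n_r,n_psi Quadrature nodes (default 501 each).
#' @return Scalar maximum absolute deviation.
#' @export
zernike_orthogonality_error <- function(max_n = 8, n_r = 501, n_psi = 501) {
  idx <- zernike_indices(max_n)
  K <- nrow(idx)
  rr <- (seq_len(n_r) - 0.5) / n_r
  pp <- (seq_len(n_psi) - 0.5) / n_psi * 2 * pi
  wr <- rr / n_r
  Zr <- vapply(seq_len(K), function(j) zernike_radial(idx$n[j], idx$m[j], rr), numeric(n_r))
  Ep <- vapply(seq_len(K), function(j) exp(1i * idx$m[j] * pp), complex(n_psi))
  dev <- 0
  for (a in seq_len(K)) {
    for (b in a:K) {
      rad <- sum(wr * Zr[, a] * Zr[, b])
      ang <- sum(Conj(Ep[, a]) * Ep[, b]) * (2 * pi / n_psi)
      expected <- if (a == b) pi / (idx$n[a] + 1) else 0
      dev <- max(dev, Mod(rad * ang - expected))
    }
  }
  dev
}

#' Export a descriptor to a long CSV
#'
#' @param moments A `zernike_moments` object.
#' @param path Output CSV path (columns `n`, `m`, `value`).
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(moments, path) {
  utils::write.csv(
    data.frame(n = moments$n, m = moments$m, value = Mod(moments$coef)),
    path,
    row.names = FALSE
  )
  invisible(path)
}
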