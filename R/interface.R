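# Interface geometry: binding-site detection, interface center, core
# residue pairs, decoy sampling, annular composition.
#
# All distances are point-to-point Euclidean in Angstrom and all membership
# rules use strict inequalities ("within 6 A" = "< 6 A"), consistent with
# the "< 3 A" / "< 5 A" core-pair wording.

# chunked cross-distance minima: for each row of A, min distance to any row
# of B (avoids an n_a x n_b allocation for large clouds). When a cutoff is
# given, points whose distance to B's bounding box already exceeds it are
# skipped (their reported distance is a lower bound >= cutoff).
min_cross_dist <- function(a, b, chunk = 512L, cutoff = Inf) {
  n <- nrow(a)
  out <- rep(Inf, n)
  lo <- apply(b, 2, min)
  hi <- apply(b, 2, max)
  gap <- sqrt(rowSums(pmax(sweep(a, 2, lo, "-") * -1, sweep(a, 2, hi, "-"), 0)^2))
  live <- which(gap < cutoff)
  skip <- which(gap >= cutoff)
  out[skip] <- pmax(gap[skip], cutoff)
  if (length(live) == 0) {
    return(out)
  }
  b2 <- rowSums(b^2)
  for (i0 in seq(1L, length(live), by = chunk)) {
    idx <- live[i0:min(i0 + chunk - 1L, length(live))]
    ab <- a[idx, , drop = FALSE]
    d2 <- outer(rowSums(ab^2), b2, "+") - 2 * tcrossprod(ab, b)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Detect the binding interface between two surface clouds
#'
#' The interface on a chain is the set of its surface points lying strictly
#' within `cutoff` of any point of the partner surface; its center is the
#' centroid of those points. The operation is symmetric: swapping the
#' arguments swaps the two regions.
#'
#' @param cloud_a,cloud_b `surface_cloud` objects for the two chains.
#' @param cutoff Interface distance cutoff in Angstrom (default 6).
#' @return An object of class `interface_pair`: a list with elements `a` and
#'   `b`, each a list holding `indices` (row indices of the member points),
#'   `center` (length-3 centroid, `NA` when empty) and `empty`. The midpoint
#'   of the two centers is stored as `$center`.
#' @export
detect_interface <- function(cloud_a, cloud_b, cutoff = 6) {
  stopifnot(nrow(cloud_a) > 0, nrow(cloud_b) > 0)
  xa <- cloud_xyz(cloud_a)
  xb <- cloud_xyz(cloud_b)
  da <- min_cross_dist(xa, xb, cutoff = cutoff)
  db <- min_cross_dist(xb, xa, cutoff = cutoff)
  region <- function(idx, xyz) {
    if (length(idx) == 0) {
      list(indices = integer(0), center = c(NA_real_, NA_real_, NA_real_), empty = TRUE)
    } else {
      list(indices = idx, center = colMeans(xyz[idx, , drop = FALSE]), empty = FALSE)
    }
  }
  a <- region(which(da < cutoff), xa)
  b <- region(which(db < cutoff), xb)
  if (a$empty || b$empty) {
    warn("empty interface: no surface points within the cutoff")
  }
  out <- list(
    a = a, b = b,
    center = if (a$empty || b$empty) {
      c(NA_real_, NA_real_, NA_real_)
    } else {
      (a$center + b$center) / 2
    },
    cutoff = cutoff
  )
  class(out) <- "interface_pair"
  out
}

#' @export
print.interface_pair <- function(x, ...) {
  cat(
    "<interface_pair> cutoff", x$cutoff, "A;",
    length(x$a$indices), "points on A,", length(x$b$indices), "points on B\n"
  )
  invisible(x)
}

# residues contributing at least one point to an interface region
interfacial_residues <- function(cloud, indices) {
  unique(cloud$resnum[indices])
}

#' Find core-interacting residue pairs
#'
#' A cross-chain residue pair is core-interacting when the centroids of the
#' surface points the two residues generate are closer than `pair_cutoff`
#' and both centroids lie closer than `center_cutoff` to the interface
#' center (the midpoint of the two per-chain region centroids).
#' Water-mediated contacts are not modelled.
#'
#' @param cloud_a,cloud_b The two chains.
#' @param interface An `interface_pair` from [detect_interface()].
#' @param pair_cutoff Centroid-centroid cutoff in Angstrom (default 3).
#' @param center_cutoff Centroid-to-interface-center cutoff (default 5).
#' @return Tibble of pairs with columns `chain_a`, `resnum_a`, `resname_a`,
#'   `chain_b`, `resnum_b`, `resname_b`, `label` (`"core"`), `pair_class`,
#'   and the centroid distance `dist`.
#' @export
find_core_pairs <- function(cloud_a, cloud_b, interface,
                            pair_cutoff = 3, center_cutoff = 5) {
  if (interface$a$empty || interface$b$empty) {
    abort("cannot search core pairs on an empty interface")
  }
  center <- interface$center
  # nonstandard residues (filler surface) do not form labeled pairs
  ca <- dplyr::filter(residue_centroids(cloud_a), !is.na(.data$class))
  cb <- dplyr::filter(residue_centroids(cloud_b), !is.na(.data$class))
  ca$d_center <- sqrt((ca$x - center[1])^2 + (ca$y - center[2])^2 + (ca$z - center[3])^2)
  cb$d_center <- sqrt((cb$x - center[1])^2 + (cb$y - center[2])^2 + (cb$z - center[3])^2)
  ca <- ca[ca$d_center < center_cutoff, ]
  cb <- cb[cb$d_center < center_cutoff, ]
  if (nrow(ca) == 0 || nrow(cb) == 0) {
    return(empty_pair_table())
  }
  d <- sqrt(outer(ca$x, cb$x, "-")^2 + outer(ca$y, cb$y, "-")^2 +
    outer(ca$z, cb$z, "-")^2)
  hit <- which(d < pair_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(empty_pair_table())
  }
  tibble::tibble(
    chain_a = ca$chain[hit[, 1]],
    resnum_a = ca$resnum[hit[, 1]],
    resname_a = ca$resname[hit[, 1]],
    chain_b = cb$chain[hit[, 2]],
    resnum_b = cb$resnum[hit[, 2]],
    resname_b = cb$resname[hit[, 2]],
    label = "core",
    pair_class = pair_class(ca$resname[hit[, 1]], cb$resname[hit[, 2]]),
    dist = d[hit]
  ) |>
    dplyr::arrange(.data$resnum_a, .data$resnum_b)
}

empty_pair_table <- function() {
  tibble::tibble(
    chain_a = character(0), resnum_a = integer(0), resname_a = character(0),
    chain_b = character(0), resnum_b = integer(0), resname_b = character(0),
    label = character(0), pair_class = character(0), dist = numeric(0)
  )
}

#' Sample non-interacting decoy residue pairs
#'
#' Decoy residues are those that generate no surface points inside the
#' interface region of their chain; they are paired uniformly at random
#' across the two chains (cross-chain only, mirroring the topology of
#' interacting pairs). Reproducible under `seed`.
#'
#' @param cloud_a,cloud_b The two chains.
#' @param interface An `interface_pair`.
#' @param n Number of decoy pairs requested.
#' @param seed Integer seed.
#' @return Tibble with the same columns as [find_core_pairs()], `label`
#'   `"decoy"`. If fewer eligible residues exist than requested the function
#'   warns and returns what it can.
#' @export
sample_decoy_pairs <- function(cloud_a, cloud_b, interface, n, seed = 1L) {
  if (n == 0) {
    return(empty_pair_table())
  }
  elig_a <- setdiff(
    unique(cloud_a$resnum[!cloud_a$nonstandard]),
    interfacial_residues(cloud_a, interface$a$indices)
  )
  elig_b <- setdiff(
    unique(cloud_b$resnum[!cloud_b$nonstandard]),
    interfacial_residues(cloud_b, interface$b$indices)
  )
  if (length(elig_a) == 0 || length(elig_b) == 0) {
    warn("no residues outside the interface; returning no decoys")
    return(empty_pair_table())
  }
  n_max <- min(length(elig_a), length(elig_b))
  if (n > n_max) {
    warn(paste0(
      "only ", n_max, " decoy pairs available (", n, " requested)"
    ))
    n <- n_max
  }
  ca <- residue_centroids(cloud_a)
  cb <- residue_centroids(cloud_b)
  with_seed(seed, {
    # sample without replacement on both sides so no residue repeats
    ra <- sample(elig_a, n)
    rb <- sample(elig_b, n)
    ia <- match(ra, ca$resnum)
    ib <- match(rb, cb$resnum)
    tibble::tibble(
      chain_a = ca$chain[ia], resnum_a = ca$resnum[ia], resname_a = ca$resname[ia],
      chain_b = cb$chain[ib], resnum_b = cb$resnum[ib], resname_b = cb$resname[ib],
      label = "decoy",
      pair_class = pair_class(ca$resname[ia], cb$resname[ib]),
      dist = sqrt((ca$x[ia] - cb$x[ib])^2 + (ca$y[ia] - cb$y[ib])^2 +
        (ca$z[ia] - cb$z[ib])^2)
    )
  })
}

#' Annular composition around an interface center
#'
#' Splits the region around `center` into concentric rings of width
#' `ring_width` and reports, per ring, the fraction of hydrophobic, polar
#' and charged residues among the residues whose surface-point centroids
#' fall in the ring. Fractions sum to 1 in every non-empty ring; empty rings
#' are reported with `NA` fractions.
#'
#' @param cloud A `surface_cloud`.
#' @param center Length-3 center (typically the interface center).
#' @param max_radius Outer radius in Angstrom (default 20).
#' @param ring_width Ring width in Angstrom (default 1).
#' @return Tibble with `ring`, `r_lo`, `r_hi`, `n`, `f_H`, `f_P`, `f_C`.
#' @export
annular_composition <- function(cloud, center, max_radius = 20, ring_width = 1) {
  stopifnot(length(center) == 3, all(is.finite(center)))
  cen <- residue_centroids(cloud)
  cen <- cen[!is.na(cen$class), ]
  d <- sqrt((cen$x - center[1])^2 + (cen$y - center[2])^2 + (cen$z - center[3])^2)
  edges <- seq(0, max_radius, by = ring_width)
  nring <- length(edges) - 1L
  out <- tibble::tibble(
    ring = seq_len(nring),
    r_lo = edges[-length(edges)],
    r_hi = edges[-1],
    n = 0L, f_H = NA_real_, f_P = NA_real_, f_C = NA_real_
  )
  bin <- findInterval(d, edges, rightmost.closed = FALSE)
  for (k in seq_len(nring)) {
    in_ring <- which(bin == k & d < max_radius)
    if (length(in_ring) == 0) next
    cls <- cen$class[in_ring]
    out$n[k] <- length(in_ring)
    out$f_H[k] <- mean(cls == "H")
    out$f_P[k] <- mean(cls == "P")
    out$f_C[k] <- mean(cls == "C")
  }
  class(out) <- c("annular_composition", class(out))
  out
}
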