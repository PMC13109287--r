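# Per-pair feature assembly: neighbor selection, residue-level shape and
# electrostatic complementarity (mean patch-descriptor distance), the
# hydropathy row, and min-max normalization against training-split stats.
#
# Feature columns follow the "kind_neighbor" convention: s_0..s_9 (shape),
# e_0..e_9 (electrostatic), h_0..h_9 (hydropathy); neighbor 0 is the
# putative partner itself, neighbors 1..9 its nearest residues.

FEATURE_KINDS <- c(s = "shape", e = "electrostatic", h = "hydropathy")

feature_columns <- function(kinds = c("s", "e", "h"), k = 10) {
  unlist(lapply(kinds, function(p) paste0(p, "_", 0:(k - 1))))
}

#' A cache for patch descriptors
#'
#' Surface points are shared between residue pairs and neighbor columns;
#' caching descriptors per (side, point, orientation) makes dataset-scale
#' feature extraction tractable.
#'
#' @return An environment used by [residue_complementarity()] and
#'   [build_pair_features()].
#' @export
descriptor_cache <- function() {
  new.env(parent = emptyenv())
}

cached_descriptor <- function(cloud, index, invert, side, cache,
                              R = 9, N = 20, theta_max = 45, grid = 25) {
  key <- paste0(side, "_", index, "_", as.integer(invert))
  hit <- cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  d <- tryCatch(
    patch_descriptor(cloud, index,
      kind = "both", invert = invert,
      R = R, N = N, theta_max = theta_max, grid = grid
    ),
    surfcomp_sparse_patch_error = function(e) NULL,
    surfcomp_projection_error = function(e) NULL,
    surfcomp_orientation_error = function(e) NULL
  )
  cache[[key]] <- if (is.null(d)) list(failed = TRUE) else d
  cache[[key]]
}

# sampled surface-point indices for a residue (seeded, reproducible)
residue_point_sample <- function(cloud, resnum, k, seed) {
  idx <- which(cloud$resnum == resnum)
  if (length(idx) == 0) {
    return(integer(0))
  }
  if (length(idx) <= k) {
    return(idx)
  }
  with_seed(derive_seed(seed, "pts", resnum), sort(sample(idx, k)))
}

#' Shape or electrostatic complementarity between two residues
#'
#' Mean [complementarity_distance()] over patch pairs centered on the
#' surface points the two residues generate, with the first residue's
#' patches oriented solvent-up and the second residue's solvent-down
#' (opposite verses). For speed the patch-pair combinations are capped at
#' `max_pairs` by seeded subsampling of `points_per_residue` points per
#' residue; `exact = TRUE` uses every combination.
#'
#' @param cloud_a,cloud_b The two chains.
#' @param resnum_a,resnum_b Residue numbers on each chain.
#' @param kind `"shape"` or `"electrostatic"` (or `"both"` for a 2-vector).
#' @param max_pairs Cap on patch-pair combinations (default 16).
#' @param points_per_residue Surface points sampled per residue (default 4).
#' @param exact Use all surface points and all combinations.
#' @param seed Subsampling seed.
#' @param cache Optional [descriptor_cache()].
#' @param R,N Patch radius and expansion order.
#' @return Scalar mean descriptor distance (named 2-vector for `"both"`).
#' @export
residue_complementarity <- function(cloud_a, resnum_a, cloud_b, resnum_b,
                                    kind = "both", max_pairs = 16,
                                    points_per_residue = 4, exact = FALSE,
                                    seed = 1L, cache = NULL, R = 9, N = 20) {
  if (is.null(cache)) cache <- descriptor_cache()
  k_pts <- if (exact) Inf else points_per_residue
  ia <- residue_point_sample(cloud_a, resnum_a, k_pts, seed)
  ib <- residue_point_sample(cloud_b, resnum_b, k_pts, seed)
  if (length(ia) == 0 || length(ib) == 0) {
    abort("residue generates no surface points")
  }
  da <- lapply(ia, function(i) cached_descriptor(cloud_a, i, FALSE, "a", cache, R = R, N = N))
  db <- lapply(ib, function(i) cached_descriptor(cloud_b, i, TRUE, "b", cache, R = R, N = N))
  ok_a <- !vapply(da, function(d) isTRUE(d$failed), logical(1))
  ok_b <- !vapply(db, function(d) isTRUE(d$failed), logical(1))
  da <- da[ok_a]
  db <- db[ok_b]
  if (length(da) == 0 || length(db) == 0) {
    abort("no usable patches for residue pair", class = "surfcomp_sparse_patch_error")
  }
  combos <- expand.grid(i = seq_along(da), j = seq_along(db))
  if (!exact && nrow(combos) > max_pairs) {
    combos <- with_seed(
      derive_seed(seed, "combo", resnum_a, resnum_b),
      combos[sample(nrow(combos), max_pairs), ]
    )
  }
  one_kind <- function(k) {
    mean(vapply(seq_len(nrow(combos)), function(r) {
      complementarity_distance(
        da[[combos$i[r]]][[k]],
        db[[combos$j[r]]][[k]]
      )
    }, numeric(1)))
  }
  if (kind == "both") {
    c(
      shape = one_kind("shape"),
      electrostatic = one_kind("electrostatic")
    )
  } else {
    kind <- match.arg(kind, c("shape", "electrostatic"))
    one_kind(kind)
  }
}

#' Neighbor residues of a residue
#'
#' Residues of the same chain whose surface-point centroids lie within
#' `radius` of the reference residue's centroid, sorted by ascending
#' centroid distance (ties broken by chain then residue number), truncated
#' to `k`. The reference residue itself is neighbor 0.
#'
#' @param cloud The chain cloud.
#' @param resnum Reference residue number.
#' @param k Number of neighbors after the reference (default 9).
#' @param radius Neighborhood radius in Angstrom (default 10).
#' @param centroids Optional precomputed [residue_centroids()] of `cloud`
#'   (avoids recomputation in dataset-scale loops).
#' @return Tibble with `neighbor` (0..k), `resnum`, `resname`, `dist`;
#'   fewer than `k + 1` rows when the neighborhood is sparse (padding is
#'   applied downstream).
#' @export
select_neighbors <- function(cloud, resnum, k = 9, radius = 10,
                             centroids = NULL) {
  cen <- centroids %||% residue_centroids(cloud)
  self <- cen[cen$resnum == resnum, ]
  if (nrow(self) == 0) abort(paste0("residue ", resnum, " not in cloud"))
  d <- sqrt((cen$x - self$x)^2 + (cen$y - self$y)^2 + (cen$z - self$z)^2)
  # nonstandard (filler) residues are surface only, never neighbors
  keep <- which(d < radius & cen$resnum != resnum & !is.na(cen$class))
  ord <- keep[order(d[keep], cen$chain[keep], cen$resnum[keep])]
  ord <- utils::head(ord, k)
  tibble::tibble(
    neighbor = seq_len(length(ord) + 1L) - 1L,
    resnum = c(resnum, cen$resnum[ord]),
    resname = c(self$resname, cen$resname[ord]),
    dist = c(0, d[ord])
  )
}

#' Complementarity feature matrix for one residue pair
#'
#' Column `j` holds the shape, electrostatic and hydropathy complementarity
#' between residue A and the j-th entry of residue B's neighbor list
#' (neighbor 0 = B itself). Missing neighbors give `NA` columns, replaced by
#' the worst-complementarity fill of 1.0 after normalization. With
#' `distance_row = TRUE` a fourth row carries the centroid distance from B
#' to each neighbor (not part of the 30-feature analysis space).
#'
#' @param cloud_a,cloud_b The two chains.
#' @param resnum_a,resnum_b The residue pair.
#' @param scale Hydrophobicity scale.
#' @param distance_row Add the optional 4th row (default FALSE).
#' @param cache Optional [descriptor_cache()].
#' @param centroids_b Optional precomputed centroids of `cloud_b`.
#' @param ... Passed to [residue_complementarity()].
#' @return Matrix with rows `s`, `e`, `h` (and optionally `d`) and 10
#'   columns, with the pair metadata as attributes.
#' @export
build_feature_matrix <- function(cloud_a, resnum_a, cloud_b, resnum_b, scale,
                                 distance_row = FALSE, cache = NULL,
                                 centroids_b = NULL, ...) {
  if (is.null(cache)) cache <- descriptor_cache()
  nb <- select_neighbors(cloud_b, resnum_b, centroids = centroids_b)
  kinds <- c("s", "e", "h", if (distance_row) "d")
  mat <- matrix(NA_real_, length(kinds), 10,
    dimnames = list(kinds, paste0("nb", 0:9))
  )
  resname_a <- cloud_a$resname[match(resnum_a, cloud_a$resnum)]
  for (j in seq_len(nrow(nb))) {
    z <- residue_complementarity(
      cloud_a, resnum_a, cloud_b, nb$resnum[j],
      kind = "both", cache = cache, ...
    )
    mat["s", j] <- z[["shape"]]
    mat["e", j] <- z[["electrostatic"]]
    mat["h", j] <- residue_hydropathy(resname_a, nb$resname[j], scale)
    if (distance_row) mat["d", j] <- nb$dist[j]
  }
  attr(mat, "pair") <- list(resnum_a = resnum_a, resnum_b = resnum_b)
  mat
}

#' Assemble the pair-feature table for a labeled pair list
#'
#' Dataset-level driver: for every row of `pairs` computes the 3 x 10
#' complementarity matrix between residue A and residue B's neighborhood
#' and returns it flattened to wide columns `s_0..s_9, e_0..e_9, h_0..h_9`
#' alongside the pair metadata. Column 0 of the shape/electrostatic rows
#' equals the direct pair complementarity used in distribution
#' stratification, so the two analysis paths agree by construction.
#'
#' @param pairs Pair table ([find_core_pairs()] / [sample_decoy_pairs()]
#'   rows, or [read_pair_table()] output).
#' @param cloud_a,cloud_b The two chains.
#' @param scale Hydrophobicity scale.
#' @param distance_row Add `d_0..d_9` columns (default FALSE).
#' @param seed Subsampling seed.
#' @param ... Passed to [residue_complementarity()].
#' @return Tibble: metadata columns then feature columns; unnormalized.
#' @export
build_pair_features <- function(pairs, cloud_a, cloud_b, scale,
                                distance_row = FALSE, seed = 1L, ...) {
  cache <- descriptor_cache()
  cen_b <- residue_centroids(cloud_b)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    mat <- build_feature_matrix(
      cloud_a, pairs$resnum_a[i], cloud_b, pairs$resnum_b[i], scale,
      distance_row = distance_row, cache = cache, centroids_b = cen_b,
      seed = seed, ...
    )
    vals <- as.list(as.vector(t(mat)))
    names(vals) <- feature_columns(rownames(mat))
    tibble::as_tibble(vals)
  })
  dplyr::bind_cols(
    tibble::as_tibble(pairs)[c(
      "chain_a", "resnum_a", "resname_a",
      "chain_b", "resnum_b", "resname_b", "label", "pair_class"
    )],
    dplyr::bind_rows(rows)
  )
}

#' Direct (neighbor-0) complementarities for a pair list
#'
#' The shape, electrostatic and hydropathy complementarity between each
#' listed pair itself, as used for distribution stratification by chemical
#' class. Cheaper than [build_pair_features()] when the neighborhood
#' columns are not needed.
#'
#' @inheritParams build_pair_features
#' @return `pairs` with columns `shape`, `electrostatic`, `hydropathy`
#'   appended.
#' @export
pair_complementarities <- function(pairs, cloud_a, cloud_b, scale,
                                   seed = 1L, ...) {
  cache <- descriptor_cache()
  z <- vapply(seq_len(nrow(pairs)), function(i) {
    residue_complementarity(
      cloud_a, pairs$resnum_a[i], cloud_b, pairs$resnum_b[i],
      kind = "both", cache = cache, seed = seed, ...
    )
  }, numeric(2))
  out <- tibble::as_tibble(pairs)
  out$shape <- z[1, ]
  out$electrostatic <- z[2, ]
  out$hydropathy <- residue_hydropathy(pairs$resname_a, pairs$resname_b, scale)
  out
}

#' Min-max normalization of feature tables
#'
#' Scales every feature column into `[0, 1]` using per-kind (shape,
#' electrostatic, hydropathy) minima and maxima estimated on the training
#' split only; pass the returned `stats` to normalize validation or test
#' data with the same transform. Out-of-range values are clipped and
#' counted; `NA` entries (padded neighbor columns) become the
#' worst-complementarity fill 1.0. A kind with zero range maps to 0 with a
#' warning. Re-normalizing an already-normalized table with the same stats
#' is a no-op.
#'
#' @param features Feature tibble from [build_pair_features()].
#' @param stats Optional stats tibble from a previous call (training split).
#' @return The normalized tibble with attributes `norm_stats` (tibble
#'   `kind`, `min`, `max`) and `n_clipped`.
#' @export
normalize_features <- function(features, stats = NULL) {
  fcols <- grep("^[sehd]_[0-9]$", names(features), value = TRUE)
  if (length(fcols) == 0) abort("no feature columns found")
  prior <- attr(features, "norm_stats")
  if (!is.null(prior) && !is.null(stats) && isTRUE(all.equal(prior, stats))) {
    return(features)
  }
  kinds <- unique(substr(fcols, 1, 1))
  if (is.null(stats)) {
    stats <- dplyr::bind_rows(lapply(kinds, function(k) {
      vals <- unlist(features[grep(paste0("^", k, "_"), fcols, value = TRUE)])
      tibble::tibble(
        kind = k,
        min = min(vals, na.rm = TRUE),
        max = max(vals, na.rm = TRUE)
      )
    }))
  }
  n_clipped <- 0L
  out <- features
  for (k in kinds) {
    st <- stats[stats$kind == k, ]
    if (nrow(st) == 0) abort(paste0("no normalization stats for kind '", k, "'"))
    rng <- st$max - st$min
    for (col in grep(paste0("^", k, "_"), fcols, value = TRUE)) {
      v <- out[[col]]
      if (rng <= 0) {
        if (any(!is.na(v))) warn(paste0("zero range for kind '", k, "'; mapped to 0"))
        v <- ifelse(is.na(v), NA_real_, 0)
      } else {
        v <- (v - st$min) / rng
        n_clipped <- n_clipped + sum(v < 0 | v > 1, na.rm = TRUE)
        v <- pmin(pmax(v, 0), 1)
      }
      v[is.na(v)] <- 1.0 # absent neighbors look maximally non-complementary
      out[[col]] <- v
    }
  }
  attr(out, "norm_stats") <- stats
  attr(out, "n_clipped") <- n_clipped
  out
}
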